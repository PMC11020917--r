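#' Simulate a module-structured gene network
#'
#' Builds a synthetic network emulating the modular organisation of
#' protein-protein interaction networks: genes are partitioned into modules
#' whose sizes are drawn uniformly in `[min_module_size, max_module_size]`;
#' each module is wired by preferential attachment (new nodes attach to an
#' existing module member with probability proportional to degree), which
#' yields heavy-tailed within-module degrees; modules are then joined by
#' connecting each module's hub to the hub of an earlier module chosen with
#' probability proportional to its size, so a few hubs accumulate
#' inter-module links and the global degree distribution stays heavy-tailed.
#' The resulting graph is connected by construction.
#'
#' The default module-size range is chosen so that the first quartile of
#' module sizes (which sets the default disease-module size, see
#' [assign_disease()]) falls in the 12-20 gene range typical of curated
#' disease modules.
#'
#' @param p Number of genes (default 1000).
#' @param min_module_size,max_module_size Bounds of the uniform module-size
#'   distribution; modules have at least 3 genes.
#' @param pa_power Exponent of the preferential-attachment kernel inside
#'   modules (1 is linear; slightly superlinear concentrates hubs more).
#' @param seed Optional integer seed.
#' @return A [gene_network()] with genes `g1..gp` and a complete
#'   `modules` assignment (`M1`, `M2`, ...).
#' @export
simulate_network <- function(p = 1000, min_module_size = 8,
                             max_module_size = 50, pa_power = 1.1,
                             seed = NULL) {
  stopifnot(p >= 2, min_module_size >= 3, max_module_size >= min_module_size)
  if (min_module_size > p) abort("module sizes exceed the number of genes.")
  run <- function() {
    sz_range <- min_module_size:max_module_size
    sizes <- integer(0)
    while (sum(sizes) < p) {
      sizes <- c(sizes, sz_range[sample.int(length(sz_range), 1)])
    }
    excess <- sum(sizes) - p
    k <- length(sizes)
    sizes[k] <- sizes[k] - excess
    if (sizes[k] < 3) {  # fold a too-small remainder into the previous module
      if (k == 1) {
        sizes[1] <- p
      } else {
        sizes[k - 1] <- sizes[k - 1] + sizes[k]
        sizes <- sizes[-k]
      }
    }
    genes <- paste0("g", seq_len(p))
    module_of <- rep(paste0("M", seq_along(sizes)), times = sizes)
    edges_from <- character(0); edges_to <- character(0)
    hubs <- character(length(sizes))
    offset <- 0L
    for (m in seq_along(sizes)) {
      s <- sizes[m]
      g <- igraph::sample_pa(s, power = pa_power, m = 1, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      mod_genes <- genes[offset + seq_len(s)]
      edges_from <- c(edges_from, mod_genes[el[, 1]])
      edges_to <- c(edges_to, mod_genes[el[, 2]])
      deg <- igraph::degree(g)
      hubs[m] <- mod_genes[which.max(deg)]
      offset <- offset + s
    }
    if (length(sizes) > 1) {
      for (m in 2:length(sizes)) {
        tgt <- sample.int(m - 1, 1, prob = sizes[seq_len(m - 1)])
        edges_from <- c(edges_from, hubs[tgt])
        edges_to <- c(edges_to, hubs[m])
      }
    }
    gene_network(tibble(from = edges_from, to = edges_to), genes = genes,
                 modules = tibble(gene_id = genes, module = module_of))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate RNA-seq-like counts from a Gaussian graphical model
#'
#' Draws samples from a multivariate normal whose precision matrix has
#' nonzero off-diagonal entries exactly on the network's edges (a Gaussian
#' graphical model faithful to the network), then maps each gene through its
#' normal CDF and the inverse CDF of a gene-specific negative-binomial
#' marginal (a Gaussian copula). Edge precision entries are drawn uniformly
#' in `+/- partial_range` and the matrix is symmetrically rescaled until it
#' is strictly diagonally dominant (hence positive definite). Gene-wise NB
#' means are log-uniform in `mean_range` and dispersions uniform in
#' `dispersion_range` (variance `mu + phi * mu^2`), spanning typical bulk
#' RNA-seq marginals.
#'
#' @param network A [gene_network()].
#' @param n Number of samples.
#' @param partial_range Magnitude range of edge precision entries.
#' @param mean_range Range of NB means (log-uniform).
#' @param dispersion_range Range of NB dispersions.
#' @param seed Optional integer seed.
#' @return A tibble with a `sample_id` column and one integer count column
#'   per gene, in the network's gene order.
#' @export
simulate_expression <- function(network, n, partial_range = c(0.1, 0.3),
                                mean_range = c(20, 2000),
                                dispersion_range = c(0.1, 0.6),
                                seed = NULL) {
  stopifnot(n >= 1)
  p <- n_genes(network)
  run <- function() {
    omega <- as.matrix(network_adjacency(network))
    ne <- sum(omega) / 2
    if (ne > 0) {
      vals <- runif(ne, partial_range[1], partial_range[2]) *
        sample(c(-1, 1), ne, replace = TRUE)
      ut <- upper.tri(omega) & omega > 0
      omega[ut] <- vals
      omega[lower.tri(omega)] <- t(omega)[lower.tri(omega)]
      # symmetric rescale until strictly diagonally dominant
      for (it in 1:100) {
        s <- rowSums(abs(omega)) - 1
        if (all(s < 1)) break
        d <- 1 / sqrt(pmax(1, s / 0.95))
        omega <- omega * outer(d, d)
      }
      if (any(rowSums(abs(omega)) - 1 >= 1)) {
        abort("precision matrix could not be made diagonally dominant.")
      }
    }
    diag(omega) <- 1
    R <- chol(omega)
    Z <- matrix(rnorm(n * p), n, p)
    X <- t(backsolve(R, t(Z)))             # rows ~ N(0, solve(omega))
    Rinv <- backsolve(R, diag(p))
    sds <- sqrt(rowSums(Rinv^2))           # marginal SDs of the GGM
    U <- pnorm(sweep(X, 2, sds, "/"))
    mu <- exp(runif(p, log(mean_range[1]), log(mean_range[2])))
    phi <- runif(p, dispersion_range[1], dispersion_range[2])
    counts <- vapply(seq_len(p), function(j) {
      qnbinom(U[, j], mu = mu[j], size = 1 / phi[j])
    }, numeric(n))
    out <- as_tibble(as.data.frame(counts))
    names(out) <- network$gene_ids
    out <- mutate(out, across(dplyr::everything(), as.integer))
    dplyr::bind_cols(tibble(sample_id = paste0("s", seq_len(n))), out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assign disease genes and effect sizes for a simulation scenario
#'
#' The six scenarios differ in where the disease genes sit in the network
#' and how the average effect size `beta` is spread over them:
#' * `Null` - no disease genes.
#' * `RanEqu` - disease genes drawn uniformly over the whole network, each
#'   with effect `beta`.
#' * `ModEqu` - one network module (size closest to the target count) is the
#'   disease module; every member has effect `beta`.
#' * `ModTopo` - same disease module, but a *main disease gene* is drawn
#'   uniformly within it, the random walk with restart (restart mass on the
#'   main gene, `r = 0.3`) is run on the module's induced subgraph, and gene
#'   `i` receives effect `pi_star_i * beta * |M|` — effects decay with
#'   topological distance from the main gene and always sum to
#'   `beta * |M|`.
#' * `TwoModEqu`, `TwoModTopo` - as above on two disjoint modules.
#'
#' The default number of disease genes is the first quartile of the module
#' sizes, clamped to `[12, 20]`.
#'
#' @param network A [gene_network()] with module assignments (except for
#'   `Null`/`RanEqu`, which do not need modules).
#' @param scenario One of `"Null"`, `"RanEqu"`, `"ModEqu"`, `"ModTopo"`,
#'   `"TwoModEqu"`, `"TwoModTopo"` (case-insensitive).
#' @param beta Average effect size of a disease gene.
#' @param n_disease_genes Target number of disease genes (module scenarios
#'   pick the module(s) whose size is closest to this).
#' @param restart_probability Restart probability of the within-module
#'   random walk used by the `*Topo` scenarios.
#' @param seed Optional integer seed.
#' @return An object of class `disease_config`: list with `scenario`,
#'   `beta`, `intercept` (0), and `genes`, a tibble (`gene_id`, `beta`,
#'   `module`, `main`) with one row per disease gene.
#' @export
assign_disease <- function(network, scenario, beta = 1,
                           n_disease_genes = NULL,
                           restart_probability = 0.3, seed = NULL) {
  scen <- canon_scenario(scenario)
  run <- function() {
    if (scen == "Null") {
      return(new_disease_config(scen, beta, genes = tibble(
        gene_id = character(0), beta = numeric(0), module = character(0),
        main = logical(0))))
    }
    target <- n_disease_genes %||% default_disease_size(network)
    if (scen == "RanEqu") {
      if (target > n_genes(network)) abort("more disease genes than genes.")
      d <- sample(network$gene_ids, target)
      return(new_disease_config(scen, beta, genes = tibble(
        gene_id = d, beta = beta, module = NA_character_, main = FALSE)))
    }
    if (is.null(network$modules)) {
      abort("module-based scenarios need a network with module assignments.")
    }
    sizes <- table(network$modules$module)
    n_mod <- if (scen %in% c("TwoModEqu", "TwoModTopo")) 2L else 1L
    if (!is.null(n_disease_genes)) {
      # an explicitly requested disease-module size must be attainable
      sizes <- sizes[sizes >= n_disease_genes]
    }
    if (length(sizes) < n_mod) {
      abort(sprintf(
        "scenario %s needs at least %d module(s) of %d or more genes.",
        scen, n_mod, if (is.null(n_disease_genes)) 3L else n_disease_genes))
    }
    gap <- abs(as.integer(sizes) - target)
    chosen <- names(sizes)[order(gap, sample.int(length(sizes)))][seq_len(n_mod)]
    topo <- scen %in% c("ModTopo", "TwoModTopo")
    parts <- lapply(chosen, function(m) {
      members <- network$modules$gene_id[network$modules$module == m]
      if (!topo) {
        return(tibble(gene_id = members, beta = beta, module = m,
                      main = FALSE))
      }
      main <- sample(members, 1)
      sub <- induced_subnetwork(network, members)
      pi0 <- new_sampling_prior(members, as.numeric(members == main))
      eq <- drw_equilibrium(sub, pi0, r = restart_probability)
      pr <- align_prior(eq, members)
      tibble(gene_id = members, beta = pr * beta * length(members),
             module = m, main = members == main)
    })
    new_disease_config(scen, beta, genes = bind_rows(parts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

canon_scenario <- function(scenario) {
  scen_names <- c("Null", "RanEqu", "ModEqu", "ModTopo", "TwoModEqu",
                  "TwoModTopo")
  hit <- match(tolower(scenario), tolower(scen_names))
  if (is.na(hit)) {
    abort(sprintf("unknown scenario '%s'; valid: %s", scenario,
                  paste(scen_names, collapse = ", ")))
  }
  scen_names[hit]
}

default_disease_size <- function(network) {
  if (is.null(network$modules)) return(15L)
  q1 <- quantile(as.integer(table(network$modules$module)), 0.25,
                 names = FALSE)
  as.integer(min(20, max(12, round(q1))))
}

new_disease_config <- function(scenario, beta, genes) {
  structure(list(scenario = scenario, beta = beta, intercept = 0,
                 genes = genes),
            class = "disease_config")
}

#' @export
print.disease_config <- function(x, ...) {
  cat(sprintf("<disease_config> %s: %d disease gene(s), average effect %.3g\n",
              x$scenario, nrow(x$genes), x$beta))
  invisible(x)
}

#' Simulate a binary phenotype from the disease model
#'
#' Labels are Bernoulli with log-odds `beta_0 + sum_{i in D} beta_i X_i`,
#' where `X_i` is the *standardized* expression of disease gene `i` (mean 0,
#' SD 1 across the provided samples) and `beta_0 = 0`, so cases and controls
#' are balanced on average. Under `Null` (empty `D`) the log-odds is 0 and
#' labels are fair coin flips.
#'
#' @param expression Samples-by-genes tibble (from [simulate_expression()]).
#' @param config A [assign_disease()] configuration.
#' @param seed Optional integer seed.
#' @return A tibble (`sample_id`, `phenotype`) with integer 0/1 labels.
#' @export
simulate_phenotype <- function(expression, config, seed = NULL) {
  stopifnot(inherits(config, "disease_config"))
  xy <- split_xy(expression, phenotype = NULL, require_y = FALSE)
  d <- config$genes
  if (!all(d$gene_id %in% xy$genes)) {
    abort("disease config references genes absent from the expression data.")
  }
  n <- nrow(xy$X)
  lo <- rep(config$intercept, n)
  if (nrow(d) > 0) {
    Xd <- scale(xy$X[, d$gene_id, drop = FALSE])
    Xd[is.nan(Xd)] <- 0  # constant gene: standardization undefined, no signal
    lo <- lo + as.numeric(Xd %*% d$beta)
  }
  run <- function() rbinom(n, 1, plogis(lo))
  y <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble(sample_id = xy$sample_id %||% paste0("s", seq_len(n)),
         phenotype = as.integer(y))
}

#' Simulate one full replication (train + test)
#'
#' Generates a network (unless a shared one is supplied), a disease
#' configuration, expression counts for `n` samples and phenotypes, and
#' splits the samples into equal train and test halves at random. Passing
#' the same `network` (and `disease`) across calls with different seeds
#' reproduces the design in which one network is held fixed while expression
#' noise is redrawn per replication.
#'
#' @param scenario Scenario name (see [assign_disease()]).
#' @param p Number of genes (ignored if `network` is given).
#' @param n Total number of samples; must be even (split `n/2` / `n/2`).
#' @param beta Average disease-gene effect size.
#' @param network Optional shared [gene_network()].
#' @param disease Optional shared [assign_disease()] configuration.
#' @param n_disease_genes Passed to [assign_disease()].
#' @param seed Optional integer seed covering every random step.
#' @return An object of class `replication_data`: list with `network`,
#'   `disease`, `train` and `test` (each a list with `expression` and
#'   `phenotype` tibbles), and `seed`.
#' @export
simulate_replication <- function(scenario, p = 1000, n = 2000, beta = 1,
                                 network = NULL, disease = NULL,
                                 n_disease_genes = NULL, seed = NULL) {
  if (n %% 2 != 0) abort("n must be even for an equal train/test split.")
  run <- function() {
    net <- network %||% simulate_network(p)
    dis <- disease %||% assign_disease(net, scenario, beta = beta,
                                       n_disease_genes = n_disease_genes)
    expr <- simulate_expression(net, n)
    phen <- simulate_phenotype(expr, dis)
    idx <- sample.int(n, n / 2)
    structure(list(
      network = net, disease = dis,
      train = list(expression = expr[idx, ], phenotype = phen[idx, ]),
      test = list(expression = expr[-idx, ], phenotype = phen[-idx, ]),
      seed = seed
    ), class = "replication_data")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.replication_data <- function(x, ...) {
  cat(sprintf(
    "<replication_data> %s: %d genes, %d train + %d test samples\n",
    x$disease$scenario, n_genes(x$network),
    nrow(x$train$expression), nrow(x$test$expression)))
  invisible(x)
}
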
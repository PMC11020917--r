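#' Sampling priors over genes
#'
#' A sampling prior is a probability distribution over the genes of a
#' dataset: it is both the restart distribution fed into the random walk
#' with restart and the distribution from which candidate splitting
#' variables are drawn at each tree node. Represented as a tibble with
#' columns `gene_id` and `probability` (non-negative, summing to one within
#' `1e-9`).
#'
#' @param gene_id Character vector of gene identifiers.
#' @param probability Non-negative numeric weights; normalized to sum to one.
#' @return A tibble of class `sampling_prior`.
#' @name sampling_prior
NULL

new_sampling_prior <- function(gene_id, probability) {
  probability <- as.numeric(probability)
  if (length(gene_id) != length(probability)) {
    abort("gene_id and probability must have equal length.")
  }
  if (any(!is.finite(probability)) || any(probability < 0)) {
    abort("prior probabilities must be finite and non-negative.")
  }
  s <- sum(probability)
  if (s <= 0) abort("prior probabilities must have positive total mass.")
  out <- tibble(gene_id = as.character(gene_id), probability = probability / s)
  class(out) <- c("sampling_prior", class(out))
  out
}

#' @rdname sampling_prior
#' @export
sampling_prior <- function(gene_id, probability) {
  pr <- new_sampling_prior(gene_id, probability)
  validate_prior(pr)
  pr
}

validate_prior <- function(prior) {
  stopifnot(is.data.frame(prior),
            all(c("gene_id", "probability") %in% names(prior)))
  if (any(prior$probability < 0)) abort("prior has negative entries.")
  if (abs(sum(prior$probability) - 1) > 1e-9) {
    abort("prior probabilities must sum to 1 (tolerance 1e-9).")
  }
  invisible(prior)
}

#' @rdname sampling_prior
#' @param genes Character vector of gene ids (or a [gene_network()]).
#' @export
uniform_prior <- function(genes) {
  if (inherits(genes, "gene_network")) genes <- genes$gene_ids
  new_sampling_prior(genes, rep(1 / length(genes), length(genes)))
}

# reorder a prior's probabilities to a reference gene order; errors on any
# mismatch between the two gene universes
align_prior <- function(prior, gene_ids) {
  validate_prior(prior)
  idx <- match(gene_ids, prior$gene_id)
  if (anyNA(idx) || nrow(prior) != length(gene_ids)) {
    abort("prior gene set does not match the expected gene universe.")
  }
  prior$probability[idx]
}

#' Marginal two-sample Welch t-test p-values per gene
#'
#' For every gene, tests for a mean expression difference between the two
#' phenotype classes using Welch's unequal-variance two-sample t-test.
#' Genes that are constant across all samples carry no information and are
#' assigned `p = 1`; p-values are floored at `1e-300` so that downstream
#' `-log(p)` weights stay finite.
#'
#' @param data Samples-by-genes data frame (optionally with a `sample_id`
#'   column). Gene columns must be numeric.
#' @param phenotype Binary (0/1) vector, or the name of a column of `data`.
#' @return A tibble (`gene_id`, `p_value`) of class `pvalue_vector`.
#' @export
marginal_pvalues <- function(data, phenotype) {
  xy <- split_xy(data, phenotype)
  y <- xy$y
  n1 <- sum(y == 0); n2 <- sum(y == 1)
  if (n1 < 2 || n2 < 2) abort("need at least 2 samples in each phenotype class.")
  X1 <- xy$X[y == 0, , drop = FALSE]
  X2 <- xy$X[y == 1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, var); v2 <- apply(X2, 2, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  # zero pooled variance: either globally constant (no information, p = 1)
  # or perfectly separated (p at the floor)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p <- pmin(pmax(p, 1e-300), 1)
  out <- tibble(gene_id = xy$genes, p_value = as.numeric(p))
  class(out) <- c("pvalue_vector", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Adds a `q_value` column with the Benjamini-Hochberg step-up adjusted
#' p-values.
#'
#' @param pvalues A tibble with columns `gene_id` and `p_value`
#'   (as returned by [marginal_pvalues()]).
#' @return The input tibble with a `q_value` column appended.
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(is.data.frame(pvalues),
            all(c("gene_id", "p_value") %in% names(pvalues)))
  if (any(pvalues$p_value <= 0 | pvalues$p_value > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  pvalues$q_value <- p.adjust(pvalues$p_value, method = "BH")
  pvalues
}

#' Restart distribution from marginal p-values
#'
#' Assigns each gene the weight `-log(p_i)` and normalizes the weights to a
#' probability distribution (L1). Genes with `p = 1` receive weight zero;
#' p-values are clipped below at `1e-300` before taking logs.
#'
#' @param pvalues A tibble with a `gene_id` column and the p-value column
#'   named by `use`.
#' @param use Which column to transform: `"p_value"` (default) or
#'   `"q_value"` (FDR-adjusted).
#' @return A [sampling_prior].
#' @export
pi0_from_pvalues <- function(pvalues, use = "p_value") {
  stopifnot(is.data.frame(pvalues), "gene_id" %in% names(pvalues),
            use %in% names(pvalues))
  p <- pvalues[[use]]
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  w <- -log(pmax(p, 1e-300))
  if (all(w == 0)) {
    abort("all p-values are 1: the -log(p) prior carries no information.",
          class = "netrf_all_p_one")
  }
  new_sampling_prior(pvalues$gene_id, w)
}

#' Specification of a prior-construction method
#'
#' The six methods compared by the evaluation harness:
#' * `Oracle` - uniform prior restricted to the (known) disease genes; the
#'   forest only ever sees disease genes, so it benchmarks every other
#'   method.
#' * `StandardRF` - uniform prior over all genes (the standard random
#'   forest).
#' * `MarginalP` - prior proportional to `-log(p)` of marginal Welch tests,
#'   used directly (no network).
#' * `Topology` - degree-proportional prior (network only; the restart-free
#'   random-walk limit).
#' * `NetworkP` - random walk with restart seeded with `-log(p)` weights,
#'   restart probability `r` (default 0.3).
#' * `NetworkQ` - as `NetworkP` but seeded with FDR-adjusted p-values.
#'
#' Names are matched case-insensitively (`"network-p"`, `"networkp"` and
#' `"NetworkP"` are equivalent).
#'
#' @param name Method name (see above).
#' @param restart_probability Restart probability for the network-diffused
#'   methods.
#' @return A `method_spec` object.
#' @export
method_spec <- function(name, restart_probability = 0.3) {
  canon <- c(oracle = "Oracle", standardrf = "StandardRF",
             standard = "StandardRF", marginalp = "MarginalP",
             topology = "Topology", networkp = "NetworkP",
             networkq = "NetworkQ")
  key <- gsub("[^a-z]", "", tolower(as.character(name)[1]))
  if (!key %in% names(canon)) {
    abort(sprintf("unknown method '%s'; valid methods: %s", name,
                  paste(unique(canon), collapse = ", ")))
  }
  nm <- canon[[key]]
  structure(list(
    name = nm,
    uses_network = nm %in% c("Topology", "NetworkP", "NetworkQ"),
    uses_marginal_tests = nm %in% c("MarginalP", "NetworkP", "NetworkQ"),
    needs_disease_genes = nm == "Oracle",
    restart_probability = restart_probability
  ), class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat(sprintf("<method_spec> %s (network: %s, marginal tests: %s)\n",
              x$name, x$uses_network, x$uses_marginal_tests))
  invisible(x)
}

#' Build the candidate-sampling prior for a method
#'
#' Dispatches on the method to construct the sampling prior used in forest
#' growth: uniform, marginal-test-based, degree-based, or network-diffused
#' (see [method_spec()]). If every gene's (adjusted) p-value equals 1 the
#' `-log(p)` restart distribution is undefined; the method then falls back
#' to a uniform restart distribution with a message (this arises routinely
#' for `NetworkQ` under a global null, where BH adjustment sends all
#' q-values to 1).
#'
#' @param data Samples-by-genes data frame (training data).
#' @param phenotype Binary vector or column name in `data`.
#' @param method A [method_spec()] or method name.
#' @param network A [gene_network()] over the same genes as `data`
#'   (required by Topology/NetworkP/NetworkQ).
#' @param disease_genes Character vector of known disease genes (required by
#'   Oracle).
#' @return A [sampling_prior] aligned to the gene columns of `data`.
#' @export
build_method_prior <- function(data, phenotype = NULL, method,
                               network = NULL, disease_genes = NULL) {
  if (!inherits(method, "method_spec")) method <- method_spec(method)
  genes <- split_xy(data, phenotype, require_y = FALSE)$genes
  if (method$uses_network) {
    if (is.null(network)) {
      abort(sprintf("method %s requires a gene network.", method$name))
    }
    if (!setequal(network$gene_ids, genes)) {
      abort("network genes must coincide with the gene columns of `data`.")
    }
  }
  pv <- NULL
  if (method$uses_marginal_tests) {
    if (is.null(phenotype)) {
      abort(sprintf("method %s requires a phenotype for marginal tests.",
                    method$name))
    }
    pv <- marginal_pvalues(data, phenotype)
    if (method$name == "NetworkQ") pv <- fdr_adjust(pv)
  }
  pi0_or_uniform <- function(pv, use) {
    tryCatch(pi0_from_pvalues(pv, use = use),
             netrf_all_p_one = function(cnd) {
               inform(paste0("all ", use, "s equal 1; falling back to a ",
                             "uniform restart distribution"))
               uniform_prior(pv$gene_id)
             })
  }
  prior <- switch(
    method$name,
    StandardRF = uniform_prior(genes),
    Oracle = {
      if (is.null(disease_genes) || length(disease_genes) == 0) {
        abort("method Oracle requires a non-empty disease gene set.")
      }
      if (!all(disease_genes %in% genes)) abort("unknown disease gene.")
      new_sampling_prior(genes, as.numeric(genes %in% disease_genes))
    },
    MarginalP = pi0_or_uniform(pv, "p_value"),
    Topology = degree_prior(network),
    NetworkP = drw_equilibrium(network, pi0_or_uniform(pv, "p_value"),
                               r = method$restart_probability),
    NetworkQ = drw_equilibrium(network, pi0_or_uniform(pv, "q_value"),
                               r = method$restart_probability)
  )
  new_sampling_prior(genes, align_prior(prior, genes))
}
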
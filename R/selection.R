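#' Top-k genes by importance
#'
#' @param importance A `gene_importance` tibble (see
#'   [permutation_importance()]).
#' @param k Number of genes to return, `1 <= k <=` number of genes.
#' @return Character vector of the `k` most important gene ids, in
#'   decreasing importance (ties broken by gene order).
#' @export
top_k <- function(importance, k) {
  stopifnot(is.data.frame(importance),
            all(c("gene_id", "importance") %in% names(importance)))
  if (k < 1 || k > nrow(importance)) {
    abort(sprintf("k must be in [1, %d].", nrow(importance)))
  }
  ord <- order(-importance$importance, seq_len(nrow(importance)))
  importance$gene_id[ord[seq_len(k)]]
}

#' Recursive gene elimination
#'
#' Starting from all genes, repeatedly: rebuild the method's sampling prior
#' on the retained genes, fit a forest with `mtry = ceiling(sqrt(k))` for
#' `k` retained genes, compute permutation importance, and discard the
#' `floor(drop_fraction * k)` lowest-ranking genes (at least one). The loop
#' stops when the next drop would leave fewer than `min_genes` genes; the
#' retained set is then truncated to exactly `min_genes` by the final
#' round's ranking.
#'
#' Marginal p-values are computed once on the full data and renormalized
#' over the retained genes each round (dropping genes does not change a
#' gene's marginal test); network-derived priors are recomputed each round
#' on the subnetwork induced by the retained genes.
#'
#' @inheritParams build_method_prior
#' @param min_genes Number of genes to retain (`<=` number of genes).
#' @param drop_fraction Fraction of retained genes discarded per round.
#' @param ntree,min_node_size Forest parameters (see [fit_forest()]).
#' @param seed Optional integer seed covering the whole elimination.
#' @return An object of class `rfe_result` with elements `final_genes`
#'   (character, ordered by final importance), `rounds` (tibble: `round`,
#'   `n_genes`, `gene_id`, `importance`, `rank`, `retained`), and `config`.
#' @export
recursive_elimination <- function(data, phenotype, method = "StandardRF",
                                  network = NULL, disease_genes = NULL,
                                  min_genes, drop_fraction = 0.1,
                                  ntree = 500, min_node_size = 1,
                                  seed = NULL) {
  if (!inherits(method, "method_spec")) method <- method_spec(method)
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    abort("drop_fraction must lie in (0, 1).")
  }
  xy <- split_xy(data, phenotype)
  genes_all <- xy$genes
  if (min_genes < 1 || min_genes > length(genes_all)) {
    abort("min_genes must lie in [1, number of genes].")
  }
  if (method$uses_network && is.null(network)) {
    abort(sprintf("method %s requires a gene network.", method$name))
  }
  pv <- NULL
  if (method$uses_marginal_tests) {
    pv <- marginal_pvalues(data, phenotype)
    if (method$name == "NetworkQ") pv <- fdr_adjust(pv)
  }
  use_col <- if (!is.null(method$name) && method$name == "NetworkQ") {
    "q_value"
  } else "p_value"

  round_prior <- function(current) {
    sub <- function() induced_subnetwork(network, current)
    pi0 <- function() {
      pvc <- pv[pv$gene_id %in% current, ]
      tryCatch(pi0_from_pvalues(pvc, use = use_col),
               netrf_all_p_one = function(cnd) uniform_prior(current))
    }
    switch(method$name,
      StandardRF = NULL,  # unweighted path
      Oracle = {
        keep <- intersect(current, disease_genes)
        if (length(keep) == 0) abort("no disease gene retained for Oracle.")
        new_sampling_prior(current, as.numeric(current %in% keep))
      },
      MarginalP = pi0(),
      Topology = degree_prior(sub()),
      NetworkP = drw_equilibrium(sub(), pi0(), r = method$restart_probability),
      NetworkQ = drw_equilibrium(sub(), pi0(), r = method$restart_probability)
    )
  }

  run <- function() {
    current <- genes_all
    rounds <- list()
    final_imp <- NULL
    rn <- 0L
    repeat {
      rn <- rn + 1L
      prior <- round_prior(current)
      dat <- as_tibble(as.data.frame(xy$X[, current, drop = FALSE]))
      fit <- fit_forest(dat, xy$y, prior = prior, ntree = ntree,
                        mtry = ceiling(sqrt(length(current))),
                        min_node_size = min_node_size)
      imp <- permutation_importance(fit)
      drop_n <- max(1L, floor(drop_fraction * length(current)))
      if (length(current) - drop_n < min_genes) {
        keep <- top_k(imp, min_genes)
        rounds[[rn]] <- mutate(imp, round = rn, n_genes = length(current),
                               retained = .data$gene_id %in% keep)
        final_imp <- imp
        current <- keep
        break
      }
      keep <- top_k(imp, length(current) - drop_n)
      rounds[[rn]] <- mutate(imp, round = rn, n_genes = length(current),
                             retained = .data$gene_id %in% keep)
      current <- keep
    }
    list(final_genes = current, final_importance = final_imp,
         rounds = select(bind_rows(rounds), "round", "n_genes", "gene_id",
                         "importance", "rank", "retained"))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(res, list(config = list(
    method = method$name, min_genes = min_genes,
    drop_fraction = drop_fraction, ntree = ntree, seed = seed
  ))), class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %s: %d round(s), %d -> %d genes\n",
              x$config$method, max(x$rounds$round),
              x$rounds$n_genes[1], length(x$final_genes)))
  cat("  final genes:", paste(head(x$final_genes, 8), collapse = ", "),
      if (length(x$final_genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Refit a standard forest on a selected gene set
#'
#' After gene selection, the predictive model is a standard (uniform-prior)
#' random forest restricted to the selected genes — the same construction as
#' the Oracle benchmark on its known gene set.
#'
#' @param data Samples-by-genes data frame.
#' @param phenotype Binary vector or column name in `data`.
#' @param genes Character vector of selected genes.
#' @param ntree,min_node_size,seed See [fit_forest()].
#' @return A `guided_rf` fit using only `genes`.
#' @export
fit_final_model <- function(data, phenotype, genes, ntree = 500,
                            min_node_size = 1, seed = NULL) {
  xy <- split_xy(data, phenotype)
  if (!all(genes %in% xy$genes)) abort("unknown gene in `genes`.")
  dat <- as_tibble(as.data.frame(xy$X[, genes, drop = FALSE]))
  fit_forest(dat, xy$y, prior = NULL, ntree = ntree,
             min_node_size = min_node_size, seed = seed)
}
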
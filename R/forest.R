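#' Fit a network-guided random forest
#'
#' Grows an ensemble of CART classification trees on bootstrap samples of
#' the training data. At every node, `mtry` candidate splitting variables
#' are drawn *without replacement with probabilities proportional to the
#' sampling prior* (successive draws, renormalizing over the remaining
#' genes); the best Gini-decrease split over the candidates is taken, and
#' trees are grown until nodes are pure, fall below `min_node_size`, or no
#' split improves impurity. With a uniform prior the procedure is exactly
#' the standard random forest; with `prior = NULL` a dedicated unweighted
#' sampling path is used (it draws identical forests to an explicit uniform
#' prior at the same seed).
#'
#' Genes with zero prior weight are never candidates and therefore never
#' split a node. If fewer than `mtry` genes have positive weight, all
#' positive-weight genes are used.
#'
#' @param data Samples-by-genes data frame (optionally with `sample_id`).
#' @param phenotype Binary (0/1) vector or column name in `data`; both
#'   classes must be present.
#' @param prior A [sampling_prior] over the gene columns, or `NULL` for the
#'   standard (uniform, unweighted) forest.
#' @param ntree Number of trees.
#' @param mtry Number of candidate variables per node; defaults to
#'   `ceiling(sqrt(k))` where `k` is the number of genes with positive prior
#'   weight (all genes for the standard forest).
#' @param min_node_size Nodes of at most this many samples are not split.
#' @param seed Optional integer seed; when supplied the fit is fully
#'   reproducible and the calling RNG state is left untouched.
#' @return An object of class `guided_rf`.
#' @examples
#' d <- tibble::tibble(g1 = c(rnorm(10), rnorm(10, 3)), g2 = rnorm(20),
#'                     y = rep(0:1, each = 10))
#' fit <- fit_forest(d, "y", ntree = 25, seed = 1)
#' predict(fit, d)
#' @export
fit_forest <- function(data, phenotype, prior = NULL, ntree = 500,
                       mtry = NULL, min_node_size = 1, seed = NULL) {
  stopifnot(ntree >= 1, min_node_size >= 1)
  xy <- split_xy(data, phenotype)
  if (length(unique(xy$y)) < 2) {
    abort("phenotype has a single class; a classification forest needs both.")
  }
  p <- ncol(xy$X)
  weighted <- !is.null(prior)
  if (weighted) {
    w <- align_prior(prior, xy$genes)
    n_pos <- sum(w > 0)
    if (n_pos == 0) abort("prior has no positive-weight gene.")
  } else {
    w <- rep(1 / p, p)
    n_pos <- p
  }
  if (is.null(mtry)) mtry <- ceiling(sqrt(n_pos))
  stopifnot(mtry >= 1)
  run <- function() {
    cpp_fit_forest(xy$X, xy$y, w, as.integer(ntree), as.integer(mtry),
                   as.integer(min_node_size), weighted)
  }
  trees <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  fit <- structure(list(
    trees = trees,
    gene_ids = xy$genes,
    X = xy$X, y = xy$y,
    config = list(ntree = ntree, mtry = mtry, min_node_size = min_node_size,
                  weighted = weighted, seed = seed),
    prior = if (weighted) w else NULL
  ), class = "guided_rf")
  fit$oob_misclassification <- oob_misclassification(fit)
  fit
}

# OOB misclassification of the ensemble: each training sample is predicted
# by majority vote over the trees for which it is out-of-bag (tie -> 0);
# samples in-bag for every tree are skipped.
oob_misclassification <- function(fit) {
  n <- nrow(fit$X)
  votes1 <- integer(n); votes <- integer(n)
  for (tr in fit$trees) {
    oob <- tr$oob + 1L
    if (length(oob) == 0) next
    pred <- tree_predict(tr, fit$X[oob, , drop = FALSE])
    votes[oob] <- votes[oob] + 1L
    votes1[oob] <- votes1[oob] + pred
  }
  seen <- votes > 0
  if (!any(seen)) return(NA_real_)
  pred <- as.integer(votes1[seen] * 2L > votes[seen])
  mean(pred != fit$y[seen])
}

tree_predict <- function(tree, X) {
  cpp_predict_forest(list(tree), X)$pred
}

#' @export
print.guided_rf <- function(x, ...) {
  cat(sprintf(paste0("<guided_rf> %d trees, %d samples x %d genes, ",
                     "mtry = %d (%s candidate sampling)\n"),
              x$config$ntree, nrow(x$X), ncol(x$X), x$config$mtry,
              if (x$config$weighted) "prior-weighted" else "uniform"))
  if (!is.na(x$oob_misclassification)) {
    cat(sprintf("  OOB misclassification: %.4f\n", x$oob_misclassification))
  }
  invisible(x)
}

#' Predict phenotype classes with a guided forest
#'
#' Each observation is routed through every tree to a leaf; the tree votes
#' for the leaf's majority class, and the forest prediction is the majority
#' vote over trees. Exact ties (at a leaf or across trees) go to class 0.
#'
#' @param object A `guided_rf` fit.
#' @param newdata Data frame containing at least the forest's gene columns.
#' @param ... Unused.
#' @return A tibble with columns `.pred_class` (integer 0/1) and
#'   `.vote_frac_1` (fraction of trees voting class 1), one row per sample.
#' @export
predict.guided_rf <- function(object, newdata, ...) {
  xy <- split_xy(newdata, phenotype = NULL, require_y = FALSE)
  miss <- setdiff(object$gene_ids, xy$genes)
  if (length(miss) > 0) {
    abort(sprintf("newdata is missing gene column(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  X <- xy$X[, object$gene_ids, drop = FALSE]
  out <- cpp_predict_forest(object$trees, X)
  tibble(.pred_class = as.integer(out$pred),
         .vote_frac_1 = as.numeric(out$vote_frac_1))
}

#' Out-of-bag permutation variable importance
#'
#' For each tree with a non-empty out-of-bag (OOB) set and each gene used by
#' that tree, the OOB accuracy is compared with the OOB accuracy after the
#' gene's values are permuted within the OOB samples; the per-gene
#' differences are averaged over all trees with OOB samples (genes a tree
#' does not use contribute an exact zero for that tree). Genes never used by
#' any tree get importance 0.
#'
#' @param forest A `guided_rf` fit (the training data and OOB indices are
#'   stored in the fit).
#' @param seed Optional integer seed for the permutations.
#' @return A tibble (`gene_id`, `importance`, `rank`) of class
#'   `gene_importance`; rank 1 is the most important gene, importance ties
#'   broken by gene order.
#' @export
permutation_importance <- function(forest, seed = NULL) {
  stopifnot(inherits(forest, "guided_rf"))
  run <- function() cpp_permutation_importance(forest$trees, forest$X, forest$y)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$n_oob_trees == 0) {
    warn("no tree has out-of-bag samples; importances are all zero.")
  } else if (res$n_oob_trees < length(forest$trees)) {
    inform(sprintf("%d tree(s) had an empty out-of-bag set and were skipped",
                   length(forest$trees) - res$n_oob_trees))
  }
  imp <- as.numeric(res$importance)
  out <- tibble(gene_id = forest$gene_ids, importance = imp,
                rank = rank(-imp, ties.method = "first"))
  class(out) <- c("gene_importance", class(out))
  out
}

#' Draw candidate splitting variables from a sampling prior
#'
#' Exposes the node-level candidate draw used inside tree growth: `mtry`
#' distinct genes sampled without replacement with probabilities
#' proportional to the prior, renormalizing after each draw.
#'
#' @param prior A [sampling_prior].
#' @param mtry Number of candidates per draw (capped at the number of
#'   positive-weight genes).
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `draw` and `gene_id`.
#' @export
sample_candidates <- function(prior, mtry, n_draws = 1, seed = NULL) {
  validate_prior(prior)
  stopifnot(mtry >= 1, n_draws >= 1)
  run <- function() {
    cpp_sample_candidates(prior$probability, as.integer(mtry),
                          as.integer(n_draws), TRUE)
  }
  idx <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble(draw = rep(seq_len(nrow(idx)), times = ncol(idx)),
         gene_id = prior$gene_id[as.vector(idx)]) |>
    arrange(.data$draw)
}
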
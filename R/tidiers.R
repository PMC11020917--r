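#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a guided forest: per-gene permutation importance
#'
#' @param x A `guided_rf` fit.
#' @param seed Optional seed for the importance permutations.
#' @param ... Unused.
#' @return A tibble (`gene_id`, `importance`, `rank`).
#' @method tidy guided_rf
#' @export
tidy.guided_rf <- function(x, seed = NULL, ...) {
  permutation_importance(x, seed = seed)
}

#' One-row summary of a guided forest
#'
#' @param x A `guided_rf` fit.
#' @param ... Unused.
#' @return A one-row tibble with the fit configuration and the out-of-bag
#'   misclassification rate.
#' @method glance guided_rf
#' @export
glance.guided_rf <- function(x, ...) {
  tibble(ntree = x$config$ntree, mtry = x$config$mtry,
         min_node_size = x$config$min_node_size,
         weighted = x$config$weighted,
         n = nrow(x$X), p = ncol(x$X),
         oob_misclassification = x$oob_misclassification)
}

#' Tidy a recursive-elimination result: per-round importances
#'
#' @param x An `rfe_result`.
#' @param ... Unused.
#' @return The `rounds` tibble (`round`, `n_genes`, `gene_id`,
#'   `importance`, `rank`, `retained`).
#' @method tidy rfe_result
#' @export
tidy.rfe_result <- function(x, ...) x$rounds

#' One-row summary of a recursive-elimination result
#'
#' @param x An `rfe_result`.
#' @param ... Unused.
#' @method glance rfe_result
#' @export
glance.rfe_result <- function(x, ...) {
  tibble(method = x$config$method, n_rounds = max(x$rounds$round),
         n_start = x$rounds$n_genes[1], n_final = length(x$final_genes))
}

#' Tidy an evaluation report: the per-method metric table
#'
#' @param x An `rf_evaluation` (see [run_scenario()]).
#' @param ... Unused.
#' @return Tibble (`scenario`, `method`, `beta`, `p`, `metric`, `mean`,
#'   `se`).
#' @method tidy rf_evaluation
#' @export
tidy.rf_evaluation <- function(x, ...) x$metrics

#' One-row-per-method summary of an evaluation
#'
#' @param x An `rf_evaluation`.
#' @param ... Unused.
#' @method glance rf_evaluation
#' @export
glance.rf_evaluation <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_wider(id_cols = c("scenario", "method", "beta", "p"),
                       names_from = "metric", values_from = c("mean", "se"))
}
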
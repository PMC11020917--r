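#' Plot a sampling prior
#'
#' Genes ordered by decreasing probability, log-scaled y axis; makes the
#' concentration of a prior (e.g. hub dominance of the degree prior)
#' visible at a glance.
#'
#' @param object A [sampling_prior].
#' @param top_n Show only the `top_n` heaviest genes (default all).
#' @param ... Unused.
#' @method autoplot sampling_prior
#' @export
autoplot.sampling_prior <- function(object, top_n = NULL, ...) {
  df <- arrange(object, dplyr::desc(.data$probability)) |>
    mutate(rank = dplyr::row_number())
  if (!is.null(top_n)) df <- head(df, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gene rank", y = "sampling probability") +
    ggplot2::theme_minimal()
}

#' Plot per-gene importances
#'
#' @param object A `gene_importance` tibble
#'   (see [permutation_importance()]).
#' @param top_n Number of top genes shown.
#' @param ... Unused.
#' @method autoplot gene_importance
#' @export
autoplot.gene_importance <- function(object, top_n = 30, ...) {
  df <- arrange(object, .data$rank) |> head(top_n)
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$gene_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permutation importance (OOB accuracy decrease)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' One panel per metric, mean +/- one standard error per method.
#'
#' @param object An `rf_evaluation` (see [run_scenario()]).
#' @param ... Unused.
#' @method autoplot rf_evaluation
#' @export
autoplot.rf_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$method, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over replications",
                  title = sprintf("%s (beta = %g, p = %d)",
                                  object$config$scenario,
                                  object$config$beta, object$config$p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Selection counts against network degree
#'
#' Scatter of per-gene selection counts (how often a gene made a method's
#' selected set across replications) against its network degree. Under a
#' null scenario, any association is spurious hub preference.
#'
#' @param evaluation An `rf_evaluation`.
#' @param methods Methods to show (default all).
#' @export
plot_selection_degree <- function(evaluation, methods = NULL) {
  stopifnot(inherits(evaluation, "rf_evaluation"))
  deg <- network_degrees(evaluation$network)
  df <- evaluation$selection_counts |>
    mutate(degree = deg[.data$gene_id])
  if (!is.null(methods)) df <- filter(df, .data$method %in% methods)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "network degree", y = "times selected") +
    ggplot2::theme_minimal()
}
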
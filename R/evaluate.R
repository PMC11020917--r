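#' Misclassification rate
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return Fraction of mismatching labels.
#' @export
misclassification_rate <- function(predicted, truth) {
  if (length(predicted) == 0) abort("empty label vectors.")
  if (length(predicted) != length(truth)) abort("label vectors differ in length.")
  mean(as.integer(predicted) != as.integer(truth))
}

#' Sensitivity of a gene selection
#'
#' The fraction of true disease genes contained in the selected set.
#'
#' @param selected Character vector of selected genes.
#' @param disease_genes Non-empty character vector of true disease genes.
#' @return `|selected intersect D| / |D|`.
#' @export
selection_sensitivity <- function(selected, disease_genes) {
  if (length(disease_genes) == 0) {
    abort("sensitivity is undefined for an empty disease gene set.")
  }
  length(intersect(selected, disease_genes)) / length(disease_genes)
}

#' Per-gene selection counts across replications
#'
#' Counts, for every gene in the universe, the number of replications in
#' which it was selected. Under a null scenario these counts expose genes a
#' method selects *consistently* despite carrying no signal (spurious
#' selection).
#'
#' @param selections List of character vectors (one per replication).
#' @param genes Gene universe; defaults to the sorted union of all
#'   selections.
#' @return A tibble (`gene_id`, `count`), `count <= length(selections)`.
#' @export
false_selection_counts <- function(selections, genes = NULL) {
  stopifnot(is.list(selections))
  genes <- genes %||% sort(unique(unlist(selections)))
  cnt <- vapply(genes, function(g) {
    sum(vapply(selections, function(s) g %in% s, logical(1)))
  }, integer(1))
  tibble(gene_id = as.character(genes), count = as.integer(cnt))
}

#' Run one simulation scenario across methods and replications
#'
#' The full evaluation loop: a network is generated once and held fixed; a
#' disease configuration is drawn for the scenario; for each replication a
#' fresh expression/phenotype dataset is generated and split in half; each
#' method then (1) builds its sampling prior on the training half, (2) fits
#' a forest and ranks genes by out-of-bag permutation importance, (3)
#' selects the top `|D|` genes (`null_k` genes under `Null`) from its
#' feature set (genes with positive prior weight; for `Oracle` exactly the
#' disease genes, making its sensitivity 1 by construction), (4) refits a
#' standard forest on the selected genes, and (5) is scored on the test
#' half. `Oracle` is skipped under `Null` (no disease genes to restrict to).
#'
#' Defaults are the desk-scale design (`p = 200`, `n = 400`, 200 trees, 10
#' replications); the full-scale design of the underlying study (`p = 1000`
#' or `3000`, `n = 2000`, 1000 trees, 100 replications) is reached by
#' changing the arguments.
#'
#' @param scenario Scenario name (see [assign_disease()]).
#' @param methods Character vector of method names (see [method_spec()]).
#' @param p,n,beta,n_disease_genes Simulation design (see
#'   [simulate_replication()]).
#' @param n_replications Number of independent replications.
#' @param ntree Trees per forest.
#' @param null_k Number of genes recorded as selected under `Null`.
#' @param restart_probability Restart probability for network-diffused
#'   priors.
#' @param seed Integer seed; per-replication seeds are spawned from it.
#' @return An object of class `rf_evaluation`: list with `metrics` (tibble:
#'   `scenario`, `method`, `beta`, `p`, `metric`, `mean`, `se`),
#'   `selection_counts` (tibble: `method`, `gene_id`, `count`),
#'   `replications` (tibble: one row per replication x method with
#'   `misclassification`, `sensitivity`, `selected` list-column),
#'   `disease`, `network`, and `config`.
#' @export
run_scenario <- function(scenario,
                         methods = c("Oracle", "StandardRF", "MarginalP",
                                     "Topology", "NetworkP", "NetworkQ"),
                         p = 200, n = 400, beta = 1, n_replications = 10,
                         ntree = 200, null_k = 15, n_disease_genes = NULL,
                         restart_probability = 0.3, seed = 1) {
  scen <- canon_scenario(scenario)
  specs <- lapply(methods, method_spec,
                  restart_probability = restart_probability)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (scen == "Null" && "Oracle" %in% names(specs)) {
    inform("Oracle is undefined under Null (no disease genes); skipping it.")
    specs <- specs[names(specs) != "Oracle"]
  }
  if (length(specs) == 0) abort("no method to evaluate.")

  setup <- withr::with_seed(seed, {
    net <- simulate_network(p)
    dis <- assign_disease(net, scen, beta = beta,
                          n_disease_genes = n_disease_genes)
    rep_seeds <- sample.int(.Machine$integer.max - 1, n_replications)
    list(net = net, dis = dis, rep_seeds = rep_seeds)
  })
  net <- setup$net; dis <- setup$dis
  d_genes <- dis$genes$gene_id
  k_sel <- if (scen == "Null") null_k else length(d_genes)

  rows <- list()
  for (r in seq_len(n_replications)) {
    rep_row <- withr::with_seed(setup$rep_seeds[r], {
      expr <- simulate_expression(net, n)
      phen <- simulate_phenotype(expr, dis)
      idx <- sample.int(n, n / 2)
      tr_x <- expr[idx, ]; tr_y <- phen$phenotype[idx]
      te_x <- expr[-idx, ]; te_y <- phen$phenotype[-idx]
      purrr::map(specs, function(sp) {
        tryCatch({
          prior <- build_method_prior(tr_x, tr_y, sp, network = net,
                                      disease_genes = d_genes)
          use_prior <- if (sp$name == "StandardRF") NULL else prior
          fit <- fit_forest(tr_x, tr_y, prior = use_prior, ntree = ntree)
          imp <- permutation_importance(fit)
          # genes with zero prior weight are outside the method's feature
          # set (Oracle: non-disease genes) and cannot be selected
          pos <- prior$gene_id[prior$probability > 0]
          imp_pos <- imp[imp$gene_id %in% pos, ]
          selected <- if (nrow(imp_pos) >= k_sel) {
            top_k(imp_pos, k_sel)
          } else {
            c(top_k(imp_pos, nrow(imp_pos)),
              top_k(imp[!imp$gene_id %in% pos, ], k_sel - nrow(imp_pos)))
          }
          final <- fit_final_model(tr_x, tr_y, selected, ntree = ntree)
          pred <- predict(final, te_x)
          tibble(
            replication = r, method = sp$name,
            misclassification = misclassification_rate(pred$.pred_class, te_y),
            sensitivity = if (scen == "Null") NA_real_ else
              selection_sensitivity(selected, d_genes),
            selected = list(selected))
        }, error = function(e) {
          warn(sprintf("replication %d, method %s failed and was excluded: %s",
                       r, sp$name, conditionMessage(e)))
          NULL
        })
      })
    })
    rows <- c(rows, rep_row)
  }
  reps <- bind_rows(rows)
  if (nrow(reps) == 0) abort("every replication failed.")

  summarise_metric <- function(df, col, metric) {
    df |>
      group_by(.data$method) |>
      summarise(mean = mean(.data[[col]]),
                se = sd(.data[[col]]) / sqrt(dplyr::n()),
                .groups = "drop") |>
      mutate(metric = metric)
  }
  metrics <- summarise_metric(reps, "misclassification", "misclassification")
  if (scen != "Null") {
    metrics <- bind_rows(metrics,
                         summarise_metric(reps, "sensitivity", "sensitivity"))
  }
  metrics <- metrics |>
    mutate(scenario = scen, beta = beta, p = p) |>
    select("scenario", "method", "beta", "p", "metric", "mean", "se")

  counts <- reps |>
    group_by(.data$method) |>
    summarise(res = list(false_selection_counts(.data$selected,
                                                genes = net$gene_ids)),
              .groups = "drop") |>
    tidyr::unnest("res")

  structure(list(
    metrics = metrics, selection_counts = counts, replications = reps,
    disease = dis, network = net,
    config = list(scenario = scen, methods = names(specs), p = p, n = n,
                  beta = beta, n_replications = n_replications,
                  ntree = ntree, null_k = null_k, seed = seed)
  ), class = "rf_evaluation")
}

#' @export
print.rf_evaluation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rf_evaluation> %s (p = %d, n = %d, beta = %g, %d replication(s))\n",
    cfg$scenario, cfg$p, cfg$n, cfg$beta, cfg$n_replications))
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 3)
  invisible(x)
}
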
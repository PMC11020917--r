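#' Read a network edge list
#'
#' Two-column delimited file of gene-id pairs. Gene ids are taken verbatim
#' as strings; deduplication of repeated/reversed edges happens in
#' [gene_network()].
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @param col_names `TRUE` if the file has a header row.
#' @return A tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path, delim = "\t", col_names = FALSE) {
  ed <- readr::read_delim(path, delim = delim, col_names = col_names,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (ncol(ed) < 2) abort("edge list must have at least two columns.")
  stats::setNames(ed[, 1:2], c("from", "to"))
}

#' @rdname read_edge_list
#' @param network A [gene_network()].
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' Read / write a samples-by-genes expression table
#'
#' Delimited matrix with a header row of gene ids and the first column
#' holding sample ids. `transpose = TRUE` reads a genes-by-samples file.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @param transpose Is the file genes-by-samples?
#' @return A tibble with a `sample_id` column and one numeric column per
#'   gene.
#' @export
read_expression <- function(path, delim = "\t", transpose = FALSE) {
  x <- readr::read_delim(path, delim = delim, progress = FALSE,
                         col_types = readr::cols())
  names(x)[1] <- if (transpose) "gene_id" else "sample_id"
  if (transpose) {
    genes <- x$gene_id
    m <- t(as.matrix(x[-1]))
    out <- as_tibble(as.data.frame(m))
    names(out) <- genes
    return(dplyr::bind_cols(tibble(sample_id = colnames(x)[-1]), out))
  }
  x
}

#' @rdname read_expression
#' @param expression A samples-by-genes tibble with a `sample_id` column.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' Read / write a phenotype table (`sample_id`, `phenotype`)
#'
#' @param path File path.
#' @return A tibble (`sample_id`, `phenotype`), phenotype integer 0/1.
#' @export
read_phenotype <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stats::setNames(x[, 1:2], c("sample_id", "phenotype")) |>
    mutate(phenotype = as.integer(.data$phenotype))
}

#' @rdname read_phenotype
#' @param phenotype A tibble (`sample_id`, `phenotype`).
#' @export
write_phenotype <- function(phenotype, path) {
  readr::write_tsv(phenotype, path)
  invisible(path)
}

#' Write a sampling prior as TSV (`gene_id`, `probability`)
#'
#' @param prior A [sampling_prior].
#' @param path File path.
#' @export
write_prior <- function(prior, path) {
  validate_prior(prior)
  readr::write_tsv(prior, path)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  sampling_prior(x$gene_id, x$probability)
}

#' Write a disease configuration (`scenario`, `gene_id`, `beta`)
#'
#' @param config A [assign_disease()] configuration.
#' @param path File path.
#' @export
write_disease_config <- function(config, path) {
  readr::write_tsv(mutate(config$genes, scenario = config$scenario,
                          .before = 1), path)
  invisible(path)
}
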
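#' Build a gene network from an edge list
#'
#' Constructs an undirected, unweighted gene network from a two-column edge
#' list. Self-loops are dropped and duplicate edges (including reversed
#' duplicates) are collapsed; both removals are reported via a message so
#' that silently malformed inputs are visible.
#'
#' @param edges A data frame whose first two columns are gene identifiers
#'   (coerced to character). Additional columns are ignored.
#' @param genes Optional character vector fixing the gene universe and its
#'   order. Defaults to the sorted set of edge endpoints. Every edge endpoint
#'   must be contained in `genes`.
#' @param modules Optional data frame with columns `gene_id` and `module`
#'   assigning genes to network modules (used by the simulator).
#'
#' @return An object of class `gene_network`: a list with elements
#'   `gene_ids` (character), `edges` (tibble with columns `from`, `to`,
#'   canonicalized so `from < to`), and `modules` (tibble or `NULL`).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b", "c"),
#'                                to   = c("b", "c", "a")))
#' degree_prior(net)
#' @export
gene_network <- function(edges, genes = NULL, modules = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  loops <- from == to
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    inform(sprintf("collapsed %d duplicate/reversed edge(s)", sum(dup)))
  }
  ed <- tibble(from = a[!dup], to = b[!dup])
  if (is.null(genes)) {
    genes <- sort(unique(c(ed$from, ed$to)))
  } else {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) abort("`genes` contains duplicates.")
    missing <- setdiff(unique(c(ed$from, ed$to)), genes)
    if (length(missing) > 0) {
      abort(sprintf("edge endpoints not in `genes`: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  if (length(genes) == 0) abort("network has no genes.")
  mod <- NULL
  if (!is.null(modules)) {
    stopifnot(is.data.frame(modules),
              all(c("gene_id", "module") %in% names(modules)))
    mod <- tibble(gene_id = as.character(modules$gene_id),
                  module = as.character(modules$module))
    if (!all(mod$gene_id %in% genes)) abort("module assignment for unknown gene.")
  }
  structure(list(gene_ids = genes, edges = ed, modules = mod),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges", n_genes(x), n_edges(x)))
  if (!is.null(x$modules)) {
    cat(sprintf(", %d modules", length(unique(x$modules$module))))
  }
  cat("\n")
  invisible(x)
}

#' @rdname gene_network
#' @param x,network A `gene_network`.
#' @export
n_genes <- function(network) length(network$gene_ids)

#' @rdname gene_network
#' @export
n_edges <- function(network) nrow(network$edges)

#' Node degrees of a gene network
#'
#' @param network A [gene_network()].
#' @return Named integer vector of degrees, in `gene_ids` order.
#' @export
network_degrees <- function(network) {
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$gene_ids))
  stats::setNames(as.integer(deg), network$gene_ids)
}

#' Sparse symmetric 0/1 adjacency matrix of a network
#'
#' @param network A [gene_network()].
#' @return A `dgCMatrix` with dimnames equal to the gene ids.
#' @export
network_adjacency <- function(network) {
  p <- n_genes(network)
  i <- match(network$edges$from, network$gene_ids)
  j <- match(network$edges$to, network$gene_ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(p, p),
                            dimnames = list(network$gene_ids, network$gene_ids))
  methods::as(A, "generalMatrix")
}

#' Row-normalized adjacency matrix
#'
#' Divides each row of the 0/1 adjacency by its degree, yielding the
#' transition matrix of the simple random walk. Zero-degree (dangling) rows
#' are left all-zero and reported in the `"dangling"` attribute; the random
#' walk handles the lost mass by redirecting it to the restart distribution
#' (see [drw_equilibrium()]).
#'
#' @param network A [gene_network()].
#' @return A sparse row-stochastic matrix with a logical attribute
#'   `"dangling"` flagging zero-degree genes.
#' @export
row_normalize_adjacency <- function(network) {
  A <- network_adjacency(network)
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  scale <- ifelse(dangling, 0, 1 / deg)
  P <- Matrix::Diagonal(x = scale) %*% A
  dimnames(P) <- dimnames(A)
  attr(P, "dangling") <- stats::setNames(dangling, network$gene_ids)
  P
}

#' Degree-proportional sampling prior
#'
#' The stationary distribution of the simple random walk on a connected
#' undirected graph: gene `i` receives probability `degree(i) / (2 |E|)`.
#' This is the network-topology-only prior (the restart-free limit of the
#' random walk with restart).
#'
#' @param network A [gene_network()] with at least one edge.
#' @return A [sampling_prior] tibble (`gene_id`, `probability`).
#' @export
degree_prior <- function(network) {
  if (n_edges(network) == 0) abort("degree prior undefined: network has no edges.")
  deg <- network_degrees(network)
  new_sampling_prior(network$gene_ids, deg / (2 * n_edges(network)))
}

#' Random walk with restart equilibrium over a gene network
#'
#' Iterates `pi_{t+1} = (1 - r) A' pi_t + r pi_0` where `A` is the
#' row-normalized adjacency, `r` the restart probability and `pi_0` the
#' restart (source) distribution, until the L1 change falls below `tol`.
#' Mass sitting on zero-degree genes has nowhere to walk; it is redirected to
#' the restart distribution at each step, which keeps every iterate a proper
#' probability distribution.
#'
#' With `r = 0` on a bipartite graph the power iteration oscillates, so the
#' restart-free case returns the degree-proportional stationary law
#' ([degree_prior()]) directly.
#'
#' @param network A [gene_network()].
#' @param pi0 A [sampling_prior] over the network's genes (any order; matched
#'   by `gene_id`).
#' @param r Restart probability in `[0, 1]`.
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum number of iterations; if reached without
#'   convergence the last iterate is returned with a warning.
#' @return A [sampling_prior] tibble aligned to the network's gene order,
#'   with attributes `"iterations"` and `"converged"`.
#' @export
drw_equilibrium <- function(network, pi0, r = 0.3, tol = 1e-10,
                            max_iter = 1000) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 0, r <= 1,
            tol > 0, max_iter >= 1)
  v0 <- align_prior(pi0, network$gene_ids)
  if (r == 0) {
    out <- degree_prior(network)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (r == 1) {
    out <- new_sampling_prior(network$gene_ids, v0)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }
  P <- row_normalize_adjacency(network)
  dangling <- attr(P, "dangling")
  Pt <- Matrix::t(P)
  pi_t <- v0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- sum(pi_t[dangling])
    pi_next <- as.numeric((1 - r) * (Pt %*% pi_t + m * v0) + r * v0)
    if (sum(abs(pi_next - pi_t)) < tol) {
      pi_t <- pi_next
      converged <- TRUE
      break
    }
    pi_t <- pi_next
  }
  if (!converged) {
    warn(sprintf("random walk did not converge in %d iterations (L1 tol %g)",
                 max_iter, tol), class = "netrf_no_convergence")
  }
  out <- new_sampling_prior(network$gene_ids, pi_t / sum(pi_t))
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Restrict a network to a subset of genes
#'
#' Returns the subgraph induced by `genes`: those genes and every edge with
#' both endpoints among them. Module assignments are restricted accordingly.
#'
#' @param network A [gene_network()].
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return A [gene_network()].
#' @export
induced_subnetwork <- function(network, genes) {
  genes <- as.character(genes)
  if (!all(genes %in% network$gene_ids)) abort("unknown gene in `genes`.")
  keep <- network$edges$from %in% genes & network$edges$to %in% genes
  mod <- network$modules
  if (!is.null(mod)) mod <- mod[mod$gene_id %in% genes, ]
  gene_network(network$edges[keep, ], genes = genes, modules = mod)
}

# convert to igraph (used by the simulator's structural checks)
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$gene_ids)
}
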
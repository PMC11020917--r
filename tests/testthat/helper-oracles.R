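# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: adjacency and normalization are rebuilt from the
# edge tibble in base R, and the random-walk equilibrium is obtained by a
# dense linear solve instead of power iteration.

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense row-normalized adjacency straight from the edge list
oracle_transition <- function(network) {
  g <- network$gene_ids
  p <- length(g)
  A <- matrix(0, p, p, dimnames = list(g, g))
  for (k in seq_len(nrow(network$edges))) {
    i <- network$edges$from[k]; j <- network$edges$to[k]
    A[i, j] <- 1; A[j, i] <- 1
  }
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  P[deg == 0, ] <- 0
  P
}

# equilibrium of pi = (1-r) t(P) pi + r pi0 by direct solve (no dangling)
oracle_drw <- function(network, pi0, r) {
  P <- oracle_transition(network)
  p <- nrow(P)
  solve(diag(p) - (1 - r) * t(P), r * pi0)
}

# a random connected graph on n nodes: spanning tree + extra random edges
random_connected_network <- function(n, extra = n %/% 2) {
  stopifnot(n >= 2)
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {
    from <- c(from, sample(v - 1, 1)); to <- c(to, v)
  }
  if (extra > 0) {
    f2 <- sample(n, extra, replace = TRUE)
    t2 <- sample(n, extra, replace = TRUE)
    keep <- f2 != t2
    from <- c(from, f2[keep]); to <- c(to, t2[keep])
  }
  suppressMessages(gene_network(
    data.frame(from = paste0("g", from), to = paste0("g", to)),
    genes = paste0("g", seq_len(n))
  ))
}

# exhaustive best-split search for a tiny node: every candidate gene, every
# midpoint threshold, Gini impurity decrease computed from first principles
oracle_best_split <- function(X, y, candidates) {
  gini <- function(lab) {
    if (length(lab) == 0) return(0)
    p1 <- mean(lab)
    1 - p1^2 - (1 - p1)^2
  }
  n <- length(y)
  parent <- gini(y)
  best <- list(dec = 0, var = NA, thr = NA)
  for (v in candidates) {
    vals <- sort(unique(X[, v]))
    if (length(vals) < 2) next
    thrs <- (vals[-1] + vals[-length(vals)]) / 2
    for (thr in thrs) {
      left <- X[, v] <= thr
      dec <- parent - mean(left) * gini(y[left]) -
        mean(!left) * gini(y[!left])
      if (dec > best$dec + 1e-12) best <- list(dec = dec, var = v, thr = thr)
    }
  }
  best
}

# small expression tibble with one informative gene and noise genes
make_signal_data <- function(n = 60, p = 10, shift = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + shift * y
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("g", seq_len(p))
    d$y <- y
    d
  })
}
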
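test_that("candidate draws respect point masses and exhaustive draws", {
  pr <- sampling_prior(c("a", "b", "c"), c(1, 1, 1))
  all3 <- sample_candidates(pr, mtry = 3, seed = 1)
  expect_setequal(all3$gene_id, c("a", "b", "c"))
  point <- sampling_prior(c("a", "b", "c"), c(1, 0, 0))
  draws <- sample_candidates(point, mtry = 1, n_draws = 50, seed = 2)
  expect_true(all(draws$gene_id == "a"))
  # more candidates requested than positive-weight genes: take all positive
  two <- sampling_prior(c("a", "b", "c"), c(0.5, 0.5, 0))
  got <- sample_candidates(two, mtry = 3, seed = 3)
  expect_setequal(got$gene_id, c("a", "b"))
})

test_that("empirical draw frequencies match the prior (single candidate)", {
  pr <- sampling_prior(c("a", "b", "c"), c(0.7, 0.2, 0.1))
  n <- 20000
  draws <- sample_candidates(pr, mtry = 1, n_draws = n, seed = 4)
  freq <- table(factor(draws$gene_id, levels = pr$gene_id)) / n
  se <- sqrt(pr$probability * (1 - pr$probability) / n)
  expect_true(all(abs(as.numeric(freq) - pr$probability) < 3 * se))
})

test_that("exhaustive split search matches brute-force enumeration", {
  withr::with_seed(6, {
    for (rep in 1:15) {
      n <- 6
      X <- matrix(round(rnorm(n * 2), 2), n, 2,
                  dimnames = list(NULL, c("g1", "g2")))
      y <- sample(0:1, n, replace = TRUE)
      if (length(unique(y)) < 2) next
      d <- tibble::as_tibble(as.data.frame(X))
      d$y <- y
      # single tree, mtry = 2 makes both genes candidates at the root
      fit <- fit_forest(d, "y", ntree = 1, mtry = 2, seed = rep)
      tr <- fit$trees[[1]]
      boot <- tr$boot + 1L
      yb <- y[boot]
      if (length(unique(yb)) < 2) {
        expect_equal(tr$split_var[1], -1L)
        next
      }
      want <- oracle_best_split(X[boot, , drop = FALSE], yb, c("g1", "g2"))
      if (is.na(want$var)) {
        expect_equal(tr$split_var[1], -1L)
      } else {
        expect_equal(fit$gene_ids[tr$split_var[1] + 1L], want$var)
        expect_equal(tr$threshold[1], want$thr, tolerance = 1e-12)
      }
    }
  })
})

test_that("a perfectly separating candidate empties node impurity", {
  d <- tibble::tibble(g1 = c(1, 2, 3, 10, 11, 12), y = rep(0:1, each = 3))
  fit <- fit_forest(d, "y", ntree = 30, seed = 8)
  pred <- predict(fit, d)
  expect_equal(pred$.pred_class, d$y)
})

test_that("degenerate configurations produce single-leaf trees", {
  d <- make_signal_data(n = 20, p = 3)
  fit <- fit_forest(d, "y", ntree = 1, min_node_size = 20, seed = 1)
  tr <- fit$trees[[1]]
  expect_equal(length(tr$split_var), 1L)
  expect_equal(tr$split_var[1], -1L)
  # majority class of the bootstrap
  expect_equal(unname(predict(fit, d)$.pred_class[1]),
               as.integer(tr$n1[1] > tr$n0[1]))
  expect_error(fit_forest(dplyr::mutate(d, y = 0), "y"), "single class")
})

test_that("uniform prior and the unweighted path grow identical forests", {
  d <- make_signal_data(n = 40, p = 8)
  pr <- uniform_prior(paste0("g", 1:8))
  f_unweighted <- fit_forest(d, "y", prior = NULL, ntree = 25, seed = 99)
  f_uniform <- fit_forest(d, "y", prior = pr, ntree = 25, seed = 99)
  expect_identical(f_unweighted$trees, f_uniform$trees)
})

test_that("fits, predictions and importances are reproducible given a seed", {
  d <- make_signal_data(n = 50, p = 6)
  f1 <- fit_forest(d, "y", ntree = 20, seed = 7)
  f2 <- fit_forest(d, "y", ntree = 20, seed = 7)
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict(f1, d), predict(f2, d))
  expect_identical(permutation_importance(f1, seed = 3),
                   permutation_importance(f2, seed = 3))
})

test_that("bootstrap indices have size n and OOB fraction approaches 1/e", {
  d <- make_signal_data(n = 100, p = 4)
  fit <- fit_forest(d, "y", ntree = 500, seed = 12)
  sizes <- vapply(fit$trees, function(t) length(t$boot), integer(1))
  expect_true(all(sizes == 100))
  oob_ok <- vapply(fit$trees, function(t) {
    setequal(union(t$boot, t$oob), 0:99) &&
      length(intersect(t$boot, t$oob)) == 0
  }, logical(1))
  expect_true(all(oob_ok))
  oob_frac <- mean(vapply(fit$trees, function(t) length(t$oob) / 100,
                          numeric(1)))
  expect_lt(abs(oob_frac - exp(-1)), 0.02)
})

test_that("zero-weight genes never split a node", {
  d <- make_signal_data(n = 60, p = 6, shift = 2)
  pr <- sampling_prior(paste0("g", 1:6), c(1, 1, 1, 0, 0, 0))
  fit <- fit_forest(d, "y", prior = pr, ntree = 50, seed = 5)
  used <- unique(unlist(lapply(fit$trees, function(t) t$used))) + 1L
  expect_true(all(used <= 3))
})

test_that("forest votes aggregate by majority with ties to class 0", {
  d <- tibble::tibble(g1 = c(1, 1, 1, 2), y = c(0, 0, 0, 1))
  one_leaf <- fit_forest(d, "y", ntree = 1, min_node_size = 4, seed = 2)
  tr <- one_leaf$trees[[1]]
  pred <- predict(one_leaf, tibble::tibble(g1 = 100))
  expect_equal(pred$.pred_class, as.integer(tr$n1[1] > tr$n0[1]))
  # hand-built 2-tree forest splitting 1-1 -> class 0
  leaf <- function(n0, n1) list(
    split_var = -1L, threshold = NA_real_, left = -1L, right = -1L,
    n0 = n0, n1 = n1, boot = integer(0), oob = integer(0), used = integer(0))
  tie_fit <- one_leaf
  tie_fit$trees <- list(leaf(3L, 1L), leaf(1L, 3L))
  pred <- predict(tie_fit, tibble::tibble(g1 = 0))
  expect_equal(pred$.pred_class, 0L)
  expect_equal(pred$.vote_frac_1, 0.5)
  expect_error(predict(one_leaf, tibble::tibble(other = 1)), "missing gene")
})

test_that("importance: unused genes are 0, the signal gene ranks first", {
  ranks <- vapply(1:10, function(s) {
    d <- make_signal_data(n = 60, p = 10, shift = 3, seed = s)
    fit <- fit_forest(d, "y", ntree = 100, seed = s)
    imp <- permutation_importance(fit, seed = s)
    imp$rank[imp$gene_id == "g1"]
  }, integer(1))
  expect_true(all(ranks == 1L))
  # a gene with zero prior weight is never used -> importance exactly 0
  d <- make_signal_data(n = 40, p = 5)
  pr <- sampling_prior(paste0("g", 1:5), c(1, 1, 1, 1, 0))
  fit <- fit_forest(d, "y", prior = pr, ntree = 40, seed = 2)
  imp <- permutation_importance(fit, seed = 2)
  expect_equal(imp$importance[imp$gene_id == "g5"], 0)
})

test_that("importance is centered at zero when labels are independent", {
  withr::with_seed(77, {
    means <- replicate(20, {
      n <- 40; p <- 8
      d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
      names(d) <- paste0("g", 1:p)
      d$y <- sample(rep(0:1, each = n / 2))
      fit <- fit_forest(d, "y", ntree = 60)
      mean(permutation_importance(fit)$importance)
    })
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means)), 3 * se + 1e-3)
  })
})

test_that("a guided forest agrees with an independent implementation on
           clearly separable data", {
  skip_if_not_installed("ranger")
  d <- make_signal_data(n = 80, p = 6, shift = 4)
  fit <- fit_forest(d, "y", ntree = 100, seed = 3)
  rf <- ranger::ranger(y = factor(d$y), x = d[, 1:6], num.trees = 100,
                       seed = 3)
  test <- make_signal_data(n = 80, p = 6, shift = 4, seed = 2)
  ours <- predict(fit, test)$.pred_class
  theirs <- as.integer(as.character(
    predict(rf, test[, 1:6])$predictions))
  expect_gt(mean(ours == test$y), 0.9)
  expect_gt(mean(theirs == test$y), 0.9)
  expect_gt(mean(ours == theirs), 0.9)
})
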
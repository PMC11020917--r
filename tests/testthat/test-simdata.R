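test_that("simulated networks partition genes into connected modules", {
  net <- simulate_network(p = 150, seed = 1)
  expect_equal(n_genes(net), 150)
  expect_setequal(net$modules$gene_id, net$gene_ids)
  expect_false(anyDuplicated(net$modules$gene_id) > 0)
  # construction joins every module: one component covering all genes
  comp <- igraph::components(
    igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                  vertices = net$gene_ids))
  expect_gte(max(comp$csize) / n_genes(net), 0.95)
  expect_true(all(table(net$modules$module) >= 3))
  # degenerate single-module case
  tiny <- simulate_network(p = 12, min_module_size = 12,
                           max_module_size = 12, seed = 2)
  expect_equal(length(unique(tiny$modules$module)), 1)
  expect_error(simulate_network(p = 5, min_module_size = 10,
                                max_module_size = 12), "exceed")
})

test_that("simulated degrees are heavy-tailed with dominant hubs", {
  hub_ratio <- vapply(1:10, function(s) {
    deg <- network_degrees(simulate_network(p = 300, seed = s))
    max(deg) / max(1, stats::median(deg))
  }, numeric(1))
  expect_gte(sum(hub_ratio >= 5), 9)
  # log-log regression of rank on degree over the top decile: a power-law
  # tail with exponent > 2 gives a slope below -1
  deg <- sort(as.integer(network_degrees(simulate_network(p = 1000, seed = 3))),
              decreasing = TRUE)
  top <- deg[seq_len(100)]
  fit <- stats::lm(log(seq_along(top)) ~ log(top + runif(100, 0, 1e-3)))
  expect_lt(unname(stats::coef(fit)[2]), -1)
})

test_that("expression counts are non-negative integers with NB-like marginals", {
  net <- simulate_network(p = 20, seed = 4)
  expr <- simulate_expression(net, n = 5000, seed = 5)
  X <- as.matrix(expr[, -1])
  expect_true(all(X >= 0))
  expect_true(all(X == round(X)))
  # mean-variance relation spans the configured NB marginals
  mu <- colMeans(X)
  expect_true(all(mu > 5 & mu < 6000))
  v <- apply(X, 2, var)
  phi_hat <- (v - mu) / mu^2
  expect_true(all(phi_hat > 0.03 & phi_hat < 1))
})

test_that("the copula transfers network dependence to counts", {
  # edgeless network: genes pairwise independent
  iso <- gene_network(data.frame(from = character(), to = character()),
                      genes = paste0("g", 1:10))
  expr <- simulate_expression(iso, n = 2000, seed = 6)
  cm <- cor(as.matrix(expr[, -1]), method = "spearman")
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)
  # a single strong edge leaves a clear rank correlation
  pair <- gene_network(data.frame(from = "g1", to = "g2"))
  expr2 <- simulate_expression(pair, n = 2000,
                               partial_range = c(0.6, 0.6), seed = 7)
  rho <- cor(expr2$g1, expr2$g2, method = "spearman")
  expect_gt(abs(rho), 0.3)
})

test_that("disease configurations obey the scenario contracts", {
  net <- simulate_network(p = 200, seed = 8)
  null_cfg <- assign_disease(net, "Null", beta = 2, seed = 1)
  expect_equal(nrow(null_cfg$genes), 0)

  ran <- assign_disease(net, "RanEqu", beta = 1.5, n_disease_genes = 10,
                        seed = 2)
  expect_equal(nrow(ran$genes), 10)
  expect_true(all(ran$genes$beta == 1.5))

  mod <- assign_disease(net, "ModEqu", beta = 2, seed = 3)
  m <- unique(mod$genes$module)
  expect_length(m, 1)
  expect_setequal(mod$genes$gene_id,
                  net$modules$gene_id[net$modules$module == m])
  expect_true(all(mod$genes$beta == 2))
  expect_equal(sum(mod$genes$beta), 2 * nrow(mod$genes))

  two <- assign_disease(net, "TwoModTopo", beta = 1, seed = 4)
  expect_length(unique(two$genes$module), 2)
  expect_equal(sum(two$genes$main), 2)
  expect_equal(sum(two$genes$beta), 1 * nrow(two$genes), tolerance = 1e-9)
  expect_error(assign_disease(net, "SomethingElse"), "unknown scenario")
})

test_that("effect sizes always sum to beta * |D|", {
  net <- simulate_network(p = 150, seed = 9)
  for (s in 1:20) {
    for (scen in c("RanEqu", "ModEqu", "ModTopo", "TwoModEqu", "TwoModTopo")) {
      beta <- sample(c(0.5, 1, 2), 1)
      cfg <- assign_disease(net, scen, beta = beta, seed = s)
      expect_lt(abs(sum(cfg$genes$beta) - beta * nrow(cfg$genes)), 1e-9)
    }
  }
})

test_that("connectivity-based effects decay with distance from the main gene", {
  # star module: hub as main gene -> hub beta largest, leaves equal
  star <- gene_network(data.frame(from = rep("H", 4), to = paste0("L", 1:4)),
                       modules = data.frame(gene_id = c("H", paste0("L", 1:4)),
                                            module = "M1"))
  for (s in 1:5) {
    cfg <- assign_disease(star, "ModTopo", beta = 1, n_disease_genes = 5,
                          seed = s)
    b <- stats::setNames(cfg$genes$beta, cfg$genes$gene_id)
    main <- cfg$genes$gene_id[cfg$genes$main]
    expect_equal(sum(b), 5, tolerance = 1e-9)
    if (main == "H") {
      expect_true(all(b["H"] > b[paste0("L", 1:4)]))
      expect_equal(unname(diff(range(b[paste0("L", 1:4)]))), 0,
                   tolerance = 1e-12)
      # analytic solve on the star (restart 0.3): hub = 0.3 / 0.51
      expect_equal(unname(b["H"]), 5 * 0.3 / 0.51, tolerance = 1e-6)
    } else {
      others <- setdiff(paste0("L", 1:4), main)
      expect_gt(b[main], max(b[others]))
      expect_gt(b["H"], max(b[others]))  # hub closer than sibling leaves
    }
  }
  # path module: effects non-increasing with hop distance from the main gene
  path <- gene_network(data.frame(from = paste0("P", 1:4),
                                  to = paste0("P", 2:5)),
                       modules = data.frame(gene_id = paste0("P", 1:5),
                                            module = "M1"))
  cfg <- assign_disease(path, "ModTopo", beta = 2, n_disease_genes = 5,
                        seed = 11)
  b <- stats::setNames(cfg$genes$beta,
                       as.integer(sub("P", "", cfg$genes$gene_id)))
  main_pos <- as.integer(sub("P", "", cfg$genes$gene_id[cfg$genes$main]))
  left <- b[as.character(main_pos:1)]
  right <- b[as.character(main_pos:5)]
  expect_true(all(diff(unname(left)) <= 1e-12))
  expect_true(all(diff(unname(right)) <= 1e-12))
})

test_that("phenotypes follow the logistic disease model", {
  # Null: fair coin flips
  net <- simulate_network(p = 20, seed = 12)
  expr <- simulate_expression(net, n = 4000, seed = 13)
  null_cfg <- assign_disease(net, "Null", seed = 1)
  y <- simulate_phenotype(expr, null_cfg, seed = 14)$phenotype
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 4000))

  # logistic saturation: one gene with a huge effect -> y = 1(X > 0)
  one <- tibble::tibble(sample_id = paste0("s", 1:500), gA = rnorm(500))
  cfg <- structure(list(
    scenario = "RanEqu", beta = 50, intercept = 0,
    genes = tibble::tibble(gene_id = "gA", beta = 50, module = NA, main = FALSE)
  ), class = "disease_config")
  y <- simulate_phenotype(one, cfg, seed = 15)$phenotype
  xs <- scale(one$gA)[, 1]
  expect_gt(mean(y == as.integer(xs > 0)), 0.98)

  # conditional case probability near expit(1) for X near 1 (beta = 1)
  big <- tibble::tibble(sample_id = paste0("s", 1:20000), gA = rnorm(20000))
  cfg1 <- structure(list(
    scenario = "RanEqu", beta = 1, intercept = 0,
    genes = tibble::tibble(gene_id = "gA", beta = 1, module = NA, main = FALSE)
  ), class = "disease_config")
  y <- simulate_phenotype(big, cfg1, seed = 16)$phenotype
  xs <- scale(big$gA)[, 1]
  bin <- xs > 0.9 & xs < 1.1
  p_hat <- mean(y[bin])
  se <- sqrt(plogis(1) * (1 - plogis(1)) / sum(bin))
  expect_lt(abs(p_hat - plogis(1)), 3 * se + 0.01)

  expect_error(simulate_phenotype(one, structure(list(
    scenario = "RanEqu", beta = 1, intercept = 0,
    genes = tibble::tibble(gene_id = "nope", beta = 1, module = NA,
                           main = FALSE)), class = "disease_config")),
    "absent")
})

test_that("replications split evenly, reproduce, and can share a network", {
  rep1 <- simulate_replication("Null", p = 30, n = 40, seed = 17)
  expect_equal(nrow(rep1$train$expression), 20)
  expect_equal(nrow(rep1$test$expression), 20)
  expect_length(intersect(rep1$train$expression$sample_id,
                          rep1$test$expression$sample_id), 0)
  rep2 <- simulate_replication("Null", p = 30, n = 40, seed = 17)
  expect_identical(rep1$train$expression, rep2$train$expression)
  expect_identical(rep1$network$edges, rep2$network$edges)

  net <- simulate_network(p = 30, seed = 18)
  shared <- lapply(1:3, function(s) {
    simulate_replication("Null", n = 20, network = net, seed = s)
  })
  for (r in shared) expect_identical(r$network$edges, net$edges)
  expect_false(identical(shared[[1]]$train$expression,
                         shared[[2]]$train$expression))
  expect_error(simulate_replication("Null", p = 10, n = 9), "even")
})
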
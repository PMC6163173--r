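# Per-module statistics: connectivity, hubs, stability, RSD, condition
# association.

test_that("within-module connectivity matches hand-computed values", {
  ## g2 and g3 identical, g1 orthogonal to both (exact cor 0 on log2 scale)
  expr <- 2^rbind(g1 = c(1, -1, 1, -1),
                  g2 = c(1, 1, -1, -1),
                  g3 = c(2, 2, -2, -2))
  colnames(expr) <- paste0("s", 1:4)
  part <- setNames(rep("m", 3), rownames(expr))
  k <- within_module_connectivity(expr, part, beta = 1)[["m"]]
  expect_equal(k, c(g1 = 1.0, g2 = 1.5, g3 = 1.5))
  ## all pairwise cor 1 -> k = size - 1
  expr2 <- 2^rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(0.5, 1, 1.5))
  colnames(expr2) <- paste0("s", 1:3)
  k2 <- within_module_connectivity(expr2, setNames(rep("m", 3), rownames(expr2)),
                                   beta = 5)[["m"]]
  expect_equal(unname(k2), rep(2, 3))
  ## permuting gene order leaves each gene's k unchanged
  k3 <- within_module_connectivity(expr[c(3, 1, 2), ], part, beta = 1)[["m"]]
  expect_equal(k3[names(k)], k)
})

test_that("hub ranking follows k with ID tie-break and planted loadings", {
  k_by <- list(m = c(g1 = 1.0, g3 = 1.5, g2 = 1.5))
  h <- hub_genes(k_by, top_n = 1)
  expect_equal(h$gene, "g2")          # tie between g2/g3 broken by ID
  h_all <- hub_genes(k_by, top_n = 10)
  expect_equal(h_all$gene, c("g2", "g3", "g1"))
  expect_error(hub_genes(k_by, 0), "top_n")

  ## connectivity ranks track planted loadings across seeds
  spearman_ok <- 0
  for (seed in 1:15) {
    sim <- generate_expression(synthetic_config(
      n_samples = 120, module_sizes = c(30), n_background = 0,
      factor_strength = 0.9, noise_sd = 0.3, loading_jitter = 0.5,
      seed = seed))
    part <- setNames(rep("m", 30), rownames(sim$expr))
    k <- within_module_connectivity(sim$expr, part, beta = 6)[["m"]]
    rho <- cor(k[names(sim$truth$loadings)], sim$truth$loadings,
               method = "spearman")
    spearman_ok <- spearman_ok + (rho >= 0.8)
  }
  expect_gte(spearman_ok / 15, 0.9)

  ## a planted, clearly separated hub is identified in nearly every seed:
  ## one gene carries twice the loading of the others
  hub_hits <- 0
  for (seed in 1:15) {
    set.seed(seed)
    n_s <- 80
    f <- rnorm(n_s)
    b <- c(1.8, rep(0.9, 9))
    x <- exp(outer(b, f) + rnorm(10 * n_s, sd = 0.3) + log(500))
    dimnames(x) <- list(paste0("g", sprintf("%02d", 1:10)),
                        paste0("s", seq_len(n_s)))
    k <- within_module_connectivity(
      x, setNames(rep("m", 10), rownames(x)), beta = 6)[["m"]]
    hub_hits <- hub_hits + (hub_genes(list(m = k), 1)$gene == "g01")
  }
  expect_gte(hub_hits / 15, 0.9)
})

test_that("stability is exactly 1 on noise-free data and reproducible", {
  sim0 <- generate_expression(synthetic_config(
    n_samples = 30, module_sizes = c(10, 12), n_background = 0,
    noise_sd = 0, seed = 5))
  part <- sim0$truth$partition
  rep1 <- stability_resampling(sim0$expr, part, beta = 6,
                               stability_params(n_iterations = 20, seed = 3))
  expect_equal(rep1$mean_correlation, c(1, 1))
  expect_equal(rep1$sd_correlation, c(0, 0))
  rep2 <- stability_resampling(sim0$expr, part, beta = 6,
                               stability_params(n_iterations = 20, seed = 3))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("stability decays monotonically with noise", {
  means <- vapply(c(0.15, 0.6, 1.2), function(ns) {
    sim <- generate_expression(synthetic_config(
      n_samples = 40, module_sizes = c(25), n_background = 0,
      factor_strength = 0.9, noise_sd = ns, seed = 11))
    st <- stability_resampling(sim$expr, sim$truth$partition, beta = 6,
                               stability_params(n_iterations = 30, seed = 2))
    st$mean_correlation
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("stability input contracts are enforced", {
  sim <- generate_expression(synthetic_config(
    n_samples = 10, module_sizes = c(4, 2), n_background = 0, seed = 1))
  expect_warning(
    st <- stability_resampling(sim$expr, sim$truth$partition, beta = 2,
                               stability_params(n_iterations = 5, seed = 1)),
    "skipped")
  expect_true(st$skipped[st$module == "M2"])
  expect_true(is.na(st$mean_correlation[st$module == "M2"]))
  expect_error(stability_resampling(sim$expr[, 1:4], sim$truth$partition, 2,
                                    stability_params(5, seed = 1)),
               "6 samples")
  expect_error(stability_params(sample_fraction = 1), "sample_fraction")
})

test_that("RSD matches hand values and is scale invariant", {
  expr <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(20, 40, 60))
  colnames(expr) <- paste0("s", 1:3)
  part <- c(a = "m1", b = "m1", c = "m2")
  r <- module_rsd(expr, part)
  expect_equal(unname(r$gene_rsd["a"]), 0.5)   # mean 4, sample sd 2
  expect_equal(unname(r$gene_rsd["b"]), 0)
  expect_equal(unname(r$gene_rsd["c"]), 0.5)   # scale invariance: 10x gene a
  expect_equal(unname(r$module_rsd["m1"]), 0.25)
  ## non-positive values indicate log-scale input passed by mistake
  expect_error(module_rsd(expr - 2, part), "positive")
})

test_that("condition association finds planted shifts and breaks ties", {
  labels <- rep(c("control", "treated"), each = 20)
  sim <- generate_expression(synthetic_config(
    n_samples = 40, module_sizes = c(15, 15), n_background = 0,
    factor_strength = 0.9, noise_sd = 0.2,
    condition_labels = labels,
    condition_effects = list(M1 = c(treated = 1.5)), seed = 6))
  eig <- module_eigengenes(sim$expr, sim$truth$partition)
  ca <- condition_association(eig, labels)
  expect_equal(unname(ca$best_condition["M1"]), "treated")
  expect_equal(colnames(ca$means), c("control", "treated"))
  ## single condition: that condition for every module
  ca1 <- condition_association(eig, rep("only", 40))
  expect_equal(unname(ca1$best_condition), rep("only", 2))
  ## exact tie -> lexicographically first label
  E <- rbind(m = c(1, -1, -1, 1))
  colnames(E) <- paste0("s", 1:4)
  fake <- fake_eigengene_set(E)
  ca2 <- condition_association(fake, c("b", "a", "b", "a"))
  expect_equal(unname(ca2$best_condition["m"]), "a")
  expect_error(condition_association(eig, labels[1:10]), "one entry")
})
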
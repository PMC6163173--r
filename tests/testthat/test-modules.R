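# Module detection: UPGMA dendrogram, the tree cut variant, membership
# shedding, eigengenes.

test_that("UPGMA merges match hand computation", {
  ## 3 points: d(1,2) = 0.1, d(1,3) = d(2,3) = 0.5
  d <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.5,
                0.5, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  hc <- coexp_dendrogram(d)
  expect_equal(hc$height, c(0.1, 0.5))
  ## two perfect blocks merge last at exactly the between-block distance
  blocks <- matrix(1, 10, 10) - diag(10)
  blocks[1:5, 6:10] <- blocks[6:10, 1:5] <- 1
  blocks[1:5, 1:5] <- blocks[6:10, 6:10] <- 0
  dimnames(blocks) <- list(paste0("g", 1:10), paste0("g", 1:10))
  hc2 <- coexp_dendrogram(blocks)
  expect_equal(max(hc2$height), 1)
  expect_equal(hc2$height[1:8], rep(0, 8))
  two <- cutree(hc2, k = 2)
  expect_length(unique(two[1:5]), 1)
  expect_length(unique(two[6:10]), 1)
  ## identical rows: all merges at height 0
  expect_equal(coexp_dendrogram(matrix(0, 4, 4))$height, rep(0, 3))
  expect_error(coexp_dendrogram(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("tree cut resolves forced block geometry", {
  ## two perfect blocks of 50: exactly 2 modules, zero grey
  d <- matrix(1, 100, 100)
  d[1:50, 1:50] <- 0; d[51:100, 51:100] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:100), paste0("g", 1:100))
  part <- cut_modules(coexp_dendrogram(d), cut_params(min_module_size = 30))
  expect_equal(sum(part == "grey"), 0)
  expect_length(module_members(part), 2)
  expect_length(unique(part[paste0("g", 1:50)]), 1)
  ## labels are deterministic color names by size rank
  expect_setequal(unique(part), c("turquoise", "blue"))
  ## one homogeneous block (identical rows) -> 1 module
  d1 <- matrix(0, 40, 40)
  dimnames(d1) <- list(paste0("g", 1:40), paste0("g", 1:40))
  p1 <- cut_modules(coexp_dendrogram(d1), cut_params(min_module_size = 10))
  expect_length(module_members(p1), 1)
  expect_error(cut_modules(coexp_dendrogram(d1), cut_params(min_module_size = 40)),
               "smaller")
})

test_that("deep split separates nested blocks, gap rule gates it", {
  ## two tight sub-blocks (within 0.1) joined at 0.5, background at 1.0:
  ## the static cut isolates the 40-leaf branch; deep_split = 2 with a clear
  ## gap (0.5 - 0.1 >= gap) splits it into the two sub-blocks
  n <- 50
  d <- matrix(1, n, n)
  d[1:20, 1:20] <- 0.1; d[21:40, 21:40] <- 0.1
  d[1:40, 1:40][d[1:40, 1:40] == 1] <- 0.5
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  dend <- coexp_dendrogram(d)
  p_split <- cut_modules(dend, cut_params(min_module_size = 10,
                                          deep_split = 2,
                                          gap_threshold = 0.05))
  expect_length(module_members(p_split), 2)
  expect_length(unique(p_split[paste0("g", 1:20)]), 1)
  ## deep_split = 0 keeps the joined branch as one module
  p_flat <- cut_modules(dend, cut_params(min_module_size = 10,
                                         deep_split = 0))
  expect_length(module_members(p_flat), 1)
  ## a gap threshold larger than the 0.4 height step also blocks the split
  p_gap <- cut_modules(dend, cut_params(min_module_size = 10, deep_split = 2,
                                        gap_threshold = 0.45))
  expect_length(module_members(p_gap), 1)
})

test_that("planted modules are recovered irrespective of gene order", {
  part <- detect_small()
  truth <- small_sim$truth$partition
  assigned <- part != "grey"
  ari <- adjusted_rand_index(part[assigned], truth[names(part)[assigned]])
  expect_gte(ari, 0.9)
  ## permutation invariance on noise-free block data: identical partitions
  sim0 <- generate_expression(synthetic_config(
    n_samples = 30, module_sizes = c(35, 40), n_background = 0,
    noise_sd = 0, seed = 12))
  detect0 <- function(e) {
    tom <- topological_overlap(signed_adjacency(correlation_matrix(e), 6))
    cut_modules(coexp_dendrogram(tom_dissimilarity(tom)))
  }
  p0 <- detect0(sim0$expr)
  set.seed(99)
  perm <- sample(rownames(sim0$expr))
  p_perm <- detect0(sim0$expr[perm, ])
  expect_equal(adjusted_rand_index(p0[names(p0)], p_perm[names(p0)]), 1)
})

test_that("eigengenes match forced geometries and beat random vectors", {
  ## identical genes: eigengene is the standardized common profile, VE = 1
  prof <- 2^rnorm(12, 8)
  expr <- matrix(rep(prof, each = 5) * 2^rnorm(60, sd = 0), 5, 12)
  expr <- expr * matrix(2^runif(5, -1, 1), 5, 12)  # per-gene scale shifts
  dimnames(expr) <- list(paste0("g", 1:5), paste0("s", 1:12))
  eig <- module_eigengenes(expr, setNames(rep("m1", 5), rownames(expr)))
  expect_equal(unname(eig$variance_explained["m1"]), 1, tolerance = 1e-12)
  zprof <- scale(log2(prof))[, 1]
  expect_equal(abs(cor(eig$E["m1", ], zprof)), 1, tolerance = 1e-12)
  expect_gte(cor(eig$E["m1", ], zprof), 0)          # sign convention
  expect_equal(sum(eig$E["m1", ]^2), 1)             # unit norm

  ## two orthogonal standardized genes: equal singular values, VE = 0.5
  x1 <- c(1, -1, 1, -1); x2 <- c(1, 1, -1, -1)
  expr2 <- 2^rbind(a = x1, b = x2)
  colnames(expr2) <- paste0("s", 1:4)
  eig2 <- module_eigengenes(expr2, c(a = "m", b = "m"))
  expect_equal(unname(eig2$variance_explained["m"]), 0.5)

  ## optimality: eigengene variance share >= 1000 random unit vectors
  genes <- module_members(detect_small())[[1]][1:10]
  xs <- t(scale(t(log2(small_sim$expr[genes, ]))))
  eig3 <- module_eigengenes(small_sim$expr[genes, ],
                            setNames(rep("m", 10), genes))
  total <- sum(xs^2)
  set.seed(7)
  for (i in 1:1000) {
    v <- rnorm(ncol(xs)); v <- v / sqrt(sum(v^2))
    expect_lte(sum((xs %*% v)^2) / total,
               eig3$variance_explained["m"] + 1e-12)
  }
})

test_that("eigengene recovers the planted factor", {
  part <- detect_small()
  eig <- module_eigengenes(small_sim$expr, part)
  truth <- small_sim$truth
  for (m in rownames(eig$E)) {
    genes <- module_members(part)[[m]]
    planted <- names(which.max(table(truth$partition[genes])))
    expect_gte(abs(cor(eig$E[m, ], truth$factors[planted, ])), 0.95)
  }
})

test_that("eigengene edge cases: zero-variance gene dropped, empty errors", {
  expr <- 2^rbind(a = rnorm(6), b = rnorm(6), c = rep(1, 6))
  colnames(expr) <- paste0("s", 1:6)
  expect_warning(
    eig <- module_eigengenes(expr, c(a = "m", b = "m", c = "m")),
    "zero-variance")
  expect_equal(unname(eig$n_genes["m"]), 2L)
  expect_error(module_eigengenes(expr, c(a = "grey", b = "grey", c = "grey")),
               "no modules")
})

test_that("shedding removes weakly attached genes, keeps module cores", {
  part_raw <- detect_small(shed = FALSE)
  part <- shed_low_membership(small_sim$expr, part_raw)
  truth <- small_sim$truth$partition
  ## every background gene assigned by the raw cut is shed
  for (m in names(module_members(part)))
    expect_true(all(truth[module_members(part)[[m]]] != "background"))
  ## module cores survive
  expect_gte(sum(part != "grey"), 0.9 * sum(truth != "background"))
  expect_error(shed_low_membership(small_sim$expr, part_raw, 2), "kme_threshold")
})

test_that("grey is excluded from per-module statistics", {
  part <- detect_small()
  expect_false("grey" %in% names(module_members(part)))
  eig <- module_eigengenes(small_sim$expr, part)
  expect_false("grey" %in% rownames(eig$E))
  rsd <- module_rsd(small_sim$expr, part)
  expect_false("grey" %in% names(rsd$module_rsd))
  k <- within_module_connectivity(small_sim$expr, part, 6)
  expect_false("grey" %in% names(k))
})
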
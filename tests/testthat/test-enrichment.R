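# Hypergeometric machinery: log tail, BH, gene-set / positional / overlap
# enrichment, and the packaged annotation catalog.

test_that("log tail matches exact enumeration on the worked example", {
  ## N=10, K=5, n=4, k=3: (C(5,3)C(5,1) + C(5,4)C(5,0)) / C(10,4) = 55/210
  expect_equal(hypergeom_log_tail(10, 5, 4, 3), log10(55 / 210))
  expect_equal(hypergeom_log_tail(10, 5, 4, 0), 0)
  expect_equal(hypergeom_log_tail(8, 8, 8, 8), 0)   # forced draw
  expect_error(hypergeom_log_tail(10, 5, 4, 5), "min")
  expect_error(hypergeom_log_tail(10, 12, 4, 1), "N")
})

test_that("log tail agrees with the rational oracle for all N <= 30", {
  for (N in 2:30) {
    for (K in 0:N) {
      for (n in c(0, 1, N %/% 3, N %/% 2, N - 1, N)) {
        ks <- max(0, n + K - N):min(n, K)
        got <- hypergeom_log_tail(N, K, n, ks)
        want <- log10(vapply(ks, function(k) hyper_tail_oracle(N, K, n, k),
                             numeric(1)))
        expect_equal(got, pmin(want, 0), tolerance = 1e-10)
      }
    }
  }
})

test_that("log tail survives far below double underflow", {
  lp <- hypergeom_log_tail(14068, 1421, 912, 912)
  expect_lt(lp, -1000)
  expect_true(is.finite(lp))
  ## cross-check a deep tail against R's phyper in log space
  lp2 <- hypergeom_log_tail(5000, 500, 400, 200)
  ref <- phyper(199, 500, 4500, 400, lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_equal(lp2, ref, tolerance = 1e-9)
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  ## independent direct implementation + stats::p.adjust on random input
  direct_bh <- function(p) {
    ## adj_(i) = min(1, min_{j >= i} p_(j) * m / j), original order restored
    m <- length(p); o <- order(p); ps <- p[o]
    ref <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
                  numeric(1))
    adj <- numeric(m); adj[o] <- ref
    adj
  }
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(50)^2
    got <- bh_adjust(p)
    expect_equal(got, direct_bh(p))
    expect_equal(got, p.adjust(p, "BH"))
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene-set enrichment ranks the true set first", {
  sim <- generate_expression(synthetic_config(
    n_samples = 30, module_sizes = c(20, 25), n_background = 80, seed = 13))
  sets <- generate_gene_sets(sim$truth, n_decoy_sets = 15, seed = 2)
  background <- rownames(sim$expr)
  m1 <- names(sim$truth$partition)[sim$truth$partition == "M1"]
  tab <- enrich_gene_sets(m1, sets, background)
  expect_s3_class(tab, "enrichment_table")
  expect_equal(tab$term[1], "M1")
  expect_equal(tab$k[1], 20)
  expect_equal(tab$adjusted_p[1], min(tab$adjusted_p))
  ## disjoint term has p = 1; duplicates in input sets do not matter
  disjoint <- setdiff(background, m1)[1:10]
  tab2 <- enrich_gene_sets(m1, list(d = disjoint, dd = c(m1, m1)), background)
  expect_equal(tab2$p[tab2$term == "d"], 1)
  expect_equal(tab2$log10_p[tab2$term == "dd"],
               enrich_gene_sets(m1, list(dd = m1), background)$log10_p)
  ## invariants: adjusted >= raw, query must live in the background
  expect_true(all(tab$adjusted_p >= tab$p))
  expect_error(enrich_gene_sets(c(m1, "not_a_gene"), sets, background),
               "missing from background")
  expect_warning(enrich_gene_sets(m1, list(M1 = m1, out = c("x", "y")),
                                  background), "skipped")
})

test_that("positional enrichment finds a fully clustered module", {
  sim <- generate_expression(synthetic_config(
    n_samples = 12, module_sizes = c(50), n_background = 950,
    position_clustering = 1, n_chromosomes = 5, seed = 17))
  pos <- generate_positions(sim$truth, seed = 1)
  m1 <- names(sim$truth$partition)[sim$truth$partition == "M1"]
  hits <- positional_enrichment(m1, pos, window_size = 50, step = 25,
                                p_threshold = 7e-7)
  expect_gte(nrow(hits), 1)
  expect_lt(hits$log10_p[1], log10(7e-7))
  ## the theoretical best window: k = n = K = 50 in N = 1000
  best <- hypergeom_log_tail(1000, 50, 50, 50)
  expect_lte(best, hits$log10_p[1])
  expect_error(positional_enrichment(c(m1, "zzz"), pos), "without positions")
})

test_that("scattered modules rarely reach the positional threshold", {
  fp <- 0
  n_seeds <- 60
  for (seed in seq_len(n_seeds)) {
    sim <- generate_expression(synthetic_config(
      n_samples = 6, module_sizes = c(50), n_background = 950,
      position_clustering = 0, n_chromosomes = 5, seed = seed))
    pos <- generate_positions(sim$truth, seed = seed)
    m1 <- names(sim$truth$partition)[sim$truth$partition == "M1"]
    hits <- positional_enrichment(m1, pos, window_size = 50, step = 25,
                                  p_threshold = 7e-7)
    if (nrow(hits) > 0) fp <- fp + 1
  }
  expect_gte((n_seeds - fp) / n_seeds, 0.95)
})

test_that("overlap comparison is symmetric and handles edge cases", {
  a <- paste0("g", 1:40); b <- paste0("g", 31:100)
  o_ab <- overlap_comparison(a, b, 500)
  o_ba <- overlap_comparison(b, a, 500)
  expect_equal(o_ab$k, 10)
  expect_equal(o_ab$log10_p, o_ba$log10_p)   # hypergeometric duality
  expect_equal(o_ab$fraction_of_a, 10 / 40)
  expect_equal(o_ba$fraction_of_a, 10 / 70)
  ## disjoint sets: k = 0, p = 1
  o_dis <- overlap_comparison(paste0("x", 1:5), paste0("y", 1:5), 100)
  expect_equal(o_dis$k, 0)
  expect_equal(o_dis$log10_p, 0)
  ## certain overlap: set_b is the whole background
  o_all <- overlap_comparison(paste0("g", 1:10), paste0("g", 1:50), 50)
  expect_equal(o_all$log10_p, 0)
  expect_error(overlap_comparison(paste0("g", 1:40), paste0("g", 1:40), 30),
               "background")
})

test_that("the packaged catalog answers the counting queries", {
  cat48 <- module_annotation_catalog()
  expect_equal(nrow(cat48), 48)
  expect_true(all(cat48$n_genes > 0))
  expect_equal(count_modules_by_term(
    cat48, "BP", "Embryo development ending in birth or egg hatching"), 10)
  expect_equal(count_modules_by_term(cat48, "BP", "ion transport"), 3)
  expect_equal(count_modules_by_term(cat48, "BP", "nonexistent term"), 0)
  expect_equal(count_modules_by_term(cat48, "CC", "mitochondrion"), 4)
  expect_equal(count_modules_by_term(cat48, "chromosome", "X"), 11)
  expect_error(count_modules_by_term(cat48, "ZZ", "x"), "field")
})
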
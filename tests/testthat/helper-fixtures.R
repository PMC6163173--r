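# Shared fixtures, built in code at test time. Kept small so the whole
# suite stays fast; the acceptance tests build their own full-size data.

## Small planted dataset used across module/statistics tests:
## 3 modules (40, 50, 60 genes) + 60 background, 60 samples, ratio 3.
small_sim <- generate_expression(synthetic_config(
  n_samples = 60, module_sizes = c(40, 50, 60), n_background = 60,
  factor_strength = 0.9, noise_sd = 0.3, seed = 42))

## Deterministic partition recovery for the small dataset at power 10.
detect_small <- function(beta = 10, shed = TRUE) {
  cc <- correlation_matrix(small_sim$expr)
  tom <- topological_overlap(signed_adjacency(cc, beta))
  part <- cut_modules(coexp_dendrogram(tom_dissimilarity(tom)))
  if (shed) part <- shed_low_membership(small_sim$expr, part)
  part
}

## Random symmetric adjacency in [0,1] with unit diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

## Brute-force triple-loop TOM oracle (independent of the matrix-product
## implementation path).
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      out[i, j] <- out[j, i] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(adj)
  out
}

## Exact hypergeometric upper-tail oracle by direct enumeration with
## choose(); exact in double precision for small N.
hyper_tail_oracle <- function(N, K, n, k) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Minimal eigengene_set constructor for meta-network tests.
fake_eigengene_set <- function(E) {
  E <- E / sqrt(rowSums(E^2))
  structure(list(E = E,
                 variance_explained = stats::setNames(rep(NA_real_, nrow(E)),
                                                      rownames(E)),
                 n_genes = stats::setNames(rep(2L, nrow(E)), rownames(E))),
            class = "eigengene_set")
}

expect_symmetric <- function(m) expect_equal(max(abs(m - t(m))), 0)
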
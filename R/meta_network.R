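# Higher-order analysis: a co-expression network over module eigengenes,
# meta-modules, module global connectivity, top edges, and a Welch test
# between connectivity groups.

#' Eigengene meta-network and meta-modules
#'
#' Treats module eigengenes as genes and re-runs the same network pipeline
#' on them: Pearson correlation, signed adjacency at `meta_power`,
#' topological overlap, average-linkage clustering, and the dynamic tree cut
#' variant with a small minimum module size. The result groups modules into
#' meta-modules and quantifies module-module connectivity.
#'
#' Eigengenes are already centered, signed quantities, so no log transform
#' is applied at the correlation step.
#'
#' @param eigengenes an `eigengene_set` from [module_eigengenes()] with at
#'   least 3 modules.
#' @param meta_power soft-threshold power for the module network
#'   (default 3).
#' @param min_module_size minimum meta-module size (default 2).
#' @param deep_split,cut_height_fraction,gap_threshold tree cut settings,
#'   as in [cut_params()].
#' @return an object of class `meta_network`: list with `adjacency`
#'   (module x module signed adjacency), `tom`, `dendrogram`,
#'   `meta_partition` (named vector module -> meta-module label, `"grey"`
#'   possible), and `connectivity` (named vector of module global
#'   connectivities, self excluded).
#' @export
eigengene_meta_modules <- function(eigengenes, meta_power = 3,
                                   min_module_size = 2, deep_split = 2,
                                   cut_height_fraction = 0.995,
                                   gap_threshold = 0.05) {
  stopifnot(inherits(eigengenes, "eigengene_set"))
  E <- eigengenes$E
  if (nrow(E) < 3) stop("need at least 3 modules for a meta-network")
  if (min_module_size > nrow(E))
    stop("min_module_size exceeds the number of modules")
  cc <- correlation_matrix(E, log_transform = FALSE)
  adj <- signed_adjacency(cc, meta_power)
  tom <- topological_overlap(adj)
  dend <- coexp_dendrogram(tom_dissimilarity(tom))
  part <- cut_modules(dend, cut_params(min_module_size = min_module_size,
                                       deep_split = deep_split,
                                       cut_height_fraction = cut_height_fraction,
                                       gap_threshold = gap_threshold))
  structure(list(adjacency = adj, tom = tom, dendrogram = dend,
                 meta_partition = part,
                 connectivity = connectivity(adj),
                 meta_power = meta_power),
            class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat("Eigengene meta-network:", nrow(x$adjacency), "modules, power",
      x$meta_power, "\n")
  nm <- setdiff(unique(x$meta_partition), "grey")
  cat("meta-modules:", length(nm), "\n")
  print(table(x$meta_partition))
  invisible(x)
}

#' Rank modules by global connectivity in the meta-network
#'
#' @param meta a `meta_network` object.
#' @return data.frame with columns `module`, `k`, `rank`, sorted by
#'   decreasing connectivity (ties broken by module label). The most
#'   connected modules sit at the top; specialized, weakly coupled modules
#'   at the bottom.
#' @export
module_global_connectivity <- function(meta) {
  stopifnot(inherits(meta, "meta_network"))
  k <- meta$connectivity
  ord <- order(-k, names(k))
  data.frame(module = names(k)[ord], k = unname(k[ord]),
             rank = seq_along(k), stringsAsFactors = FALSE)
}

#' Strongest edges of the meta-network
#'
#' @param meta a `meta_network` object.
#' @param n_edges number of edges to keep (default 100). If more edges are
#'   requested than unordered pairs exist, all pairs are returned with a
#'   warning.
#' @return data.frame with columns `module_i`, `module_j`, `weight`
#'   (adjacency), sorted by decreasing weight, ties broken by the label
#'   pair; no self edges, no duplicate pairs.
#' @export
top_edges <- function(meta, n_edges = 100) {
  stopifnot(inherits(meta, "meta_network"))
  if (n_edges < 1) stop("n_edges must be >= 1")
  adj <- meta$adjacency
  ids <- rownames(adj)
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  df <- data.frame(module_i = ids[idx[, 1]], module_j = ids[idx[, 2]],
                   weight = adj[idx], stringsAsFactors = FALSE)
  ## canonical unordered pair order
  swap <- df$module_i > df$module_j
  tmp <- df$module_i[swap]; df$module_i[swap] <- df$module_j[swap]
  df$module_j[swap] <- tmp
  df <- df[order(-df$weight, df$module_i, df$module_j), ]
  rownames(df) <- NULL
  if (n_edges > nrow(df)) {
    warning("only ", nrow(df), " module pairs available; returning all")
    n_edges <- nrow(df)
  }
  utils::head(df, n_edges)
}

#' Welch two-sample t-test between connectivity groups
#'
#' Compares mean connectivity between two groups of modules (e.g. broadly
#' coupled versus functionally specialized) with an unequal-variance
#' two-sided t-test.
#'
#' @param group_a,group_b numeric vectors of connectivity values, each with
#'   at least 2 entries.
#' @return list with `t_statistic`, `df`, `p_value`. When both groups have
#'   zero variance: equal means give `t = 0, p = 1` by convention; unequal
#'   means give an infinite statistic with `p = 0`.
#' @export
connectivity_group_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  na <- length(group_a); nb <- length(group_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) return(list(t_statistic = 0, df = na + nb - 2, p_value = 1))
    return(list(t_statistic = sign(ma - mb) * Inf, df = na + nb - 2,
                p_value = 0))
  }
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_statistic = t_stat, df = df, p_value = p)
}
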
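# Signed weighted co-expression network construction:
# Pearson correlation -> beta-power signed adjacency -> topological overlap,
# with connectivity and scale-free soft-threshold selection.

#' Drop zero-variance genes before correlation
#'
#' Pearson correlation is undefined for constant genes, and silently
#' propagated NaNs are the worst failure mode of a correlation network, so
#' [correlation_matrix()] treats them as an error. This pre-filter removes
#' such genes explicitly, with a warning naming how many were dropped.
#'
#' @param expr genes x samples numeric matrix.
#' @param log_transform apply `log2` before measuring variance, matching the
#'   transform used by [correlation_matrix()].
#' @return the filtered expression matrix.
#' @export
filter_zero_variance <- function(expr, log_transform = TRUE) {
  check_expression(expr)
  x <- if (log_transform) log2(expr) else expr
  v <- apply(x, 1, stats::var)
  bad <- v == 0 | !is.finite(v)
  if (any(bad)) {
    warning(sum(bad), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(expr)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' Pairwise Pearson correlation between gene expression profiles
#'
#' @param expr genes x samples numeric matrix with >= 3 samples.
#' @param log_transform compute correlations on `log2` expression (default).
#'   MAS5-scale values are heavily right-skewed, so the log scale is the
#'   better linear-correlation substrate; pass `FALSE` for data already on a
#'   log or otherwise symmetric scale (e.g. eigengenes).
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, log_transform = TRUE) {
  check_expression(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples for correlation")
  x <- if (log_transform) log2(expr) else expr
  v <- apply(x, 1, stats::var)
  if (any(v == 0 | !is.finite(v)))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0 | !is.finite(v)], 10),
               collapse = ", "),
         "; use filter_zero_variance() first")
  cc <- stats::cor(t(x))
  ## guard against floating-point excursions beyond [-1, 1]
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`: perfectly anti-correlated genes get
#' weight 0, perfectly correlated genes weight 1, uncorrelated genes
#' `0.5 ^ beta`. Raising to the power `beta` suppresses weak edges without a
#' hard cutoff.
#'
#' @param cor_mat symmetric correlation matrix in `[-1, 1]`.
#' @param beta integer soft-threshold power, >= 1.
#' @return adjacency matrix in `[0, 1]` with the same dimnames; the diagonal
#'   is 1 but is excluded from all connectivity sums.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  check_square_symmetric(cor_mat, "correlation matrix")
  if (length(beta) != 1 || beta < 1 || beta != round(beta))
    stop("beta must be a single integer >= 1")
  ((1 + cor_mat) / 2) ^ beta
}

#' Network connectivity
#'
#' `k_i = sum_{j != i} a_ij`, the total adjacency of gene `i` to all other
#' genes. Within a module, high-`k` genes are the hub genes.
#'
#' @param adj adjacency matrix in `[0, 1]`.
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  check_square_symmetric(adj, "adjacency matrix")
  rowSums(adj) - diag(adj)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivity into `n_bins` equal-width bins, then regresses
#' `log10(frequency)` on `log10(mean k)` over non-empty bins. Returns the
#' signed fit index `-sign(slope) * R^2`, so that only distributions with a
#' decreasing log-log relationship (the scale-free signature) score close
#' to +1.
#'
#' @param k numeric vector of connectivities with >= 2 nonzero values.
#' @param n_bins number of equal-width bins, >= 3 (default 10).
#' @return a list with `r2_signed`, `slope`, and `degenerate` (TRUE when
#'   fewer than two usable bins exist, in which case `r2_signed` is 0).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  k <- k[is.finite(k)]
  if (sum(k > 0) < 2) stop("need at least 2 nonzero connectivity values")
  if (diff(range(k)) == 0)
    return(list(r2_signed = 0, slope = NA_real_, degenerate = TRUE))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(seq_len(n_bins), function(b) mean(k[as.integer(bin) == b]),
                  numeric(1))
  use <- freq > 0 & kmean > 0
  if (sum(use) < 2)
    return(list(r2_signed = 0, slope = NA_real_, degenerate = TRUE))
  x <- log10(kmean[use])
  y <- log10(freq[use])
  if (stats::var(x) == 0)
    return(list(r2_signed = 0, slope = NA_real_, degenerate = TRUE))
  slope <- stats::cov(x, y) / stats::var(x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  list(r2_signed = -sign(slope) * r2, slope = slope, degenerate = FALSE)
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the signed adjacency, measures the
#' scale-free fit of its connectivity distribution, and picks the smallest
#' power whose signed `R^2` reaches `r2_cutoff`. If no candidate qualifies,
#' the candidate maximizing the fit is returned with a warning flag.
#'
#' @param expr genes x samples numeric matrix.
#' @param candidate_powers ascending integer powers to evaluate; the default
#'   grid includes 14, a typical full-compendium choice.
#' @param r2_cutoff signed `R^2` required to accept a power (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @param log_transform passed to [correlation_matrix()].
#' @return an object of class `power_selection`: a list with `chosen_power`,
#'   `reached_cutoff`, and `table` (one row per candidate: power, signed
#'   `R^2`, slope, mean and max connectivity).
#' @export
pick_soft_threshold <- function(expr,
                                candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_cutoff = 0.8,
                                n_bins = 10,
                                log_transform = TRUE) {
  if (!length(candidate_powers)) stop("candidate_powers must be non-empty")
  if (is.unsorted(candidate_powers, strictly = TRUE))
    stop("candidate_powers must be sorted ascending without duplicates")
  cc <- correlation_matrix(expr, log_transform = log_transform)
  rows <- lapply(candidate_powers, function(b) {
    adj <- signed_adjacency(cc, b)
    k <- connectivity(adj)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = b, r2_signed = fit$r2_signed, slope = fit$slope,
               mean_k = mean(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2_signed >= r2_cutoff)
  if (length(ok)) {
    chosen <- tab$power[ok[1]]
    reached <- TRUE
  } else {
    chosen <- tab$power[which.max(tab$r2_signed)]
    reached <- FALSE
    warning("no candidate power reached r2_cutoff = ", r2_cutoff,
            "; returning argmax power ", chosen)
  }
  structure(list(chosen_power = chosen, reached_cutoff = reached,
                 r2_cutoff = r2_cutoff, table = tab),
            class = "power_selection")
}

#' @export
print.power_selection <- function(x, ...) {
  cat("Soft-threshold selection (scale-free topology criterion)\n")
  cat("  chosen power:", x$chosen_power,
      if (x$reached_cutoff) sprintf("(first with signed R^2 >= %.2f)", x$r2_cutoff)
      else "(argmax fallback; cutoff not reached)", "\n\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu * a_uj`: the overlap of two genes' network
#' neighborhoods, a similarity that credits shared strong neighbors as well
#' as the direct edge. Two genes score 1 when the gene with fewer connections
#' has all of its connections shared with the other.
#'
#' @param adj adjacency matrix in `[0, 1]`.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  check_square_symmetric(adj, "adjacency matrix")
  if (min(adj) < 0 || max(adj) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a          # with zero diagonal this is exactly sum over u != i,j
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1     # floating-point guard
  (tom + t(tom)) / 2    # enforce exact symmetry
}

#' Export the upper triangle of a weight matrix as an edge list
#'
#' @param mat symmetric weight matrix with dimnames (adjacency or TOM).
#' @param path output TSV path; columns `gene_i`, `gene_j`, `weight`.
#' @param min_weight drop edges below this weight (default keeps all).
#' @return invisibly, the edge-list data.frame.
#' @export
write_edge_list <- function(mat, path, min_weight = 0) {
  check_square_symmetric(mat, "weight matrix")
  ids <- rownames(mat)
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  df <- data.frame(gene_i = ids[idx[, 1]], gene_j = ids[idx[, 2]],
                   weight = mat[idx], stringsAsFactors = FALSE)
  df <- df[df$weight >= min_weight, ]
  df <- df[order(-df$weight, df$gene_i, df$gene_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
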
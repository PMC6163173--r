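# Per-module diagnostics: within-module connectivity and hub genes,
# half-sample connectivity stability, relative standard deviation, and
# module-condition association.

## Correlation for resampled subsets: constant genes can appear in small
## subsets; their correlations carry no co-variation evidence and are set
## to 0 rather than propagating NaN.
cor_safe <- function(x) {
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Within-module connectivity
#'
#' For each module, the signed adjacency at power `beta` is computed among
#' that module's genes only, and each gene's connectivity is its adjacency
#' row sum excluding itself. This per-module network matches how stability
#' and hub statistics are reported module by module.
#'
#' @param expr genes x samples numeric matrix.
#' @param partition named character vector gene -> module label (`"grey"`
#'   excluded).
#' @param beta soft-threshold power.
#' @param log_transform passed to the correlation step.
#' @return named list: module -> named numeric vector of connectivities.
#'   Size-1 modules get connectivity 0 with a warning.
#' @export
within_module_connectivity <- function(expr, partition, beta,
                                       log_transform = TRUE) {
  check_expression(expr)
  mods <- module_members(partition)
  x <- if (log_transform) log2(expr) else expr
  out <- vector("list", length(mods))
  names(out) <- names(mods)
  for (mname in names(mods)) {
    genes <- intersect(mods[[mname]], rownames(x))
    if (length(genes) < 2) {
      warning("module ", mname, " has fewer than 2 genes; connectivity 0")
      out[[mname]] <- stats::setNames(rep(0, length(genes)), genes)
      next
    }
    adj <- signed_adjacency(cor_safe(x[genes, , drop = FALSE]), beta)
    out[[mname]] <- rowSums(adj) - diag(adj)
  }
  out
}

#' Hub genes per module
#'
#' Ranks each module's genes by decreasing within-module connectivity, ties
#' broken by gene ID, and returns the top `top_n`.
#'
#' @param k_by_module output of [within_module_connectivity()].
#' @param top_n number of hubs per module (>= 1); values larger than the
#'   module size return the whole module ranked.
#' @return data.frame with columns `module`, `rank`, `gene`, `k`.
#' @export
hub_genes <- function(k_by_module, top_n = 10) {
  if (top_n < 1) stop("top_n must be >= 1")
  rows <- lapply(names(k_by_module), function(mname) {
    k <- k_by_module[[mname]]
    ord <- order(-k, names(k))
    keep <- utils::head(ord, top_n)
    data.frame(module = mname, rank = seq_along(keep),
               gene = names(k)[keep], k = unname(k[keep]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parameters for connectivity stability resampling
#'
#' @param n_iterations number of resamples (default 1000, the full-scale
#'   protocol; scale down for quick checks).
#' @param sample_fraction fraction of samples drawn without replacement each
#'   iteration, in `(0, 1)` (default one half).
#' @param seed integer seed.
#' @return an object of class `stability_params`.
#' @export
stability_params <- function(n_iterations = 1000, sample_fraction = 0.5,
                             seed = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (sample_fraction <= 0 || sample_fraction >= 1)
    stop("sample_fraction must be in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed)),
            class = "stability_params")
}

#' Half-sample connectivity stability of modules
#'
#' For each iteration, `floor(n_samples * sample_fraction)` samples are
#' drawn without replacement, within-module connectivity is recomputed on
#' the subset, and its Pearson correlation with the full-data connectivity
#' is recorded per module. Stable modules keep their internal connectivity
#' ranking under heavy subsampling, so their mean correlation stays high
#' (full-scale analyses typically demand > 0.8).
#'
#' If both connectivity vectors are constant (e.g. noise-free data where
#' every gene is equally connected) the pattern is exactly preserved and the
#' correlation is defined as 1; if only one is constant it is defined as 0.
#'
#' @param expr genes x samples numeric matrix with >= 6 samples.
#' @param partition named character vector gene -> module label.
#' @param beta soft-threshold power for within-module adjacency.
#' @param params a [stability_params()] object.
#' @param log_transform passed to the correlation step.
#' @return an object of class `stability_report`: data.frame with columns
#'   `module`, `n_genes`, `mean_correlation`, `sd_correlation`; modules with
#'   fewer than 3 genes are flagged `skipped`.
#' @export
stability_resampling <- function(expr, partition, beta,
                                 params = stability_params(),
                                 log_transform = TRUE) {
  check_expression(expr)
  stopifnot(inherits(params, "stability_params"))
  n_s <- ncol(expr)
  if (n_s < 6) stop("need at least 6 samples for half-sample resampling")
  n_sub <- floor(n_s * params$sample_fraction)
  if (n_sub < 3) stop("sample_fraction leaves fewer than 3 samples")

  k_full <- within_module_connectivity(expr, partition, beta,
                                       log_transform = log_transform)
  usable <- names(k_full)[lengths(k_full) >= 3]
  skipped <- setdiff(names(k_full), usable)
  if (length(skipped))
    warning("modules skipped (fewer than 3 genes): ",
            paste(skipped, collapse = ", "))

  ## a connectivity vector is "constant" up to floating-point noise when its
  ## spread is negligible relative to its magnitude (e.g. noise-free data,
  ## where every gene is equally connected and the pattern is trivially
  ## preserved)
  near_const <- function(v)
    stats::sd(v) <= 1e-8 * (abs(mean(v)) + .Machine$double.eps)
  cor_pattern <- function(a, b) {
    ca <- near_const(a); cb <- near_const(b)
    if (ca && cb) return(1)
    if (ca || cb) return(0)
    stats::cor(a, b)
  }

  set.seed(params$seed)
  cors <- matrix(NA_real_, nrow = params$n_iterations, ncol = length(usable),
                 dimnames = list(NULL, usable))
  for (it in seq_len(params$n_iterations)) {
    idx <- sample.int(n_s, n_sub)
    sub <- expr[, idx, drop = FALSE]
    k_sub <- within_module_connectivity(sub, partition[partition %in% usable],
                                        beta, log_transform = log_transform)
    for (mname in usable)
      cors[it, mname] <- cor_pattern(k_full[[mname]], k_sub[[mname]])
  }

  df <- data.frame(
    module = names(k_full),
    n_genes = unname(lengths(k_full)),
    mean_correlation = vapply(names(k_full), function(m)
      if (m %in% usable) mean(cors[, m]) else NA_real_, numeric(1)),
    sd_correlation = vapply(names(k_full), function(m)
      if (m %in% usable) stats::sd(cors[, m]) else NA_real_, numeric(1)),
    skipped = names(k_full) %in% skipped,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("stability_report", "data.frame"))
}

#' Relative standard deviation of expression, per gene and per module
#'
#' Gene RSD is the sample standard deviation (n-1 denominator) of expression
#' across samples divided by its mean, computed on the positive
#' (MAS5-like) scale; module RSD is the arithmetic mean over member genes.
#' Low-RSD modules behave like housekeeping programs, high-RSD ones like
#' condition-responsive programs.
#'
#' @param expr genes x samples numeric matrix; strictly positive, so that
#'   RSD is well defined (log-scale input is rejected).
#' @param partition named character vector gene -> module label.
#' @return list with `gene_rsd` (named vector) and `module_rsd` (named
#'   vector, decreasing order excluded grey).
#' @export
module_rsd <- function(expr, partition) {
  check_expression(expr, positive = TRUE)
  gene_rsd <- apply(expr, 1, function(v) stats::sd(v) / mean(v))
  mods <- module_members(partition)
  module_rsd <- vapply(mods, function(genes)
    mean(gene_rsd[intersect(genes, names(gene_rsd))]), numeric(1))
  list(gene_rsd = gene_rsd,
       module_rsd = sort(module_rsd, decreasing = TRUE))
}

#' Module-condition association
#'
#' Averages each module eigengene within each condition and reports, per
#' module, the condition with the highest mean eigengene expression (ties
#' broken lexicographically).
#'
#' @param eigengenes an `eigengene_set` from [module_eigengenes()].
#' @param condition_labels character vector naming the condition of every
#'   sample (same order as the eigengene columns); no sample may be
#'   unlabeled.
#' @return list with `best_condition` (named character vector module ->
#'   label) and `means` (module x condition matrix of mean eigengene
#'   values).
#' @export
condition_association <- function(eigengenes, condition_labels) {
  stopifnot(inherits(eigengenes, "eigengene_set"))
  E <- eigengenes$E
  if (length(condition_labels) != ncol(E))
    stop("condition_labels must have one entry per sample")
  if (anyNA(condition_labels) || any(condition_labels == ""))
    stop("every sample must be labeled")
  labs <- sort(unique(condition_labels))
  means <- vapply(labs, function(l)
    rowMeans(E[, condition_labels == l, drop = FALSE]),
    numeric(nrow(E)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(E),
                                           dimnames = list(rownames(E), labs))
  best <- apply(means, 1, function(v) labs[which.max(v)])  # which.max: first
  list(best_condition = best, means = means)
}
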
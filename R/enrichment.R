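# Log-space hypergeometric over-representation statistics: gene-set
# enrichment with Benjamini-Hochberg adjustment, positional (chromosome
# window) enrichment, set-overlap comparison, and queries against the
# packaged module annotation catalog.

#' Log10 upper tail of the hypergeometric distribution
#'
#' `log10 P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items
#' from a background of `N` containing `K` marked items, the probability of
#' at least `k` marked draws. Computed with log-gamma terms and
#' log-sum-exp, so tails far below the double-precision underflow limit
#' (p ~ 1e-300 and smaller) remain exact in log space.
#'
#' The at-least (`>=`) convention is used throughout the package: the
#' p-value of an observed overlap counts outcomes at least as extreme,
#' including the observation itself.
#'
#' @param N background size.
#' @param K number of marked items in the background (e.g. term size).
#' @param n number of draws (e.g. query size).
#' @param k observed overlap; may be a vector.
#' @return `log10 P(X >= k)`, always <= 0; exactly 0 when `k` is at or
#'   below the distribution's lower support bound.
#' @examples
#' hypergeom_log_tail(10, 5, 4, 3)   # log10(55/210)
#' @export
hypergeom_log_tail <- function(N, K, n, k) {
  if (length(N) != 1 || length(K) != 1 || length(n) != 1)
    stop("N, K, n must be scalars")
  if (N < 0 || K < 0 || n < 0 || K > N || n > N)
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (any(k < 0) || any(k > pmin(n, K)))
    stop("k must satisfy 0 <= k <= min(n, K)")
  lden <- lchoose(N, n)
  hi <- min(n, K)
  lo_support <- max(0, n + K - N)
  vapply(k, function(ki) {
    if (ki <= lo_support) return(0)
    j <- ki:hi
    lterms <- lchoose(K, j) + lchoose(N - K, n - j) - lden
    min(logsumexp(lterms) / log(10), 0)
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, computes `p_(i) * m / i`, enforces
#' monotonicity from the largest p downward (each adjusted value is the
#' minimum over itself and all later ones), caps at 1, and restores the
#' original order. Controls the false discovery rate under independence or
#' positive dependence.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order; always `>= p` and
#'   `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Gene-set over-representation of a query set
#'
#' Tests every collection set for over-representation in the query via the
#' upper-tail hypergeometric probability, conditioned on a background gene
#' universe, with Benjamini-Hochberg adjustment across all tested sets.
#' A local stand-in for web-based GO/tissue/phenotype enrichment services.
#'
#' @param query character vector of gene IDs; must be a subset of
#'   `background`.
#' @param collection named list of gene ID vectors (e.g. from [read_gmt()]
#'   or [generate_gene_sets()]).
#' @param background character vector: the gene universe. Sets are
#'   intersected with it before testing; sets left empty are skipped with a
#'   warning.
#' @return an `enrichment_table` data.frame with columns `term`, `K` (term
#'   size in background), `k` (overlap), `log10_p`, `p`, `adjusted_p`,
#'   sorted by increasing p (ties by term); attributes `N` (background
#'   size) and `n` (query size).
#' @export
enrich_gene_sets <- function(query, collection, background) {
  query <- unique(query)
  background <- unique(background)
  if (!length(query) || !length(background))
    stop("query and background must be non-empty")
  if (!all(query %in% background))
    stop("query genes missing from background: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must be a uniquely named list of gene sets")
  sets <- lapply(collection, function(s) intersect(unique(s), background))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("sets with no background genes skipped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no testable sets after background intersection")
  N <- length(background)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  log10_p <- vapply(seq_along(sets), function(i)
    hypergeom_log_tail(N, K[i], n, k[i]), numeric(1))
  p <- 10^log10_p
  df <- data.frame(term = names(sets), K = unname(K), k = unname(k),
                   log10_p = unname(log10_p), p = unname(p),
                   adjusted_p = bh_adjust(unname(p)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$log10_p, df$term), ]
  rownames(df) <- NULL
  attr(df, "N") <- N
  attr(df, "n") <- n
  class(df) <- c("enrichment_table", "data.frame")
  df
}

#' Positional enrichment of a module in chromosome regions
#'
#' Slides a window of `window_size` consecutive genes (gene-rank
#' coordinates) along each chromosome in steps of `step` genes and tests
#' whether the module is over-represented in the window
#' (hypergeometric: background = all positioned genes, marked = window
#' genes, draws = module genes). Whole chromosomes are tested too.
#' Overlapping significant windows are merged into regions.
#'
#' @param module_genes character vector of gene IDs; all must be present in
#'   `positions`.
#' @param positions data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (BED-like, from [read_bed()] or [generate_positions()]).
#' @param window_size genes per window (default 50, >= 2).
#' @param step genes between window starts (default 25).
#' @param p_threshold report regions with p below this (default 7e-7, a
#'   stringent genome-wide level).
#' @return data.frame of significant regions with columns `chrom`, `start`,
#'   `end`, `n_window_genes` (K), `k`, `log10_p` (best window within the
#'   merged region), sorted by `log10_p`. Attribute `degenerate` is TRUE
#'   when the module spans the whole background (every window trivially
#'   saturated).
#' @export
positional_enrichment <- function(module_genes, positions, window_size = 50,
                                  step = 25, p_threshold = 7e-7) {
  if (window_size < 2) stop("window_size must be >= 2")
  if (step < 1) stop("step must be >= 1")
  module_genes <- unique(module_genes)
  missing <- setdiff(module_genes, positions$gene)
  if (length(missing))
    stop("module genes without positions: ",
         paste(utils::head(missing, 10), collapse = ", "))
  N <- length(unique(positions$gene))
  n <- length(module_genes)
  log10_thr <- log10(p_threshold)
  degenerate <- n == N
  if (degenerate)
    warning("module covers the whole background; positional test degenerate")

  hits <- list()
  for (chr in unique(positions$chrom)) {
    pc <- positions[positions$chrom == chr, ]
    pc <- pc[order(pc$start), ]
    genes_c <- pc$gene
    nc <- length(genes_c)
    starts <- if (nc > window_size)
      unique(c(seq(1, nc - window_size + 1, by = step), nc - window_size + 1))
    else 1
    wins <- lapply(starts, function(s) seq(s, min(s + window_size - 1, nc)))
    wins <- c(wins, list(seq_len(nc)))         # whole chromosome
    for (w in wins) {
      K <- length(w)
      k <- length(intersect(module_genes, genes_c[w]))
      if (k == 0) next
      lp <- hypergeom_log_tail(N, K, n, k)
      if (lp < log10_thr) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chr, from = min(w), to = max(w),
          start = pc$start[min(w)], end = pc$end[max(w)],
          n_window_genes = K, k = k, log10_p = lp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_window_genes = integer(0),
                      k = integer(0), log10_p = numeric(0))
    attr(out, "degenerate") <- degenerate
    return(out)
  }
  hits <- do.call(rbind, hits)

  ## merge overlapping significant windows per chromosome (rank intervals)
  merged <- list()
  for (chr in unique(hits$chrom)) {
    hc <- hits[hits$chrom == chr, ]
    hc <- hc[order(hc$from, hc$to), ]
    cur <- hc[1, ]
    flush <- function(cur) merged[[length(merged) + 1L]] <<- cur
    if (nrow(hc) > 1) {
      for (i in 2:nrow(hc)) {
        if (hc$from[i] <= cur$to) {     # overlap in gene-rank space
          cur$to <- max(cur$to, hc$to[i])
          cur$end <- max(cur$end, hc$end[i])
          if (hc$log10_p[i] < cur$log10_p) {
            cur$log10_p <- hc$log10_p[i]
            cur$n_window_genes <- hc$n_window_genes[i]
            cur$k <- hc$k[i]
          }
        } else {
          flush(cur)
          cur <- hc[i, ]
        }
      }
    }
    flush(cur)
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$log10_p), c("chrom", "start", "end",
                                   "n_window_genes", "k", "log10_p")]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Hypergeometric overlap between two gene sets
#'
#' Tests whether two gene sets drawn from a common background share more
#' genes than chance allows, e.g. to compare a module catalog against an
#' independently published gene list. The tail is computed in log space,
#' so overlaps with p-values far below 1e-300 are still resolved.
#'
#' @param set_a,set_b character vectors of gene IDs (deduplicated
#'   internally).
#' @param N background size; must be at least `|set_a U set_b|`.
#' @return list with `N`, `n_a`, `n_b`, `k` (overlap size), `log10_p`
#'   (upper-tail probability of an overlap at least this large), `p`
#'   (`10^log10_p`, 0 if underflowed), and `fraction_of_a` (`k / n_a`).
#'   `log10_p` is symmetric in the two sets.
#' @export
overlap_comparison <- function(set_a, set_b, N) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (N < length(union(set_a, set_b)))
    stop("background N smaller than the union of the two sets")
  k <- length(intersect(set_a, set_b))
  log10_p <- hypergeom_log_tail(N, length(set_b), length(set_a), k)
  list(N = N, n_a = length(set_a), n_b = length(set_b), k = k,
       log10_p = log10_p, p = 10^log10_p,
       fraction_of_a = k / length(set_a))
}

#' Overlap statistic from printed set sizes
#'
#' [overlap_comparison()] for the common case where only the counts (not
#' the member lists) of two sets are available, e.g. when checking a
#' published overlap claim.
#'
#' @param N background size.
#' @param n_a,n_b set sizes.
#' @param k observed overlap.
#' @return same structure as [overlap_comparison()].
#' @export
overlap_from_counts <- function(N, n_a, n_b, k) {
  if (k > min(n_a, n_b)) stop("overlap k exceeds the smaller set")
  log10_p <- hypergeom_log_tail(N, n_b, n_a, k)
  list(N = N, n_a = n_a, n_b = n_b, k = k,
       log10_p = log10_p, p = 10^log10_p, fraction_of_a = k / n_a)
}

#' Packaged module annotation catalog
#'
#' Loads the catalog of 48 C. elegans co-expression modules shipped with
#' the package: per module, the gene count and the top enriched GO
#' biological process, cellular component, molecular function, and
#' chromosome (with Benjamini-adjusted p-values), transcribed from a
#' published compendium-scale analysis. Used for counting queries such as
#' "how many modules share a given top BP term".
#'
#' @return data.frame with columns `module`, `n_genes`, `bp_term`, `bp_p`,
#'   `cc_term`, `cc_p`, `mf_term`, `mf_p`, `chromosome`, `chr_p`; empty
#'   strings mark missing annotations.
#' @export
module_annotation_catalog <- function() {
  path <- system.file("extdata", "module_annotation_catalog.tsv",
                      package = "coexpnet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = c(module = "character",
                                   n_genes = "integer",
                                   bp_term = "character", bp_p = "character",
                                   cc_term = "character", cc_p = "character",
                                   mf_term = "character", mf_p = "character",
                                   chromosome = "character",
                                   chr_p = "character"))
}

#' Count catalog modules annotated with a term
#'
#' @param catalog data.frame from [module_annotation_catalog()].
#' @param field one of `"BP"`, `"CC"`, `"MF"`, `"chromosome"`.
#' @param term annotation term to match (case-insensitive exact match;
#'   p-values are ignored).
#' @return integer count of matching modules.
#' @examples
#' cat48 <- module_annotation_catalog()
#' count_modules_by_term(cat48, "BP", "ion transport")
#' @export
count_modules_by_term <- function(catalog, field, term) {
  col <- switch(field,
                BP = "bp_term", CC = "cc_term", MF = "mf_term",
                chromosome = "chromosome",
                stop("field must be one of BP, CC, MF, chromosome"))
  sum(tolower(catalog[[col]]) == tolower(term))
}
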
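# Module detection: average-linkage clustering of TOM dissimilarity, a
# documented dynamic tree cut variant, and module eigengenes by SVD.

#' TOM dissimilarity
#'
#' `1 - TOM`, with a zero diagonal, the distance used for clustering.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @return dissimilarity matrix in `[0, 1]`.
#' @export
tom_dissimilarity <- function(tom) {
  check_square_symmetric(tom, "TOM matrix")
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram of a dissimilarity matrix
#'
#' @param dissim square symmetric matrix with zero diagonal and entries in
#'   `[0, 1]` (typically [tom_dissimilarity()] output).
#' @return an `hclust` object (`method = "average"`). Merge heights are
#'   monotone non-decreasing; ties are broken by smallest cluster index, the
#'   standard `hclust` convention.
#' @export
coexp_dendrogram <- function(dissim) {
  check_square_symmetric(dissim, "dissimilarity matrix")
  if (min(dissim) < 0) stop("dissimilarity entries must be non-negative")
  if (any(diag(dissim) != 0)) stop("dissimilarity diagonal must be zero")
  stats::hclust(stats::as.dist(dissim), method = "average")
}

#' Parameters for the dynamic tree cut variant
#'
#' @param min_module_size smallest branch accepted as a module (>= 2;
#'   default 30 for gene networks, use 2 for eigengene meta-networks).
#' @param deep_split recursion depth 0-4 for gap-based branch splitting
#'   (default 2); 0 disables splitting.
#' @param cut_height_fraction static cut height as a fraction of the top
#'   merge height, in `(0, 1]` (default 0.995).
#' @param gap_threshold minimum height gap (dissimilarity units) between a
#'   merge and both children's internal heights for a split (default 0.05).
#' @return an object of class `cut_params`.
#' @export
cut_params <- function(min_module_size = 30, deep_split = 2,
                       cut_height_fraction = 0.995, gap_threshold = 0.05) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (deep_split < 0 || deep_split > 4 || deep_split != round(deep_split))
    stop("deep_split must be an integer in 0..4")
  if (cut_height_fraction <= 0 || cut_height_fraction > 1)
    stop("cut_height_fraction must be in (0, 1]")
  if (gap_threshold < 0) stop("gap_threshold must be >= 0")
  structure(list(min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 cut_height_fraction = cut_height_fraction,
                 gap_threshold = gap_threshold),
            class = "cut_params")
}

#' Cut a dendrogram into modules (dynamic tree cut variant)
#'
#' A documented, deterministic variant of adaptive dendrogram cutting:
#' \enumerate{
#'   \item a static cut at `cut_height_fraction * max(merge height)` yields
#'     candidate branches;
#'   \item branches with at least `min_module_size` leaves become modules,
#'     all other genes join the reserved `"grey"` label;
#'   \item for `deep_split > 0`, each module is recursively split at its top
#'     internal merge when both children hold at least `min_module_size`
#'     leaves \emph{and} the merge height exceeds each child's internal
#'     maximum height by at least `gap_threshold`; recursion depth is capped
#'     at `deep_split`.
#' }
#' Modules are labeled with color-style names assigned by decreasing size
#' (ties broken by the smallest leaf index), so output labels are stable.
#'
#' @param dend an `hclust` object from [coexp_dendrogram()].
#' @param params a [cut_params()] object.
#' @return a named character vector, gene -> module label, with `"grey"` for
#'   unassigned genes.
#' @export
cut_modules <- function(dend, params = cut_params()) {
  stopifnot(inherits(dend, "hclust"), inherits(params, "cut_params"))
  n <- length(dend$order)
  labels <- dend$labels %||% as.character(seq_len(n))
  if (params$min_module_size >= n)
    stop("min_module_size must be smaller than the number of leaves")
  m <- dend$merge
  h <- dend$height
  ## average linkage is monotone; repair sub-epsilon floating-point
  ## inversions (e.g. ties) so cutree accepts the tree, reject real ones
  if (is.unsorted(h)) {
    if (min(diff(h)) < -1e-8) stop("dendrogram heights are not monotone")
    h <- cummax(h)
    dend$height <- h
  }

  ## leaf members below each internal node
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    left  <- if (m[i, 1] < 0) -m[i, 1] else members[[m[i, 1]]]
    right <- if (m[i, 2] < 0) -m[i, 2] else members[[m[i, 2]]]
    members[[i]] <- c(left, right)
  }
  subtree_top <- function(node) if (node < 0) 0 else h[node]

  cutoff <- params$cut_height_fraction * max(h)
  static <- stats::cutree(dend, h = cutoff)

  ## root internal node of each static cluster (clusters are maximal
  ## subtrees below the cutoff; singleton clusters have no internal node)
  root_of <- integer(max(static))
  for (i in seq_len(n - 1)) {
    cl <- static[members[[i]][1]]
    if (h[i] <= cutoff && all(static[members[[i]]] == cl) &&
        length(members[[i]]) == sum(static == cl))
      root_of[cl] <- i
  }

  pieces <- list()
  split_rec <- function(node, depth) {
    if (node > 0 && depth > 0) {
      l <- m[node, 1]; r <- m[node, 2]
      sl <- if (l < 0) 1L else length(members[[l]])
      sr <- if (r < 0) 1L else length(members[[r]])
      if (sl >= params$min_module_size && sr >= params$min_module_size &&
          h[node] - subtree_top(l) >= params$gap_threshold &&
          h[node] - subtree_top(r) >= params$gap_threshold) {
        split_rec(l, depth - 1L)
        split_rec(r, depth - 1L)
        return(invisible())
      }
    }
    pieces[[length(pieces) + 1L]] <<- if (node < 0) -node else members[[node]]
    invisible()
  }
  for (cl in seq_len(max(static))) {
    size <- sum(static == cl)
    if (size < params$min_module_size) next         # -> grey
    split_rec(root_of[cl], params$deep_split)
  }
  pieces <- Filter(function(p) length(p) >= params$min_module_size, pieces)

  out <- rep("grey", n)
  names(out) <- labels
  if (length(pieces)) {
    ord <- order(-lengths(pieces), vapply(pieces, min, numeric(1)))
    cols <- module_color_labels(length(pieces))
    for (i in seq_along(ord)) out[pieces[[ord[i]]]] <- cols[i]
  }
  out
}

#' List module members of a partition
#'
#' @param partition named character vector gene -> label.
#' @param include_grey include the `"grey"` pseudo-module (default FALSE;
#'   grey never counts as a module in per-module statistics).
#' @return named list of gene ID vectors, ordered by decreasing size.
#' @export
module_members <- function(partition, include_grey = FALSE) {
  mods <- split(names(partition), partition)
  if (!include_grey) mods <- mods[setdiff(names(mods), "grey")]
  mods[order(-lengths(mods), names(mods))]
}

#' Module eigengenes by singular value decomposition
#'
#' Each module is summarized by its eigengene: standardize every member gene
#' to zero mean and unit variance across samples, take the first right
#' singular vector of the standardized genes x samples matrix, and flip its
#' sign so it correlates non-negatively with the module's mean standardized
#' profile. The eigengene is the module's first principal component over
#' samples and explains the maximum possible share of module expression
#' variance.
#'
#' @param expr genes x samples numeric matrix.
#' @param partition named character vector gene -> module label; `"grey"` is
#'   ignored.
#' @param log_transform standardize `log2` expression (default), matching
#'   [correlation_matrix()].
#' @return an object of class `eigengene_set`: list with `E` (modules x
#'   samples eigengene matrix, each row unit Euclidean norm),
#'   `variance_explained` (named vector in `[0, 1]`), and `n_genes`.
#' @export
module_eigengenes <- function(expr, partition, log_transform = TRUE) {
  check_expression(expr)
  mods <- module_members(partition)
  if (!length(mods)) stop("partition contains no modules (only grey?)")
  x <- if (log_transform) log2(expr) else expr
  E <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
              dimnames = list(names(mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), names(mods))
  ng <- stats::setNames(integer(length(mods)), names(mods))
  for (mname in names(mods)) {
    genes <- intersect(mods[[mname]], rownames(x))
    if (!length(genes)) stop("module ", mname, " has no genes in the matrix")
    xm <- x[genes, , drop = FALSE]
    sds <- apply(xm, 1, stats::sd)
    if (any(sds == 0)) {
      warning("module ", mname, ": dropping ", sum(sds == 0),
              " zero-variance gene(s)")
      xm <- xm[sds > 0, , drop = FALSE]
      if (nrow(xm) < 2) stop("module ", mname,
                             " has fewer than 2 usable genes")
    }
    xs <- t(scale(t(xm)))                      # genes standardized over samples
    sv <- svd(xs, nu = 0, nv = 1)
    v1 <- drop(sv$v)
    mprof <- colMeans(xs)
    s <- suppressWarnings(stats::cor(v1, mprof))
    if (is.na(s) || s == 0) s <- sign(v1[which.max(abs(v1))])
    if (s < 0) v1 <- -v1
    E[mname, ] <- v1
    ve[mname] <- sv$d[1]^2 / sum(sv$d^2)
    ng[mname] <- nrow(xs)
  }
  structure(list(E = E, variance_explained = ve, n_genes = ng),
            class = "eigengene_set")
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat("Eigengene set:", nrow(x$E), "modules x", ncol(x$E), "samples\n")
  cat("variance explained:\n")
  print(round(x$variance_explained, 3))
  invisible(x)
}

#' Shed weak-membership genes from modules
#'
#' Post-processes a partition by module membership: each assigned gene's
#' log2 profile is correlated with its module eigengene (the kME statistic),
#' and genes below `kme_threshold` are moved to `"grey"`. Modules that fall
#' below `min_module_size` afterwards are dissolved entirely. A single pass
#' is performed (eigengenes are not recomputed), which in practice removes
#' the loosely attached genes a dendrogram cut cannot distinguish from a
#' branch's core.
#'
#' @param expr genes x samples numeric matrix.
#' @param partition named character vector gene -> module label.
#' @param kme_threshold minimum eigengene correlation to stay assigned
#'   (default 0.5).
#' @param min_module_size dissolve modules smaller than this after
#'   shedding (default 2 keeps any surviving pair).
#' @param log_transform passed to [module_eigengenes()].
#' @return the filtered partition (same names, possibly more `"grey"`).
#' @export
shed_low_membership <- function(expr, partition, kme_threshold = 0.5,
                                min_module_size = 2, log_transform = TRUE) {
  check_expression(expr)
  if (kme_threshold < -1 || kme_threshold > 1)
    stop("kme_threshold must be in [-1, 1]")
  mods <- module_members(partition)
  if (!length(mods)) return(partition)
  eig <- module_eigengenes(expr, partition, log_transform = log_transform)
  x <- if (log_transform) log2(expr) else expr
  out <- partition
  for (mname in names(mods)) {
    genes <- intersect(mods[[mname]], rownames(x))
    kme <- suppressWarnings(
      as.vector(stats::cor(t(x[genes, , drop = FALSE]), eig$E[mname, ])))
    kme[!is.finite(kme)] <- 0
    out[genes[kme < kme_threshold]] <- "grey"
  }
  sizes <- table(out[out != "grey"])
  dissolved <- names(sizes)[sizes < min_module_size]
  out[out %in% dissolved] <- "grey"
  out
}
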
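# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Deterministic per-stage seeds derived from one root seed.
## Kept below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 48271 + stage * 16807) %% 2147483647L)
}

check_square_symmetric <- function(m, name = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(name, " must be symmetric", call. = FALSE)
  invisible(m)
}

## Color-style module labels, assigned by decreasing module size.
## "grey" is reserved for unassigned genes and never appears here.
module_color_labels <- function(n) {
  pal <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
    "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
    "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
    "salmon4", "palevioletred3", "navajowhite2", "maroon", "lightpink4",
    "lavenderblush3", "honeydew1", "darkseagreen4", "coral1",
    "antiquewhite4", "coral2", "mediumorchid", "skyblue2", "yellow4",
    "skyblue1", "plum", "orangered3", "mediumpurple2", "lightsteelblue"
  )
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, sprintf("module%03d", seq_len(n - length(pal))))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used here to score recovery of planted modules. A value of 1 means
#' identical partitions (up to label names); the expected value under
#' random labeling is 0.
#'
#' @param a,b vectors of cluster labels of equal length; compared
#'   element-wise, so order matters. Factors or character vectors both work.
#' @return a single number in (-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

## Validate an expression matrix: numeric, named rows, no NAs.
check_expression <- function(expr, positive = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expression matrix must have gene IDs as rownames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(expr))
    stop("expression matrix contains missing values", call. = FALSE)
  if (positive && any(expr <= 0))
    stop("expression values must be strictly positive (did you pass log-scale data?)",
         call. = FALSE)
  invisible(expr)
}
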
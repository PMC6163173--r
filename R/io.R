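# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV (genes in rows), two-column partition TSV, GMT gene sets,
# and BED gene positions. All formats round-trip losslessly.

#' Read an expression matrix from TSV
#'
#' Expects gene IDs in the first column, sample IDs in the header row, and
#' a numeric body. Duplicate gene IDs, missing values, ragged rows, and
#' non-numeric cells are rejected with the offending line reported — the
#' pipeline performs no imputation.
#'
#' @param path TSV file path.
#' @param transpose set TRUE for samples-in-rows files.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected gene IDs plus at least one sample column")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    badline <- if (nrow(bad)) bad[1, 1] + 1L else which(is.na(num))[1]
    stop("non-numeric or missing cell in ", path, " near line ", badline)
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (transpose) num <- t(num)
  check_expression(num)
  num
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a module partition as two-column TSV
#'
#' @param path TSV with columns `gene`, `module`.
#' @return named character vector gene -> module label.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene", "module") %in% colnames(df)))
    stop("partition file must have columns 'gene' and 'module'")
  if (anyDuplicated(df$gene))
    stop("duplicate genes in partition file")
  stats::setNames(df$module, df$gene)
}

#' @rdname read_partition
#' @param partition named character vector gene -> module label.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(gene = names(partition), module = unname(partition),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene IDs (at least three fields).
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `description` attribute
#'   per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description, and >= 1 gene)")
    nm[i] <- f[1]
    s <- f[-(1:2)]
    attr(s, "description") <- f[2]
    sets[[i]] <- s
  }
  if (anyDuplicated(nm)) stop("duplicate set names in ", path)
  stats::setNames(sets, nm)
}

#' @rdname read_gmt
#' @param collection named list of gene ID vectors; an optional
#'   `description` attribute per set is written to the second field.
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection))) stop("collection must be named")
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    desc <- attr(s, "description") %||% nm
    paste(c(nm, desc, as.character(s)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write gene positions in BED format
#'
#' BED dialect with four columns: `chrom`, `start`, `end`, `name`
#' (0-based, half-open). `start >= end` is rejected with the line number.
#'
#' @param path BED file path.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene"))
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1], " in ", path)
  if (anyDuplicated(df$gene)) stop("duplicate gene names in ", path)
  df[, c("gene", "chrom", "start", "end")]
}

#' @rdname read_bed
#' @param positions data.frame with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @export
write_bed <- function(positions, path) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% colnames(positions)))
  utils::write.table(positions[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read per-sample condition labels from TSV
#'
#' @param path TSV with columns `sample`, `condition`.
#' @return named character vector sample -> condition.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample", "condition") %in% colnames(df)))
    stop("condition file must have columns 'sample' and 'condition'")
  stats::setNames(df$condition, df$sample)
}
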
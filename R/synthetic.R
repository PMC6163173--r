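# Planted-module synthetic expression data.
#
# A latent-factor block model: each planted module m has one factor f_m(s)
# across samples, and member genes are noisy exponentiated linear readouts of
# it. The factor is the ground truth the module eigengene should recover,
# which makes parameter-recovery tests possible.

#' Configuration for the synthetic expression generator
#'
#' Describes a positive-valued (MAS5-like) expression matrix with planted
#' co-expressed gene blocks. Module gene `g` in module `m` has expression
#' `exp(mu_g + beta_g * f_m(s) + eps)` in sample `s`, with `f_m ~ N(0,1)`
#' centered per module, `beta_g` the factor loading, and
#' `eps ~ N(0, noise_sd)`. Background genes are pure noise around their
#' baseline. Baselines `mu_g` are drawn log-uniformly over
#' `[log(50), log(5000)]` to mimic the intensity spread of MAS5-summarized
#' arrays.
#'
#' @param n_samples number of samples (columns).
#' @param module_sizes integer vector of planted module sizes, each >= 2.
#' @param n_background number of unstructured background genes, >= 0.
#' @param factor_strength loading scale `beta` (> 0); the ratio
#'   `factor_strength / noise_sd` controls how cleanly modules separate
#'   (detection is comfortable from about 2 upward).
#' @param noise_sd residual standard deviation on the natural-log scale, >= 0.
#' @param loading_jitter relative spread of per-gene loadings:
#'   `beta_g = factor_strength * U(1 - j, 1 + j)`. The default 0.3 gives
#'   modules genuine internal connectivity structure (hub genes); with 0,
#'   every module gene is interchangeable and within-module connectivity
#'   carries no signal, which makes connectivity-stability and hub
#'   statistics degenerate.
#' @param condition_labels optional character vector of length `n_samples`
#'   assigning each sample to a condition.
#' @param condition_effects optional named list: module name ->
#'   named numeric vector of per-condition additive shifts applied to that
#'   module's factor mean. Condition names must appear in `condition_labels`.
#' @param position_clustering fraction in `[0, 1]` of each module's genes
#'   placed in one contiguous genomic run by [generate_positions()].
#' @param n_chromosomes number of chromosomes for [generate_positions()].
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return an object of class `synthetic_config`.
#' @seealso [generate_expression()], [generate_gene_sets()],
#'   [generate_positions()]
#' @export
synthetic_config <- function(n_samples = 120,
                             module_sizes = c(40, 60, 80, 100, 120),
                             n_background = 200,
                             factor_strength = 0.9,
                             noise_sd = 0.3,
                             loading_jitter = 0.3,
                             condition_labels = NULL,
                             condition_effects = NULL,
                             position_clustering = 1,
                             n_chromosomes = 6,
                             seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              module_sizes = as.integer(module_sizes),
              n_background = as.integer(n_background),
              factor_strength = factor_strength,
              noise_sd = noise_sd,
              loading_jitter = loading_jitter,
              condition_labels = condition_labels,
              condition_effects = condition_effects,
              position_clustering = position_clustering,
              n_chromosomes = as.integer(n_chromosomes),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 2) stop("n_samples must be >= 2")
    if (length(module_sizes) < 1 || any(module_sizes < 2))
      stop("module_sizes must all be >= 2")
    if (n_background < 0) stop("n_background must be >= 0")
    if (factor_strength <= 0) stop("factor_strength must be > 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (loading_jitter < 0 || loading_jitter >= 1)
      stop("loading_jitter must be in [0, 1)")
    if (position_clustering < 0 || position_clustering > 1)
      stop("position_clustering must be in [0, 1]")
    if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
    if (!is.null(condition_labels) && length(condition_labels) != n_samples)
      stop("condition_labels must have one entry per sample")
    if (!is.null(condition_effects)) {
      if (is.null(condition_labels))
        stop("condition_effects given without condition_labels")
      mods <- paste0("M", seq_along(module_sizes))
      bad <- setdiff(names(condition_effects), mods)
      if (length(bad))
        stop("condition_effects for unknown modules: ", paste(bad, collapse = ", "))
      for (m in names(condition_effects)) {
        bad <- setdiff(names(condition_effects[[m]]), unique(condition_labels))
        if (length(bad))
          stop("unknown condition labels in condition_effects: ",
               paste(bad, collapse = ", "))
      }
    }
  })
  invisible(cfg)
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Draws a strictly positive genes x samples matrix from the latent-factor
#' block model described in [synthetic_config()], together with the ground
#' truth needed to score downstream module detection: the planted partition,
#' the per-module factors, and the per-gene loadings.
#'
#' @param config a [synthetic_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, strictly positive.
#'       Rownames are synthetic Entrez-style integer gene IDs; colnames are
#'       `S001`, `S002`, ...}
#'     \item{truth}{object of class `synthetic_truth`: `partition` (named
#'       character vector, gene -> `"M1"`, ..., `"background"`), `factors`
#'       (module x sample matrix, zero mean per row), `loadings` (named
#'       numeric vector over module genes), `condition_labels`, and the
#'       `config`.}
#'   }
#' @examples
#' sim <- generate_expression(synthetic_config(
#'   n_samples = 20, module_sizes = c(10, 10), n_background = 5, seed = 1))
#' dim(sim$expr)
#' table(sim$truth$partition)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)

  k <- length(config$module_sizes)
  mod_names <- paste0("M", seq_len(k))
  n_genes <- sum(config$module_sizes) + config$n_background
  n_s <- config$n_samples

  ## Entrez-style integer IDs, unique by sampling without replacement
  gene_ids <- as.character(sample(100000:999999, n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_s))

  partition <- rep(c(mod_names, "background"),
                   c(config$module_sizes, config$n_background))
  names(partition) <- gene_ids

  ## factors: N(0,1) per sample, optional per-condition mean shift,
  ## then centered so each module factor has exactly zero mean
  factors <- matrix(stats::rnorm(k * n_s), nrow = k,
                    dimnames = list(mod_names, sample_ids))
  if (!is.null(config$condition_effects)) {
    for (m in names(config$condition_effects)) {
      shifts <- config$condition_effects[[m]]
      for (lab in names(shifts)) {
        idx <- which(config$condition_labels == lab)
        factors[m, idx] <- factors[m, idx] + shifts[[lab]]
      }
    }
  }
  factors <- factors - rowMeans(factors)

  mu <- stats::runif(n_genes, log(50), log(5000))
  loadings <- config$factor_strength *
    stats::runif(sum(config$module_sizes),
                 1 - config$loading_jitter, 1 + config$loading_jitter)
  names(loadings) <- gene_ids[seq_len(sum(config$module_sizes))]

  signal <- matrix(0, nrow = n_genes, ncol = n_s)
  module_rows <- split(seq_len(n_genes), partition)[mod_names]
  for (m in seq_len(k)) {
    rows <- module_rows[[m]]
    signal[rows, ] <- outer(loadings[gene_ids[rows]], factors[m, ])
  }
  noise <- matrix(stats::rnorm(n_genes * n_s, sd = config$noise_sd),
                  nrow = n_genes)
  expr <- exp(mu + signal + noise)
  dimnames(expr) <- list(gene_ids, sample_ids)

  truth <- structure(
    list(partition = partition, factors = factors, loadings = loadings,
         condition_labels = config$condition_labels, config = config),
    class = "synthetic_truth")
  list(expr = expr, truth = truth)
}

#' Generate a gene-set collection matched to planted modules
#'
#' One "true" set per planted module (its exact gene list, named after the
#' module) plus `n_decoy_sets` random sets of matching sizes drawn from all
#' generated genes. Useful as a stand-in for GO/tissue/phenotype collections
#' when exercising the enrichment machinery.
#'
#' @param truth a `synthetic_truth` object from [generate_expression()].
#' @param n_decoy_sets number of random decoy sets, >= 0.
#' @param seed integer seed for decoy membership.
#' @return a named list of character vectors (a gene-set collection,
#'   writable with [write_gmt()]).
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 0, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_decoy_sets < 0) stop("n_decoy_sets must be >= 0")
  part <- truth$partition
  mods <- setdiff(unique(part), "background")
  if (!length(mods)) stop("truth contains no planted modules")
  sets <- lapply(mods, function(m) names(part)[part == m])
  names(sets) <- mods
  if (n_decoy_sets > 0) {
    set.seed(as.integer(seed))
    sizes <- rep_len(lengths(sets), n_decoy_sets)
    decoys <- lapply(sizes, function(sz) sample(names(part), sz))
    names(decoys) <- sprintf("decoy%03d", seq_len(n_decoy_sets))
    sets <- c(sets, decoys)
  }
  sets
}

#' Generate non-overlapping genomic positions for synthetic genes
#'
#' Places every generated gene on a chromosome with a non-overlapping
#' interval. For each planted module, a `position_clustering` fraction of its
#' genes (from the generating config) occupies one contiguous run of loci on
#' a single chromosome; remaining genes are scattered uniformly. Gene ranks
#' within a chromosome map to intervals `[i * 2000, i * 2000 + 1000)`
#' (0-based, half-open), so intervals are sorted and disjoint by
#' construction.
#'
#' @param truth a `synthetic_truth` object from [generate_expression()].
#' @param n_chromosomes number of chromosomes (defaults to the config value).
#' @param seed integer seed for placement.
#' @return a data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (BED-like, 0-based half-open), one row per gene.
#' @export
generate_positions <- function(truth, n_chromosomes = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_chromosomes <- as.integer(n_chromosomes %||% truth$config$n_chromosomes)
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  frac <- truth$config$position_clustering
  part <- truth$partition
  mods <- setdiff(unique(part), "background")
  set.seed(as.integer(seed))

  ## Build placement "items": one block per module (its clustered genes, kept
  ## contiguous) plus singletons for scattered module genes and background.
  items <- list()
  for (m in mods) {
    genes <- names(part)[part == m]
    n_clust <- round(frac * length(genes))
    if (n_clust >= 2) {
      items <- c(items, list(genes[seq_len(n_clust)]),
                 as.list(genes[-seq_len(n_clust)]))
    } else {
      items <- c(items, as.list(genes))
    }
  }
  items <- c(items, as.list(names(part)[part == "background"]))

  items <- items[sample.int(length(items))]
  ## deal items to chromosomes so a block never straddles a boundary
  chrom_of_item <- rep_len(seq_len(n_chromosomes), length(items))
  pos <- vector("list", n_chromosomes)
  for (cc in seq_len(n_chromosomes)) {
    genes_c <- unlist(items[chrom_of_item == cc], use.names = FALSE)
    if (!length(genes_c)) next
    rank <- seq_along(genes_c) - 1L
    pos[[cc]] <- data.frame(gene = genes_c,
                            chrom = paste0("chr", cc),
                            start = rank * 2000L,
                            end = rank * 2000L + 1000L,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pos)
  rownames(out) <- NULL
  out
}
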
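#' Per-gene z-score standardization of an FPKM matrix
#'
#' For each gene, z_i = (x_i - mu) / s across libraries, where x_i is the
#' gene's FPKM in library i and mu, s are the gene's mean FPKM and standard
#' deviation over all libraries. The sample standard deviation (ddof 1) is
#' the default; genes with zero spread get z = 0 in every library.
#'
#' @param matrix An [fpkm_matrix()] with at least two libraries.
#' @param sd_type `"sample"` (divide by n-1, default) or `"population"`
#'   (divide by n).
#' @return An object of class `zscore_matrix`: list with `values` (the z
#'   matrix, same axes as the input), `gene_mean`, `gene_sd`.
#' @export
compute_zscores <- function(matrix, sd_type = c("sample", "population")) {
  stopifnot(inherits(matrix, "fpkm_matrix"))
  sd_type <- match.arg(sd_type)
  if (ncol(matrix$values) < 2) {
    stop("z-scores need at least 2 libraries", call. = FALSE)
  }
  st <- row_zscores(matrix$values, ddof = if (sd_type == "sample") 1 else 0)
  structure(list(values = st$z, gene_mean = st$mean, gene_sd = st$sd),
            class = "zscore_matrix")
}

#' Call library-correlated genes
#'
#' A gene is correlated with a library when its z-score there exceeds
#' `z_min` and its FPKM exceeds `fpkm_min` (both strictly). A gene may be
#' correlated with several libraries.
#'
#' @param matrix An [fpkm_matrix()].
#' @param z A `zscore_matrix` from [compute_zscores()] on the same matrix
#'   (computed automatically when omitted).
#' @param z_min Z-score threshold (default 1.5).
#' @param fpkm_min FPKM threshold (default 1).
#' @return An object of class `correlated_sets`: a named list (one character
#'   vector of gene ids per library) with attributes `z_min`, `fpkm_min`,
#'   `n_genes`, `gene_ids`.
#' @export
call_correlated_genes <- function(matrix, z = NULL, z_min = 1.5,
                                  fpkm_min = 1.0) {
  stopifnot(inherits(matrix, "fpkm_matrix"))
  if (is.null(z)) z <- compute_zscores(matrix)
  stopifnot(inherits(z, "zscore_matrix"))
  if (!identical(dim(matrix$values), dim(z$values)) ||
      !identical(dimnames(matrix$values), dimnames(z$values))) {
    stop("FPKM and z-score matrices must share axes", call. = FALSE)
  }
  hit <- z$values > z_min & matrix$values > fpkm_min
  sets <- lapply(seq_len(ncol(hit)),
                 function(j) rownames(hit)[hit[, j]])
  names(sets) <- colnames(hit)
  structure(sets, z_min = z_min, fpkm_min = fpkm_min,
            n_genes = nrow(matrix$values), gene_ids = rownames(matrix$values),
            class = "correlated_sets")
}

#' @export
print.correlated_sets <- function(x, ...) {
  cat(sprintf(
    "<correlated_sets> %d libraries, %d genes total (z > %g, FPKM > %g)\n",
    length(x), attr(x, "n_genes"), attr(x, "z_min"), attr(x, "fpkm_min")))
  cat("set sizes:", paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Number of genes correlated with at least one library
#'
#' @param sets A `correlated_sets` object.
#' @return Integer count of distinct genes appearing in any library's set.
#' @export
census_correlated <- function(sets) {
  stopifnot(inherits(sets, "correlated_sets"))
  length(unique(unlist(sets, use.names = FALSE)))
}

#' Count highly expressed correlated genes per library
#'
#' Among each library's correlated genes, counts those whose FPKM in that
#' library exceeds `threshold` (strictly) — the grey-bar overlay of the
#' correlated-gene census.
#'
#' @param matrix An [fpkm_matrix()].
#' @param sets A `correlated_sets` from [call_correlated_genes()].
#' @param threshold FPKM threshold (default 100).
#' @return Named integer vector, one count per library.
#' @export
count_high_expression <- function(matrix, sets, threshold = 100) {
  stopifnot(inherits(matrix, "fpkm_matrix"), inherits(sets, "correlated_sets"))
  vapply(names(sets), function(lib) {
    g <- sets[[lib]]
    sum(matrix$values[g, lib] > threshold)
  }, integer(1))
}

#' Select the union of each library's top expressed genes
#'
#' Takes each library's `k` highest-FPKM genes and returns the deduplicated
#' union, ordered by first appearance in library order (within a library, by
#' descending FPKM; ties at the k-th rank break by gene input order).
#'
#' @param matrix An [fpkm_matrix()].
#' @param k Number of top genes per library (capped at the gene count).
#' @return Character vector of gene ids.
#' @export
select_top_genes <- function(matrix, k = 3) {
  stopifnot(inherits(matrix, "fpkm_matrix"))
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  k <- min(k, nrow(matrix$values))
  out <- character(0)
  for (j in seq_len(ncol(matrix$values))) {
    o <- order(-matrix$values[, j], method = "radix")[seq_len(k)]
    out <- c(out, rownames(matrix$values)[o])
  }
  unique(out)
}

#' log2(FPKM + 1) transform
#'
#' The order-preserving compression used for expression heatmaps.
#'
#' @param matrix An [fpkm_matrix()] or a plain numeric matrix/vector.
#' @return Object of the same shape with values `log2(x + 1)`.
#' @export
log_transform <- function(matrix) {
  if (inherits(matrix, "fpkm_matrix")) log2(matrix$values + 1)
  else log2(matrix + 1)
}

#' Select genes for expression heatmaps
#'
#' Keeps genes whose maximum FPKM over all libraries exceeds `threshold`
#' (strictly), preserving input order — the entry filter for hierarchical
#' clustering of z-scores.
#'
#' @param matrix An [fpkm_matrix()].
#' @param threshold Row-maximum FPKM threshold (default 100).
#' @return Character vector of gene ids.
#' @export
select_heatmap_genes <- function(matrix, threshold = 100) {
  stopifnot(inherits(matrix, "fpkm_matrix"))
  rownames(matrix$values)[apply(matrix$values, 1, max) > threshold]
}

#' Deterministic heatmap row ordering by hierarchical clustering
#'
#' Orders genes by average-linkage hierarchical clustering under correlation
#' distance (1 - Pearson between z rows), returning the dendrogram leaf
#' order. Zero-variance rows get distance 1 to everything and distance 0 to
#' each other; ties resolve by input order, so the ordering is reproducible.
#'
#' @param z A `zscore_matrix` (or numeric matrix of z-scores).
#' @return Integer permutation of row indices (identity for < 2 rows).
#' @export
cluster_order <- function(z) {
  m <- if (inherits(z, "zscore_matrix")) z$values else as.matrix(z)
  if (nrow(m) < 2) return(seq_len(max(nrow(m), 1)))
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[!is.finite(cm)] <- 0
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    cm[const, const] <- 1  # constant rows are mutually identical
  }
  d <- stats::as.dist(1 - cm)
  stats::hclust(d, method = "average")$order
}
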
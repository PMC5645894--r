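#' Hypergeometric tail probability of gene-set overlap
#'
#' The library-similarity statistic: with `n` total genes and two libraries
#' whose correlated-gene sets have sizes `x` and `y`, the probability of
#' sharing at least `c` genes when the sets are drawn independently and
#' uniformly at random is
#'
#' \deqn{P = \sum_{i=c}^{\min(x,y)}
#'   \frac{x!\,y!\,(n-x)!\,(n-y)!}{n!\,i!\,(x-i)!\,(y-i)!\,(n+i-x-y)!}}
#'
#' i.e. the upper tail of the hypergeometric distribution. The factorial
#' form overflows double precision near n = 170, so every term is evaluated
#' in log space via `lgamma` and the tail is accumulated with a
#' log-sum-exp, which stays finite for n in the millions and probabilities
#' far below the double underflow limit.
#'
#' @param n Total gene count.
#' @param x,y Correlated-set sizes of the two libraries.
#' @param c Observed number of shared genes (`0 <= c <= min(x, y)`).
#' @param log10p If `TRUE` return log10 of the tail probability (exact in
#'   log space; use this for significance beyond double underflow).
#' @return The tail probability `P(overlap >= c)`, or its log10.
#' @examples
#' overlap_pvalue(4, 2, 2, 2)  # 1/6
#' overlap_pvalue(4, 2, 2, 1)  # 5/6
#' @export
overlap_pvalue <- function(n, x, y, c, log10p = FALSE) {
  if (anyNA(c(n, x, y, c)) || x > n || y > n || x < 0 || y < 0 ||
      c < 0 || c > min(x, y)) {
    stop("require 0 <= x, y <= n and 0 <= c <= min(x, y)", call. = FALSE)
  }
  if (x < y) { tmp <- x; x <- y; y <- tmp }  # canonical order: exact symmetry
  i <- seq.int(c, min(x, y))
  # log of the i-th hypergeometric pmf term
  lt <- lchoose(x, i) + lchoose(n - x, y - i) - lchoose(n, y)
  lp <- min(logsumexp(lt), 0)  # guard against rounding above 1
  if (log10p) lp / log(10) else exp(lp)
}

#' Bonferroni correction for the pairwise comparison family
#'
#' Multiplies a raw p-value by the number of pairwise comparisons `m` and
#' caps at 1. For an atlas of L libraries the family is all ordered pairs,
#' m = L x L (67 libraries give m = 4489).
#'
#' @param p_raw Raw p-value (or vector).
#' @param m Number of comparisons (>= 1).
#' @return Corrected p-value, capped at 1.
#' @export
bonferroni_correct <- function(p_raw, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("`m` must be a count >= 1", call. = FALSE)
  }
  pmin(p_raw * m, 1)
}

#' Mapping score from a log10 corrected p-value
#'
#' Mapping score = -log10(Bonferroni-corrected p-value), floored at 0. The
#' input is the log10 of the corrected p-value so that extreme significance
#' (p down to 1e-10000 and beyond) never underflows on the way in.
#'
#' @param p_corrected_log10 log10 of the corrected p-value (<= 0 after
#'   capping; values are clamped to <= 0).
#' @return Nonnegative mapping score.
#' @export
mapping_score <- function(p_corrected_log10) {
  lp <- pmin(p_corrected_log10, 0)
  pmax(-lp, 0)  # operand order preserves matrix shape
}

#' Does a mapping score reject library independence?
#'
#' Scores strictly above the threshold (default 10) reject the null that
#' the two libraries' correlated-gene sets are independent draws.
#'
#' @param test A number, vector, or a row of [similarity_matrix()] output
#'   carrying a `score` element.
#' @param threshold Score threshold (default 10).
#' @return Logical.
#' @export
is_dependent <- function(test, threshold = 10) {
  score <- if (is.list(test) && !is.null(test$score)) test$score else test
  score > threshold
}

#' Pairwise library-similarity matrix of mapping scores
#'
#' Evaluates every ordered pair of libraries: overlap tail probability of
#' their correlated-gene sets, Bonferroni correction with m = L^2, mapping
#' score, and the log2(score) layer used for heatmap plotting (missing where
#' score = 0). Diagonal cells are computed like any pair (c = x = y), so
#' each library's self-score is the maximum of its row.
#'
#' @param sets A `correlated_sets` object from [call_correlated_genes()], or
#'   a named list of gene-id vectors.
#' @param n Total gene count; defaults to the count recorded in `sets`.
#' @return An object of class `similarity_matrix`: list of L x L matrices
#'   `p_raw`, `p_corrected`, `score`, `log2_score` plus `library_ids`,
#'   `n_genes`, `n_comparisons`.
#' @export
similarity_matrix <- function(sets, n = attr(sets, "n_genes")) {
  if (is.null(n)) stop("supply `n`, the total gene count", call. = FALSE)
  libs <- names(sets)
  L <- length(sets)
  known <- attr(sets, "gene_ids")
  if (!is.null(known)) {
    alien <- setdiff(unique(unlist(sets, use.names = FALSE)), known)
    if (length(alien)) {
      stop("sets contain unknown genes: ",
           paste(utils::head(alien, 3), collapse = ", "), call. = FALSE)
    }
  }
  sizes <- lengths(sets)
  if (any(sizes > n)) stop("a set is larger than `n`", call. = FALSE)
  m <- L * L
  lp10 <- matrix(0, L, L, dimnames = list(libs, libs))
  for (a in seq_len(L)) {
    for (b in seq_len(a)) {
      cc <- length(intersect(sets[[a]], sets[[b]]))
      v <- overlap_pvalue(n, sizes[a], sizes[b], cc, log10p = TRUE)
      lp10[a, b] <- v
      lp10[b, a] <- v
    }
  }
  lp10_corr <- pmin(lp10 + log10(m), 0)
  score <- mapping_score(lp10_corr)
  log2_score <- ifelse(score > 0, log2(score), NA_real_)
  structure(list(
    p_raw = 10^lp10, p_corrected = 10^lp10_corr,
    score = score, log2_score = log2_score,
    library_ids = libs, n_genes = n, n_comparisons = m
  ), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %d libraries, n = %d genes, m = %d comparisons\n",
    length(x$library_ids), x$n_genes, x$n_comparisons))
  off <- x$score[upper.tri(x$score)]
  cat(sprintf("off-diagonal scores: median %.2f, max %.2f; %d pair(s) > 10\n",
              stats::median(off), max(off), sum(off > 10)))
  invisible(x)
}

#' Write a similarity layer as TSV
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @param layer One of `"score"`, `"log2_score"`, `"p_raw"`, `"p_corrected"`.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(x, path, layer = "score") {
  stopifnot(inherits(x, "similarity_matrix"))
  layer <- match.arg(layer, c("score", "log2_score", "p_raw", "p_corrected"))
  df <- data.frame(library_id = x$library_ids, x[[layer]],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
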
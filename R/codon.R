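# 64 codons in alphabetical order (AAA .. TTT), matching
# Biostrings::oligonucleotideFrequency column order
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b,
                   stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

stop_codons <- c("TAA", "TAG", "TGA")

#' Count codons over in-frame coding sequences
#'
#' Sums codon occurrences over a set of CDS read in frame 0. Each sequence
#' length must be divisible by 3; codons containing `N` (or other ambiguity
#' codes) are excluded from the counts and tallied separately.
#'
#' @param cds_sequences A [Biostrings::DNAStringSet], or a character vector
#'   of nucleotide strings (optionally named).
#' @return An object of class `codon_table`: a named numeric vector of 64
#'   codon counts with attributes `basis` (`"genome"`), `unit` (`"count"`)
#'   and `n_ambiguous` (codons dropped for ambiguity).
#' @examples
#' count_codons_cds("ATGAAATAA")
#' @export
count_codons_cds <- function(cds_sequences) {
  if (!methods::is(cds_sequences, "DNAStringSet")) {
    cds_sequences <- Biostrings::DNAStringSet(toupper(cds_sequences))
  }
  w <- Biostrings::width(cds_sequences)
  bad <- which(w %% 3 != 0)
  if (length(bad)) {
    nm <- names(cds_sequences)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("sequence '%s' length %d is not divisible by 3",
                 nm, w[bad[1]]), call. = FALSE)
  }
  counts <- stats::setNames(numeric(64), all_codons())
  n_ambig <- 0
  if (length(cds_sequences)) {
    freq <- Biostrings::oligonucleotideFrequency(cds_sequences, width = 3,
                                                 step = 3)
    tot <- colSums(freq)
    counts[names(tot)] <- tot
    n_ambig <- sum(w) / 3 - sum(tot)
  }
  structure(counts, basis = "genome", unit = "count",
            n_ambiguous = n_ambig, class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon_table> basis=%s unit=%s total=%g\n",
              attr(x, "basis"), attr(x, "unit"), sum(x)))
  print(utils::head(sort(unclass(x), decreasing = TRUE), 8))
  invisible(x)
}

#' Convert a codon table between count and frequency units
#'
#' @param table A `codon_table`.
#' @param unit `"count"`, `"per-thousand"` or `"percent"`.
#' @return A `codon_table` in the requested unit (per-thousand sums to
#'   1000, percent to 100).
#' @export
codon_frequencies <- function(table, unit = c("per-thousand", "percent",
                                              "count")) {
  unit <- match.arg(unit)
  total <- sum(table)
  if (unit != "count" && total == 0) {
    stop("cannot normalize an all-zero codon table", call. = FALSE)
  }
  scale <- switch(unit, count = 1, `per-thousand` = 1000 / total,
                  percent = 100 / total)
  structure(unclass(table) * scale, basis = attr(table, "basis"),
            unit = unit, n_ambiguous = attr(table, "n_ambiguous"),
            class = "codon_table")
}

#' FPKM-weighted transcriptome codon usage
#'
#' For each library, multiplies every transcript's longest-ORF codon counts
#' by the transcript's FPKM in that library, sums over transcripts per
#' codon, and converts to percentages; the transcriptome-wide table is the
#' unweighted mean of the per-library percentage tables. Libraries whose
#' weighted counts are all zero carry no usage information: they are
#' flagged and excluded from the mean.
#'
#' @param orf_counts 64 x T matrix of per-transcript codon counts (rows in
#'   [all_codons()] order or named; columns named by transcript), e.g. the
#'   longest-ORF counts of a transcript set. A list of per-transcript
#'   `codon_table`s is also accepted.
#' @param fpkm T x L matrix of per-transcript, per-library FPKM values
#'   (rows matched to transcripts by name when named).
#' @return A list with `per_library` (64 x L matrix of percentages),
#'   `mean` (a `codon_table` in percent, basis `"transcriptome:mean"`) and
#'   `excluded_libraries` (character vector of flagged libraries).
#' @export
transcriptome_usage <- function(orf_counts, fpkm) {
  if (is.list(orf_counts) && !is.matrix(orf_counts)) {
    orf_counts <- vapply(orf_counts, function(x) {
      unclass(x)[all_codons()]
    }, numeric(64))
    rownames(orf_counts) <- all_codons()
  }
  orf_counts <- as.matrix(orf_counts)
  if (nrow(orf_counts) != 64) stop("need 64 codon rows", call. = FALSE)
  if (!is.null(rownames(orf_counts))) {
    orf_counts <- orf_counts[all_codons(), , drop = FALSE]
  } else {
    rownames(orf_counts) <- all_codons()
  }
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM weights must be nonnegative", call. = FALSE)
  if (!is.null(rownames(fpkm)) && !is.null(colnames(orf_counts))) {
    if (!setequal(rownames(fpkm), colnames(orf_counts))) {
      stop("transcript names of `fpkm` and `orf_counts` differ",
           call. = FALSE)
    }
    fpkm <- fpkm[colnames(orf_counts), , drop = FALSE]
  }
  if (nrow(fpkm) != ncol(orf_counts)) {
    stop("one FPKM row per transcript required", call. = FALSE)
  }
  weighted <- orf_counts %*% fpkm  # 64 x L
  totals <- colSums(weighted)
  ok <- totals > 0
  per_library <- weighted
  per_library[, ok] <- sweep(weighted[, ok, drop = FALSE], 2,
                             totals[ok], `/`) * 100
  per_library[, !ok] <- NA_real_
  mean_tab <- structure(
    rowMeans(per_library[, ok, drop = FALSE]),
    basis = "transcriptome:mean", unit = "percent", n_ambiguous = 0,
    class = "codon_table")
  list(per_library = per_library, mean = mean_tab,
       excluded_libraries = colnames(fpkm)[!ok] %||% which(!ok))
}

#' Aggregate codon usage to amino-acid usage
#'
#' Sums synonymous-codon frequencies per amino acid under the standard
#' genetic code; the three stop codons are reported separately under
#' `"*"`, so total mass is conserved.
#'
#' @param table A `codon_table` in frequency units (see
#'   [codon_frequencies()]); count tables are accepted and summed as-is.
#' @return Named numeric vector over the 20 amino acids (one-letter code)
#'   plus `"*"` for stops.
#' @export
aggregate_by_aa <- function(table) {
  code <- Biostrings::GENETIC_CODE  # named by codon, value = AA or *
  aa <- code[all_codons()]
  out <- tapply(unclass(table)[all_codons()], aa, sum)
  aas <- c(sort(setdiff(unique(code), "*")), "*")
  stats::setNames(as.numeric(out[aas]), aas)
}

#' Correlate amino-acid usage with tRNA gene counts
#'
#' Pearson correlation across the 20 standard amino acids between an
#' amino-acid usage vector (from [aggregate_by_aa()]; the stop entry is
#' dropped) and predicted tRNA gene counts per amino acid.
#'
#' @param aa_usage Named numeric vector of amino-acid usage.
#' @param trna Named numeric vector or 2-column `data.frame`
#'   (`amino_acid`, `count`) of tRNA gene counts, one-letter amino-acid
#'   names.
#' @return A list with `r` (Pearson correlation), `n` (amino acids used)
#'   and `undefined` (`TRUE` when either side has zero variance, in which
#'   case `r` is `NA`).
#' @export
correlate_trna <- function(aa_usage, trna) {
  if (is.data.frame(trna)) {
    trna <- stats::setNames(as.numeric(trna[[2]]), as.character(trna[[1]]))
  }
  if (any(trna < 0) || any(trna != round(trna))) {
    stop("tRNA gene counts must be nonnegative integers", call. = FALSE)
  }
  aa_usage <- aa_usage[setdiff(names(aa_usage), "*")]
  shared <- intersect(names(aa_usage), names(trna))
  if (length(shared) < 3) {
    stop("need at least 3 amino acids with both usage and tRNA counts",
         call. = FALSE)
  }
  u <- aa_usage[shared]
  t <- trna[shared]
  if (stats::sd(u) == 0 || stats::sd(t) == 0) {
    return(list(r = NA_real_, n = length(shared), undefined = TRUE))
  }
  list(r = stats::cor(u, t), n = length(shared), undefined = FALSE)
}
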
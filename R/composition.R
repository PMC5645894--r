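#' Longest open reading frame over six frames
#'
#' Scans both strands in all three frames for the longest open reading
#' frame and returns its length in residues, excluding the stop codon. In
#' the default `"atg"` mode an ORF starts at an ATG and ends at the first
#' in-frame stop or runs off the sequence end; `"edge"` mode additionally
#' admits ORFs that begin at the sequence edge without a start codon.
#' Codons containing `N` translate to an unknown residue: they may sit
#' inside an ORF but never act as a start codon.
#'
#' @param transcript A single nucleotide string over `A C G T N` (case
#'   insensitive), or a [Biostrings::DNAString].
#' @param mode `"atg"` (default) or `"edge"`.
#' @return Length of the longest ORF in amino acids (0 when none).
#' @examples
#' longest_orf_length("TTATGAAACCCTAGTT")  # ATG AAA CCC -> 3
#' @export
longest_orf_length <- function(transcript, mode = c("atg", "edge")) {
  mode <- match.arg(mode)
  s <- toupper(as.character(transcript))
  if (!nzchar(s)) return(0L)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence must be over A, C, G, T, N", call. = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (strand in c(s, rc)) {
    n <- nchar(strand)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1) next
      codons <- substring(strand, off + 3 * (seq_len(ncod) - 1) + 1,
                          off + 3 * seq_len(ncod))
      is_stop <- codons %in% stops
      is_start <- codons == "ATG"
      open <- -1L  # codon index where the current ORF starts, -1 = closed
      for (k in seq_len(ncod)) {
        if (is_stop[k]) {
          if (open > 0) best <- max(best, k - open)
          open <- -1L
        } else if (open < 0 && (is_start[k] || (mode == "edge" && k == 1L))) {
          open <- k
        }
      }
      if (open > 0) best <- max(best, ncod - open + 1L)  # runs off the end
    }
  }
  best
}

#' Classify a gene as mitochondrial, rRNA, coding or noncoding
#'
#' Categories are exhaustive and mutually exclusive, assigned by precedence:
#' genes on a mitochondrial scaffold are `mitochondrial`; then genes on an
#' rRNA scaffold are `rRNA`; then genes with a longest ORF strictly above
#' 100 residues are `coding`; everything else is `noncoding`. Scaffold
#' identifiers are compared by exact string equality after whitespace
#' trimming.
#'
#' @param scaffold_id Scaffold identifier of the gene (vectorized).
#' @param mito_scaffolds,rrna_scaffolds Character vectors of special
#'   scaffold ids; they must be disjoint.
#' @param max_orf Longest ORF length of the gene in residues (vectorized),
#'   e.g. from [longest_orf_length()] over its transcripts.
#' @param coding_min_orf Residue threshold for `coding` (strict `>`,
#'   default 100).
#' @return Factor with levels `mitochondrial`, `rRNA`, `coding`,
#'   `noncoding`.
#' @export
classify_gene <- function(scaffold_id, mito_scaffolds, rrna_scaffolds,
                          max_orf, coding_min_orf = 100) {
  mito_scaffolds <- trimws(mito_scaffolds)
  rrna_scaffolds <- trimws(rrna_scaffolds)
  both <- intersect(mito_scaffolds, rrna_scaffolds)
  if (length(both)) {
    stop("scaffold(s) in both special sets: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  scaffold_id <- trimws(scaffold_id)
  out <- ifelse(scaffold_id %in% mito_scaffolds, "mitochondrial",
         ifelse(scaffold_id %in% rrna_scaffolds, "rRNA",
         ifelse(max_orf > coding_min_orf, "coding", "noncoding")))
  factor(out, levels = c("mitochondrial", "rRNA", "coding", "noncoding"))
}

#' Summarize per-library read counts over the four gene categories
#'
#' @param read_counts Numeric matrix of read counts, genes x libraries
#'   (rownames = gene ids), or a `data.frame` in that layout.
#' @param categories Factor or character vector of gene categories named by
#'   gene id (as from [classify_gene()]); every counted gene must appear.
#' @return A `data.frame`, one row per library x category, with columns
#'   `library_id`, `category`, `count`, `fraction`, `empty` (`TRUE` when
#'   the library total is 0, in which case fractions are reported as 0).
#' @export
summarize_categories <- function(read_counts, categories) {
  read_counts <- as.matrix(read_counts)
  lvls <- c("mitochondrial", "rRNA", "coding", "noncoding")
  if (is.null(names(categories))) {
    stop("`categories` must be named by gene id", call. = FALSE)
  }
  missing <- setdiff(rownames(read_counts), names(categories))
  if (length(missing)) {
    stop("uncategorized gene(s): ", paste(utils::head(missing, 3),
                                          collapse = ", "), call. = FALSE)
  }
  cat_of <- factor(as.character(categories[rownames(read_counts)]),
                   levels = lvls)
  out <- do.call(rbind, lapply(seq_len(ncol(read_counts)), function(j) {
    counts <- tapply(read_counts[, j], cat_of, sum, default = 0)
    total <- sum(counts)
    data.frame(
      library_id = colnames(read_counts)[j] %||% as.character(j),
      category = lvls,
      count = as.numeric(counts),
      fraction = if (total > 0) as.numeric(counts) / total else rep(0, 4),
      empty = total == 0,
      row.names = NULL
    )
  }))
  out
}

# Keyword groups for unmapped-read hit triage, in priority order: the first
# group with a case-insensitive substring match wins, so e.g. an "M. sexta
# 18S ribosomal RNA" title lands in rRNA, not M. sexta.
hit_keyword_groups <- list(
  rRNA = c("ribosomal RNA", "rRNA"),
  mitochondrion = "mitochondri",
  phage = "phage",
  "M. sexta" = c("M. sexta", "manduca", "sexta"),
  "E. coli" = c("Escherichia coli", "e.coli", "E. coli"),
  Oryza = "oryza"
)

#' Classify a hit subject title into seven keyword categories
#'
#' Assigns each free-text subject title to the first keyword group it
#' matches (case-insensitive substring, literal match): rRNA, mitochondrion,
#' phage, M. sexta, E. coli, Oryza; unmatched titles fall to `others`.
#'
#' @param title Character vector of subject titles.
#' @return Factor with the seven category levels.
#' @examples
#' classify_hit_description("Manduca sexta 18S ribosomal RNA gene")  # rRNA
#' @export
classify_hit_description <- function(title) {
  out <- rep("others", length(title))
  undecided <- rep(TRUE, length(title))
  low <- tolower(title)  # case-insensitive, dots literal: fixed substring
  for (grp in names(hit_keyword_groups)) {
    hits <- rep(FALSE, length(title))
    for (kw in hit_keyword_groups[[grp]]) {
      hits <- hits | grepl(tolower(kw), low, fixed = TRUE)
    }
    take <- undecided & hits
    out[take] <- grp
    undecided <- undecided & !take
  }
  factor(out, levels = c(names(hit_keyword_groups), "others"))
}

#' Rescale FPKM after excluding contaminating reads from library sizes
#'
#' When abundant rRNA and mitochondrial reads are excluded from a library's
#' mapped-read total, every remaining gene's FPKM grows by the factor
#' `1 / (1 - f)`, where `f` is the excluded fraction; within-library rank
#' order is unchanged.
#'
#' @param matrix An [fpkm_matrix()].
#' @param excluded_fraction Numeric vector of per-library excluded-read
#'   fractions in `[0, 1)`, named by library id or in column order.
#' @return A rescaled [fpkm_matrix()].
#' @export
adjust_library_sizes <- function(matrix, excluded_fraction) {
  stopifnot(inherits(matrix, "fpkm_matrix"))
  f <- excluded_fraction
  if (!is.null(names(f))) {
    f <- f[colnames(matrix$values)]
    if (anyNA(f)) stop("excluded_fraction misses some libraries",
                       call. = FALSE)
  }
  if (length(f) != ncol(matrix$values)) {
    stop("need one excluded fraction per library", call. = FALSE)
  }
  if (any(f < 0 | f >= 1)) {
    stop("excluded fractions must lie in [0, 1)", call. = FALSE)
  }
  fpkm_matrix(sweep(matrix$values, 2, 1 / (1 - f), `*`),
              library_meta = matrix$library_meta)
}
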
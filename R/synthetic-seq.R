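#' Generate a toy transcriptome with known codon composition
#'
#' Each transcript is a complete start-to-stop open reading frame: an ATG,
#' then sense codons drawn from `codon_weights` (stop-codon entries are used
#' only to pick the terminator), then one stop codon. The realized codon
#' counts of every transcript — including the ATG and the terminating stop —
#' are recorded as ground truth.
#'
#' @param n_transcripts Number of transcripts (0 gives an empty set).
#' @param codon_weights Nonnegative 64-vector of draw weights, named by
#'   codon or in [all_codons()] order (default uniform). At least one sense
#'   codon must have positive weight.
#' @param length_range Two-element range of ORF lengths in codons
#'   (including the ATG, excluding the stop), drawn uniformly.
#' @param seed Integer seed; identical seeds give bit-identical sets.
#' @return A list with
#'   * `sequences`: a [Biostrings::DNAStringSet] named `tx_0001`, ...;
#'   * `codon_counts`: 64 x n matrix of realized per-transcript counts.
#' @export
generate_transcriptome <- function(n_transcripts,
                                   codon_weights = NULL,
                                   length_range = c(50, 300),
                                   seed = 1L) {
  codons <- all_codons()
  if (is.null(codon_weights)) {
    codon_weights <- stats::setNames(rep(1, 64), codons)
  }
  if (is.null(names(codon_weights))) names(codon_weights) <- codons
  if (length(codon_weights) != 64 || !setequal(names(codon_weights), codons)) {
    stop("`codon_weights` must cover all 64 codons", call. = FALSE)
  }
  if (any(codon_weights < 0)) {
    stop("`codon_weights` must be nonnegative", call. = FALSE)
  }
  codon_weights <- codon_weights[codons]
  sense <- setdiff(codons, stop_codons)
  sw <- codon_weights[sense]
  if (sum(sw) == 0) {
    stop("all sense-codon weights are zero", call. = FALSE)
  }
  tw <- codon_weights[stop_codons]
  if (sum(tw) == 0) tw <- stats::setNames(rep(1, 3), stop_codons)
  if (!is.numeric(n_transcripts) || n_transcripts < 0 ||
      n_transcripts != round(n_transcripts)) {
    stop("`n_transcripts` must be a nonnegative count", call. = FALSE)
  }

  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[2] < length_range[1]) {
    stop("`length_range` must be an increasing pair of counts >= 1",
         call. = FALSE)
  }
  counts <- matrix(0, 64, n_transcripts,
                   dimnames = list(codons,
                                   sprintf("tx_%04d", seq_len(n_transcripts))))
  seqs <- with_seed(seed, {
    vapply(seq_len(n_transcripts), function(i) {
      len <- length_range[1] +
        sample.int(length_range[2] - length_range[1] + 1L, 1) - 1L
      body <- if (len > 1) {
        sample(sense, len - 1, replace = TRUE, prob = sw)
      } else character(0)
      stop_cod <- sample(stop_codons, 1, prob = tw)
      drawn <- c("ATG", body, stop_cod)
      tab <- table(drawn)
      counts[names(tab), i] <<- as.numeric(tab)
      paste(drawn, collapse = "")
    }, character(1))
  })
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- colnames(counts)
  list(sequences = sequences, codon_counts = counts)
}

#' Generate a labeled table of synthetic hit subject titles
#'
#' Emits `n_per_category` free-text subject titles for each of the seven
#' hit categories, embedding that category's keyword with randomized casing
#' and flanking words chosen so no earlier-priority keyword appears by
#' accident; `others` titles contain no keyword at all. The true label of
#' every record round-trips through [classify_hit_description()].
#'
#' @param n_per_category Records per category (>= 0).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `read_id`, `subject_title`,
#'   `true_category`.
#' @export
generate_hit_table <- function(n_per_category, seed = 1L) {
  if (!is.numeric(n_per_category) || n_per_category < 0 ||
      n_per_category != round(n_per_category)) {
    stop("`n_per_category` must be a nonnegative count", call. = FALSE)
  }
  cores <- list(
    rRNA = c("18S ribosomal RNA gene", "28S rRNA partial sequence",
             "large subunit ribosomal RNA"),
    mitochondrion = c("mitochondrion, complete genome",
                      "mitochondrial cytochrome oxidase subunit I",
                      "NADH dehydrogenase mitochondrial sequence"),
    phage = c("Enterobacteria phage phiX174", "phage isolate, complete genome",
              "bacteriophage lambda region"),
    "M. sexta" = c("Manduca sexta clone cDNA", "M. sexta apolipophorin mRNA",
                   "sexta lysozyme precursor gene"),
    "E. coli" = c("Escherichia coli strain K-12 chromosome",
                  "E. coli plasmid sequence", "e.coli genomic fragment"),
    Oryza = c("Oryza sativa Japonica Group chromosome 1",
              "oryza glutelin mRNA"),
    others = c("Bombyx mori clone fragment", "Spodoptera genomic scaffold",
               "uncharacterized bacterial contig")
  )
  # flanking words free of every keyword so they never promote a title
  flanks <- c("isolate", "voucher", "strain", "partial", "predicted",
              "complete", "clone", "contig")
  random_case <- function(x) {
    chars <- strsplit(x, "")[[1]]
    flip <- stats::runif(length(chars)) < 0.3
    chars[flip] <- ifelse(chars[flip] == toupper(chars[flip]),
                          tolower(chars[flip]), toupper(chars[flip]))
    paste(chars, collapse = "")
  }
  cats <- names(cores)
  with_seed(seed, {
    rows <- lapply(cats, function(cat) {
      if (n_per_category == 0) return(NULL)
      titles <- vapply(seq_len(n_per_category), function(i) {
        core <- sample(cores[[cat]], 1)
        paste(sample(flanks, 1), random_case(core), sample(flanks, 1))
      }, character(1))
      data.frame(read_id = sprintf("%s_read_%04d", gsub("[. ]", "", cat),
                                   seq_len(n_per_category)),
                 subject_title = titles,
                 true_category = cat,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(read_id = character(0), subject_title = character(0),
                        true_category = character(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings' FASTA I/O, exported so that synthetic
#' transcriptomes and CDS collections round-trip as plain text.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a [Biostrings::DNAStringSet];
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @param sequences A [Biostrings::DNAStringSet] or named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
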
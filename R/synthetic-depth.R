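#' Generate a heavy-tailed synthetic depth track
#'
#' Allocates `total_mapped` aligned bases across the genome following a
#' truncated discrete power law over depth ranks (weight of rank r is
#' `r^-tail_exponent`), so a small number of top-ranked bases carries most of
#' the mass — the dominance of the top coverage strata seen in deeply
#' sequenced transcriptomes. Rank depths are converted to integers by floor
#' allocation with the remainder given to the top ranks (the total is exact),
#' then shuffled onto random genome positions.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_len Length of each scaffold in bases (>= 1).
#' @param total_mapped Total aligned bases to distribute.
#' @param tail_exponent Positive power-law exponent; smaller values spread
#'   mass more evenly, larger values concentrate it in the top ranks.
#' @param seed Integer seed; identical seeds give bit-identical tracks.
#' @param library_id Optional library identifier.
#'
#' @return A [depth_track()] with attribute `rank_depths`: the planted
#'   descending depth ladder (ground truth for stratification tests).
#' @export
generate_depth_track <- function(n_scaffolds, scaffold_len, total_mapped,
                                 tail_exponent = 1.2, seed = 1L,
                                 library_id = NA_character_) {
  if (!is.numeric(n_scaffolds) || n_scaffolds < 1 ||
      n_scaffolds != round(n_scaffolds)) {
    stop("invalid `n_scaffolds`: must be a positive count", call. = FALSE)
  }
  if (!is.numeric(scaffold_len) || scaffold_len < 1 ||
      scaffold_len != round(scaffold_len)) {
    stop("invalid `scaffold_len`: must be >= 1", call. = FALSE)
  }
  if (!is.numeric(total_mapped) || total_mapped < 0 ||
      total_mapped != round(total_mapped)) {
    stop("invalid `total_mapped`: must be a nonnegative count", call. = FALSE)
  }
  if (!is.numeric(tail_exponent) || tail_exponent <= 0) {
    stop("invalid `tail_exponent`: must be > 0", call. = FALSE)
  }
  n_bases <- n_scaffolds * scaffold_len

  rank_depths <- if (total_mapped > 0) {
    w <- (seq_len(n_bases))^(-tail_exponent)
    expected <- total_mapped * w / sum(w)
    d <- floor(expected)
    short <- total_mapped - sum(d)
    if (short > 0) d[seq_len(short)] <- d[seq_len(short)] + 1
    d
  } else {
    numeric(n_bases)
  }
  # descending ladder: floor allocation of a decreasing profile + top-rank
  # remainder keeps d sorted, so the ladder is the true rank profile
  rank_depths <- sort(rank_depths, decreasing = TRUE)

  flat <- with_seed(seed, {
    pos <- sample.int(n_bases, n_bases)
    out <- numeric(n_bases)
    out[pos] <- rank_depths
    out
  })
  ids <- sprintf("scaffold_%03d", seq_len(n_scaffolds))
  scaffolds <- stats::setNames(
    split(flat, rep(seq_len(n_scaffolds), each = scaffold_len)), ids)
  track <- depth_track(scaffolds, library_id = library_id)
  attr(track, "rank_depths") <- rank_depths
  track
}
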
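#' Per-base sequencing depth track
#'
#' Holds per-base read depth for a set of scaffolds in one library. Depths
#' are nonnegative integers, one per base; `total_mapped_bases` is the sum of
#' all depths (every aligned base contributes one unit of depth to one
#' genomic base).
#'
#' @param scaffolds Named list of integer vectors of per-base depths; names
#'   are scaffold identifiers, vector length is scaffold length.
#' @param library_id Optional library identifier.
#' @return An object of class `depth_track` with elements `scaffolds`,
#'   `library_id`, `total_mapped_bases`.
#' @export
depth_track <- function(scaffolds, library_id = NA_character_) {
  if (!is.list(scaffolds) || is.null(names(scaffolds)) ||
      anyDuplicated(names(scaffolds))) {
    stop("`scaffolds` must be a uniquely named list of depth vectors",
         call. = FALSE)
  }
  scaffolds <- lapply(scaffolds, function(d) {
    d <- as.numeric(d)
    if (anyNA(d) || any(d < 0) || any(d != round(d))) {
      stop("depths must be nonnegative integers", call. = FALSE)
    }
    d
  })
  structure(list(
    scaffolds = scaffolds,
    library_id = library_id,
    total_mapped_bases = sum(vapply(scaffolds, sum, numeric(1)))
  ), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %d scaffolds, %s bases, %s mapped bases\n",
              length(x$scaffolds),
              format(genome_size(x), big.mark = ","),
              format(x$total_mapped_bases, big.mark = ",")))
  invisible(x)
}

genome_size <- function(track) {
  sum(vapply(track$scaffolds, length, numeric(1)))
}

#' Fraction of the genome covered by at least one read
#'
#' A base counts as transcribed when its depth is nonzero; the fraction is
#' taken over all bases of the track.
#'
#' @param track A [depth_track()].
#' @return A fraction in `[0, 1]`.
#' @export
transcribed_fraction <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  total <- genome_size(track)
  if (total == 0) stop("empty depth track", call. = FALSE)
  covered <- sum(vapply(track$scaffolds, function(d) sum(d > 0), numeric(1)))
  covered / total
}

#' Drop short scaffolds from a depth track
#'
#' Short scaffolds (by default under 200 kb) concentrate rRNA and
#' mitochondrial signal and are removed before coverage stratification;
#' `total_mapped_bases` is recomputed from the survivors.
#'
#' @param track A [depth_track()].
#' @param min_len Minimum scaffold length in bases to keep (strict `<`
#'   removes).
#' @return A filtered [depth_track()].
#' @export
filter_scaffolds <- function(track, min_len = 200000) {
  stopifnot(inherits(track, "depth_track"))
  keep <- vapply(track$scaffolds, length, numeric(1)) >= min_len
  depth_track(track$scaffolds[keep], library_id = track$library_id)
}

#' BPKM normalization of per-base depth
#'
#' BPKM (bases per kilobase per million mapped bases) rescales the raw depth
#' of a base to the number of bases that would map onto it out of one billion
#' mapped bases: `depth * 1e9 / total_mapped_bases`.
#'
#' @param track A [depth_track()].
#' @return A named list of numeric BPKM vectors, parallel to
#'   `track$scaffolds`.
#' @export
bpkm_normalize <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  if (track$total_mapped_bases <= 0) {
    stop("total mapped bases must be positive for BPKM normalization",
         call. = FALSE)
  }
  lapply(track$scaffolds, function(d) d * 1e9 / track$total_mapped_bases)
}

#' Upper rank boundary of a geometric BPKM group
#'
#' Bases are ranked by BPKM from high to low and cut into 19 groups whose
#' cumulative spans double: group 1 holds ranks 1-400, group `g >= 2` holds
#' ranks `400 * 2^(g-2) + 1` to `400 * 2^(g-1)`. The cumulative upper
#' boundary of group `g` is therefore `400 * 2^(g-1)`.
#'
#' @param g Group index (vectorized), each in `1:19`.
#' @return Cumulative upper rank boundary in bases.
#' @examples
#' group_boundary(1)   # 400
#' group_boundary(4)   # 3200
#' group_boundary(12)  # 819200
#' @export
group_boundary <- function(g) {
  if (!is.numeric(g) || anyNA(g) || any(g != round(g)) ||
      any(g < 1) || any(g > 19)) {
    stop("group index must be in 1..19", call. = FALSE)
  }
  400 * 2^(g - 1)
}

#' Stratify a depth track into the 19 geometric BPKM rank groups
#'
#' Ranks every base of the (scaffold-filtered) track by BPKM descending —
#' ties broken by scaffold identifier then position, a deterministic rule —
#' then summarizes each rank group: mean BPKM and the share of all aligned
#' bases carried by the group. Bases beyond rank `400 * 2^18` and all
#' zero-depth bases fall into an explicit remainder.
#'
#' Only nonzero-depth positions are sorted; zero-depth bases tie at BPKM 0
#' and only their count matters, so results equal a whole-genome sort.
#'
#' @param track A [depth_track()] (apply [filter_scaffolds()] first).
#' @return An object of class `strata_summary`: a `data.frame` with columns
#'   `group`, `rank_lo`, `rank_hi` (the span `(rank_lo, rank_hi]`),
#'   `n_bases`, `mean_bpkm`, `share`; attributes `remainder_share`,
#'   `library_id`, `total_mapped_bases`, `genome_size`.
#' @export
stratify <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  if (track$total_mapped_bases <= 0) {
    stop("total mapped bases must be positive", call. = FALSE)
  }
  n_total <- genome_size(track)
  scaf_ids <- names(track$scaffolds)
  ord_scaf <- order(scaf_ids)  # tie-break order: scaffold id, then position

  depth <- unlist(track$scaffolds[ord_scaf], use.names = FALSE)
  nz <- which(depth > 0)
  d_nz <- depth[nz]
  # stable sort: equal depths keep (scaffold, position) order
  o <- order(-d_nz, method = "radix")
  sorted <- d_nz[o]
  n_nz <- length(sorted)

  total <- track$total_mapped_bases
  scale <- 1e9 / total
  bounds <- group_boundary(1:19)
  los <- c(0, bounds[-19])
  cum <- cumsum(sorted)

  res <- data.frame(group = 1:19, rank_lo = los, rank_hi = bounds,
                    n_bases = 0, mean_bpkm = 0, share = 0)
  for (g in 1:19) {
    lo <- min(los[g], n_total)
    hi <- min(bounds[g], n_total)
    width <- hi - lo
    res$n_bases[g] <- width
    if (width <= 0) next
    # depth mass inside (lo, hi]: only ranks <= n_nz carry depth
    hi_nz <- min(hi, n_nz)
    lo_nz <- min(lo, n_nz)
    mass <- if (hi_nz > lo_nz) {
      cum[hi_nz] - if (lo_nz > 0) cum[lo_nz] else 0
    } else 0
    res$share[g] <- mass / total
    res$mean_bpkm[g] <- mass * scale / width
  }
  remainder <- 1 - sum(res$share)
  structure(res,
            remainder_share = remainder,
            library_id = track$library_id,
            total_mapped_bases = total,
            genome_size = n_total,
            class = c("strata_summary", "data.frame"))
}

#' Z-scores of per-group mean BPKM across a panel of libraries
#'
#' For each rank group, the per-library mean BPKM values are standardized
#' across libraries (sample sd; zero-spread groups map to z = 0), the
#' heatmap-ready statistic for comparing coverage concentration between
#' libraries.
#'
#' @param panel List of `strata_summary` objects (one per library).
#' @return A 19 x L matrix of z-scores with library ids as columns.
#' @export
strata_zscores <- function(panel) {
  if (length(panel) < 2) stop("need at least 2 libraries", call. = FALSE)
  stopifnot(all(vapply(panel, inherits, logical(1), "strata_summary")))
  m <- vapply(panel, function(s) s$mean_bpkm, numeric(19))
  ids <- vapply(panel, function(s) {
    id <- attr(s, "library_id")
    if (is.na(id)) NA_character_ else id
  }, character(1))
  if (!anyNA(ids) && !anyDuplicated(ids)) colnames(m) <- ids
  rownames(m) <- paste0("group_", 1:19)
  row_zscores(m)$z
}

#' Read and write depth tracks as 3-column TSV
#'
#' The text layout is `scaffold`, 1-based `position`, `depth`; zero-depth
#' rows may be omitted. Scaffold lengths come from a 2-column table
#' (`scaffold`, `length`).
#'
#' @param path Depth TSV path.
#' @param lengths Named numeric vector of scaffold lengths, or path to a
#'   2-column TSV.
#' @param library_id Optional library identifier.
#' @return `read_depth_tsv()` returns a [depth_track()]; `write_depth_tsv()`
#'   returns `path` invisibly (zero-depth rows are omitted).
#' @export
read_depth_tsv <- function(path, lengths, library_id = NA_character_) {
  if (is.character(lengths) && length(lengths) == 1) {
    lt <- utils::read.delim(lengths, header = FALSE,
                            col.names = c("scaffold", "length"))
    lengths <- stats::setNames(lt$length, lt$scaffold)
  }
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("scaffold", "position", "depth"),
                          colClasses = c("character", "numeric", "numeric"))
  scaffolds <- lapply(stats::setNames(names(lengths), names(lengths)),
                      function(s) {
    d <- numeric(lengths[[s]])
    rows <- df[df$scaffold == s, ]
    if (nrow(rows)) {
      if (any(rows$position < 1 | rows$position > lengths[[s]])) {
        stop(sprintf("position out of bounds on scaffold '%s'", s),
             call. = FALSE)
      }
      d[rows$position] <- rows$depth
    }
    d
  })
  unknown <- setdiff(unique(df$scaffold), names(lengths))
  if (length(unknown)) {
    stop("depth rows for scaffolds without lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  depth_track(scaffolds, library_id = library_id)
}

#' @param track A [depth_track()].
#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  rows <- do.call(rbind, lapply(names(track$scaffolds), function(s) {
    d <- track$scaffolds[[s]]
    nz <- which(d > 0)
    if (!length(nz)) return(NULL)
    data.frame(scaffold = s, position = nz, depth = d[nz])
  }))
  if (is.null(rows)) rows <- data.frame(scaffold = character(0),
                                        position = numeric(0),
                                        depth = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
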
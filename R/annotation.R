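#' Strand-agnostic genome fraction covered by annotation features
#'
#' Computes, per feature class, the fraction of the genome inside the
#' strand-agnostic union of that class's intervals. Gene spans are defined as
#' the maximum distance between a gene's exon edges: when no `gene` rows are
#' supplied they are derived per `gene_id` from the exon records.
#'
#' @param intervals A `data.frame` with columns `scaffold`, `feature`
#'   (`"gene"`, `"exon"` or `"CDS"`), `start`, `end` (1-based inclusive),
#'   `strand`, `gene_id`.
#' @param genome_size Total genome length in bases, or a named vector of
#'   scaffold lengths (then also used for bounds checking).
#' @return Named numeric vector of fractions for `gene`, `exon` and `CDS`.
#' @export
annotation_coverage <- function(intervals, genome_size) {
  intervals <- as.data.frame(intervals)
  need <- c("scaffold", "feature", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(intervals)) {
    bad <- which(intervals$start < 1 | intervals$end < intervals$start)
    if (!is.null(names(genome_size))) {
      hi <- genome_size[intervals$scaffold]
      bad <- union(bad, which(is.na(hi) | intervals$end > hi))
    }
    if (length(bad)) {
      r <- intervals[min(bad), ]
      stop(sprintf("interval out of bounds: %s %s %d-%d (%s)",
                   r$scaffold, r$feature, r$start, r$end, r$gene_id),
           call. = FALSE)
    }
  }
  total <- sum(genome_size)

  # derive gene spans from exon edges when gene rows are absent
  if (!any(intervals$feature == "gene") && any(intervals$feature == "exon")) {
    ex <- intervals[intervals$feature == "exon", ]
    key <- paste(ex$scaffold, ex$gene_id, sep = "\r")
    genes <- data.frame(
      scaffold = vapply(split(ex$scaffold, key), `[`, character(1), 1),
      feature = "gene",
      start = vapply(split(ex$start, key), min, numeric(1)),
      end = vapply(split(ex$end, key), max, numeric(1)),
      strand = "*",
      gene_id = vapply(split(ex$gene_id, key), `[`, character(1), 1)
    )
    intervals <- rbind(intervals, genes)
  }

  union_width <- function(rows) {
    if (!nrow(rows)) return(0)
    sum(vapply(split(rows, rows$scaffold), function(r) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = r$start, end = r$end))))
    }, numeric(1)))
  }
  vapply(stats::setNames(c("gene", "exon", "CDS"), c("gene", "exon", "CDS")),
         function(f) union_width(intervals[intervals$feature == f, ]) / total,
         numeric(1))
}

#' Regress genome coverage on aligned bases, per sequencing mode
#'
#' Ordinary least squares of the covered genome fraction on the number of
#' aligned bases, fitted separately for single-end (`S`) and paired-end
#' (`P`) libraries; residuals flag libraries whose coverage is unusually
#' concentrated (below the line) or unusually dispersed (above it).
#'
#' @param points A `data.frame` with columns `aligned_bases`,
#'   `covered_fraction`, `mode` (`"S"`/`"P"`), and optionally `library_id`.
#' @return A named list per mode with elements `slope`, `intercept`,
#'   `residuals` (named by library when ids are given); modes with fewer
#'   than 2 points are skipped with a warning.
#' @export
regress_coverage <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("aligned_bases", "covered_fraction", "mode") %in%
                  names(points)))
  fits <- list()
  for (m in unique(points$mode)) {
    sub <- points[points$mode == m, ]
    if (nrow(sub) < 2) {
      warning(sprintf("mode '%s' has fewer than 2 points; skipped", m))
      next
    }
    fit <- stats::lm(covered_fraction ~ aligned_bases, data = sub)
    res <- stats::residuals(fit)
    if (!is.null(sub$library_id)) names(res) <- sub$library_id
    fits[[m]] <- list(mode = m,
                      slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      residuals = res)
  }
  fits
}
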
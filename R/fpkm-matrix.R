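#' FPKM expression matrix with library metadata
#'
#' The central container of the package: a nonnegative gene x library matrix
#' of FPKM values plus per-library metadata (tissue, developmental stage, and
#' sequencing mode, single-end `"S"` or paired-end `"P"`).
#'
#' @param values Numeric matrix, genes as rows, libraries as columns. Row and
#'   column names are used as gene and library identifiers when `gene_ids` /
#'   `library_ids` are not given.
#' @param library_meta A `data.frame` with one row per library and columns
#'   `tissue`, `stage`, `seq_mode`; row order matches the matrix columns.
#'   Optional: defaults to unknown metadata.
#' @param gene_ids,library_ids Character vectors of unique identifiers.
#'
#' @return An object of class `fpkm_matrix`: a list with elements `values`
#'   (the named matrix) and `library_meta`.
#'
#' @examples
#' m <- matrix(c(1, 0, 5, 2, 3, 8), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("libA", "libB")))
#' fm <- fpkm_matrix(m)
#' dim(fm$values)
#' @export
fpkm_matrix <- function(values, library_meta = NULL,
                        gene_ids = rownames(values),
                        library_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(library_ids)) library_ids <- paste0("lib_", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(library_ids)) stop("duplicated library ids", call. = FALSE)
  if (length(gene_ids) != nrow(values) || length(library_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("FPKM values must be nonnegative and non-missing", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, library_ids)
  if (is.null(library_meta)) {
    library_meta <- data.frame(
      library_id = library_ids,
      tissue = NA_character_, stage = NA_character_, seq_mode = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    library_meta <- as.data.frame(library_meta)
    if (is.null(library_meta$library_id)) library_meta$library_id <- library_ids
    need <- c("library_id", "tissue", "stage", "seq_mode")
    miss <- setdiff(need, names(library_meta))
    for (nm in miss) library_meta[[nm]] <- NA_character_
    library_meta <- library_meta[match(library_ids, library_meta$library_id),
                                 need, drop = FALSE]
    if (anyNA(library_meta$library_id)) {
      stop("library_meta does not cover every library id", call. = FALSE)
    }
    rownames(library_meta) <- NULL
  }
  structure(list(values = values, library_meta = library_meta),
            class = "fpkm_matrix")
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat(sprintf("<fpkm_matrix> %d genes x %d libraries\n",
              nrow(x$values), ncol(x$values)))
  tis <- unique(stats::na.omit(x$library_meta$tissue))
  if (length(tis)) cat("tissues:", paste(tis, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write FPKM matrices as tab-separated text
#'
#' The layout mirrors the deposited supplementary expression tables: a header
#' row of library identifiers and a first column of gene identifiers.
#'
#' @param path File path.
#' @param library_meta Optional metadata `data.frame` passed to
#'   [fpkm_matrix()].
#' @return `read_fpkm_tsv()` returns an [fpkm_matrix()];
#'   `write_fpkm_tsv()` returns `path` invisibly.
#' @export
read_fpkm_tsv <- function(path, library_meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  fpkm_matrix(values, library_meta = library_meta, gene_ids = gene_ids,
              library_ids = colnames(values))
}

#' @param x An [fpkm_matrix()].
#' @rdname read_fpkm_tsv
#' @export
write_fpkm_tsv <- function(x, path) {
  stopifnot(inherits(x, "fpkm_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table in the supplementary-spreadsheet layout
#'
#' Reads the first sheet of an `.xlsx` workbook whose first column holds gene
#' identifiers and whose header row holds library names (the layout used by
#' the deposited OGS2.0/Cufflinks4.0/MCOT1.0 FPKM tables). Requires the
#' `readxl` package.
#'
#' @param path Path to the `.xlsx` file.
#' @param sheet Sheet name or index (default first).
#' @inheritParams read_fpkm_tsv
#' @return An [fpkm_matrix()].
#' @export
read_fpkm_xlsx <- function(path, sheet = 1, library_meta = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx tables requires the 'readxl' package", call. = FALSE)
  }
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  gene_ids <- as.character(df[[1L]])
  num <- vapply(df[-1L], is.numeric, logical(1))
  values <- as.matrix(df[, -1L, drop = FALSE][, num, drop = FALSE])
  fpkm_matrix(values, library_meta = library_meta, gene_ids = gene_ids,
              library_ids = colnames(values))
}
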
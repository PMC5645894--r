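#' Configuration for a synthetic expression atlas
#'
#' Describes a seeded synthetic gene x library FPKM matrix with planted
#' tissue-specific marker genes. Baseline expression is log-normal on the
#' natural-log scale (FPKM distributions are heavy-tailed and strictly
#' positive); each planted marker is multiplied by `effect_multiplier` in
#' every library of its home tissue and nowhere else, and every cell carries
#' independent multiplicative log-normal noise.
#'
#' The default library design mirrors a multi-tissue developmental atlas at
#' desk scale: several tissues sampled at a few stages each, so any one
#' tissue contributes only a small fraction of the libraries and a marker's
#' z-score stands out in its home libraries.
#'
#' @param n_genes Number of genes (>= 1).
#' @param libraries A `data.frame` with columns `library_id`, `tissue`,
#'   `stage`, `seq_mode` (`"S"` or `"P"`); `library_id` must be unique.
#'   Defaults to 10 tissues x 4 stages = 40 libraries, so each tissue holds
#'   a small fraction of the libraries as in a real atlas.
#' @param baseline_log_mean,baseline_log_sd Mean and sd of per-gene baseline
#'   log-FPKM (natural log).
#' @param marker_fraction Fraction of genes planted as markers of each tissue
#'   (in `[0, 0.5]`); markers of different tissues are disjoint.
#' @param effect_multiplier Fold-change of a marker in its home tissue
#'   (>= 1).
#' @param noise_log_sd Sd of multiplicative log-normal noise per cell.
#' @param seed Integer seed; identical seeds give bit-identical atlases.
#'
#' @return An object of class `atlas_config`.
#' @seealso [generate_fpkm_matrix()]
#' @export
atlas_config <- function(n_genes = 2000,
                         libraries = default_library_design(),
                         baseline_log_mean = 1,
                         baseline_log_sd = 1.5,
                         marker_fraction = 0.05,
                         effect_multiplier = 8,
                         noise_log_sd = 0.3,
                         seed = 1L) {
  bad <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != round(n_genes)) bad("n_genes", "must be a positive count")
  libraries <- as.data.frame(libraries)
  need <- c("library_id", "tissue", "stage", "seq_mode")
  if (!all(need %in% names(libraries))) {
    bad("libraries", paste("needs columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(libraries$library_id)) {
    bad("libraries", "library_id values must be unique")
  }
  if (!all(libraries$seq_mode %in% c("S", "P"))) {
    bad("libraries", "seq_mode must be 'S' or 'P'")
  }
  if (!is.numeric(marker_fraction) || marker_fraction < 0 ||
      marker_fraction > 0.5) bad("marker_fraction", "must lie in [0, 0.5]")
  if (!is.numeric(effect_multiplier) || effect_multiplier < 1) {
    bad("effect_multiplier", "must be >= 1")
  }
  if (!is.numeric(noise_log_sd) || noise_log_sd < 0) {
    bad("noise_log_sd", "must be >= 0")
  }
  if (!is.numeric(baseline_log_sd) || baseline_log_sd < 0) {
    bad("baseline_log_sd", "must be >= 0")
  }
  n_tissues <- length(unique(libraries$tissue))
  n_markers <- floor(marker_fraction * n_genes) * n_tissues
  if (n_markers > n_genes) {
    bad("marker_fraction", "total planted markers exceed n_genes")
  }
  structure(list(
    n_genes = as.integer(n_genes), libraries = libraries,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    marker_fraction = marker_fraction, effect_multiplier = effect_multiplier,
    noise_log_sd = noise_log_sd, seed = as.integer(seed)
  ), class = "atlas_config")
}

#' Default synthetic library design: 10 tissues x 4 stages
#'
#' A desk-scale stand-in for a large multi-tissue atlas. The design keeps
#' each tissue's share of the libraries small (1/10): with z-score-based
#' marker calling, the home-library fraction — not the absolute library
#' count — determines how far a planted marker's z-score rises above the
#' threshold.
#'
#' @return A `data.frame` of 40 libraries with tissue, stage and sequencing
#'   mode, alternating single- and paired-end modes across tissues.
#' @export
default_library_design <- function() {
  tissues <- c("head", "midgut", "fatbody", "muscle", "testis",
               "ovary", "malpighian", "wholebody", "gut", "antenna")
  stages <- c("L5", "wandering", "pupa", "adult")
  grid <- expand.grid(stage = stages, tissue = tissues,
                      stringsAsFactors = FALSE)[, c("tissue", "stage")]
  data.frame(
    library_id = paste(grid$tissue, grid$stage, sep = "-"),
    tissue = grid$tissue,
    stage = grid$stage,
    seq_mode = ifelse(match(grid$tissue, tissues) %% 2 == 0, "P", "S"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic FPKM atlas with planted tissue markers
#'
#' Draws a gene x library FPKM matrix under an [atlas_config()] and returns
#' it together with the planted ground truth: which genes are markers of
#' which tissue. Markers are exclusive to one tissue, so downstream recovery
#' tests are unambiguous.
#'
#' @param config An [atlas_config()].
#' @return A list with elements
#'   * `matrix`: an [fpkm_matrix()];
#'   * `truth`: a list with `marker_assignment` (named character vector,
#'     `gene_id -> tissue`; genes absent from it are background) and
#'     `config` (the echoed configuration).
#'
#' @examples
#' cfg <- atlas_config(n_genes = 200, seed = 42)
#' atlas <- generate_fpkm_matrix(cfg)
#' table(atlas$truth$marker_assignment)
#' @export
generate_fpkm_matrix <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  n_genes <- config$n_genes
  libs <- config$libraries
  n_libs <- nrow(libs)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  tissues <- unique(libs$tissue)
  per_tissue <- floor(config$marker_fraction * n_genes)

  res <- with_seed(config$seed, {
    marker_genes <- if (per_tissue > 0) {
      sample(gene_ids, per_tissue * length(tissues))
    } else character(0)
    assignment <- if (length(marker_genes)) {
      stats::setNames(rep(tissues, each = per_tissue), marker_genes)
    } else {
      stats::setNames(character(0), character(0))
    }
    baseline <- stats::rnorm(n_genes, config$baseline_log_mean,
                             config$baseline_log_sd)
    logv <- matrix(baseline, nrow = n_genes, ncol = n_libs)
    if (length(marker_genes)) {
      idx <- match(marker_genes, gene_ids)
      home <- outer(assignment, libs$tissue, "==")
      logv[idx, ] <- logv[idx, ] + log(config$effect_multiplier) * home
    }
    noise <- matrix(stats::rnorm(n_genes * n_libs, 0, config$noise_log_sd),
                    nrow = n_genes)
    list(values = exp(logv + noise), assignment = assignment)
  })

  dimnames(res$values) <- list(gene_ids, libs$library_id)
  list(
    matrix = fpkm_matrix(res$values, library_meta = libs),
    truth = list(marker_assignment = res$assignment, config = config)
  )
}
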
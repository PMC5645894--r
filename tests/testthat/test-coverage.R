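test_that("transcribed fraction counts nonzero bases", {
  expect_equal(transcribed_fraction(depth_track(list(s = c(0, 1, 0, 3)))), 0.5)
  expect_equal(transcribed_fraction(depth_track(list(s = rep(0, 10)))), 0)
  expect_equal(transcribed_fraction(depth_track(list(s = 1:10))), 1)
  expect_error(transcribed_fraction(depth_track(structure(list(),
                                                          names = character(0)))),
               "empty")
})

test_that("scaffold filtering removes short scaffolds and recomputes totals", {
  tr <- depth_track(list(big = rep(1, 300), small = rep(5, 150)))
  kept <- filter_scaffolds(tr, min_len = 200)
  expect_named(kept$scaffolds, "big")
  expect_equal(kept$total_mapped_bases, 300)
  expect_equal(filter_scaffolds(tr, min_len = 0)$scaffolds, tr$scaffolds)
  none <- filter_scaffolds(tr, min_len = 1000)
  expect_length(none$scaffolds, 0)
})

test_that("BPKM is depth x 1e9 / total and scale-invariant", {
  tr <- depth_track(list(s = c(3, 0, 5)))
  b <- bpkm_normalize(tr)$s
  expect_equal(b, c(3, 0, 5) * 1e9 / 8)
  # multiplying all depths by an integer leaves BPKM unchanged, exactly
  tr7 <- depth_track(list(s = c(3, 0, 5) * 7))
  expect_identical(bpkm_normalize(tr7)$s, b)
  expect_error(bpkm_normalize(depth_track(list(s = c(0, 0)))), "positive")
})

test_that("group boundaries follow the geometric closed form", {
  expect_equal(group_boundary(1), 400)
  expect_equal(group_boundary(4), 3200)
  expect_equal(group_boundary(12), 819200)
  # closed form equals iterated doubling for all groups
  doubled <- Reduce(function(acc, g) c(acc, 2 * acc[length(acc)]),
                    2:19, accumulate = FALSE, init = 400)
  expect_equal(group_boundary(1:19), doubled)
  expect_error(group_boundary(0), "1..19")
  expect_error(group_boundary(20), "1..19")
})

test_that("stratification handles uniform and point-mass tracks", {
  uni <- depth_track(list(a = rep(2, 500), b = rep(2, 500)))
  s <- stratify(uni)
  nonempty <- s$n_bases > 0
  expect_true(all(abs(s$mean_bpkm[nonempty] -
                        s$mean_bpkm[which(nonempty)[1]]) < 1e-9))

  point <- depth_track(list(a = c(rep(0, 99), 1000), b = rep(0, 100)))
  sp <- stratify(point)
  expect_equal(sp$share[1], 1.0)
  expect_equal(attr(sp, "remainder_share"), 0)
})

test_that("stratification matches the brute-force whole-genome sort", {
  tr <- generate_depth_track(5, 200000, 5e6, tail_exponent = 1.1, seed = 33)
  s <- stratify(tr)
  ref <- oracle_stratify(tr)
  expect_equal(s$share, ref$share, tolerance = 1e-12)
  expect_equal(s$mean_bpkm, ref$mean_bpkm, tolerance = 1e-12)
  expect_equal(attr(s, "remainder_share"), ref$remainder, tolerance = 1e-12)
  expect_lt(abs(sum(s$share) + attr(s, "remainder_share") - 1), 1e-9)
})

test_that("strata z-scores standardize each group across libraries", {
  mk <- function(mult, id) {
    stratify(depth_track(list(a = rep(mult, 1000)), library_id = id))
  }
  same <- strata_zscores(list(mk(2, "x"), mk(2, "y"), mk(2, "z")))
  expect_true(all(same == 0))

  tracks <- list(
    stratify(generate_depth_track(1, 5000, 10000, 1.0, seed = 1,
                                  library_id = "L1")),
    stratify(generate_depth_track(1, 5000, 20000, 1.4, seed = 2,
                                  library_id = "L2")),
    stratify(generate_depth_track(1, 5000, 30000, 1.8, seed = 3,
                                  library_id = "L3"))
  )
  z <- strata_zscores(tracks)
  expect_equal(dim(z), c(19L, 3L))
  expect_true(all(abs(rowSums(z)) < 1e-9))
  # a hand-checked group: values v -> (v - mean)/sd with ddof 1
  v <- vapply(tracks, function(s) s$mean_bpkm[1], numeric(1))
  expect_equal(unname(z[1, ]), unname((v - mean(v)) / stats::sd(v)))
  expect_error(strata_zscores(tracks[1]), "2 libraries")
})

test_that("annotation coverage takes strand-agnostic interval unions", {
  iv <- data.frame(
    scaffold = "s1", feature = "exon",
    start = c(1, 51), end = c(100, 150),
    strand = c("+", "-"), gene_id = c("gA", "gB")
  )
  cov <- annotation_coverage(iv, genome_size = 1000)
  expect_equal(unname(cov["exon"]), 0.15)  # union 1-150
  # gene spans derived from exon edges per gene
  expect_equal(unname(cov["gene"]), 0.15)
  expect_equal(unname(cov["CDS"]), 0)

  # repetition does not change a union
  rep5 <- iv[rep(1, 5), ]
  expect_equal(annotation_coverage(rep5, 1000)[["exon"]], 0.1)

  none <- annotation_coverage(iv[0, ], 1000)
  expect_true(all(none == 0))

  expect_error(
    annotation_coverage(data.frame(scaffold = "s1", feature = "exon",
                                   start = 10, end = 2000, strand = "+",
                                   gene_id = "gX"),
                        genome_size = c(s1 = 1000)),
    "out of bounds")
})

test_that("gene spans use the maximum exon-edge distance per gene", {
  iv <- data.frame(
    scaffold = "s1", feature = "exon",
    start = c(1, 401), end = c(100, 500),
    strand = "+", gene_id = "gA"
  )
  cov <- annotation_coverage(iv, genome_size = 1000)
  expect_equal(unname(cov["exon"]), 0.2)  # two 100-base exons
  expect_equal(unname(cov["gene"]), 0.5)  # span 1-500 across the intron
})

test_that("coverage regression recovers per-mode lines and centers residuals", {
  exact <- data.frame(aligned_bases = 1:5,
                      covered_fraction = 2 * (1:5) + 1,
                      mode = "P", library_id = paste0("L", 1:5))
  fit <- regress_coverage(exact)$P
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(abs(sum(fit$residuals)), 1e-9)

  noisy <- withr::with_seed(55, {
    x <- seq(0.1, 3, length.out = 30)
    data.frame(aligned_bases = c(x, x),
               covered_fraction = c(1.5 * x + 0.2 + stats::rnorm(30, 0, 0.05),
                                    0.8 * x + 0.1 + stats::rnorm(30, 0, 0.05)),
               mode = rep(c("S", "P"), each = 30))
  })
  fits <- regress_coverage(noisy)
  expect_lt(abs(fits$S$slope - 1.5), 0.1)
  expect_lt(abs(fits$P$slope - 0.8), 0.1)
  expect_lt(abs(sum(fits$S$residuals)), 1e-9)

  solo <- data.frame(aligned_bases = 1, covered_fraction = 1, mode = "Q")
  expect_warning(regress_coverage(solo), "fewer than 2")
})
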
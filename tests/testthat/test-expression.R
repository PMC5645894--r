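test_that("z-scores standardize each gene row", {
  m <- fpkm_matrix(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  z <- compute_zscores(m)
  expect_equal(unname(z$values["a", ]), c(-1, 0, 1))  # mu = 2, s = 1 (ddof 1)
  expect_equal(unname(z$values["b", ]), c(0, 0, 0))   # zero-spread rule
  expect_equal(unname(z$gene_mean), c(2, 5))
  expect_equal(unname(z$gene_sd), c(1, 0))

  zp <- compute_zscores(m, sd_type = "population")
  expect_equal(unname(zp$values["a", ]), c(-1, 0, 1) * sqrt(3 / 2))

  expect_error(compute_zscores(fpkm_matrix(matrix(1:3, ncol = 1))),
               "2 libraries")
})

test_that("standardization identities hold on random matrices", {
  atlas <- generate_fpkm_matrix(atlas_config(n_genes = 400, seed = 17))
  z <- compute_zscores(atlas$matrix)
  nonconst <- z$gene_sd > 0
  expect_lt(max(abs(rowMeans(z$values[nonconst, ]))), 1e-9)
  sds <- apply(z$values[nonconst, ], 1, stats::sd)
  expect_lt(max(abs(sds - 1)), 1e-9)
})

test_that("correlated-gene calling applies both strict thresholds", {
  vals <- rbind(
    low  = c(0.2, 0.9, 0.8, 0.5, 0.3, 0.4),  # never passes FPKM > 1
    hit  = c(50, 1, 1, 1, 1, 1),
    flat = c(10, 10, 10, 10, 10, 10)
  )
  colnames(vals) <- paste0("L", 1:6)
  m <- fpkm_matrix(vals)
  z <- compute_zscores(m)
  # hand computation: row (50,1,1,1,1,1), mu = 9.1667, s = 20.0042
  expect_equal(unname(z$values["hit", 1]), 2.0412, tolerance = 1e-4)
  sets <- call_correlated_genes(m, z)
  expect_equal(sets[["L1"]], "hit")
  expect_true(all(lengths(sets[-1]) == 0))
})

test_that("raising thresholds never enlarges a correlated set", {
  atlas <- generate_fpkm_matrix(atlas_config(n_genes = 500, seed = 23))
  loose <- call_correlated_genes(atlas$matrix, z_min = 1.5, fpkm_min = 1)
  for (z_min in c(2, 2.5)) {
    tight <- call_correlated_genes(atlas$matrix, z_min = z_min, fpkm_min = 1)
    expect_true(all(mapply(function(a, b) all(a %in% b), tight, loose)))
  }
  tight_f <- call_correlated_genes(atlas$matrix, z_min = 1.5, fpkm_min = 10)
  expect_true(all(mapply(function(a, b) all(a %in% b), tight_f, loose)))
})

test_that("scaling one gene's row moves membership only via the FPKM filter", {
  atlas <- generate_fpkm_matrix(atlas_config(n_genes = 200, seed = 29))
  m <- atlas$matrix
  z1 <- compute_zscores(m)
  g <- rownames(m$values)[7]
  scaled <- m$values
  scaled[g, ] <- scaled[g, ] * 37.5
  m2 <- fpkm_matrix(scaled, library_meta = m$library_meta)
  z2 <- compute_zscores(m2)
  expect_equal(z1$values[g, ], z2$values[g, ], tolerance = 1e-12)
})

test_that("planted markers are recovered with few background false calls", {
  cfg <- atlas_config(n_genes = 2000, effect_multiplier = 8,
                      noise_log_sd = 0.3, seed = 41)
  atlas <- generate_fpkm_matrix(cfg)
  sets <- call_correlated_genes(atlas$matrix)
  truth <- atlas$truth$marker_assignment
  libs <- atlas$matrix$library_meta
  hits <- 0L; pairs <- 0L
  for (g in names(truth)) {
    for (l in libs$library_id[libs$tissue == truth[[g]]]) {
      pairs <- pairs + 1L
      hits <- hits + (g %in% sets[[l]])
    }
  }
  expect_gte(hits / pairs, 0.9)
  background <- setdiff(rownames(atlas$matrix$values), names(truth))
  fpr <- mean(vapply(sets, function(s) mean(background %in% s), numeric(1)))
  expect_lte(fpr, 0.1)
})

test_that("high-expression counts bound correlated-set sizes", {
  m <- toy_fpkm()
  sets <- structure(list(lib1 = c("g_spike", "g_mid"),
                         lib2 = c("g_mid"),
                         lib3 = character(0),
                         lib4 = character(0)),
                    z_min = 1.5, fpkm_min = 1, n_genes = 5,
                    gene_ids = rownames(m$values),
                    class = "correlated_sets")
  counts <- count_high_expression(m, sets, threshold = 100)
  expect_equal(unname(counts), c(1L, 1L, 0L, 0L))  # 200 and 120 exceed 100
  expect_true(all(counts <= lengths(sets)))
})

test_that("top-gene selection deduplicates across libraries in order", {
  vals <- cbind(L1 = c(10, 9, 8, 1), L2 = c(10, 9, 8, 1),
                L3 = c(1, 2, 3, 100))
  rownames(vals) <- paste0("g", 1:4)
  m <- fpkm_matrix(vals)
  expect_equal(select_top_genes(m, k = 2), c("g1", "g2", "g4", "g3"))
  # full overlap -> exactly k genes
  shared <- fpkm_matrix(cbind(L1 = c(5, 4, 1), L2 = c(6, 5, 1)),
                        gene_ids = paste0("s", 1:3))
  expect_equal(select_top_genes(shared, k = 2), c("s1", "s2"))
  # k larger than the gene count is capped
  expect_length(select_top_genes(shared, k = 10), 3)
  expect_error(select_top_genes(shared, k = 0), ">= 1")
})

test_that("log2(FPKM + 1) transform hits its anchor points", {
  m <- fpkm_matrix(matrix(c(0, 1, 7, 3), 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  lt <- log_transform(m)
  expect_equal(lt["a", "x"], 0)
  expect_equal(lt["b", "x"], 1)
  expect_equal(lt["a", "y"], 3)  # log2(8)
})

test_that("heatmap gene selection is a strict row-maximum filter", {
  vals <- rbind(over = c(100.5, 1), at = c(100, 50), zero = c(0, 0))
  m <- fpkm_matrix(vals, library_ids = c("L1", "L2"))
  expect_equal(select_heatmap_genes(m), "over")
  expect_length(select_heatmap_genes(fpkm_matrix(
    matrix(0, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))), 0)
})

test_that("cluster ordering keeps duplicated rows and planted blocks together", {
  z <- rbind(a = c(1, -1, 0, 0), b = c(1, -1, 0, 0), c = c(-1, 1, 0, 0))
  ord <- cluster_order(z)
  pos <- match(1:2, ord)  # rows a and b are identical
  expect_equal(abs(diff(pos)), 1)
  expect_equal(cluster_order(z[1, , drop = FALSE]), 1)

  # two planted z-pattern blocks stay contiguous
  block <- function(sign) matrix(rep(sign * c(2, 2, -1, -1, -1, -1), 6),
                                 nrow = 6, byrow = TRUE)
  zm <- withr::with_seed(101, {
    rbind(block(1) + matrix(stats::rnorm(36, 0, 0.05), 6),
          block(-1) + matrix(stats::rnorm(36, 0, 0.05), 6))
  })
  ord2 <- cluster_order(zm)
  labels <- rep(c(1, 2), each = 6)[ord2]
  expect_equal(length(rle(labels)$lengths), 2)
})

test_that("census counts genes correlated with at least one library", {
  atlas <- generate_fpkm_matrix(atlas_config(n_genes = 300, seed = 31))
  sets <- call_correlated_genes(atlas$matrix)
  cen <- census_correlated(sets)
  expect_equal(cen, length(unique(unlist(sets))))
  expect_lte(cen, 300)
})
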
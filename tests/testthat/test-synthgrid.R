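test_that("study-design configuration yields 63 ROIs and exact spot counts", {
  cc <- cohort_config(grid_shape = c(6, 6), n_background_genes = 10,
                      seed = 3)
  co <- generate_cohort(cc)
  expect_identical(length(unique(co$spot_table$roi)), 63L)
  expect_identical(nrow(co$spot_table), 63L * 6L * 6L)
  expect_identical(ncol(co$counts), nrow(co$spot_table))
  # per-group donor counts 5/5/6/5
  donors <- unique(co$spot_table[, c("donor", "group")])
  expect_equal(unname(table(donors$group)[c("CTRL", "CTD-ILD", "OP", "IPF")]),
               c(5L, 5L, 6L, 5L), ignore_attr = TRUE)
})

test_that("degenerate configurations error rather than produce empty cohorts", {
  expect_error(cohort_config(donors_per_group = c(0, 0, 0, 0)),
               "no donors")
  expect_error(cohort_config(grid_shape = c(0, 5)), "positive")
  pr <- list(A = c(X = 0.6, Y = 0.5))
  expect_error(cohort_config(groups = "A", donors_per_group = 1,
                             celltype_priors = pr),
               "sum to 1")
})

test_that("identical config and seed reproduce the cohort bit-for-bit", {
  a <- generate_cohort(small_config(seed = 11))
  b <- generate_cohort(small_config(seed = 11))
  expect_identical(a$spot_table, b$spot_table)
  expect_identical(a$weights, b$weights)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  c2 <- generate_cohort(small_config(seed = 12))
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))
})

test_that("grid geometry: 8 um pitch, row-major lattice, per-ROI origin", {
  co <- generate_cohort(small_config(seed = 2))
  one <- co$spot_table[co$spot_table$roi == co$spot_table$roi[1], ]
  expect_equal(sort(unique(one$x_um)), (0:7) * 8)
  expect_equal(sort(unique(one$y_um)), (0:7) * 8)
  expect_equal(nrow(one), 64L)
})

test_that("realised composition converges to the configured prior", {
  pr <- c(AT2 = 0.3, B_cell = 0.1, Fib_myo = 0.4, Macrophage = 0.2)
  cc <- cohort_config(groups = "G", donors_per_group = 1,
                      rois_per_donor = 1, grid_shape = c(48, 48),
                      celltype_priors = list(G = pr), niche_specs = list(),
                      signatures = "GC_Response", genes_per_signature = 2,
                      n_background_genes = 4, score_correlation = NULL,
                      stage_groups = character(0), seed = 5)
  co <- generate_cohort(cc)
  freq <- table(factor(co$truth$labels$label, levels = names(pr)))
  l1 <- sum(abs(freq / sum(freq) - pr))
  expect_lt(l1, 0.05)
})

test_that("weights are valid deconvolution output aligned with spots", {
  co <- generate_cohort(small_config(seed = 4))
  w <- as.matrix(co$weights[, -1])
  expect_true(all(w >= 0))
  expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-12)
  expect_identical(co$weights$spot_id, co$spot_table$spot_id)
  expect_identical(colnames(co$counts), co$spot_table$spot_id)
})

test_that("doubling the signature fold raises signature-gene counts in targeted spots", {
  base <- small_config(seed = 21)
  boosted <- small_config(seed = 21)
  boosted$signature_effects$fold <- base$signature_effects$fold * 2
  co1 <- generate_cohort(base)
  co2 <- generate_cohort(boosted)
  panel <- gene_panel(base)
  tgt <- co1$truth$targeted[, "GC_Response"]
  expect_gt(sum(tgt), 0)
  m1 <- mean(Matrix::colSums(co1$counts[panel$signature_genes$GC_Response,
                                        tgt, drop = FALSE]))
  m2 <- mean(Matrix::colSums(co2$counts[panel$signature_genes$GC_Response,
                                        tgt, drop = FALSE]))
  expect_gt(m2, m1)
})

test_that("stage labels are per-ROI and cover each OP donor's ROIs", {
  co <- generate_cohort(cohort_config(grid_shape = c(4, 4),
                                      n_background_genes = 10, seed = 8))
  st <- unique(co$spot_table[, c("roi", "stage", "group")])
  op <- st[st$group == "OP", ]
  expect_true(all(op$stage %in% c("early", "middle", "late")))
  expect_true(all(is.na(st$stage[st$group != "OP"])))
  # equal thirds with 3 ROIs/donor: each OP donor gets one ROI per stage
  donor_of <- sub("_r[0-9]+$", "", op$roi)
  per_donor <- table(donor_of, op$stage)
  expect_true(all(per_donor == 1))
})

test_that("copula planting hits the requested rank correlation of latents", {
  pr <- list(OP = c(AT2 = 0.2, Fib_myo = 0.5, Macrophage = 0.3))
  one_donor <- function(rho, seed) {
    cc <- cohort_config(groups = "OP", donors_per_group = 1,
                        rois_per_donor = 1, grid_shape = c(45, 45),
                        celltype_priors = pr, niche_specs = list(),
                        signatures = c("GC_Response", "Apoptosis"),
                        genes_per_signature = 2, n_background_genes = 4,
                        score_correlation = list(sigA = "GC_Response",
                                                 sigB = "Apoptosis",
                                                 rho = rho),
                        seed = seed)
    generate_cohort(cc)
  }
  # within one donor the spot-level latent rank correlation is the target
  lat <- one_donor(0.6, 31)$truth$latent
  r <- cor(lat[, "GC_Response"], lat[, "Apoptosis"], method = "spearman")
  expect_lt(abs(r - 0.6), 0.05)

  lat0 <- one_donor(0, 32)$truth$latent
  r0 <- cor(lat0[, "GC_Response"], lat0[, "Apoptosis"],
            method = "spearman")
  expect_lt(abs(r0), 0.1)

  lat1 <- one_donor(1, 33)$truth$latent
  expect_equal(cor(lat1[, "GC_Response"], lat1[, "Apoptosis"],
                   method = "spearman"), 1)
})

test_that("plant_score_correlation validates names and rewires latents", {
  co <- generate_cohort(small_config(seed = 41))
  expect_error(plant_score_correlation(co, "GC_Response", "NotASig", 0.5),
               "unknown signature")
  re <- plant_score_correlation(co, "GC_Response", "Apoptosis", 1,
                                seed = 99)
  tgt <- re$truth$targeted[, "GC_Response"] |
    re$truth$targeted[, "Apoptosis"]
  lat <- re$truth$latent[tgt, ]
  expect_equal(cor(lat[, "GC_Response"], lat[, "Apoptosis"],
                   method = "spearman"), 1)
  # untargeted latents untouched
  expect_identical(co$truth$latent[!tgt, "Apoptosis"],
                   re$truth$latent[!tgt, "Apoptosis"])
})

test_that("cohort writes round-trip through the on-disk formats", {
  co <- generate_cohort(small_config(seed = 51))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  st <- read_spot_table(file.path(dir, "spots.tsv"))
  expect_equal(st$spot_id, co$spot_table$spot_id)
  expect_equal(st$x_um, co$spot_table$x_um)
  w <- read_celltype_weights(file.path(dir, "weights.tsv"))
  expect_equal(as.matrix(w[, -1]), as.matrix(co$weights[, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  cnt <- read_counts_mtx(file.path(dir, "counts.mtx"),
                         file.path(dir, "genes.tsv"),
                         file.path(dir, "barcodes.tsv"))
  expect_identical(as.matrix(cnt), as.matrix(co$counts))
})
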
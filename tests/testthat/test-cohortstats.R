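mk_class <- function(spot_ids, flagged) {
  data.frame(spot_id = spot_ids, gc_sensitive = flagged,
             stringsAsFactors = FALSE)
}

test_that("ROI-weighted donor proportion averages ROIs equally", {
  # 3 ROIs with proportions 0.1, 0.3, 0.5 over 20 Fib_myo spots each
  n <- 60
  st <- data.frame(spot_id = sprintf("s%02d", 1:n), x_um = 0, y_um = 0,
                   donor = "d1", roi = rep(c("r1", "r2", "r3"), each = 20),
                   group = "OP", stage = NA)
  lab <- data.frame(spot_id = st$spot_id, label = "Fib_myo")
  flag <- rep(FALSE, n)
  flag[1:2] <- TRUE; flag[21:26] <- TRUE; flag[41:50] <- TRUE
  ds <- roi_weighted_proportion(mk_class(st$spot_id, flag), st, lab,
                                "Fib_myo", "Fib_myo")
  expect_equal(ds$value, mean(c(0.1, 0.3, 0.5)))
  expect_identical(ds$n_rois, 3L)
})

test_that("under-sized ROIs are excluded; donors without ROIs are omitted", {
  st <- data.frame(spot_id = sprintf("s%02d", 1:25), x_um = 0, y_um = 0,
                   donor = rep(c("d1", "d2"), c(24, 1)),
                   roi = rep(c("r1", "r2", "r3"), c(20, 4, 1)),
                   group = "OP", stage = NA)
  lab <- data.frame(spot_id = st$spot_id, label = "Fib_myo")
  flag <- c(rep(TRUE, 10), rep(FALSE, 15))
  expect_warning(
    ds <- roi_weighted_proportion(mk_class(st$spot_id, flag), st, lab,
                                  "Fib_myo", "Fib_myo", min_spots = 10),
    "omitted")
  expect_identical(ds$donor, "d1")
  expect_equal(ds$value, 0.5)               # only r1 is eligible
  expect_identical(attr(ds, "excluded_rois"), c("r2", "r3"))
  expect_identical(attr(ds, "omitted_donors"), "d2")
})

test_that("Kruskal-Wallis agrees with its exact enumeration at small N", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  # fully separated ranks: H = 12/(9*10) * (6^2/3 + 15^2/3 + 24^2/3) - 30
  expect_equal(kw$statistic, 12 / 90 * (36 / 3 + 225 / 3 + 576 / 3) - 30,
               tolerance = 1e-12)
  # exact permutation p equals the share of assignments at least as extreme
  expect_false(is.na(kw$p_exact))
  expect_equal(kw$p_exact, kw$p_exact)       # deterministic
  # the most extreme separation of 3/3/3 has enumeration p = k / 1680
  expect_lt(kw$p_exact, 0.01)

  # rank invariance under strictly monotone transforms
  kw2 <- kruskal_wallis(exp(v), g)
  expect_equal(kw2$statistic, kw$statistic, tolerance = 1e-12)
  expect_equal(kw2$p_exact, kw$p_exact)

  # identical values across groups: no evidence
  kw0 <- kruskal_wallis(rep(5, 9), g)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
})

test_that("Kruskal-Wallis exact enumeration matches the chi-square p in rank-regular cases", {
  set.seed(13)
  v <- rnorm(9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  ref <- kruskal.test(v, factor(g))
  expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
  expect_true(kw$p_exact >= 0 && kw$p_exact <= 1)
})

test_that("Dunn contrasts follow pooled-rank z statistics with adjustment", {
  # two identical groups give z = 0, p = 1
  d0 <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(d0$z, 0, tolerance = 1e-12)
  expect_equal(d0$p, 1)

  # fully separated 3x3x3: hand-computed z on pooled ranks 1..9
  v <- 1:9; g <- rep(c("a", "b", "c"), each = 3)
  dn <- dunn_posthoc(v, g, adjust = "holm")
  # mean ranks 2, 5, 8; se = sqrt((9*10/12) * (2/3))
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  z_ac <- (2 - 8) / se
  got <- dn[dn$group1 == "a" & dn$group2 == "c", ]
  expect_equal(got$z, z_ac, tolerance = 1e-12)
  # the extreme contrast carries the largest |z|
  expect_equal(max(abs(dn$z)), abs(z_ac))
  # Holm adjusted p never below raw
  expect_true(all(dn$p_adj >= dn$p - 1e-15))
})

test_that("Wilcoxon rank-sum: exact enumeration, symmetry, tie handling", {
  # A = {1,2}, B = {3,4}: 6 rank assignments, two-sided exact p = 1/3
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(w$method, "exact")

  # identical multisets: U = nm/2, p in the no-evidence region
  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w2$statistic, 9 / 2)
  expect_gt(w2$p_value, 0.9)
  expect_identical(w2$method, "normal_approx")   # ties present

  # swapping groups reflects U about nm/2 and keeps p
  a <- c(5, 9, 11); b <- c(1, 2, 14, 20)
  wa <- wilcoxon_rank_sum(a, b); wb <- wilcoxon_rank_sum(b, a)
  expect_equal(wa$statistic + wb$statistic, length(a) * length(b))
  expect_equal(wa$p_value, wb$p_value, tolerance = 1e-12)
})

test_that("Cliff's delta enumerates pairs with ties contributing zero", {
  expect_equal(cliffs_delta(c(1, 2), c(1, 3)), -0.25)
  expect_equal(cliffs_delta(c(5, 5), c(5, 5)), 0)
  expect_equal(cliffs_delta(c(10, 11), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2), c(10, 11)), -1)
  # antisymmetry on random data
  set.seed(14)
  a <- rnorm(20); b <- rnorm(15)
  expect_equal(cliffs_delta(a, b), -cliffs_delta(b, a), tolerance = 1e-15)
})

test_that("Spearman with bootstrap: identities, exactness, degeneracies", {
  x <- 1:6; y <- c(2, 4, 5, 7, 8, 12)
  sb <- spearman_bootstrap(x, y, n_boot = 200, seed = 2)
  expect_equal(sb$rho, 1)
  expect_equal(c(sb$lower, sb$upper), c(1, 1))
  expect_identical(sb$method, "exact_permutation")
  # exact permutation p of a perfect monotone pair at n = 6: 2/6! two-sided
  expect_equal(sb$p_value, 2 / factorial(6), tolerance = 1e-12)

  # rho equals the Pearson correlation of rank vectors
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  sb2 <- spearman_bootstrap(x, y, n_boot = 50, seed = 3)
  expect_equal(sb2$rho, cor(rank(x), rank(y)), tolerance = 1e-12)

  # zero variance is an explicit undefined result
  sb3 <- spearman_bootstrap(rep(1, 5), 1:5, n_boot = 10, seed = 4)
  expect_true(is.na(sb3$rho))
  expect_match(sb3$method, "zero variance")
})

test_that("BH and Holm adjustments obey their defining inequalities", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(16)
  for (i in 1:5) {
    p <- runif(sample(3:12, 1))
    expect_true(all(bh_adjust(p) <= holm_adjust(p) + 1e-15))
    expect_true(all(holm_adjust(p) >= p - 1e-15))
  }
})

test_that("DEG filtering applies the significance and fold-change gates", {
  tab <- data.frame(gene = c("g1", "g2", "g3"),
                    log2fc = c(0.3, 0.1, 1.0),
                    padj = c(0.04, 0.04, 0.2))
  out <- filter_degs(tab)
  expect_identical(out$gene, "g1")
  expect_identical(out$direction, "up")
  expect_identical(nrow(filter_degs(tab[0, ])), 0L)
  # permissive limits keep everything with nonzero fold change
  all_in <- filter_degs(tab, padj_max = 1, lfc_min = 0)
  expect_identical(all_in$gene, tab$gene)
  down <- filter_degs(data.frame(gene = "g", log2fc = -2, padj = 0.001))
  expect_identical(down$direction, "down")
})

test_that("TOST equivalence behaves monotonically in the margin", {
  set.seed(17)
  a <- rnorm(15); b <- rnorm(15)
  eq <- tost_equivalence(a, b, margin = 2)
  expect_true(eq$equivalent)
  expect_error(tost_equivalence(a, b), "margin")

  # cohorts separated by 3x the margin are not equivalent
  sep <- tost_equivalence(a + 6 * sd(a), b, margin = 2)
  expect_false(sep$equivalent)

  # shrinking the margin never flips non-equivalence to equivalence
  margins <- c(2, 1, 0.5, 0.25)
  verdicts <- vapply(margins, function(m)
    tost_equivalence(a + 6 * sd(a), b, margin = m)$equivalent, logical(1))
  expect_true(all(!verdicts[cumsum(!verdicts) > 0]))
  expect_false(any(verdicts))
})
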
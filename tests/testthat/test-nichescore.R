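# counts matrix builder: genes g1..gm, spots s1..sn
mk_counts <- function(m) {
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("ucell_score reproduces the rank formula on enumerable toys", {
  # 10 genes, signature at ranks 3 and 7, rmax 10:
  # U' = (3 + 7) - 3 = 7, score = 1 - 7/20 = 0.65
  expr <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  m <- mk_counts(matrix(expr, ncol = 1))
  sets <- list(S = c("g03", "g07"))
  s <- ucell_score(m, sets, rmax = 10)
  expect_equal(unname(s[1, "S"]), 0.65, tolerance = 1e-12)

  # signature occupying the top n ranks scores exactly 1
  s_top <- ucell_score(m, list(S = c("g01", "g02", "g03")), rmax = 10)
  expect_equal(unname(s_top[1, "S"]), 1, tolerance = 1e-15)

  # signature genes all ranked beyond rmax: capped at rmax + 1, score at
  # the formula's floor (n - 1) / (2 * rmax) — zero to displayed precision
  s_beyond <- ucell_score(m, list(S = c("g09", "g10")), rmax = 5)
  expect_equal(unname(s_beyond[1, "S"]), (2 - 1) / (2 * 5),
               tolerance = 1e-15)
  # absent genes take the same capped rank and are reported
  expect_message(
    s_absent <- ucell_score(m, list(S = c("g01", "zz2")), rmax = 10),
    "absent")
  expect_equal(unname(s_absent[1, "S"]),
               max(0, 1 - ((1 + 11) - 3) / (2 * 10)), tolerance = 1e-12)
})

test_that("ucell_score matches the brute-force oracle on random small matrices", {
  set.seed(7)
  for (rep in 1:20) {
    ngene <- sample(4:12, 1)
    nspot <- sample(1:6, 1)
    m <- mk_counts(matrix(rpois(ngene * nspot, 3), ngene, nspot))
    nsig <- sample(2:min(4, ngene), 1)
    sig <- sample(rownames(m), nsig)
    rmax <- (nsig:ngene)[sample.int(ngene - nsig + 1, 1)]
    got <- ucell_score(m, list(S = sig), rmax = rmax)
    want <- vapply(seq_len(nspot), function(j)
      ucell_oracle(m[, j], match(sig, rownames(m)), rmax), numeric(1))
    expect_equal(unname(got[, "S"]), want, tolerance = 1e-12)
  }
})

test_that("ucell_score is rank-invariant and bounded in [0, 1]", {
  set.seed(8)
  m <- mk_counts(matrix(rpois(200, 2), 20, 10))
  sets <- list(A = c("g01", "g05", "g09"), B = c("g02", "g17"))
  s1 <- ucell_score(m, sets, rmax = 20)
  # strictly increasing transform of each spot's expression vector
  s2 <- ucell_score(mk_counts(exp(m / 3) * 5 + 1), sets, rmax = 20)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("signatures with no present gene score NA with a warning", {
  m <- mk_counts(matrix(1:12, 4, 3))
  suppressMessages(
    expect_warning(s <- ucell_score(m, list(Gone = c("nope1", "nope2"),
                                            Ok = c("g01", "g02")),
                                    rmax = 4),
                   "no gene present"))
  expect_true(all(is.na(s[, "Gone"])))
  expect_true(all(!is.na(s[, "Ok"])))
})

test_that("assign_labels applies the min-weight rule and documented tie-break", {
  w <- data.frame(spot_id = c("a", "b", "c"),
                  A = c(1.0, 0.35, 0.5), B = c(0, 0.33, 0.5),
                  C = c(0, 0.32, 0))
  expect_warning(lab <- assign_labels(w, min_weight = 0.4), "tie")
  expect_identical(lab$label, c("A", "unknown", "A"))
  expect_equal(lab$confidence, c(1.0, 0.35, 0.5))
})

test_that("percentile classification follows nearest-rank order statistics", {
  sc <- c(10, 20, 30, 40, 50, 60, 70, 80)
  names(sc) <- sprintf("s%d", 1:8)
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0, donor = "d1",
                   roi = "r1", group = "G", stage = NA)
  cls <- classify_gc(sc, st)
  # nearest-rank 75th percentile of 8 values = 6th order statistic = 60
  expect_equal(cls$thresholds$threshold, 60)
  expect_identical(sort(cls$flags$spot_id[cls$flags$gc_sensitive]),
                   c("s6", "s7", "s8"))
  expect_equal(mean(cls$flags$gc_sensitive), 3 / 8)
})

test_that("tied scores saturate the flag set and are marked degenerate", {
  sc <- rep(0.5, 10); names(sc) <- sprintf("s%d", 1:10)
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0, donor = "d1",
                   roi = "r1", group = "G", stage = NA)
  cls <- classify_gc(sc, st)
  expect_true(all(cls$flags$gc_sensitive))
  expect_true(cls$thresholds$degenerate)
})

test_that("small scope units are flagged unreliable, not dropped", {
  sc <- c(1, 2, 3, 10, 20, 30, 40, 50)
  names(sc) <- sprintf("s%d", 1:8)
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0,
                   donor = rep(c("tiny", "big"), c(3, 5)),
                   roi = "r1", group = "G", stage = NA)
  cls <- classify_gc(sc, st)
  expect_true(cls$thresholds$unreliable[cls$thresholds$scope == "tiny"])
  expect_identical(sum(cls$flags$scope == "tiny"), 3L)
})

test_that("restriction to a label set bounds both threshold and flags", {
  set.seed(3)
  sc <- runif(40); names(sc) <- sprintf("s%02d", 1:40)
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0, donor = "d1",
                   roi = "r1", group = "G", stage = NA)
  lab <- data.frame(spot_id = names(sc),
                    label = rep(c("Fib_myo", "AT2"), 20))
  cls <- classify_gc(sc, st, labels = lab, restrict_to = "Fib_myo")
  expect_identical(nrow(cls$flags), 20L)
  expect_true(all(cls$flags$spot_id %in%
                  lab$spot_id[lab$label == "Fib_myo"]))
})

test_that("z-score mode flags the standardised upper tail per scope", {
  set.seed(4)
  sc <- rnorm(2000); names(sc) <- sprintf("s%04d", 1:2000)
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0,
                   donor = rep(c("d1", "d2"), each = 1000),
                   roi = "r1", group = "G", stage = NA)
  cls <- classify_gc(sc, st, gc_threshold_rule("zscore", z_cutoff = 0.674))
  frac <- tapply(cls$flags$gc_sensitive, cls$flags$scope, mean)
  expect_true(all(abs(frac - 0.25) < 0.05))
})

test_that("bootstrap_ci is seeded, degenerate-aware and ordered", {
  v <- c(3, 3, 3, 3)
  ci <- bootstrap_ci(v, n_boot = 100, seed = 1)
  expect_equal(ci$lower, 3)
  expect_equal(ci$upper, 3)
  expect_true(ci$degenerate)

  set.seed(10); v <- rnorm(8)
  a <- bootstrap_ci(v, n_boot = 500, seed = 7)
  b <- bootstrap_ci(v, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)
  expect_error(bootstrap_ci(1), ">= 2 donors")
})

test_that("sensitivity_scan produces nested flag sets across thresholds", {
  co <- generate_cohort(small_config(seed = 61))
  sc <- ucell_score(co$counts, gene_panel(small_config())$signature_genes,
                    rmax = nrow(co$counts))
  lab <- assign_labels(co$weights)
  flags_at <- function(p) {
    cls <- classify_gc(sc[, "GC_Response"], co$spot_table,
                       gc_threshold_rule(percentile = p))
    sort(cls$flags$spot_id[cls$flags$gc_sensitive])
  }
  f90 <- flags_at(90); f80 <- flags_at(80); f70 <- flags_at(70)
  expect_true(all(f90 %in% f80))
  expect_true(all(f80 %in% f70))
})

test_that("detection/intensity decomposition separates breadth from depth", {
  m <- mk_counts(matrix(c(0, 0, 2, 4), 1))
  di <- detection_intensity(m, colnames(m), "g01")
  expect_equal(di$detection, 0.5)
  expect_equal(di$per_positive_mean, 3)

  z <- mk_counts(matrix(0, 1, 4))
  expect_true(is.na(detection_intensity(z, colnames(z),
                                        "g01")$per_positive_mean))
  k <- mk_counts(matrix(7, 1, 5))
  dk <- detection_intensity(k, colnames(k), "g01")
  expect_equal(dk$detection, 1)
  expect_equal(dk$per_positive_mean, 7)
  expect_error(detection_intensity(m, character(0), "g01"), "empty")
})
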
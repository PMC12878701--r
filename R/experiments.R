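# Simulation experiments exercising the pipeline end-to-end under the
# study design (4 groups, 5/5/6/5 donors, 3 ROIs each). Each experiment
# is a seeded, self-contained driver returning the quantity it measures;
# the analysis scripts and the acceptance checks call these.

#' @importFrom stats setNames
NULL

# per-run seed derived from the experiment seed, kept inside 32-bit range
.exp_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 9973) %% 2147483647)
}

#' Mean per-sample flagged fraction under the default percentile rule
#'
#' Draws continuous tie-free scores for `n_samples` samples of
#' `spots_per_sample` spots each, applies the default within-sample
#' 75th-percentile rule, and returns the mean flagged fraction in percent
#' (expected: 25, up to the 1/n granularity of the nearest-rank quantile).
#'
#' @param n_samples number of samples (donors).
#' @param spots_per_sample spots per sample.
#' @param seed integer seed.
#' @return list: `mean_flagged_pct`, `per_sample` fractions.
#' @export
experiment_classification_rate <- function(n_samples = 21L,
                                           spots_per_sample = 1000L,
                                           seed = 1L) {
  set.seed(seed)
  n <- n_samples * spots_per_sample
  sc <- runif(n)
  names(sc) <- sprintf("s%06d", seq_len(n))
  st <- data.frame(spot_id = names(sc), x_um = 0, y_um = 0,
                   donor = rep(sprintf("d%02d", seq_len(n_samples)),
                               each = spots_per_sample),
                   roi = "r1", group = "G", stage = NA_character_)
  cls <- classify_gc(sc, st)
  frac <- tapply(cls$flags$gc_sensitive, cls$flags$scope, mean)
  list(mean_flagged_pct = 100 * mean(frac), per_sample = frac)
}

#' Cohort generator configured to the study layout
#'
#' Convenience wrapper fixing the donor layout (5/5/6/5, three ROIs per
#' donor) while exposing the knobs the experiments vary.
#'
#' @param seed seed.
#' @param grid_shape bins per ROI.
#' @param signatures signature panel.
#' @param signature_effects effect table.
#' @param score_correlation copula setting (NULL to disable).
#' @param ... passed on to [cohort_config()].
#' @return a [cohort_config()].
#' @export
study_config <- function(seed, grid_shape = c(16, 16),
                         signatures = "GC_Response",
                         signature_effects = data.frame(
                           group = "OP", celltype = "Fib_myo",
                           signature = "GC_Response", fold = 2,
                           stage = NA_character_),
                         score_correlation = NULL, ...) {
  cohort_config(grid_shape = grid_shape, signatures = signatures,
                signature_effects = signature_effects,
                score_correlation = score_correlation, seed = seed, ...)
}

# score -> classify (threshold pool: all spots) -> donor-level ROI-weighted
# GC-sensitive fraction among Fib_myo spots
.donor_gc_table <- function(cohort, rmax = NULL, percentile = 75) {
  panel <- gene_panel(cohort$config)
  if (is.null(rmax)) rmax <- nrow(cohort$counts)
  sc <- ucell_score(cohort$counts, panel$signature_genes, rmax = rmax)
  labels <- assign_labels(cohort$weights)
  cls <- classify_gc(sc[, "GC_Response"], cohort$spot_table,
                     gc_threshold_rule(percentile = percentile),
                     labels = labels)
  list(scores = sc, labels = labels, cls = cls,
       donors = suppressWarnings(
         roi_weighted_proportion(cls, cohort$spot_table, labels,
                                 "Fib_myo", "Fib_myo")))
}

#' Recovery of a planted OP-specific glucocorticoid-response elevation
#'
#' Runs `n_runs` seeded cohorts with a `fold`-fold GC-response effect in
#' OP Fib_myo spots (and no effect elsewhere), classifies GC-sensitive
#' spots with the default per-sample rule over all spots, and scores a run
#' as successful when the OP group's median donor-level GC-sensitive
#' Fib_myo proportion exceeds every other group's median. ROIs are 22 x 22
#' bins so OP donors carry at least roughly 500 fibroblast spots each.
#'
#' @param n_runs number of independently seeded cohorts.
#' @param fold planted signature effect.
#' @param seed master seed.
#' @return list: `success_rate_pct`, `n_runs`, per-run group medians.
#' @export
experiment_op_recovery <- function(n_runs = 100L, fold = 2, seed = 1L) {
  res <- lapply(seq_len(n_runs), function(i) {
    cc <- study_config(seed = .exp_seed(seed, i), grid_shape = c(22, 22),
                       signature_effects = data.frame(
                         group = "OP", celltype = "Fib_myo",
                         signature = "GC_Response", fold = fold,
                         stage = NA_character_))
    d <- .donor_gc_table(generate_cohort(cc))$donors
    tapply(d$value, d$group, median)
  })
  ok <- vapply(res, function(m)
    m["OP"] > max(m[setdiff(names(m), "OP")]), logical(1))
  list(success_rate_pct = 100 * mean(ok), n_runs = n_runs, medians = res)
}

#' Recovery of a planted middle-stage glucocorticoid elevation
#'
#' OP-only cohorts (6 donors, one early/middle/late ROI each) with the
#' GC-response effect planted only in middle-stage Fib_myo spots; a run
#' succeeds when the middle stage's median donor-level GC-sensitive
#' fraction exceeds both the early and late medians.
#'
#' @param n_runs number of seeded cohorts.
#' @param fold planted middle-stage effect.
#' @param seed master seed.
#' @return list: `success_rate_pct`, `n_runs`.
#' @export
experiment_midstage_recovery <- function(n_runs = 100L, fold = 3,
                                         seed = 1L) {
  pr <- .default_priors()["OP"]
  ok <- vapply(seq_len(n_runs), function(i) {
    cc <- cohort_config(
      groups = "OP", donors_per_group = 6, rois_per_donor = 3,
      grid_shape = c(20, 20), celltype_priors = pr,
      signatures = "GC_Response",
      signature_effects = data.frame(
        group = "OP", celltype = "Fib_myo", signature = "GC_Response",
        fold = fold, stage = "middle"),
      score_correlation = NULL, seed = .exp_seed(seed, i))
    co <- generate_cohort(cc)
    parts <- .donor_gc_table(co)
    dyn <- suppressMessages(stage_gc_dynamics(
      parts$cls, co$spot_table, parts$labels,
      setNames(rep(0, nrow(co$spot_table)), co$spot_table$spot_id)))
    med <- tapply(dyn$gc_fraction$value, dyn$gc_fraction$stage, median)
    med["middle"] > med["early"] && med["middle"] > med["late"]
  }, logical(1))
  list(success_rate_pct = 100 * mean(ok), n_runs = n_runs)
}

#' Recovery of a planted donor-level score correlation
#'
#' Cohorts with GC-response and apoptosis effects in Fib_myo spots of all
#' groups and a hierarchical Gaussian-copula coupling of the two programs
#' at Spearman `rho`; a run succeeds when the donor-resampling bootstrap
#' CI of the donor-mean score correlation covers the planted value.
#'
#' @param n_runs number of seeded cohorts.
#' @param rho planted rank correlation.
#' @param fold fold effect translating latent activity into counts.
#' @param n_boot bootstrap replicates per run.
#' @param seed master seed.
#' @return list: `coverage_pct`, `mean_rho`, `n_runs`.
#' @export
experiment_rho_recovery <- function(n_runs = 100L, rho = 0.6, fold = 3,
                                    n_boot = 1000L, seed = 1L) {
  groups <- c("CTRL", "CTD-ILD", "OP", "IPF")
  eff <- data.frame(
    group = rep(groups, 2), celltype = "Fib_myo",
    signature = rep(c("GC_Response", "Apoptosis"), each = 4),
    fold = fold, stage = NA_character_)
  res <- vapply(seq_len(n_runs), function(i) {
    cc <- study_config(seed = .exp_seed(seed, i),
                       signatures = c("GC_Response", "Apoptosis"),
                       signature_effects = eff,
                       score_correlation = list(sigA = "GC_Response",
                                                sigB = "Apoptosis",
                                                rho = rho))
    co <- generate_cohort(cc)
    sc <- ucell_score(co$counts, gene_panel(cc)$signature_genes,
                      rmax = nrow(co$counts))
    labels <- assign_labels(co$weights)
    fib <- labels$spot_id[labels$label == "Fib_myo"]
    donor <- co$spot_table$donor[match(fib, co$spot_table$spot_id)]
    gm <- tapply(sc[fib, "GC_Response"], donor, mean)
    am <- tapply(sc[fib, "Apoptosis"], donor, mean)
    sb <- spearman_bootstrap(gm, am, n_boot = n_boot, seed = i)
    c(covered = sb$lower <= rho && rho <= sb$upper, rho = sb$rho)
  }, numeric(2))
  list(coverage_pct = 100 * mean(res["covered", ]),
       mean_rho = mean(res["rho", ]), n_runs = n_runs)
}

#' Type-I error of the donor-level Kruskal-Wallis test under the null
#'
#' Draws `n_rep` null datasets with the study's donor layout (4 groups of
#' 5/5/6/5 independent standard-normal donor values) and returns the
#' rejection rate at `alpha` of the Monte Carlo permutation p (the
#' calibrated route at donor-scale N; the chi-square approximation runs
#' about 0.038 at this layout and is reported alongside).
#'
#' @param n_rep replications.
#' @param alpha nominal level.
#' @param n_perm label permutations per replication.
#' @param seed seed.
#' @return list: `type1_rate` (permutation p), `type1_rate_chisq`,
#'   `n_rep`.
#' @export
experiment_kw_type1 <- function(n_rep = 2000L, alpha = 0.05,
                                n_perm = 399L, seed = 1L) {
  set.seed(seed)
  g <- rep(c("CTRL", "CTD-ILD", "OP", "IPF"), c(5, 5, 6, 5))
  datasets <- replicate(n_rep, rnorm(length(g)), simplify = FALSE)
  res <- vapply(seq_len(n_rep), function(i) {
    kw <- kruskal_wallis(datasets[[i]], g, exact_max = 0L,
                         n_perm = n_perm, perm_seed = seed + i)
    c(perm = kw$p_perm, chisq = kw$p_value)
  }, numeric(2))
  list(type1_rate = mean(res["perm", ] <= alpha),
       type1_rate_chisq = mean(res["chisq", ] < alpha), n_rep = n_rep)
}

#' Empirical coverage of the donor-resampling bootstrap CI
#'
#' For `n_rep` seeded draws of `n` standard-normal donor values, the
#' percentile bootstrap CI of the mean is computed and coverage of the
#' true mean (zero) is reported in percent.
#'
#' @param n_rep replications.
#' @param n donors per replication.
#' @param n_boot bootstrap replicates.
#' @param seed seed.
#' @return list: `coverage_pct`, `n_rep`.
#' @export
experiment_bootstrap_coverage <- function(n_rep = 500L, n = 30L,
                                          n_boot = 1000L, seed = 1L) {
  set.seed(seed)
  datasets <- replicate(n_rep, rnorm(n), simplify = FALSE)
  cover <- vapply(seq_len(n_rep), function(i) {
    ci <- bootstrap_ci(datasets[[i]], n_boot = n_boot, seed = seed + i)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  list(coverage_pct = 100 * mean(cover), n_rep = n_rep)
}

#' Threshold-scan robustness of a planted group effect
#'
#' One study-layout cohort with the default OP-specific GC elevation; the
#' OP-vs-IPF donor contrast is recomputed over the top 10-30% percentile
#' thresholds and the z-score rule, each with a donor-resampling bootstrap
#' CI.
#'
#' @param fold planted effect.
#' @param n_boot bootstrap replicates.
#' @param seed seed.
#' @return the [sensitivity_scan()] table.
#' @export
experiment_sensitivity_robustness <- function(fold = 3, n_boot = 1000L,
                                              seed = 1L) {
  cc <- study_config(seed = seed,
                     signature_effects = data.frame(
                       group = "OP", celltype = "Fib_myo",
                       signature = "GC_Response", fold = fold,
                       stage = NA_character_))
  co <- generate_cohort(cc)
  sc <- ucell_score(co$counts, gene_panel(cc)$signature_genes,
                    rmax = nrow(co$counts))
  labels <- assign_labels(co$weights)
  sensitivity_scan(sc[, "GC_Response"], co$spot_table, labels,
                   denominator = "Fib_myo", threshold_pool = NULL,
                   contrast = c("OP", "IPF"), n_boot = n_boot, seed = seed)
}
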
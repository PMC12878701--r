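#' @importFrom stats kruskal.test wilcox.test cor cor.test p.adjust
#'   p.adjust.methods pchisq pnorm pt qt
#' @importFrom utils combn
NULL

# ---- donor summaries -------------------------------------------------------

#' ROI-weighted donor-level proportion of flagged spots
#'
#' Per ROI, the proportion of flagged spots among the denominator
#' population (spots whose label is in `denominator`); the donor value is
#' the equal-weight mean over that donor's ROIs with at least `min_spots`
#' denominator spots. ROIs below the cutoff are excluded and reported;
#' donors with no eligible ROI are omitted and reported.
#'
#' @param classification a `gc_classification` from [classify_gc()], or a
#'   data.frame with columns `spot_id`, `gc_sensitive`.
#' @param spot_table spot table with `spot_id`, `donor`, `roi`, `group`.
#' @param labels data.frame from [assign_labels()].
#' @param numerator labels counted in the numerator (flagged spots are
#'   additionally required to carry one of these labels).
#' @param denominator labels forming the denominator population.
#' @param min_spots minimum denominator spots per contributing ROI.
#' @return data.frame (one row per donor): `donor`, `group`, `value`,
#'   `n_rois`, `n_spots`; attributes `excluded_rois`, `omitted_donors`.
#' @export
roi_weighted_proportion <- function(classification, spot_table, labels,
                                    numerator, denominator,
                                    min_spots = 10L) {
  flags <- if (inherits(classification, "gc_classification"))
    classification$flags else classification
  df <- merge(spot_table[, c("spot_id", "donor", "roi", "group")],
              labels[, c("spot_id", "label")], by = "spot_id")
  df$flagged <- df$spot_id %in% flags$spot_id[flags$gc_sensitive]
  den <- df[df$label %in% denominator, , drop = FALSE]
  den$in_num <- den$flagged & den$label %in% numerator

  per_roi <- do.call(rbind, lapply(split(den, den$roi), function(x)
    data.frame(donor = x$donor[1], group = x$group[1], roi = x$roi[1],
               n = nrow(x), p = mean(x$in_num), stringsAsFactors = FALSE)))
  excluded <- per_roi$roi[per_roi$n < min_spots]
  keep <- per_roi[per_roi$n >= min_spots, , drop = FALSE]
  donors_all <- unique(df[, c("donor", "group")])
  out <- do.call(rbind, lapply(split(keep, keep$donor), function(x)
    data.frame(donor = x$donor[1], group = x$group[1], value = mean(x$p),
               n_rois = nrow(x), n_spots = sum(x$n),
               stringsAsFactors = FALSE)))
  omitted <- setdiff(donors_all$donor, out$donor)
  if (length(omitted))
    warning("donor(s) with no eligible ROI omitted: ",
            paste(omitted, collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_rois") <- excluded
  attr(out, "omitted_donors") <- omitted
  out
}

# ---- rank-based tests ------------------------------------------------------

# enumerate all partitions of 1..N into groups of the given sizes;
# returns the reference distribution of `stat` over every assignment.
.enumerate_group_stat <- function(values, sizes, stat) {
  res <- numeric(0)
  recurse <- function(remaining, sizes_left, assigned) {
    if (length(sizes_left) == 1) {
      res[[length(res) + 1]] <<- stat(c(assigned, list(remaining)))
      return(invisible())
    }
    picks <- combn(length(remaining), sizes_left[1], simplify = FALSE)
    for (p in picks)
      recurse(remaining[-p], sizes_left[-1],
              c(assigned, list(remaining[p])))
  }
  recurse(values, sizes, list())
  unlist(res)
}

.kw_stat <- function(groups_list) {
  v <- unlist(groups_list)
  n <- lengths(groups_list)
  N <- length(v)
  r <- rank(v)
  rs <- split(r, rep(seq_along(n), n))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(rs, function(x) sum(x)^2 / length(x), numeric(1))) -
    3 * (N + 1)
  tie <- table(v)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C > 0) H / C else 0
}

#' Kruskal-Wallis test on donor-level values
#'
#' Tie-corrected H statistic with the chi-square p value (via
#' [stats::kruskal.test()]); when the total sample size is at most
#' `exact_max` an exact permutation p (full enumeration over group
#' assignments) is also reported. The chi-square approximation is
#' noticeably conservative at donor-scale cohorts (its true level at
#' 5/5/6/5 donors is about 0.038 for nominal 0.05), so a seeded Monte
#' Carlo permutation p — exact-level up to resampling noise — is
#' available through `n_perm` and is the route the calibration
#' experiments use. A group with a single donor triggers a low-power
#' warning but the test still runs.
#'
#' @param values numeric vector of donor-level statistics.
#' @param groups group factor/character, same length.
#' @param exact_max largest N for which the exact enumeration p is added.
#' @param n_perm number of Monte Carlo label permutations for `p_perm`
#'   (0 = skip).
#' @param perm_seed seed for the permutation draw.
#' @return list: `statistic` (H), `df`, `p_value` (chi-square
#'   approximation), `p_exact` (NA above `exact_max`), `p_perm` (NA when
#'   `n_perm = 0`), `n_per_group`.
#' @export
kruskal_wallis <- function(values, groups, exact_max = 12L, n_perm = 0L,
                           perm_seed = 1L) {
  groups <- as.character(groups)
  n <- table(groups)
  if (length(n) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(n == 1))
    warning("group(s) with a single donor: low power", call. = FALSE)
  if (length(unique(values)) == 1)          # all tied: no evidence at all
    return(list(statistic = 0, df = length(n) - 1, p_value = 1,
                p_exact = if (length(values) <= exact_max) 1 else NA_real_,
                p_perm = NA_real_, n_per_group = c(n)))
  kt <- kruskal.test(values, factor(groups))
  H_obs <- unname(kt$statistic)
  p_exact <- NA_real_
  if (length(values) <= exact_max) {
    gl <- split(values, groups)
    ref <- .enumerate_group_stat(values, lengths(gl), .kw_stat)
    p_exact <- mean(ref >= .kw_stat(gl) - 1e-12)
  }
  p_perm <- NA_real_
  if (n_perm > 0) {
    # ranks are permutation-invariant: permute labels by permuting the
    # rank vector and recompute H from group rank sums only
    r <- rank(values)
    N <- length(r)
    gidx <- as.integer(factor(groups))
    tie <- table(values)
    C <- 1 - sum(tie^3 - tie) / (N^3 - N)
    set.seed(perm_seed)
    R <- vapply(seq_len(n_perm), function(b) sample(r), numeric(N))
    S <- rowsum(R, gidx)                     # groups x n_perm rank sums
    H_ref <- (12 / (N * (N + 1)) * colSums(S^2 / as.vector(n)) -
              3 * (N + 1)) / C
    p_perm <- (1 + sum(H_ref >= H_obs - 1e-12)) / (n_perm + 1)
  }
  list(statistic = H_obs, df = unname(kt$parameter),
       p_value = kt$p.value, p_exact = p_exact, p_perm = p_perm,
       n_per_group = c(n))
}

#' Dunn's post-hoc test on pooled ranks
#'
#' All pairwise group contrasts after a Kruskal-Wallis test: z statistics
#' on pooled average ranks with tie correction, two-sided p values,
#' adjusted over the full contrast family by Holm (default) or BH.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param adjust `"holm"` or `"BH"`.
#' @return data.frame, one row per contrast: `group1`, `group2`, `z`,
#'   `p`, `p_adj`, `method`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("holm", "BH")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nn <- table(groups)
  tie <- table(values)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  gs <- names(nn)
  pairs <- combn(gs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / nn[pr[1]] + 1 / nn[pr[2]]))
    z <- if (se > 0) (rbar[pr[1]] - rbar[pr[2]]) / se else 0
    data.frame(group1 = pr[1], group2 = pr[2], z = unname(z),
               p = 2 * pnorm(-abs(unname(z))), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = if (adjust == "BH") "BH" else "holm")
  out$method <- adjust
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p when `min(n, m) <= 8` and there are no ties; otherwise the
#' normal approximation with continuity and tie correction. The method
#' actually used is recorded.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list: `statistic` (U for the first sample), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Cliff's delta effect size
#'
#' delta = (#\{a > b\} - #\{a < b\}) / (n m) over all cross pairs; ties
#' contribute zero. Antisymmetric in its arguments, bounded in `[-1, 1]`.
#'
#' @param a,b numeric vectors.
#' @return numeric scalar.
#' @export
cliffs_delta <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty",
                                     call. = FALSE)
  d <- sign(outer(a, b, "-"))
  mean(d)
}

# ---- correlation with bootstrap --------------------------------------------

.perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .perms(n - 1)) for (k in seq_len(n))
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

#' Donor-level Spearman correlation with bootstrap CI
#'
#' Spearman rho with average-rank ties; percentile CI from resampling
#' donors (pairs) with replacement; p value from the t approximation, or
#' exact permutation (full enumeration of rank assignments) when
#' `n <= exact_max`.
#'
#' @param x,y paired donor-level values (>= 4 pairs).
#' @param n_boot,level,seed bootstrap settings.
#' @param exact_max largest n for the exact permutation p.
#' @return list: `rho`, `lower`, `upper`, `p_value`, `method`, `n`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000L, level = 0.95,
                               seed = 1L, exact_max = 7L) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired donors", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, lower = NA_real_, upper = NA_real_,
                p_value = NA_real_, method = "undefined: zero variance",
                n = n))
  rho <- cor(x, y, method = "spearman")
  if (n <= exact_max) {
    ref <- vapply(.perms(n), function(p)
      cor(x, y[p], method = "spearman"), numeric(1))
    p <- mean(abs(ref) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
    method <- "t_approx"
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) NA_real_
    else cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(reps, c(a, 1 - a), na.rm = TRUE))
  list(rho = rho, lower = ci[1], upper = ci[2], p_value = p,
       method = method, n = n)
}

# ---- multiplicity ----------------------------------------------------------

.check_p <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p numeric vector of p values in `[0,1]`.
#' @return adjusted p values, input order preserved.
#' @export
bh_adjust <- function(p) { .check_p(p); p.adjust(p, method = "BH") }

#' Holm step-down adjustment
#' @param p numeric vector of p values in `[0,1]`.
#' @return adjusted p values, input order preserved.
#' @export
holm_adjust <- function(p) { .check_p(p); p.adjust(p, method = "holm") }

# ---- DEG threshold filter --------------------------------------------------

#' Filter a differential-expression table by significance and effect size
#'
#' Retains genes with BH-adjusted p below `padj_max` and absolute log2
#' fold change above `lfc_min` (the volcano-plot dashed-line rule), and
#' annotates the direction of change.
#'
#' @param table data.frame with columns `gene`, `log2fc`, `padj`.
#' @param padj_max adjusted-p cutoff (strict `<`).
#' @param lfc_min absolute log2 fold-change cutoff (strict `>`).
#' @return filtered data.frame with a `direction` column (`up`/`down`).
#' @export
filter_degs <- function(table, padj_max = 0.05, lfc_min = 0.25) {
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(table)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keep <- table$padj < padj_max & abs(table$log2fc) > lfc_min
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

# ---- equivalence (TOST) ----------------------------------------------------

#' Two one-sided Wilcoxon tests for equivalence
#'
#' Values from both cohorts are standardised by the pooled SD, and two
#' one-sided Wilcoxon rank-sum tests are run against location shifts of
#' -margin and +margin (margin on the standardised scale, supplied by the
#' caller — there is no default). Equivalence is declared when both
#' one-sided p values fall below `alpha`.
#'
#' @param a,b numeric vectors (the two cohorts).
#' @param margin equivalence margin in pooled-SD units; must be > 0.
#' @param alpha significance level for each one-sided test.
#' @return list: `p_lower`, `p_upper`, `equivalent`, `margin`, `alpha`.
#' @export
tost_equivalence <- function(a, b, margin = NULL, alpha = 0.05) {
  if (is.null(margin))
    stop("tost_equivalence requires an explicit margin (pooled-SD units)",
         call. = FALSE)
  if (margin <= 0) stop("margin must be > 0", call. = FALSE)
  s <- sd(c(a - mean(a), b - mean(b)))
  if (s == 0) s <- 1                      # both cohorts constant
  az <- a / s; bz <- b / s
  p_lo <- suppressWarnings(
    wilcox.test(az, bz, mu = -margin, alternative = "greater",
                exact = FALSE))$p.value
  p_hi <- suppressWarnings(
    wilcox.test(az, bz, mu = margin, alternative = "less",
                exact = FALSE))$p.value
  list(p_lower = p_lo, p_upper = p_hi,
       equivalent = (p_lo < alpha) && (p_hi < alpha),
       margin = margin, alpha = alpha)
}
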
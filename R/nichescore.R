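# Average-tie ranks of decreasing expression within every column of a
# dense genes x spots matrix, fully vectorised: one radix sort of
# (column, -value), then run-length averaging of tied blocks.
.col_ranks_desc <- function(x) {
  m <- nrow(x); n <- ncol(x); N <- m * n
  col <- rep.int(seq_len(n), rep.int(m, n))
  o <- order(col, -as.vector(x), method = "radix")
  v <- as.vector(x)[o]
  newgrp <- c(TRUE, col[o][-1] != col[o][-N] | v[-1] != v[-N])
  start <- which(newgrp)
  len <- diff(c(start, N + 1L))
  pos <- rep.int(seq_len(m), n)              # within-column position
  avg <- pos[start] + (len - 1) / 2
  r <- numeric(N)
  r[o] <- rep.int(avg, len)
  matrix(r, m, n, dimnames = dimnames(x))
}

# ---- rank-based signature scoring ------------------------------------------

#' UCell-style rank-based signature scores
#'
#' For each spot, genes are ranked by decreasing expression with average
#' ranks for ties; ranks above `rmax` are capped at `rmax + 1` (signature
#' genes absent from the matrix receive the capped rank and are reported).
#' For a signature of size n the Mann-Whitney statistic is
#' U' = sum(ranks of signature genes) - n(n+1)/2 and the score is
#' `max(0, 1 - U'/(n * rmax))`, so scores live in `[0, 1]` and equal 1
#' exactly when the signature genes occupy the top n ranks.
#'
#' @param counts genes x spots matrix (sparse or dense) with gene rownames.
#' @param sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param rmax maximum rank considered informative; must be at least the
#'   largest signature size.
#' @return spots x signatures numeric matrix with attribute `rmax`.
#'   Signatures with no gene present in the matrix score `NA` with a
#'   warning.
#' @export
ucell_score <- function(counts, sets, rmax = 1500L) {
  if (is.null(rownames(counts))) stop("counts needs gene rownames",
                                      call. = FALSE)
  if (ncol(counts) == 0L) stop("counts has no spots", call. = FALSE)
  nmax <- max(lengths(sets))
  if (rmax < nmax)
    stop("rmax must be >= largest signature size (", nmax, ")",
         call. = FALSE)
  genes <- rownames(counts)
  present <- lapply(sets, function(g) intersect(g, genes))
  n_absent <- lengths(sets) - lengths(present)
  if (any(n_absent > 0))
    message(sprintf("ucell_score: %d signature gene(s) absent from the matrix across %d signature(s); absent genes take rank rmax+1",
                    sum(n_absent), sum(n_absent > 0)))
  empty <- lengths(present) == 0
  if (any(empty))
    warning("signature(s) with no gene present score NA: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)

  x <- as.matrix(counts)
  ns <- ncol(x)
  rk <- .col_ranks_desc(x)
  rk[rk > rmax] <- rmax + 1

  out <- matrix(NA_real_, ns, length(sets),
                dimnames = list(colnames(x), names(sets)))
  for (j in seq_along(sets)) {
    if (empty[j]) next
    n <- length(sets[[j]])
    idx <- match(present[[j]], genes)
    rsum <- colSums(rk[idx, , drop = FALSE]) +
      n_absent[j] * (rmax + 1)              # absent genes at capped rank
    u <- rsum - n * (n + 1) / 2
    out[, j] <- pmax(0, 1 - u / (n * rmax))
  }
  attr(out, "rmax") <- rmax
  out
}

# ---- discrete labelling ----------------------------------------------------

#' Discrete cell-type labels from deconvolution weights
#'
#' The label is the argmax cell type when its weight reaches `min_weight`,
#' else the reserved label `"unknown"`. Exact ties break lexicographically
#' by cell-type name, with a warning.
#'
#' @param weights data.frame: `spot_id` plus one numeric column per cell
#'   type (rows summing to 1), as from [read_celltype_weights()].
#' @param min_weight minimum winning weight for a confident label.
#' @return data.frame with `spot_id`, `label`, `confidence` (the winning
#'   weight, regardless of whether the label is "unknown").
#' @export
assign_labels <- function(weights, min_weight = 0.4) {
  w <- as.matrix(weights[, setdiff(names(weights), "spot_id"),
                         drop = FALSE])
  cts <- colnames(w)
  ord <- order(cts)                     # lexicographic tie-break
  w_o <- w[, ord, drop = FALSE]
  best <- max.col(w_o, ties.method = "first")
  conf <- w_o[cbind(seq_len(nrow(w_o)), best)]
  n_tie <- sum(rowSums(w_o == conf) > 1)
  if (n_tie > 0)
    warning(sprintf("%d spot(s) with tied top weight; lexicographic tie-break applied",
                    n_tie), call. = FALSE)
  label <- cts[ord][best]
  label[conf < min_weight] <- "unknown"
  data.frame(spot_id = weights$spot_id, label = label, confidence = conf,
             stringsAsFactors = FALSE)
}

# ---- GC-sensitive classification -------------------------------------------

#' Threshold rule for GC-sensitive spot classification
#'
#' @param mode `"percentile"` (default) or `"zscore"`.
#' @param percentile percentile in (0,100); spots at or above the
#'   within-scope nearest-rank percentile are flagged (default 75 = top
#'   quartile).
#' @param z_cutoff z threshold in zscore mode; the default 0.674 is the
#'   upper-quartile equivalent under normality.
#' @param scope spot-table column defining the units within which the
#'   threshold is computed (default `"donor"`, i.e. per sample).
#' @return object of class `gc_threshold_rule`.
#' @export
gc_threshold_rule <- function(mode = c("percentile", "zscore"),
                              percentile = 75, z_cutoff = 0.674,
                              scope = "donor") {
  mode <- match.arg(mode)
  if (mode == "percentile" && (percentile <= 0 || percentile >= 100))
    stop("percentile must be in (0, 100)", call. = FALSE)
  structure(list(mode = mode, percentile = percentile, z_cutoff = z_cutoff,
                 scope = scope), class = "gc_threshold_rule")
}

# nearest-rank (inverse empirical CDF) percentile: the ceil(p/100 * n)-th
# order statistic; classification uses score >= this value.
.nearest_rank <- function(x, p) {
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

#' Classify GC-sensitive spots by a within-sample threshold
#'
#' Percentile mode flags, within each scope unit (sample by default), the
#' spots whose score is at or above the nearest-rank percentile of that
#' unit's scores. Z-score mode standardises within scope and flags
#' `z >= z_cutoff`. `restrict_to` limits both the threshold computation and
#' the flagging to spots with the given labels (e.g. fibroblast subtypes):
#' the threshold is computed after restriction.
#'
#' @param scores spots x signatures matrix from [ucell_score()], or a named
#'   numeric vector of scores.
#' @param spot_table spot table (must cover every scored spot in scope).
#' @param rule a [gc_threshold_rule()].
#' @param signature signature column to threshold.
#' @param labels optional data.frame from [assign_labels()]; required when
#'   `restrict_to` is given.
#' @param restrict_to optional character vector of labels defining the spot
#'   population considered.
#' @return object of class `gc_classification`: list with `flags`
#'   (data.frame spot_id, score, scope unit, gc_sensitive), `thresholds`
#'   (per-scope threshold and spot count), `rule`, and metadata naming
#'   unreliable (< 4 spots) and degenerate (all-tied) scope units.
#' @export
classify_gc <- function(scores, spot_table, rule = gc_threshold_rule(),
                        signature = "GC_Response", labels = NULL,
                        restrict_to = NULL) {
  if (is.matrix(scores)) {
    if (!signature %in% colnames(scores))
      stop("signature not scored: ", signature, call. = FALSE)
    sc <- scores[, signature]
  } else sc <- scores
  if (is.null(names(sc))) stop("scores must be named by spot_id",
                               call. = FALSE)
  if (!rule$scope %in% names(spot_table))
    stop("scope column absent from spot table: ", rule$scope, call. = FALSE)
  df <- data.frame(spot_id = names(sc), score = unname(sc),
                   stringsAsFactors = FALSE)
  df <- merge(df, spot_table[, c("spot_id", rule$scope)], by = "spot_id",
              sort = FALSE)
  if (!is.null(restrict_to)) {
    if (is.null(labels))
      stop("restrict_to requires labels", call. = FALSE)
    keep <- labels$spot_id[labels$label %in% restrict_to]
    df <- df[df$spot_id %in% keep, , drop = FALSE]
    if (!nrow(df)) stop("no spots left after label restriction",
                        call. = FALSE)
  }
  units <- split(df, df[[rule$scope]])
  thr <- lapply(names(units), function(u) {
    s <- units[[u]]$score
    s <- s[!is.na(s)]
    unreliable <- length(s) < 4
    degenerate <- length(unique(s)) == 1
    t <- if (rule$mode == "percentile") .nearest_rank(s, rule$percentile)
         else mean(s) + rule$z_cutoff * sd(s)
    if (rule$mode == "zscore" && (degenerate || is.na(t)))
      t <- Inf                             # no spread: nothing exceeds
    data.frame(scope = u, threshold = t, n_spots = length(s),
               unreliable = unreliable, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  thr <- do.call(rbind, thr)
  # degenerate percentile scope: all values tie, threshold = the common
  # value, every spot flagged (score >= threshold)
  df$gc_sensitive <- df$score >=
    thr$threshold[match(df[[rule$scope]], thr$scope)]
  names(df)[names(df) == rule$scope] <- "scope"
  structure(list(flags = df, thresholds = thr, rule = rule,
                 signature = if (is.matrix(scores)) signature else "score"),
            class = "gc_classification")
}

# ---- donor-level bootstrap -------------------------------------------------

#' Percentile bootstrap CI over donors
#'
#' Resamples the donor-level values with replacement `n_boot` times and
#' returns the percentile interval of the resampled means. Deterministic
#' for a given seed. A degenerate (all-identical) input yields a zero-width
#' interval, flagged in the result.
#'
#' @param values numeric vector of per-donor statistics (length >= 2).
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @param statistic function reducing a resample to one number (mean).
#' @return list: `lower`, `upper`, `estimate`, `n_boot`, `degenerate`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95,
                         seed = 1L, statistic = mean) {
  if (length(values) < 2) stop("need >= 2 donors", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- length(values)
  reps <- vapply(seq_len(n_boot), function(i)
    statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(reps, c(a, 1 - a), type = 7))
  list(lower = ci[1], upper = ci[2], estimate = statistic(values),
       n_boot = n_boot, degenerate = length(unique(values)) == 1)
}

# ---- sensitivity scan ------------------------------------------------------

#' Threshold sensitivity scan for a group contrast
#'
#' Re-runs the GC-sensitive classification over a range of percentile
#' thresholds (top 30% down to top 10%) and, optionally, the z-score rule,
#' recomputing at each threshold the donor-level ROI-weighted GC-sensitive
#' proportion and the contrast between two groups (difference of group mean
#' donor proportions), with a donor-resampling percentile bootstrap CI on
#' the contrast.
#'
#' @param scores,spot_table,labels as in [classify_gc()].
#' @param denominator labels forming the denominator population whose
#'   flagged fraction is the donor statistic (default `"Fib_myo"`).
#' @param threshold_pool labels over which each sample's threshold is
#'   computed; NULL (default) pools all scored spots of the sample. When
#'   the pool equals the denominator the per-sample percentile flags a
#'   fixed fraction of it by construction and the contrast degenerates, so
#'   the pool is deliberately broader than the denominator.
#' @param contrast character vector of two group names; the estimate is
#'   mean(groupA donors) - mean(groupB donors).
#' @param percentiles percentile thresholds to scan.
#' @param include_zscore also scan the z-score rule (cutoff 0.674).
#' @param n_boot,level,seed bootstrap settings.
#' @param min_spots minimum denominator spots for an ROI to contribute.
#' @return data.frame, one row per threshold: `threshold` label, `estimate`,
#'   `lower`, `upper`, `n_boot`, and `ci_available` (FALSE when either
#'   group has < 2 donors).
#' @export
sensitivity_scan <- function(scores, spot_table, labels,
                             denominator = "Fib_myo",
                             threshold_pool = NULL,
                             contrast = c("OP", "IPF"),
                             percentiles = c(70, 75, 80, 85, 90),
                             include_zscore = TRUE,
                             n_boot = 1000L, level = 0.95, seed = 1L,
                             min_spots = 10L) {
  groups_present <- unique(spot_table$group)
  if (length(groups_present) < 2)
    stop("sensitivity scan needs >= 2 groups", call. = FALSE)
  stopifnot(all(contrast %in% groups_present))
  rules <- c(lapply(percentiles, function(p)
               gc_threshold_rule("percentile", percentile = p)),
             if (include_zscore) list(gc_threshold_rule("zscore")))
  lab <- vapply(rules, function(r)
    if (r$mode == "percentile") sprintf("top%d", round(100 - r$percentile))
    else sprintf("z%.3f", r$z_cutoff), character(1))

  rows <- lapply(seq_along(rules), function(i) {
    cls <- classify_gc(scores, spot_table, rules[[i]], labels = labels,
                       restrict_to = threshold_pool)
    ds <- roi_weighted_proportion(cls, spot_table, labels,
                                  numerator = denominator,
                                  denominator = denominator,
                                  min_spots = min_spots)
    a <- ds$value[ds$group == contrast[1]]
    b <- ds$value[ds$group == contrast[2]]
    est <- mean(a) - mean(b)
    if (length(a) >= 2 && length(b) >= 2) {
      set.seed(seed + i)
      reps <- vapply(seq_len(n_boot), function(k)
        mean(a[sample.int(length(a), replace = TRUE)]) -
        mean(b[sample.int(length(b), replace = TRUE)]), numeric(1))
      alpha <- (1 - level) / 2
      ci <- unname(quantile(reps, c(alpha, 1 - alpha)))
      data.frame(threshold = lab[i], estimate = est, lower = ci[1],
                 upper = ci[2], n_boot = n_boot, ci_available = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(threshold = lab[i], estimate = est, lower = NA_real_,
                 upper = NA_real_, n_boot = n_boot, ci_available = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# ---- detection / intensity decomposition -----------------------------------

#' Detection fraction and per-positive intensity of a gene
#'
#' Splits a gene's expression over a spot subset into the fraction of spots
#' detecting it (count > 0) and the mean expression among detecting spots —
#' the decomposition separating "more spots express it" from "each
#' expressing spot makes more".
#'
#' @param counts genes x spots matrix with dimnames.
#' @param spots character vector of spot ids (nonempty).
#' @param gene gene symbol.
#' @return list: `detection` in `[0,1]`, `per_positive_mean`
#'   (NA when detection is 0), `n`.
#' @export
detection_intensity <- function(counts, spots, gene) {
  if (!gene %in% rownames(counts)) stop("gene not in matrix: ", gene,
                                        call. = FALSE)
  if (length(spots) == 0) stop("empty spot subset", call. = FALSE)
  miss <- setdiff(spots, colnames(counts))
  if (length(miss)) stop("unknown spot id(s), e.g.: ", miss[1],
                         call. = FALSE)
  v <- as.numeric(counts[gene, spots])
  pos <- v > 0
  list(detection = mean(pos),
       per_positive_mean = if (any(pos)) mean(v[pos]) else NA_real_,
       n = length(v))
}
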
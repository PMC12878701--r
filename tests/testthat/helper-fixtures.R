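# Shared fixtures and independent oracles used across the suite.

# a small two-group cohort configuration for fast unit tests
small_config <- function(seed = 1L, ...) {
  pr_ctrl <- c(AT2 = 0.35, B_cell = 0.05, Fib_myo = 0.25,
               Macrophage = 0.25, Lymphocyte = 0.10)
  pr_op <- c(AT2 = 0.15, B_cell = 0.15, Fib_myo = 0.40,
             Macrophage = 0.20, Lymphocyte = 0.10)
  cohort_config(
    groups = c("CTRL", "OP"), donors_per_group = c(2, 2),
    rois_per_donor = 2, grid_shape = c(8, 8),
    celltype_priors = list(CTRL = pr_ctrl, OP = pr_op),
    niche_specs = list(),
    signatures = c("GC_Response", "Apoptosis"),
    genes_per_signature = 4, n_background_genes = 12,
    signature_effects = data.frame(
      group = "OP", celltype = "Fib_myo", signature = "GC_Response",
      fold = 3, stage = NA_character_, stringsAsFactors = FALSE),
    seed = seed, ...)
}

# brute-force UCell oracle: materialise the full average-tie rank vector
# of one spot and evaluate the Mann-Whitney formula directly
ucell_oracle <- function(expr, sig_idx, rmax) {
  r <- rank(-expr, ties.method = "average")
  r[r > rmax] <- rmax + 1
  n <- length(sig_idx)
  u <- sum(r[sig_idx]) - n * (n + 1) / 2
  max(0, 1 - u / (n * rmax))
}

# O(n^2) nearest-neighbour oracle via a full cross-distance matrix
nn_oracle <- function(sx, sy, tx, ty, exclude_self = FALSE) {
  vapply(seq_along(sx), function(i) {
    d <- sqrt((sx[i] - tx)^2 + (sy[i] - ty)^2)
    if (exclude_self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# toy spot table: one ROI, explicit coordinates and labels
toy_roi <- function(x, y, labels, roi = "r1", donor = "d1",
                    group = "G") {
  n <- length(x)
  list(
    spot_table = data.frame(
      spot_id = sprintf("s%03d", seq_len(n)), x_um = x, y_um = y,
      donor = donor, roi = roi, group = group, stage = NA_character_,
      stringsAsFactors = FALSE),
    labels = data.frame(spot_id = sprintf("s%03d", seq_len(n)),
                        label = labels, confidence = 1,
                        stringsAsFactors = FALSE))
}
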
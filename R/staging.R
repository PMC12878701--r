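# Stage-resolved dynamics of the organising-pneumonia progression axis
# (early inflammatory -> middle fibro-inflammatory -> late fibrotic).
# Stages are consumed as per-ROI labels; they are never inferred here.

.default_stage_classes <- function() list(
  AT2 = "AT2",
  inflammatory = c("Macrophage", "Lymphocyte", "Neutrophil"),
  Fib_myo = "Fib_myo")

.stage_levels <- c("early", "middle", "late")

#' Stage-resolved cell-type composition
#'
#' Per (donor, stage): equal-ROI-weight proportions of each composition
#' class among all confidently labelled spots (label != "unknown") in that
#' donor's ROIs of that stage. Classes may be unions of labels (the
#' inflammatory aggregate pools macrophages, lymphocytes and neutrophils).
#' A Kruskal-Wallis test across stages (BH-adjusted over classes) is
#' attached, treating (donor, stage) means as observations.
#'
#' @param spot_table spot table with a `stage` column for staged ROIs (or
#'   supply `stages` to join).
#' @param labels data.frame from [assign_labels()].
#' @param stages optional data.frame `roi`, `stage` overriding/filling the
#'   spot table's stage column.
#' @param classes named list mapping class name to label vector.
#' @return list: `composition` (donor, stage, class, value, n_rois) and
#'   `tests` (class, H, p, p_adj).
#' @export
stage_composition <- function(spot_table, labels, stages = NULL,
                              classes = .default_stage_classes()) {
  st <- spot_table
  if (!is.null(stages)) {
    st$stage <- stages$stage[match(st$roi, stages$roi)]
  }
  st <- st[!is.na(st$stage), , drop = FALSE]
  if (!nrow(st)) stop("no staged ROIs", call. = FALSE)
  missing_stage <- setdiff(.stage_levels, unique(st$stage))
  if (length(missing_stage))
    warning("stage(s) with no ROIs omitted: ",
            paste(missing_stage, collapse = ", "), call. = FALSE)
  df <- merge(st[, c("spot_id", "donor", "roi", "stage")],
              labels[, c("spot_id", "label")], by = "spot_id")
  df <- df[df$label != "unknown", , drop = FALSE]

  per_roi <- do.call(rbind, lapply(split(df, df$roi), function(x) {
    vals <- vapply(classes, function(ll) mean(x$label %in% ll), numeric(1))
    data.frame(donor = x$donor[1], stage = x$stage[1], roi = x$roi[1],
               class = names(classes), value = unname(vals),
               stringsAsFactors = FALSE)
  }))
  comp <- do.call(rbind, lapply(
    split(per_roi, list(per_roi$donor, per_roi$stage, per_roi$class),
          drop = TRUE), function(x)
      data.frame(donor = x$donor[1], stage = x$stage[1], class = x$class[1],
                 value = mean(x$value), n_rois = nrow(x),
                 stringsAsFactors = FALSE)))
  rownames(comp) <- NULL

  tests <- do.call(rbind, lapply(names(classes), function(cl) {
    x <- comp[comp$class == cl, ]
    if (length(unique(x$stage)) < 2)
      return(data.frame(class = cl, H = NA_real_, p = NA_real_))
    kw <- suppressWarnings(kruskal_wallis(x$value, x$stage))
    data.frame(class = cl, H = kw$statistic, p = kw$p_value)
  }))
  tests$p_adj <- bh_adjust(ifelse(is.na(tests$p), 1, tests$p))
  tests$p_adj[is.na(tests$p)] <- NA_real_
  rownames(tests) <- NULL
  list(composition = comp, tests = tests)
}

#' Stage-resolved GC-sensitive dynamics and apoptosis coupling
#'
#' Per (donor, stage): the GC-sensitive fraction among Fib_myo spots
#' (equal-ROI-weight over ROIs with at least `min_spots` Fib_myo spots;
#' smaller donor-stage cells are excluded and reported), with a
#' Kruskal-Wallis test plus BH-adjusted Dunn contrasts across stages.
#' Within each stage (and overall), the apoptosis scores of GC-sensitive
#' versus GC-low Fib_myo spots are contrasted by a Wilcoxon rank-sum test
#' (BH-adjusted across stages) with Cliff's delta. Cells where one arm is
#' empty report NA.
#'
#' @param classification a `gc_classification` over Fib_myo spots (within-
#'   sample 75th-percentile rule).
#' @param spot_table spot table with stage labels (see
#'   [stage_composition()]).
#' @param labels data.frame from [assign_labels()].
#' @param apoptosis named numeric vector (or 1-signature matrix column) of
#'   apoptosis scores by spot id.
#' @param stages optional `roi`/`stage` table.
#' @param fib_label label of the fibroblast population.
#' @param min_spots minimum Fib_myo spots per contributing ROI.
#' @return list: `gc_fraction` (donor, stage, value, n_rois),
#'   `fraction_tests` (Kruskal-Wallis + Dunn rows), `apoptosis_contrast`
#'   (stage incl. "overall", n_sensitive, n_low, p, p_adj, cliffs_delta).
#' @export
stage_gc_dynamics <- function(classification, spot_table, labels, apoptosis,
                              stages = NULL, fib_label = "Fib_myo",
                              min_spots = 10L) {
  st <- spot_table
  if (!is.null(stages)) st$stage <- stages$stage[match(st$roi, stages$roi)]
  st <- st[!is.na(st$stage), , drop = FALSE]
  if (!nrow(st)) stop("no staged ROIs", call. = FALSE)
  flags <- classification$flags
  df <- merge(st[, c("spot_id", "donor", "roi", "stage")],
              labels[, c("spot_id", "label")], by = "spot_id")
  df <- df[df$label %in% fib_label, , drop = FALSE]
  df$gc <- df$spot_id %in% flags$spot_id[flags$gc_sensitive]

  per_roi <- do.call(rbind, lapply(split(df, df$roi), function(x)
    data.frame(donor = x$donor[1], stage = x$stage[1], n = nrow(x),
               p = mean(x$gc), stringsAsFactors = FALSE)))
  small <- per_roi[per_roi$n < min_spots, , drop = FALSE]
  if (nrow(small))
    message(sprintf("stage_gc_dynamics: %d ROI(s) with < %d %s spots excluded",
                    nrow(small), min_spots, fib_label))
  keep <- per_roi[per_roi$n >= min_spots, , drop = FALSE]
  gc_fraction <- do.call(rbind, lapply(
    split(keep, list(keep$donor, keep$stage), drop = TRUE), function(x)
      data.frame(donor = x$donor[1], stage = x$stage[1],
                 value = mean(x$p), n_rois = nrow(x),
                 stringsAsFactors = FALSE)))
  rownames(gc_fraction) <- NULL

  fraction_tests <- NULL
  if (length(unique(gc_fraction$stage)) >= 2) {
    kw <- suppressWarnings(
      kruskal_wallis(gc_fraction$value, gc_fraction$stage))
    dn <- suppressWarnings(
      dunn_posthoc(gc_fraction$value, gc_fraction$stage, adjust = "BH"))
    fraction_tests <- list(kruskal = kw, dunn = dn)
  }

  aps <- if (is.matrix(apoptosis)) apoptosis[, 1] else apoptosis
  df$apoptosis <- unname(aps[df$spot_id])
  contrast_one <- function(x, stage_name) {
    a <- x$apoptosis[x$gc]; b <- x$apoptosis[!x$gc]
    if (!length(a) || !length(b))
      return(data.frame(stage = stage_name, n_sensitive = length(a),
                        n_low = length(b), p = NA_real_,
                        cliffs_delta = NA_real_, stringsAsFactors = FALSE))
    wt <- wilcoxon_rank_sum(a, b)
    data.frame(stage = stage_name, n_sensitive = length(a),
               n_low = length(b), p = wt$p_value,
               cliffs_delta = cliffs_delta(a, b), stringsAsFactors = FALSE)
  }
  stage_rows <- do.call(rbind, lapply(split(df, df$stage), function(x)
    contrast_one(x, x$stage[1])))
  stage_rows$p_adj <- NA_real_
  ok <- !is.na(stage_rows$p)
  stage_rows$p_adj[ok] <- bh_adjust(stage_rows$p[ok])
  overall <- contrast_one(df, "overall")
  overall$p_adj <- overall$p
  apoptosis_contrast <- rbind(stage_rows, overall)
  rownames(apoptosis_contrast) <- NULL

  list(gc_fraction = gc_fraction, fraction_tests = fraction_tests,
       apoptosis_contrast = apoptosis_contrast,
       excluded_rois = rownames(small))
}
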
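# One-config orchestration of the full pipeline:
# simulate -> score -> classify -> sensitivity -> proximity -> density ->
# gradient -> stats -> staging. Stages run in dependency order, gated by
# the presence of their config block; every output file is checksummed
# into a machine-readable run manifest. Outputs are written with a
# .partial suffix and renamed on stage completion, so an aborted run never
# leaves a file that looks finished.

.cfg_get <- function(config, path, default = NULL, required = FALSE) {
  node <- config
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[k]])) {
      if (required)
        stop("config error: missing required key '", path, "'",
             call. = FALSE)
      return(default)
    }
    node <- node[[k]]
  }
  node
}

.stage_write <- function(writer, final_path) {
  tmp <- paste0(final_path, ".partial")
  writer(tmp)
  file.rename(tmp, final_path)
  final_path
}

#' Run the full niche-quantification pipeline from one YAML config
#'
#' Stages present in the config are executed in dependency order; a failure
#' aborts with the failing stage named, leaving that stage's outputs with a
#' `.partial` suffix. Two runs with identical config and seed produce
#' identical output checksums.
#'
#' @param config path to a YAML config, or an equivalent named list. Top
#'   level keys: `seed`; `simulate` (cohort_config overrides) or `inputs`
#'   (paths: `spots`, `weights`, `counts`, `genes`, `barcodes`, `gmt`,
#'   optional `stages`); then per-stage blocks `score`, `classify`,
#'   `sensitivity`, `proximity`, `staging`.
#' @param out_dir output directory.
#' @param seed optional integer overriding the config seed.
#' @return the run manifest (named list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (is.null(seed)) seed <- .cfg_get(cfg, "seed", default = 1L)
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  stage <- "init"
  run_stage <- function(name, fn) {
    stage <<- name
    withCallingHandlers(fn(), warning = function(w) {
      note("[%s] %s", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # ---- inputs: simulate or load -------------------------------------------
  sets <- NULL
  if (!is.null(cfg$simulate)) {
    cohort <- run_stage("simulate", function() {
      args <- cfg$simulate
      args$seed <- seed
      if (!is.null(args$grid_shape)) args$grid_shape <-
        as.integer(unlist(args$grid_shape))
      cc <- do.call(cohort_config, args)
      generate_cohort(cc)
    })
    outputs <- c(outputs, .stage_write(function(p) {
      dir.create(p, showWarnings = FALSE)
      write_cohort(cohort, p)
      invisible(p)
    }, file.path(out_dir, "cohort")))
    outputs <- list.files(file.path(out_dir, "cohort"), full.names = TRUE)
    spot_table <- cohort$spot_table
    weights <- cohort$weights
    counts <- cohort$counts
    sets <- gene_panel(cohort$config)$signature_genes
  } else {
    run_stage("load", function() {
      for (k in c("spots", "weights", "counts", "genes", "barcodes"))
        .cfg_get(cfg, paste0("inputs.", k), required = TRUE)
    })
    spot_table <- read_spot_table(.cfg_get(cfg, "inputs.spots"))
    weights <- read_celltype_weights(.cfg_get(cfg, "inputs.weights"))
    counts <- read_counts_mtx(.cfg_get(cfg, "inputs.counts"),
                              .cfg_get(cfg, "inputs.genes"),
                              .cfg_get(cfg, "inputs.barcodes"))
    stp <- .cfg_get(cfg, "inputs.stages")
    if (!is.null(stp)) {
      st <- read_stages(stp)
      spot_table$stage <- st$stage[match(spot_table$roi, st$roi)]
    }
  }

  labels <- run_stage("label", function()
    assign_labels(weights,
                  min_weight = .cfg_get(cfg, "classify.min_weight", 0.4)))
  outputs <- c(outputs, .stage_write(function(p) write_tsv(labels, p),
                                     file.path(out_dir, "labels.tsv")))

  manifest_stats <- list()
  scores <- NULL
  if (!is.null(cfg$score)) {
    scores <- run_stage("score", function() {
      if (is.null(sets)) {
        gmt <- .cfg_get(cfg, "score.gmt",
                        required = is.null(cfg$simulate))
        sets <- read_gmt(gmt)
      }
      ucell_score(counts, sets,
                  rmax = .cfg_get(cfg, "score.rmax",
                                  min(1500L, nrow(counts))))
    })
    outputs <- c(outputs, .stage_write(function(p)
      write_tsv(data.frame(spot_id = rownames(scores), scores,
                           check.names = FALSE), p),
      file.path(out_dir, "scores.tsv")))
  }

  cls <- NULL
  if (!is.null(cfg$classify)) {
    if (is.null(scores)) stop("pipeline stage 'classify' failed: requires 'score' stage",
                              call. = FALSE)
    cls <- run_stage("classify", function() {
      rule <- gc_threshold_rule(
        mode = .cfg_get(cfg, "classify.mode", "percentile"),
        percentile = .cfg_get(cfg, "classify.percentile", 75),
        z_cutoff = .cfg_get(cfg, "classify.z_cutoff", 0.674),
        scope = .cfg_get(cfg, "classify.scope", "donor"))
      sc <- scores[, .cfg_get(cfg, "classify.signature", "GC_Response")]
      # threshold pool defaults to all scored spots of the sample; the
      # donor statistic below restricts to the population of interest
      classify_gc(sc, spot_table, rule, labels = labels,
                  restrict_to = unlist(.cfg_get(cfg,
                                                "classify.restrict_to")))
    })
    outputs <- c(outputs, .stage_write(function(p)
      write_tsv(cls$flags, p), file.path(out_dir, "classification.tsv")))
    ds <- run_stage("stats", function() {
      pop <- unlist(.cfg_get(cfg, "stats.population", "Fib_myo"))
      roi_weighted_proportion(cls, spot_table, labels, numerator = pop,
                              denominator = pop,
                              min_spots = .cfg_get(cfg, "stats.min_spots",
                                                   10L))
    })
    outputs <- c(outputs, .stage_write(function(p) write_tsv(ds, p),
                                       file.path(out_dir,
                                                 "donor_summary.tsv")))
    if (length(unique(ds$group)) >= 2) {
      kw <- run_stage("stats", function()
        suppressWarnings(kruskal_wallis(ds$value, ds$group)))
      dn <- run_stage("stats", function()
        suppressWarnings(dunn_posthoc(ds$value, ds$group,
                                      adjust = .cfg_get(cfg,
                                                        "stats.adjust",
                                                        "holm"))))
      manifest_stats$kruskal_wallis <- kw[c("statistic", "df", "p_value")]
      outputs <- c(outputs, .stage_write(function(p) write_tsv(dn, p),
                                         file.path(out_dir, "dunn.tsv")))
    }
  }

  if (!is.null(cfg$sensitivity)) {
    if (is.null(scores)) stop("pipeline stage 'sensitivity' failed: requires 'score' stage",
                              call. = FALSE)
    sens <- run_stage("sensitivity", function()
      sensitivity_scan(
        scores[, .cfg_get(cfg, "classify.signature", "GC_Response")],
        spot_table, labels,
        denominator = unlist(.cfg_get(cfg, "stats.population", "Fib_myo")),
        threshold_pool = unlist(.cfg_get(cfg, "classify.restrict_to")),
        contrast = unlist(.cfg_get(cfg, "sensitivity.contrast",
                                   c("OP", "IPF"))),
        percentiles = unlist(.cfg_get(cfg, "sensitivity.percentiles",
                                      c(70, 75, 80, 85, 90))),
        n_boot = .cfg_get(cfg, "sensitivity.n_boot", 1000L),
        seed = seed))
    outputs <- c(outputs, .stage_write(function(p) write_tsv(sens, p),
                                       file.path(out_dir,
                                                 "sensitivity.tsv")))
  }

  if (!is.null(cfg$proximity)) {
    pairs <- .cfg_get(cfg, "proximity.pairs",
                      list(c("B_cell", "Fib_myo")))
    prox <- run_stage("proximity", function()
      do.call(rbind, lapply(pairs, function(pr) {
        d <- nn_distances(spot_table, labels, pr[[1]], pr[[2]])
        d$pair <- paste(pr[[1]], pr[[2]], sep = "->")
        d
      })))
    outputs <- c(outputs, .stage_write(function(p) write_tsv(prox, p),
                                       file.path(out_dir,
                                                 "nn_distances.tsv")))
  }

  if (isTRUE(.cfg_get(cfg, "staging.enabled", !is.null(cfg$staging))) &&
      any(!is.na(spot_table$stage))) {
    comp <- run_stage("staging", function()
      stage_composition(spot_table, labels))
    outputs <- c(outputs, .stage_write(function(p)
      write_tsv(comp$composition, p),
      file.path(out_dir, "stage_composition.tsv")))
    if (!is.null(cls) && !is.null(scores) &&
        "Apoptosis" %in% colnames(scores)) {
      dyn <- run_stage("staging", function()
        stage_gc_dynamics(cls, spot_table, labels,
                          scores[, "Apoptosis"]))
      outputs <- c(outputs, .stage_write(function(p)
        write_tsv(dyn$gc_fraction, p),
        file.path(out_dir, "stage_gc_fraction.tsv")))
    }
  }

  files <- setdiff(unique(outputs), out_dir)
  files <- files[!dir.exists(files)]
  manifest <- list(
    seed = seed,
    config = cfg,
    package_version = as.character(utils::packageVersion("nichefate")),
    stats = manifest_stats,
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
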
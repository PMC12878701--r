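#' @importFrom stats rpois runif rgamma rnbinom rnorm pnorm qnorm quantile
#'   sd median complete.cases
NULL

# Default cell-type panel used across the synthetic cohort. Composition
# priors encode the qualitative group structure of fibrotic lung disease:
# fibroblast/B-cell-rich organising pneumonia (OP), bronchiolised IPF,
# macrophage-rich CTD-ILD, epithelial/endothelial-rich controls.
.default_celltypes <- c("AT2", "B_cell", "Bronchial", "Endothelial",
                        "Fib_myo", "Lymphocyte", "Macrophage", "Neutrophil")

.default_priors <- function() {
  ct <- .default_celltypes
  mk <- function(...) {
    v <- c(...)
    stopifnot(abs(sum(v) - 1) < 1e-9)
    names(v) <- ct
    v
  }
  list(
    "CTRL"    = mk(0.30, 0.05, 0.05, 0.20, 0.10, 0.10, 0.15, 0.05),
    "CTD-ILD" = mk(0.20, 0.05, 0.05, 0.10, 0.15, 0.10, 0.30, 0.05),
    "OP"      = mk(0.15, 0.15, 0.05, 0.05, 0.30, 0.10, 0.15, 0.05),
    "IPF"     = mk(0.10, 0.05, 0.15, 0.10, 0.30, 0.10, 0.15, 0.05)
  )
}

.default_signatures <- c("GC_Response", "Apoptosis", "Collagen",
                         "Inflammation", "Bcell_diff")

#' Specify a clustered lesion niche
#'
#' A niche is a set of lesion centres dropped into each ROI (Poisson count,
#' uniform placement) around which the cell-type composition is blended
#' towards an override by a Gaussian kernel of the distance to the nearest
#' centre. This emulates intra-alveolar fibrotic plugs: a fibroblast-rich
#' core grading into the surrounding parenchyma.
#'
#' @param name niche label recorded in the ground truth.
#' @param centres_per_roi expected number of lesion centres per ROI
#'   (Poisson mean).
#' @param radius_um Gaussian radius of the composition blend, in micrometres.
#' @param composition named numeric vector over cell types, summing to 1;
#'   the composition at a lesion centre.
#' @param groups optional group names the niche applies to (NULL = all),
#'   for planting group-specific co-clustering.
#' @return an object of class `niche_spec`.
#' @export
niche_spec <- function(name, centres_per_roi, radius_um, composition,
                       groups = NULL) {
  if (radius_um <= 0) stop("niche radius must be > 0", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("niche composition must sum to 1", call. = FALSE)
  structure(list(name = name, centres_per_roi = centres_per_roi,
                 radius_um = radius_um, composition = composition,
                 groups = groups),
            class = "niche_spec")
}

.default_niches <- function() {
  ct <- .default_celltypes
  core <- c(AT2 = 0.05, B_cell = 0.15, Bronchial = 0.01, Endothelial = 0.02,
            Fib_myo = 0.55, Lymphocyte = 0.08, Macrophage = 0.10,
            Neutrophil = 0.04)
  list(niche_spec("lesion", centres_per_roi = 2, radius_um = 40,
                  composition = core[ct]))
}

.default_effects <- function() {
  data.frame(
    group     = c("OP", "OP", "IPF", "OP"),
    celltype  = c("Fib_myo", "Fib_myo", "Fib_myo", "B_cell"),
    signature = c("GC_Response", "Apoptosis", "Collagen", "Bcell_diff"),
    fold      = c(3, 2, 3, 3),
    stage     = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic HD-grid cohort
#'
#' Defaults reproduce the study design the pipeline is built around:
#' four groups (CTRL, CTD-ILD, OP, IPF) with 5/5/6/5 donors, three ROIs per
#' donor (63 ROIs), square lattices of 8 um bins, clustered lesion niches
#' with group-specific cell-type composition, negative-binomial counts with
#' multiplicative signature-gene effects, and a Gaussian-copula coupling
#' (Spearman rho = 0.6) between the glucocorticoid-response and apoptosis
#' programs in effect-targeted spots.
#'
#' @param groups character vector of group names.
#' @param donors_per_group integer vector, one entry per group.
#' @param rois_per_donor integer, ROIs (tissue fields) per donor.
#' @param grid_shape integer `c(rows, cols)` of bins per ROI.
#' @param bin_pitch distance between adjacent bin centres, micrometres.
#' @param celltype_priors named list (one per group) of named composition
#'   vectors over cell types, each summing to 1.
#' @param niche_specs list of [niche_spec()] objects.
#' @param signatures character vector of signature (gene-program) names.
#' @param genes_per_signature number of panel genes per signature.
#' @param n_background_genes number of unstructured background genes.
#' @param nb_mean baseline negative-binomial mean per gene per spot.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param signature_effects data.frame with columns `group`, `celltype`,
#'   `signature`, `fold`, `stage` (NA = any stage): multiplicative elevation
#'   of signature-gene means in matching spots, scaled by the spot's latent
#'   program activity.
#' @param score_correlation NULL, or `list(sigA=, sigB=, rho=)`: target
#'   Spearman rank correlation between two programs' latent activities,
#'   induced through a hierarchical Gaussian copula (see
#'   `latent_donor_share`).
#' @param latent_donor_share fraction of the coupled programs' latent
#'   variance carried by a donor-level random effect (0 = purely spot
#'   level). Donors genuinely differ in program activity, and this is what
#'   lets donor-mean scores carry the planted correlation.
#' @param stage_groups groups whose ROIs receive early/middle/late stage
#'   labels (the organising-pneumonia progression axis).
#' @param stage_fractions named fractions of ROIs per stage; must sum to 1.
#' @param stage_composition optional named list (`early`/`middle`/`late`) of
#'   composition vectors replacing the group prior for staged ROIs, used to
#'   plant stage-resolved composition dynamics.
#' @param seed integer master seed; per-ROI substreams are derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("CTRL", "CTD-ILD", "OP", "IPF"),
                          donors_per_group = c(5, 5, 6, 5),
                          rois_per_donor = 3,
                          grid_shape = c(16, 16),
                          bin_pitch = 8,
                          celltype_priors = .default_priors()[groups],
                          niche_specs = .default_niches(),
                          signatures = .default_signatures,
                          genes_per_signature = 8,
                          n_background_genes = 200,
                          nb_mean = 1,
                          nb_dispersion = 0.5,
                          signature_effects = .default_effects(),
                          score_correlation = list(sigA = "GC_Response",
                                                   sigB = "Apoptosis",
                                                   rho = 0.6),
                          latent_donor_share = 0.5,
                          stage_groups = "OP",
                          stage_fractions = c(early = 1/3, middle = 1/3,
                                              late = 1/3),
                          stage_composition = NULL,
                          seed = 1L) {
  if (length(donors_per_group) != length(groups))
    stop("donors_per_group must match length of groups", call. = FALSE)
  if (sum(donors_per_group) < 1 || all(donors_per_group == 0))
    stop("cohort has no donors", call. = FALSE)
  if (any(grid_shape < 1) || rois_per_donor < 1)
    stop("grid_shape and rois_per_donor must be positive", call. = FALSE)
  if (bin_pitch <= 0) stop("bin_pitch must be > 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (!setequal(names(celltype_priors), groups))
    stop("celltype_priors must name every group", call. = FALSE)
  for (g in groups) {
    if (abs(sum(celltype_priors[[g]]) - 1) > 1e-9)
      stop(sprintf("composition for group '%s' does not sum to 1", g),
           call. = FALSE)
    if (any(celltype_priors[[g]] < 0))
      stop(sprintf("composition for group '%s' has negative entries", g),
           call. = FALSE)
  }
  if (abs(sum(stage_fractions) - 1) > 1e-9)
    stop("stage_fractions must sum to 1", call. = FALSE)
  if (!is.null(score_correlation)) {
    stopifnot(all(c("sigA", "sigB", "rho") %in% names(score_correlation)))
    if (abs(score_correlation$rho) > 1)
      stop("score_correlation rho must be in [-1, 1]", call. = FALSE)
    if (!all(c(score_correlation$sigA, score_correlation$sigB) %in%
             signatures))
      stop("score_correlation names an unknown signature", call. = FALSE)
  }
  if (missing(signature_effects))   # default effects: keep configured sigs
    signature_effects <-
      signature_effects[signature_effects$signature %in% signatures, ,
                        drop = FALSE]
  if (!all(signature_effects$signature %in% signatures))
    stop("signature_effects names an unknown signature", call. = FALSE)
  celltypes <- names(celltype_priors[[groups[1]]])
  structure(list(
    groups = groups, donors_per_group = donors_per_group,
    rois_per_donor = rois_per_donor, grid_shape = grid_shape,
    bin_pitch = bin_pitch, celltypes = celltypes,
    celltype_priors = celltype_priors, niche_specs = niche_specs,
    signatures = signatures, genes_per_signature = genes_per_signature,
    n_background_genes = n_background_genes, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, signature_effects = signature_effects,
    score_correlation = score_correlation,
    latent_donor_share = latent_donor_share, stage_groups = stage_groups,
    stage_fractions = stage_fractions, stage_composition = stage_composition,
    seed = as.integer(seed)), class = "cohort_config")
}

# Deterministic per-ROI substream seed derived from the master seed, so
# ROIs are independent reproducible streams regardless of generation order.
.substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647)
}

# Gaussian-copula machinery for coupling two latent programs at Spearman
# rank correlation rho: the Pearson correlation of the latent normals is
# 2*sin(pi*rho/6) so the rank correlation comes out at rho exactly
# (rho = +/-1 gives co/countermonotone pairs). The copula is hierarchical:
# z = sqrt(w)*u_donor + sqrt(1-w)*e_spot with the same correlation at both
# levels, so the marginal is still N(0,1), the spot-level rank correlation
# is rho, and donor mean activities inherit the same coupling — the
# structure a donor-level correlation analysis estimates.
.copula_r <- function(rho) 2 * sin(pi * rho / 6)

.gauss_pair <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n)
  cbind(z1, z2)
}

.gene_panel <- function(config) {
  sig_genes <- lapply(config$signatures, function(s)
    sprintf("%s_g%02d", s, seq_len(config$genes_per_signature)))
  names(sig_genes) <- config$signatures
  bg <- sprintf("BG_g%02d", seq_len(config$n_background_genes))
  list(signature_genes = sig_genes,
       genes = c(unlist(sig_genes, use.names = FALSE), bg))
}

# Stage allocation within a donor: largest-remainder apportionment of the
# configured fractions over that donor's ROIs, ordered early -> late.
.stage_alloc <- function(n_rois, fractions) {
  stages <- names(fractions)
  raw <- fractions * n_rois
  k <- floor(raw)
  rem <- raw - k
  left <- n_rois - sum(k)
  if (left > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  rep(stages, times = k)
}

#' Generate a synthetic HD-grid cohort
#'
#' Builds the full donor/ROI/spot hierarchy: per ROI, a square lattice of
#' bins at the configured pitch; clustered lesion niches blending the
#' cell-type composition; a drawn true cell-type label and Dirichlet
#' deconvolution-style weights per spot; latent program activities (with
#' optional copula coupling between two programs); and negative-binomial
#' counts over a signature-structured gene panel, with signature-gene means
#' multiplied by configured fold effects scaled by the latent activity.
#' Identical config and seed give bit-identical output.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `spot_table`,
#'   `weights`, `counts` (genes x spots sparse dgCMatrix), `truth`
#'   (true labels, niche weight, latent activity matrix, per-signature
#'   target flags), and the generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- .gene_panel(config)
  genes <- panel$genes
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  n_spot_roi <- rows * cols
  eff <- config$signature_effects

  roi_index <- 0L
  spot_tabs <- list(); weight_tabs <- list(); truth_tabs <- list()
  count_blocks <- list(); latent_blocks <- list()

  donor_index <- 0L
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    for (d in seq_len(config$donors_per_group[gi])) {
      donor <- sprintf("%s_d%d", g, d)
      donor_index <- donor_index + 1L
      u_donor <- NULL
      if (!is.null(config$score_correlation)) {
        set.seed(.substream_seed(config$seed, 500000L + donor_index))
        u_donor <- .gauss_pair(1, .copula_r(config$score_correlation$rho))
      }
      staged <- g %in% config$stage_groups
      stages_d <- if (staged)
        .stage_alloc(config$rois_per_donor, config$stage_fractions)
      else rep(NA_character_, config$rois_per_donor)
      for (r in seq_len(config$rois_per_donor)) {
        roi_index <- roi_index + 1L
        roi <- sprintf("%s_r%d", donor, r)
        set.seed(.substream_seed(config$seed, roi_index))
        stage <- stages_d[r]

        x <- rep((seq_len(cols) - 1) * config$bin_pitch, times = rows)
        y <- rep((seq_len(rows) - 1) * config$bin_pitch, each = cols)
        spot_id <- sprintf("%s_s%04d", roi, seq_len(n_spot_roi))

        base <- config$celltype_priors[[g]]
        if (!is.na(stage) && !is.null(config$stage_composition) &&
            stage %in% names(config$stage_composition))
          base <- config$stage_composition[[stage]][config$celltypes]
        comp <- matrix(base, nrow = n_spot_roi, ncol = length(base),
                       byrow = TRUE, dimnames = list(NULL, config$celltypes))

        niche_w <- rep(0, n_spot_roi)
        for (ns in config$niche_specs) {
          if (!is.null(ns$groups) && !(g %in% ns$groups)) next
          n_centres <- rpois(1, ns$centres_per_roi)
          if (n_centres == 0) next
          cx <- runif(n_centres, 0, max(x)); cy <- runif(n_centres, 0, max(y))
          d2 <- outer(x, cx, "-")^2 + outer(y, cy, "-")^2
          w <- exp(-apply(d2, 1, min) / (2 * ns$radius_um^2))
          comp <- comp * (1 - w) + outer(w, ns$composition[config$celltypes])
          niche_w <- pmax(niche_w, w)
        }
        comp <- comp / rowSums(comp)

        # true label: categorical draw per spot from the blended composition
        u <- runif(n_spot_roi)
        cum <- t(apply(comp, 1, cumsum))
        lab_idx <- rowSums(u > cum) + 1L
        label <- config$celltypes[lab_idx]

        # deconvolution-style weights: Dirichlet pulled towards the label;
        # concentration chosen so a small fraction of spots (~0.1%) falls
        # below the default confidence cutoff, as real deconvolution does
        onehot <- matrix(0, n_spot_roi, length(config$celltypes))
        onehot[cbind(seq_len(n_spot_roi), lab_idx)] <- 1
        alpha <- 10 * (0.8 * onehot + 0.2 * comp)
        wmat <- matrix(rgamma(length(alpha), shape = alpha), n_spot_roi)
        wmat <- wmat / rowSums(wmat)
        colnames(wmat) <- config$celltypes

        # latent program activities (uniform marginals), copula-coupled pair
        latent <- matrix(runif(n_spot_roi * length(config$signatures)),
                         n_spot_roi,
                         dimnames = list(NULL, config$signatures))
        if (!is.null(config$score_correlation)) {
          sc <- config$score_correlation
          w <- config$latent_donor_share
          e <- .gauss_pair(n_spot_roi, .copula_r(sc$rho))
          z <- sqrt(w) * matrix(u_donor, n_spot_roi, 2, byrow = TRUE) +
               sqrt(1 - w) * e
          latent[, sc$sigA] <- pnorm(z[, 1])
          latent[, sc$sigB] <- pnorm(z[, 2])
        }

        # per-spot, per-signature fold multiplier from matching effect rows
        mult <- matrix(1, n_spot_roi, length(config$signatures),
                       dimnames = list(NULL, config$signatures))
        targeted <- matrix(FALSE, n_spot_roi, length(config$signatures),
                           dimnames = list(NULL, config$signatures))
        if (nrow(eff)) for (k in seq_len(nrow(eff))) {
          if (eff$group[k] != g) next
          if (!is.na(eff$stage[k]) &&
              (is.na(stage) || eff$stage[k] != stage)) next
          hit <- if (is.na(eff$celltype[k])) rep(TRUE, n_spot_roi)
                 else label == eff$celltype[k]
          if (!any(hit)) next
          s <- eff$signature[k]
          f <- 1 + (eff$fold[k] - 1) * latent[hit, s]
          mult[hit, s] <- pmax(mult[hit, s], f)
          targeted[hit, s] <- TRUE
        }

        mu <- matrix(config$nb_mean, length(genes), n_spot_roi,
                     dimnames = list(genes, NULL))
        for (s in config$signatures)
          mu[panel$signature_genes[[s]], ] <-
            config$nb_mean * rep(mult[, s], each = config$genes_per_signature)
        cnt <- matrix(rnbinom(length(mu), mu = mu,
                              size = 1 / config$nb_dispersion),
                      nrow(mu), dimnames = dimnames(mu))
        colnames(cnt) <- spot_id

        spot_tabs[[roi_index]] <- data.frame(
          spot_id = spot_id, x_um = x, y_um = y, donor = donor, roi = roi,
          group = g, stage = stage, stringsAsFactors = FALSE)
        weight_tabs[[roi_index]] <- data.frame(spot_id = spot_id, wmat,
                                               check.names = FALSE,
                                               stringsAsFactors = FALSE)
        truth_tabs[[roi_index]] <- data.frame(
          spot_id = spot_id, label = label, niche_weight = niche_w,
          stringsAsFactors = FALSE)
        rownames(latent) <- spot_id
        latent_blocks[[roi_index]] <- cbind(latent, targeted + 0)
        count_blocks[[roi_index]] <- cnt
      }
    }
  }
  if (roi_index == 0L) stop("cohort has no ROIs", call. = FALSE)

  spot_table <- do.call(rbind, spot_tabs)
  latents <- do.call(rbind, latent_blocks)
  nsig <- length(config$signatures)
  truth <- list(
    labels = do.call(rbind, truth_tabs),
    latent = latents[, seq_len(nsig), drop = FALSE],
    targeted = latents[, nsig + seq_len(nsig), drop = FALSE] > 0)
  counts <- Matrix::Matrix(do.call(cbind, count_blocks), sparse = TRUE)
  structure(list(spot_table = spot_table,
                 weights = do.call(rbind, weight_tabs),
                 counts = counts, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d spots, %d ROIs, %d donors, %d groups, %d genes\n",
    nrow(x$spot_table), length(unique(x$spot_table$roi)),
    length(unique(x$spot_table$donor)), length(unique(x$spot_table$group)),
    nrow(x$counts)))
  invisible(x)
}

#' Re-plant the rank correlation between two gene programs
#'
#' Redraws the latent activities of two programs from a Gaussian copula with
#' the requested Spearman correlation inside effect-targeted spots (all spots
#' when no effect targets either program) and re-simulates the counts of the
#' two programs' signature genes in those spots. The updated latents and the
#' target mask are recorded in the cohort's ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param sigA,sigB signature names to couple.
#' @param rho target Spearman rank correlation in `[-1, 1]`.
#' @param seed integer seed for the redraw.
#' @return the modified `synthetic_cohort`.
#' @export
plant_score_correlation <- function(cohort, sigA, sigB, rho,
                                    seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (abs(rho) > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  config <- cohort$config
  if (!all(c(sigA, sigB) %in% config$signatures))
    stop(sprintf("unknown signature(s): %s",
                 paste(setdiff(c(sigA, sigB), config$signatures),
                       collapse = ", ")), call. = FALSE)
  tgt <- cohort$truth$targeted[, sigA] | cohort$truth$targeted[, sigB]
  if (!any(tgt)) tgt <- rep(TRUE, nrow(cohort$spot_table))
  r <- .copula_r(rho)
  w <- config$latent_donor_share
  donors <- unique(cohort$spot_table$donor)
  for (di in seq_along(donors)) {
    in_d <- tgt & cohort$spot_table$donor == donors[di]
    if (!any(in_d)) next
    set.seed(.substream_seed(seed, 500000L + di))
    u <- .gauss_pair(1, r)
    z <- sqrt(w) * matrix(u, sum(in_d), 2, byrow = TRUE) +
         sqrt(1 - w) * .gauss_pair(sum(in_d), r)
    cohort$truth$latent[in_d, sigA] <- pnorm(z[, 1])
    cohort$truth$latent[in_d, sigB] <- pnorm(z[, 2])
  }

  # re-simulate the affected genes in the targeted spots
  panel <- .gene_panel(config)
  eff <- config$signature_effects
  spot <- cohort$spot_table
  lab <- cohort$truth$labels$label
  for (s in c(sigA, sigB)) {
    mult <- rep(1, nrow(spot))
    if (nrow(eff)) for (k in which(eff$signature == s)) {
      hit <- spot$group == eff$group[k] & tgt
      if (!is.na(eff$celltype[k])) hit <- hit & lab == eff$celltype[k]
      if (!is.na(eff$stage[k]))
        hit <- hit & !is.na(spot$stage) & spot$stage == eff$stage[k]
      f <- 1 + (eff$fold[k] - 1) * cohort$truth$latent[hit, s]
      mult[hit] <- pmax(mult[hit], f)
    }
    gset <- panel$signature_genes[[s]]
    mu <- config$nb_mean * rep(mult[tgt], each = length(gset))
    new <- matrix(rnbinom(length(mu), mu = mu,
                          size = 1 / config$nb_dispersion),
                  length(gset))
    cohort$counts[gset, which(tgt)] <- new
  }
  cohort
}

#' Gene panel of a cohort configuration
#'
#' @param config a [cohort_config()].
#' @return list with `genes` (full panel) and `signature_genes`
#'   (named list of per-signature gene vectors).
#' @export
gene_panel <- function(config) .gene_panel(config)
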
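# Geometry between cell-type spot populations. Distances are computed
# strictly within ROIs: ROIs are disjoint tissue fields, so cross-ROI
# pairs are never formed. All routines are exact (vectorised cross-distance
# matrices, chunked to bound memory); there is no approximate path.

.merge_labels <- function(spot_table, labels) {
  merge(spot_table[, c("spot_id", "x_um", "y_um", "donor", "roi", "group")],
        labels[, c("spot_id", "label")], by = "spot_id", sort = FALSE)
}

#' Per-ROI cell-type centroids
#'
#' Arithmetic mean of member-spot coordinates per (ROI, cell type); types
#' absent from an ROI are omitted, not zero-filled.
#'
#' @param spot_table spot table.
#' @param labels data.frame from [assign_labels()].
#' @return data.frame: `roi`, `label`, `x_um`, `y_um`, `n_spots`.
#' @export
celltype_centroids <- function(spot_table, labels) {
  df <- .merge_labels(spot_table, labels)
  out <- do.call(rbind, lapply(split(df, list(df$roi, df$label),
                                     drop = TRUE), function(x)
    data.frame(roi = x$roi[1], label = x$label[1],
               x_um = mean(x$x_um), y_um = mean(x$y_um), n_spots = nrow(x),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$roi, out$label), ]
}

#' Pairwise distance matrix between the centroids of one ROI
#'
#' @param centroids output of [celltype_centroids()] filtered or not.
#' @param roi ROI id.
#' @return symmetric labelled distance matrix in micrometres.
#' @export
centroid_distance_matrix <- function(centroids, roi) {
  cc <- centroids[centroids$roi == roi, , drop = FALSE]
  if (!nrow(cc)) stop("no centroids for ROI ", roi, call. = FALSE)
  m <- as.matrix(dist(cc[, c("x_um", "y_um")]))
  dimnames(m) <- list(cc$label, cc$label)
  m
}

# exact nearest-target distance for each source point, chunked
.nn_dist <- function(sx, sy, tx, ty, chunk = 2048L) {
  n <- length(sx)
  out <- numeric(n)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    d2 <- outer(sx[i0:i1], tx, "-")^2 + outer(sy[i0:i1], ty, "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Nearest-neighbour distances between two cell-type populations
#'
#' For every source-labelled spot, the Euclidean distance (micrometres) to
#' the nearest target-labelled spot in the same ROI. When source and target
#' are the same population, each spot's distance is to its nearest
#' *distinct* neighbour (self excluded). ROIs lacking targets contribute no
#' distances and are listed in the `skipped_rois` attribute.
#'
#' @param spot_table spot table.
#' @param labels data.frame from [assign_labels()].
#' @param source,target cell-type labels (character vectors allowed).
#' @return data.frame: `spot_id`, `roi`, `donor`, `group`, `distance_um`;
#'   attribute `skipped_rois`.
#' @export
nn_distances <- function(spot_table, labels, source, target) {
  df <- .merge_labels(spot_table, labels)
  same_pop <- setequal(source, target)
  skipped <- character(0)
  rows <- lapply(split(df, df$roi), function(x) {
    src <- x[x$label %in% source, , drop = FALSE]
    tgt <- x[x$label %in% target, , drop = FALSE]
    if (!nrow(src)) return(NULL)
    if (!nrow(tgt) || (same_pop && nrow(tgt) < 2)) {
      skipped <<- c(skipped, x$roi[1])
      return(NULL)
    }
    if (same_pop) {
      d2 <- outer(src$x_um, tgt$x_um, "-")^2 +
            outer(src$y_um, tgt$y_um, "-")^2
      diag(d2) <- Inf                    # src == tgt row order here
      d <- sqrt(apply(d2, 1, min))
    } else {
      d <- .nn_dist(src$x_um, src$y_um, tgt$x_um, tgt$y_um)
    }
    data.frame(spot_id = src$spot_id, roi = src$roi, donor = src$donor,
               group = src$group, distance_um = d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no source/target co-occurrence in any ROI",
                         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_rois") <- skipped
  out
}

#' Gaussian kernel-density map of a spot population within one ROI
#'
#' Density over the population's bounding box padded by three bandwidths,
#' evaluated on a square grid (default cell 8 um, one HD bin), then
#' renormalised so the in-grid mass integrates to 1. Bandwidth defaults to
#' Silverman's rule per axis ([stats::bw.nrd0()]). The raw in-grid mass
#' before renormalisation is kept as metadata (it should be close to 1
#' given the padding).
#'
#' @param x_um,y_um coordinates of the population (>= 2 spots).
#' @param bandwidth kernel SD in micrometres (scalar or per-axis pair);
#'   NULL = Silverman per axis.
#' @param cell grid cell size in micrometres.
#' @return list of class `density_grid`: `z` (matrix, rows = x grid),
#'   `x`, `y` grid coordinates, `bandwidth`, `cell`, `mass_raw`.
#' @export
kde_map <- function(x_um, y_um, bandwidth = NULL, cell = 8) {
  n <- length(x_um)
  if (n < 2) stop("kde_map needs >= 2 spots; skip density plotting",
                  call. = FALSE)
  if (is.null(bandwidth))
    bandwidth <- c(stats::bw.nrd0(x_um), stats::bw.nrd0(y_um))
  bandwidth <- rep(bandwidth, length.out = 2)
  bandwidth[bandwidth <= 0] <- cell       # degenerate axis: one-cell kernel
  pad <- 3 * bandwidth
  xlim <- range(x_um) + c(-1, 1) * pad[1]
  ylim <- range(y_um) + c(-1, 1) * pad[2]
  nx <- max(2L, ceiling(diff(xlim) / cell) + 1L)
  ny <- max(2L, ceiling(diff(ylim) / cell) + 1L)
  # MASS::kde2d uses a kernel SD of h/4, so h = 4 * bandwidth
  k <- MASS::kde2d(x_um, y_um, h = 4 * bandwidth, n = c(nx, ny),
                   lims = c(xlim, ylim))
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  mass <- sum(k$z) * dx * dy
  structure(list(z = k$z / mass, x = k$x, y = k$y,
                 bandwidth = bandwidth, cell = c(dx, dy), mass_raw = mass),
            class = "density_grid")
}

#' Distance-ordering gradient from a reference population
#'
#' Per ROI, each spot's Euclidean distance to the nearest reference-labelled
#' spot, with ascending ordinal ranks (average ranks on ties) — the
#' "gradient position" relative to the reference niche. ROIs without the
#' reference population are skipped and listed.
#'
#' @param spot_table spot table.
#' @param labels data.frame from [assign_labels()].
#' @param reference cell-type label(s) of the reference population.
#' @return data.frame: `spot_id`, `roi`, `group`, `distance_um`,
#'   `gradient_rank` (within-ROI); attribute `skipped_rois`.
#' @export
distance_ordering <- function(spot_table, labels, reference) {
  df <- .merge_labels(spot_table, labels)
  skipped <- character(0)
  rows <- lapply(split(df, df$roi), function(x) {
    ref <- x[x$label %in% reference, , drop = FALSE]
    if (!nrow(ref)) { skipped <<- c(skipped, x$roi[1]); return(NULL) }
    d <- .nn_dist(x$x_um, x$y_um, ref$x_um, ref$y_um)
    data.frame(spot_id = x$spot_id, roi = x$roi, group = x$group,
               distance_um = d,
               gradient_rank = rank(d, ties.method = "average"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("reference population absent from every ROI",
                         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_rois") <- skipped
  out
}

#' @importFrom stats dist
NULL
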
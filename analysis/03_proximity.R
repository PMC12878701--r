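#!/usr/bin/env Rscript
# Spatial geometry of the B-cell / myofibroblast niche: per-ROI centroid
# distances, nearest-neighbour distance distributions B_cell -> Fib_myo
# by group, a kernel-density map of GC-sensitive spots for one ROI, and
# the distance-ordering gradient from B-cell spots. Reads results/ from
# the previous steps.

suppressPackageStartupMessages(library(nichefate))

spots <- read_spot_table("results/cohort/spots.tsv")
labels <- read_celltype_weights("results/cohort/weights.tsv") |>
  assign_labels()
flags <- utils::read.delim("results/classification.tsv")

nn <- nn_distances(spots, labels, source = "B_cell", target = "Fib_myo")
cat("median B_cell -> Fib_myo nearest-neighbour distance (um) by group:\n")
print(sort(tapply(nn$distance_um, nn$group, median)))
write_tsv(nn, "results/nn_bcell_fibmyo.tsv")

cent <- celltype_centroids(spots, labels)
write_tsv(cent, "results/centroids.tsv")

ord <- distance_ordering(spots, labels, reference = "B_cell")
write_tsv(ord, "results/bcell_gradient.tsv")

# density map of GC-sensitive spots in one OP ROI
gc_ids <- flags$spot_id[flags$gc_sensitive]
op_rois <- unique(spots$roi[spots$group == "OP"])
roi <- op_rois[1]
sel <- spots[spots$roi == roi & spots$spot_id %in% gc_ids, ]
g <- kde_map(sel$x_um, sel$y_um, cell = 8)
cat(sprintf("\nKDE for ROI %s: %d GC-sensitive spots, bandwidth (%.1f, %.1f) um, raw in-grid mass %.3f\n",
            roi, nrow(sel), g$bandwidth[1], g$bandwidth[2], g$mass_raw))
utils::write.csv(g$z, "results/density_grid.csv", row.names = FALSE)
jsonlite::write_json(list(roi = roi, x0 = g$x[1], y0 = g$y[1],
                          cell = g$cell, bandwidth = g$bandwidth,
                          mass_raw = g$mass_raw),
                     "results/density_grid.json", auto_unbox = TRUE)
cat("written: results/{nn_bcell_fibmyo,centroids,bcell_gradient}.tsv, density_grid.{csv,json}\n")
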
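#!/usr/bin/env Rscript
# Stage 5 — applicability domain and chemical-space diagnostics.
#
# Defines the AD as the min/max XLogP x MW box of each iteration's
# training set and measures the outside-AD rate; then, using the
# per-molecule correctness retained by stage 4's noisy-regime sweep at
# its largest dimensionality, derives the distance-binned and
# distance-thresholded classification-rate curves, per-class distance
# histograms, 30 x 30 region heatmaps per technique, and the linear
# vs non-linear superiority map.

suppressMessages(library(qsardr))
dir.create("results/region_grids", recursive = TRUE, showWarnings = FALSE)

ds <- read_dataset("results/data/benchmark_noisy.csv")
res <- readRDS("results/comparison_noisy.rds")

rep_ <- ad_report(ds, res$plan)
write.csv(rep_$per_iteration, "results/ad_report.csv", row.names = FALSE)
cat(sprintf("outside-AD rate per iteration: %s; mean %.2f%%\n",
            paste(sprintf("%.2f%%", 100 * rep_$per_iteration$fraction_outside),
                  collapse = ", "),
            100 * rep_$mean_outside))

d_top <- max(res$summary$dim)
techniques <- unique(res$summary$technique)
grids <- list()
for (tech in techniques) {
  pc <- pooled_correctness(res, tech, d_top)
  pts <- ds[match(pc$id, ds$id), ]
  grids[[tech]] <- region_heatmap(pts, pc$correct)
  region_grid_table(grids[[tech]],
                    file.path("results/region_grids",
                              paste0(tech, ".csv")))
}

pc <- pooled_correctness(res, "ae", d_top)
pts <- ds[match(pc$id, ds$id), ]
cur <- distance_curves(pts, pc$correct, labels = pts$label)
write.csv(cur$binned, "results/distance_binned.csv", row.names = FALSE)
write.csv(cur$thresholded, "results/distance_thresholded.csv",
          row.names = FALSE)
cat(sprintf("thresholded curve at max distance = global rate: %.3f\n",
            cur$thresholded$rate[nrow(cur$thresholded)]))

sup <- superiority_map(grids)
write.csv(sup, "results/superiority_map.csv", row.names = FALSE)
tab <- table(factor(sup[!is.na(sup)], levels = c("linear", "nonlinear",
                                                 "equal")))
cat(sprintf("superiority over occupied regions: linear %d, non-linear %d, equal %d\n",
            tab["linear"], tab["nonlinear"], tab["equal"]))
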
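#!/usr/bin/env Rscript
# Stage 3 — hyperparameter grid search at a controlled reduction
# dimensionality.
#
# The benchmark searches the two most influential hyperparameters per
# technique (ICA 2x9, autoencoder 8x5, LLE 5x12, isomap 12x10 states)
# with the reduction controlled at 100 dimensions; PCA and kernel PCA
# are not searched. At desk scale the controlled dimensionality is
# clamped to the training-fold size and a reduced MLP is used; the full
# ICA grid is executed here, the heavier autoencoder/LLE/isomap grids
# can be enabled with RUN_ALL_GRIDS=1.

suppressMessages(library(qsardr))
dir.create("results/grids", recursive = TRUE, showWarnings = FALSE)

ds <- read_dataset("results/data/benchmark_linear.csv")
space <- tanimoto_matrix(fingerprint_matrix(ds), ids = ds$id)
labels <- stats::setNames(ds$label, ds$id)
plan <- read_fold_plan("results/fold_plan.json")
mlp <- mlp_config(hidden_layers = c(100, 100), max_epochs = 300, seed = 9)

techniques <- if (nzchar(Sys.getenv("RUN_ALL_GRIDS"))) {
  c("ica", "ae", "lle", "isomap")
} else "ica"

for (tech in techniques) {
  spec <- grid_spec(tech)
  cat(sprintf("%s grid: %d states (%s x %s)\n", tech, length(spec$hyper),
              spec$axis1_name, spec$axis2_name))
  res <- suppressWarnings(
    run_grid(space, labels, plan, spec, dim = 50, mlp = mlp, seed = 700))
  write_grid_result(res, file.path("results/grids", tech))
  sel <- select_optimum(res)
  jsonlite::write_json(sel, file.path("results/grids",
                                      paste0(tech, "_optimum.json")),
                       auto_unbox = TRUE)
  cat(sprintf("  best mean accuracy %.3f at %s = %s, %s = %s\n",
              sel$mean_accuracy,
              spec$axis1_name, as.character(spec$axis1[sel$i1]),
              spec$axis2_name, as.character(spec$axis2[sel$i2])))
}
cat("note: the shipped full-scale optima (ica arbitrary/800, ae 320/1,\n")
cat("lle 1e-6/115, isomap 65/auto) remain the defaults for stage 4;\n")
cat("desk-scale grids are flat when the task saturates.\n")
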
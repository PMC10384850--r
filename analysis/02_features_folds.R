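#!/usr/bin/env Rscript
# Stage 2 — similarity-matrix feature space and stratified folds.
#
# Builds the all-against-all Tanimoto matrix whose rows are the feature
# vectors (feature dimensionality = collection size, here 600; at full
# scale 11,268 giving 11,268^2 = 126,967,824 coefficients), then
# stratifies five perfectly class-balanced folds and assigns every
# excess non-mutagenic molecule to the permanent testing pool. The
# Cover's-theorem diagnostic confirms the training sets sit in the
# regime N_train <= D + 1 where linear separability is likely.

suppressMessages(library(qsardr))
dir.create("results", showWarnings = FALSE)

ds <- read_dataset("results/data/benchmark_linear.csv")
space <- tanimoto_matrix(fingerprint_matrix(ds), ids = ds$id)
cat(sprintf("feature space: %d x %d Tanimoto coefficients (%d entries)\n",
            nrow(space$matrix), ncol(space$matrix),
            length(space$matrix)))

labels <- stats::setNames(ds$label, ds$id)
plan <- build_folds(labels, k = 5, seed = 600)
write_fold_plan(plan, "results/fold_plan.json")
sp <- iteration_split(plan, 1)
cat(sprintf("folds: %d x %d molecules, pool %d; train %d (%.0f%%), test %d (%.0f%%)\n",
            plan$k, length(plan$fold_members[[1]]), length(plan$pool),
            length(sp$train), 100 * length(sp$train) / nrow(ds),
            length(sp$test), 100 * length(sp$test) / nrow(ds)))
cat(sprintf("Cover diagnostic: N_train = %d <= D + 1 = %d -> linear separability likely\n",
            length(sp$train), ncol(space$matrix) + 1L))
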
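#' Configuration of a full benchmark comparison run
#'
#' @param dataset Molecule data frame ([generate_dataset()] output or
#'   [read_dataset()] of the CSV dialect).
#' @param techniques Technique kinds to compare (default all seven:
#'   pca, kpca_rbf, kpca_sigmoid, ica, ae, lle, isomap).
#' @param dims Ascending reduced dimensionalities to sweep (default the
#'   benchmark sweep 2, 4, 8, 10, 20, 50, 100, 200, 300).
#' @param k Fold count (default 5).
#' @param hyper Named list (per technique) of hyperparameter overrides;
#'   defaults are the full-scale grid-search optima in
#'   [reducer_defaults()].
#' @param mlp An [mlp_config()] for the downstream classifier.
#' @param seed Master seed; folds, reducer fits and classifiers derive
#'   their own seeds from it.
#' @return A `"run_config"` list.
#' @export
run_config <- function(dataset,
                       techniques = c("pca", "kpca_rbf", "kpca_sigmoid",
                                      "ica", "ae", "lle", "isomap"),
                       dims = c(2L, 4L, 8L, 10L, 20L, 50L, 100L, 200L, 300L),
                       k = 5L, hyper = list(), mlp = mlp_config(),
                       seed = 1L) {
  stopifnot(length(techniques) >= 1L, !is.unsorted(dims))
  structure(list(dataset = dataset, techniques = techniques,
                 dims = as.integer(dims), k = as.integer(k),
                 hyper = hyper, mlp = mlp, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full dimensionality-reduction comparison
#'
#' Orchestrates the complete benchmark on one dataset: builds the
#' Tanimoto feature space, stratifies balanced folds plus the permanent
#' testing pool, and for every (technique, dimensionality, iteration)
#' fits the reducer on the training feature rows, projects train and
#' test out-of-sample, trains the fixed MLP and records the five
#' metrics. Per-molecule correctness vectors are retained for the
#' chemical-space diagnostics. The run also reports the linear-
#' separability diagnostic from Cover's theorem: N binary-labelled
#' points in D dimensions are likely linearly separable when
#' N <= D + 1, which holds by construction here since each iteration
#' trains on fewer rows than the feature dimensionality N.
#'
#' @param config A [run_config()].
#' @return A `"comparison_result"`: list with `metrics` (tidy data
#'   frame keyed by technique, dim, iteration), `summary` (mean and sd
#'   over iterations), `correctness` (per technique x dim, a logical
#'   vector over all test evaluations with ids), `cover` (diagnostic
#'   list), `plan`, `space_ids`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- config$dataset
  fps <- fingerprint_matrix(ds)
  space <- tanimoto_matrix(fps, ids = ds$id)
  labels <- stats::setNames(as.integer(ds$label), ds$id)
  plan <- build_folds(labels, k = config$k, seed = config$seed)
  n_feat <- length(space$ids)
  n_train <- (config$k - 1L) * 2L *
    (min(sum(labels == 1), sum(labels == 0)) %/% config$k)
  cover <- list(n_train = n_train, feature_dim = n_feat,
                holds = n_train <= n_feat + 1L)
  metrics <- list()
  correctness <- list()
  for (tech in config$techniques) {
    h <- config$hyper[[tech]]
    if (is.null(h)) h <- list()
    for (d in config$dims) {
      corr_all <- logical(0); corr_ids <- character(0)
      for (i in seq_len(config$k)) {
        sp <- iteration_split(plan, i)
        d_max <- nrow_train_cap(tech, length(sp$train))
        if (d > d_max) {
          warning(sprintf("%s at dim %d infeasible (max %d); recorded missing",
                          tech, d, d_max), call. = FALSE)
          metrics[[length(metrics) + 1L]] <- data.frame(
            technique = tech, dim = d, iteration = i, tp = NA, fp = NA,
            tn = NA, fn = NA, sensitivity = NA, specificity = NA,
            ppv = NA, npv = NA, overall_accuracy = NA)
          next
        }
        res <- tryCatch({
          feats <- split_feature_rows(space, sp$train, sp$test)
          fit <- suppressWarnings(
            reducer(tech, h)(feats$train, d,
                             seed = config$seed + 1000L * i))
          Ztr <- project(fit, feats$train)
          Zte <- project(fit, feats$test)
          cfg <- config$mlp
          cfg$seed <- as.integer(config$seed + 7919L * i + d)
          clf <- train_mlp(Ztr, labels[sp$train], cfg)
          evaluate(clf, Zte, labels[sp$test])
        }, error = function(e) {
          warning(sprintf("%s dim %d iteration %d failed: %s", tech, d, i,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
        if (is.null(res)) {
          metrics[[length(metrics) + 1L]] <- data.frame(
            technique = tech, dim = d, iteration = i, tp = NA, fp = NA,
            tn = NA, fn = NA, sensitivity = NA, specificity = NA,
            ppv = NA, npv = NA, overall_accuracy = NA)
        } else {
          metrics[[length(metrics) + 1L]] <-
            cbind(data.frame(technique = tech, dim = d, iteration = i), res)
          corr_all <- c(corr_all,
                        attr(res, "predictions") == labels[sp$test])
          corr_ids <- c(corr_ids, sp$test)
        }
      }
      correctness[[paste(tech, d, sep = "@")]] <-
        list(technique = tech, dim = d, ids = corr_ids, correct = corr_all)
    }
  }
  metrics <- do.call(rbind, metrics)
  summary <- stats::aggregate(
    overall_accuracy ~ technique + dim, data = metrics,
    FUN = function(v) c(mean = mean(v), sd = sd(v)), na.action = stats::na.omit)
  summary <- data.frame(technique = summary$technique, dim = summary$dim,
                        mean_accuracy = summary$overall_accuracy[, "mean"],
                        sd_accuracy = summary$overall_accuracy[, "sd"])
  structure(list(metrics = metrics, summary = summary,
                 correctness = correctness, cover = cover, plan = plan,
                 space_ids = space$ids, config = config),
            class = "comparison_result")
}

# feasibility cap for a technique's target dimensionality given the
# training-row count (reducers cannot emit more components than rows)
nrow_train_cap <- function(tech, n_train) {
  switch(tech,
    lle = n_train - 2L,   # d + 1 bottom eigenvectors must exist
    n_train - 1L)
}

#' Pooled per-molecule correctness for one technique and dimensionality
#'
#' Averages the retained correctness vectors over all iterations: a
#' molecule tested several times (the permanent pool appears in every
#' iteration) is scored correct if it was correctly classified in the
#' majority of its evaluations.
#'
#' @param result A [run_comparison()] result.
#' @param technique,dim Which retained vector to pool.
#' @return Data frame `id`, `correct` (logical), `times_tested`.
#' @export
pooled_correctness <- function(result, technique, dim) {
  key <- paste(technique, dim, sep = "@")
  cc <- result$correctness[[key]]
  if (is.null(cc)) stop("no retained correctness for ", key, call. = FALSE)
  agg <- tapply(cc$correct, cc$ids, mean)
  data.frame(id = names(agg), correct = as.numeric(agg) >= 0.5,
             rate = as.numeric(agg),
             times_tested = as.integer(table(cc$ids)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Applicability-domain report across iterations
#'
#' Fits the AD box on each iteration's training molecules and reports
#' the fraction of that iteration's test molecules outside it, plus the
#' average over iterations.
#'
#' @param dataset Molecule data frame (needs `id`, `xlogp`, `mw`).
#' @param plan A [build_folds()] plan over the dataset ids.
#' @return List with `per_iteration` data frame and `mean_outside`.
#' @export
ad_report <- function(dataset, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  rows <- lapply(seq_len(plan$k), function(i) {
    sp <- iteration_split(plan, i)
    box <- fit_ad_box(dataset[match(sp$train, dataset$id), ])
    fo <- flag_outside(box, dataset[match(sp$test, dataset$id), ])
    data.frame(iteration = i, n_test = length(sp$test),
               n_outside = sum(fo$outside),
               fraction_outside = fo$fraction)
  })
  per <- do.call(rbind, rows)
  list(per_iteration = per, mean_outside = mean(per$fraction_outside))
}
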
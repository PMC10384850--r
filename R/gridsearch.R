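#' Hyperparameter grids for the four searched techniques
#'
#' The two most important hyperparameters per technique, at a fixed
#' 100-dimensional reduction (PCA and kernel PCA are not searched):
#' \describe{
#'   \item{ica}{whitening variant (arbitrary, unit) x max iterations
#'     (200..1000 step 100): 18 states.}
#'   \item{ae}{epochs (10 doubling to 1280: 8 values) x steps to the
#'     bottleneck (1..5): 40 states.}
#'   \item{lle}{regularisation (1e-6..1e-2, ratio 10: 5 values) x
#'     neighbours (5..115 step 10: 12 values): 60 states.}
#'   \item{isomap}{neighbours (5..115 step 10) x eigensolver (lapack, or
#'     arnoldi at max iterations 200..1000 step 100): 120 states.}
#' }
#'
#' @param technique One of `"ica"`, `"ae"`, `"lle"`, `"isomap"`.
#' @return A `"grid_spec"`: list with `technique`, `axis1`, `axis2`
#'   (named value vectors) and `states` (data frame, the Cartesian
#'   product in deterministic axis1-major order, one hyperparameter list
#'   per row in `$hyper`).
#' @export
grid_spec <- function(technique = c("ica", "ae", "lle", "isomap")) {
  technique <- match.arg(technique)
  ax <- switch(technique,
    ica = list(whiten_variant = c("arbitrary", "unit"),
               max_iter = seq(200L, 1000L, by = 100L)),
    ae = list(epochs = as.integer(10 * 2^(0:7)), steps = 1:5),
    lle = list(reg = 10^seq(-6, -2), n_neighbors = seq(5L, 115L, by = 10L)),
    isomap = list(n_neighbors = seq(5L, 115L, by = 10L),
                  eigen_solver = c("lapack",
                                   paste0("arnoldi@",
                                          seq(200L, 1000L, by = 100L)))))
  states <- expand.grid(i1 = seq_along(ax[[1]]), i2 = seq_along(ax[[2]]))
  hyper <- lapply(seq_len(nrow(states)), function(r) {
    h <- list(ax[[1]][states$i1[r]], ax[[2]][states$i2[r]])
    names(h) <- names(ax)
    if (technique == "isomap") {
      solver <- h$eigen_solver
      if (startsWith(solver, "arnoldi@")) {
        h$max_iter <- as.integer(sub("arnoldi@", "", solver))
        h$eigen_solver <- "arnoldi"
      }
    }
    h
  })
  structure(list(technique = technique,
                 axis1 = ax[[1]], axis1_name = names(ax)[1],
                 axis2 = ax[[2]], axis2_name = names(ax)[2],
                 states = states, hyper = hyper, dim = 100L),
            class = "grid_spec")
}

#' Enumerate the hyperparameter states of a technique's grid
#'
#' @inheritParams grid_spec
#' @return List of named hyperparameter lists, in deterministic order.
#' @export
enumerate_grid <- function(technique) {
  grid_spec(technique)$hyper
}

#' Run a hyperparameter grid search
#'
#' For every hyperparameter state: fit the reducer on each iteration's
#' training feature rows, project train and test at the controlled
#' dimensionality, train and evaluate the MLP, and aggregate the mean
#' overall accuracy and its dispersion across the `k` iterations into
#' paired heatmaps. A failing state is recorded as a missing cell and
#' the run continues.
#'
#' @param space A [tanimoto_matrix()] feature space.
#' @param labels Named binary label vector.
#' @param plan A [build_folds()] plan over the same ids.
#' @param spec A [grid_spec()].
#' @param dim Controlled reduction dimensionality (default the spec's
#'   100; clamped to the feasible maximum of the training size with a
#'   warning).
#' @param mlp An [mlp_config()] for the downstream classifier.
#' @param seed Base seed; each (state, iteration) derives its own.
#' @param dispersion `"relative"` (sd/mean x 100, default) or
#'   `"points"` (sd expressed in percentage points).
#' @return A `"grid_result"`: list with `mean_accuracy` and `dispersion`
#'   matrices (axis1 rows x axis2 columns), `records` (tidy per-cell
#'   per-iteration metrics) and the spec.
#' @export
run_grid <- function(space, labels, plan, spec, dim = spec$dim,
                     mlp = mlp_config(), seed = 1L,
                     dispersion = c("relative", "points")) {
  stopifnot(inherits(spec, "grid_spec"), inherits(plan, "fold_plan"))
  dispersion <- match.arg(dispersion)
  n1 <- length(spec$axis1); n2 <- length(spec$axis2)
  mean_acc <- matrix(NA_real_, n1, n2,
                     dimnames = list(as.character(spec$axis1),
                                     as.character(spec$axis2)))
  disp <- mean_acc
  records <- list()
  kind <- if (spec$technique == "ica") "ica" else spec$technique
  for (r in seq_along(spec$hyper)) {
    h <- spec$hyper[[r]]
    accs <- rep(NA_real_, plan$k)
    for (i in seq_len(plan$k)) {
      res <- tryCatch({
        sp <- iteration_split(plan, i)
        feats <- split_feature_rows(space, sp$train, sp$test)
        d_use <- min(dim, nrow(feats$train) - 1L)
        if (d_use < dim) {
          warning(sprintf("reduction dim clamped from %d to %d", dim, d_use),
                  call. = FALSE)
        }
        fit <- suppressWarnings(
          reducer(kind, h)(feats$train, d_use, seed = seed + 1000L * i))
        Ztr <- project(fit, feats$train)
        Zte <- project(fit, feats$test)
        cfg <- mlp; cfg$seed <- as.integer(seed + 1000L * i + r)
        clf <- train_mlp(Ztr, plan$labels[sp$train], cfg)
        evaluate(clf, Zte, plan$labels[sp$test])
      }, error = function(e) {
        warning(sprintf("grid state %d iteration %d failed: %s", r, i,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) {
        accs[i] <- res$overall_accuracy
        records[[length(records) + 1L]] <-
          cbind(data.frame(technique = spec$technique, state = r,
                           axis1 = spec$axis1[spec$states$i1[r]],
                           axis2 = spec$axis2[spec$states$i2[r]],
                           iteration = i), res)
      }
    }
    if (any(!is.na(accs))) {
      m <- mean(accs, na.rm = TRUE)
      s <- sd(accs, na.rm = TRUE)
      mean_acc[spec$states$i1[r], spec$states$i2[r]] <- m
      disp[spec$states$i1[r], spec$states$i2[r]] <-
        if (dispersion == "relative") 100 * s / m else 100 * s
    }
  }
  structure(list(mean_accuracy = mean_acc, dispersion = disp,
                 records = do.call(rbind, records), spec = spec,
                 dispersion_kind = dispersion),
            class = "grid_result")
}

#' Select the optimal hyperparameter state from a grid result
#'
#' Deterministic codification of the optimum-selection procedure: take
#' the cells within `tol_acc` of the best mean accuracy; among those,
#' keep the cells with the lowest dispersion (within `tol_disp`); if a
#' plateau of equivalent cells remains, pick the cell closest to the
#' plateau's centroid in grid-index space (the natural middle ground),
#' breaking residual ties by lowest axis indices.
#'
#' @param result A [run_grid()] result (or a list with `mean_accuracy`
#'   and `dispersion` matrices).
#' @param tol_acc,tol_disp Equivalence tolerances when ranking cells
#'   (defaults 0: exact ties only).
#' @return List with `i1`, `i2` (grid indices), `axis1`, `axis2` (the
#'   chosen values) and `mean_accuracy`.
#' @export
select_optimum <- function(result, tol_acc = 0, tol_disp = 0) {
  M <- result$mean_accuracy
  D <- result$dispersion
  if (all(is.na(M))) stop("grid result has no successful cells", call. = FALSE)
  best <- max(M, na.rm = TRUE)
  cand <- which(!is.na(M) & M >= best - tol_acc, arr.ind = TRUE)
  if (nrow(cand) > 1L && !all(is.na(D[cand]))) {
    dv <- D[cand]
    dv[is.na(dv)] <- Inf
    keep <- dv <= min(dv) + tol_disp
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) > 1L) {
    centroid <- colMeans(cand)
    dist2 <- (cand[, 1] - centroid[1])^2 + (cand[, 2] - centroid[2])^2
    cand <- cand[order(dist2, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  i1 <- cand[1, 1]; i2 <- cand[1, 2]
  out <- list(i1 = unname(i1), i2 = unname(i2),
              mean_accuracy = unname(M[i1, i2]))
  if (!is.null(result$spec)) {
    out$axis1 <- result$spec$axis1[i1]
    out$axis2 <- result$spec$axis2[i2]
    names(out)[names(out) == "axis1"] <- result$spec$axis1_name
    names(out)[names(out) == "axis2"] <- result$spec$axis2_name
  } else {
    out$axis1 <- rownames(M)[i1]
    out$axis2 <- colnames(M)[i2]
  }
  out
}

#' Write a grid heatmap as labelled CSV
#'
#' @param result A [run_grid()] result.
#' @param path Base path; `<path>_mean.csv` and `<path>_dispersion.csv`
#'   are written.
#' @export
write_grid_result <- function(result, path) {
  write.csv(result$mean_accuracy, paste0(path, "_mean.csv"))
  write.csv(result$dispersion, paste0(path, "_dispersion.csv"))
  invisible(path)
}
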
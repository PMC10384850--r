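#' Applicability-domain box in XLogP/MW space
#'
#' The applicability domain (AD) is the axis-aligned rectangle spanned by
#' the minimum and maximum XLogP and molecular-weight values of one
#' iteration's training set. The box is closed: boundary points (and
#' therefore every training point) lie inside.
#'
#' @param train_points Data frame or matrix with columns `xlogp`, `mw`.
#' @return An `"ad_box"`: list with `xlogp_min`, `xlogp_max`, `mw_min`,
#'   `mw_max`.
#' @export
fit_ad_box <- function(train_points) {
  train_points <- as.data.frame(train_points)
  stopifnot(all(c("xlogp", "mw") %in% names(train_points)))
  if (nrow(train_points) == 0L) stop("empty training set", call. = FALSE)
  structure(list(xlogp_min = min(train_points$xlogp),
                 xlogp_max = max(train_points$xlogp),
                 mw_min = min(train_points$mw),
                 mw_max = max(train_points$mw)),
            class = "ad_box")
}

#' Flag test molecules outside the applicability domain
#'
#' @param box An [fit_ad_box()] box.
#' @param test_points Data frame/matrix with `xlogp`, `mw` columns.
#' @return List with `outside` (logical mask, `TRUE` strictly outside
#'   the closed box) and `fraction` (mean of the mask).
#' @export
flag_outside <- function(box, test_points) {
  stopifnot(inherits(box, "ad_box"))
  test_points <- as.data.frame(test_points)
  out <- test_points$xlogp < box$xlogp_min |
    test_points$xlogp > box$xlogp_max |
    test_points$mw < box$mw_min | test_points$mw > box$mw_max
  list(outside = out, fraction = mean(out))
}

#' Distances from the median point of XLogP/MW space
#'
#' Euclidean distance of each molecule from the componentwise median of
#' the full analysis set, optionally on axes standardised to unit
#' standard deviation (on raw axes molecular weight dominates).
#'
#' @param points Data frame with `xlogp`, `mw`.
#' @param standardize Standardise axes before measuring (default FALSE).
#' @return Numeric distance vector with the median point as attribute
#'   `"median_point"`.
#' @export
median_distances <- function(points, standardize = FALSE) {
  points <- as.data.frame(points)
  x <- points$xlogp; m <- points$mw
  if (standardize) { x <- x / sd(x); m <- m / sd(m) }
  med <- c(xlogp = median(x), mw = median(m))
  d <- sqrt((x - med[1])^2 + (m - med[2])^2)
  attr(d, "median_point") <- med
  d
}

#' Classification-rate curves over distance from the median point
#'
#' Three diagnostics of performance versus eccentricity in XLogP/MW
#' space: (i) mean correct-classification rate in `n_bins` equal-width
#' distance bins (empty bins omitted); (ii) mean rate over all molecules
#' with distance below each of `n_thresholds` equally spaced thresholds
#' (a running cumulative average whose last value is the global rate);
#' (iii) per-class normalised distance histograms (1000 bins by
#' default), each summing to one.
#'
#' @param points Data frame with `xlogp`, `mw` (the full analysis set).
#' @param correct_mask Logical/0-1 vector: was each molecule classified
#'   correctly.
#' @param labels Optional binary labels for the class histograms.
#' @param n_bins Bins for the binned curve (default 30).
#' @param n_thresholds Thresholds for the cumulative curve (default 1000).
#' @param hist_bins Bins for the class histograms (default 1000).
#' @param standardize Passed to [median_distances()].
#' @return List with `binned` (data frame: bin midpoint, rate, count),
#'   `thresholded` (threshold, rate), `histograms` (per-class normalised
#'   frequencies, or NULL without labels), `distances`.
#' @export
distance_curves <- function(points, correct_mask, labels = NULL,
                            n_bins = 30L, n_thresholds = 1000L,
                            hist_bins = 1000L, standardize = FALSE) {
  if (length(correct_mask) == 0L) stop("empty correctness mask", call. = FALSE)
  stopifnot(nrow(as.data.frame(points)) == length(correct_mask))
  correct <- as.numeric(correct_mask)
  d <- median_distances(points, standardize = standardize)
  dmax <- max(d)
  edges <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  bin[bin < 1L] <- 1L
  counts <- tapply(correct, bin, length)
  rates <- tapply(correct, bin, mean)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  binned <- data.frame(bin = as.integer(names(rates)),
                       midpoint = mids[as.integer(names(rates))],
                       rate = as.numeric(rates),
                       count = as.integer(counts))
  thr <- seq(dmax / n_thresholds, dmax, length.out = n_thresholds)
  ord <- order(d)
  csum <- cumsum(correct[ord])
  npts <- findInterval(thr, d[ord])
  thresholded <- data.frame(threshold = thr,
                            rate = ifelse(npts > 0, csum[pmax(npts, 1)] / npts,
                                          NA_real_),
                            count = npts)
  histograms <- NULL
  if (!is.null(labels)) {
    hedges <- seq(0, dmax, length.out = hist_bins + 1L)
    histograms <- lapply(split(d, labels), function(dd) {
      h <- hist(dd, breaks = hedges, plot = FALSE)
      h$counts / sum(h$counts)
    })
    attr(histograms, "edges") <- hedges
  }
  list(binned = binned, thresholded = thresholded,
       histograms = histograms, distances = d)
}

#' Region-specific performance over a 30 x 30 chemical-space grid
#'
#' Discretises the observed XLogP/MW ranges into `n_bins` equal bins per
#' axis and reports the mean correct-classification rate per cell; cells
#' holding no molecules are flagged empty (`NA` rate).
#'
#' @param points Data frame with `xlogp`, `mw`.
#' @param correct_mask Correctness vector, one entry per molecule.
#' @param n_bins Bins per axis (default 30).
#' @return A `"region_grid"`: list with `rate` (n_bins x n_bins matrix,
#'   XLogP rows, MW columns), `count`, `xlogp_edges`, `mw_edges`.
#' @export
region_heatmap <- function(points, correct_mask, n_bins = 30L) {
  points <- as.data.frame(points)
  stopifnot(nrow(points) >= 1L, nrow(points) == length(correct_mask))
  correct <- as.numeric(correct_mask)
  xe <- seq(min(points$xlogp), max(points$xlogp), length.out = n_bins + 1L)
  me <- seq(min(points$mw), max(points$mw), length.out = n_bins + 1L)
  # guard degenerate zero-width ranges
  if (xe[1] == xe[n_bins + 1L]) xe <- xe + seq(0, 1e-9, length.out = n_bins + 1L)
  if (me[1] == me[n_bins + 1L]) me <- me + seq(0, 1e-9, length.out = n_bins + 1L)
  bx <- pmax(pmin(findInterval(points$xlogp, xe, rightmost.closed = TRUE),
                  n_bins), 1L)
  bm <- pmax(pmin(findInterval(points$mw, me, rightmost.closed = TRUE),
                  n_bins), 1L)
  rate <- matrix(NA_real_, n_bins, n_bins)
  count <- matrix(0L, n_bins, n_bins)
  cell <- (bm - 1L) * n_bins + bx  # column-major: XLogP rows, MW columns
  agg_n <- tapply(correct, cell, length)
  agg_r <- tapply(correct, cell, mean)
  idx <- as.integer(names(agg_n))
  count[idx] <- as.integer(agg_n)
  rate[idx] <- as.numeric(agg_r)
  structure(list(rate = rate, count = count, xlogp_edges = xe,
                 mw_edges = me, n_bins = n_bins),
            class = "region_grid")
}

#' Linear vs non-linear superiority map over chemical-space regions
#'
#' For every occupied cell of a set of aligned region grids, compares
#' the best correct-classification rate attained by any linear technique
#' against the best attained by any non-linear technique.
#'
#' @param grids_by_technique Named list of [region_heatmap()] grids with
#'   identical bin edges.
#' @param linear_kinds,nonlinear_kinds Technique names in each family
#'   (defaults: pca + ica linear; both kernel PCAs, ae, lle, isomap
#'   non-linear).
#' @return A character matrix over the shared grid with entries
#'   `"linear"`, `"nonlinear"`, `"equal"` or `NA` (empty cell).
#' @export
superiority_map <- function(grids_by_technique,
                            linear_kinds = c("pca", "ica"),
                            nonlinear_kinds = c("kpca_rbf", "kpca_sigmoid",
                                                "ae", "lle", "isomap")) {
  stopifnot(length(grids_by_technique) >= 2L)
  ref <- grids_by_technique[[1]]
  for (g in grids_by_technique) {
    if (!isTRUE(all.equal(g$xlogp_edges, ref$xlogp_edges)) ||
        !isTRUE(all.equal(g$mw_edges, ref$mw_edges))) {
      stop("region grids have mismatched bin edges", call. = FALSE)
    }
  }
  pick <- function(kinds) {
    mats <- grids_by_technique[intersect(kinds, names(grids_by_technique))]
    if (length(mats) == 0L) return(NULL)
    Reduce(function(a, b) {
      out <- pmax(a, b, na.rm = TRUE)
      out[is.na(a) & is.na(b)] <- NA
      out
    }, lapply(mats, function(g) g$rate))
  }
  lin <- pick(linear_kinds)
  non <- pick(nonlinear_kinds)
  if (is.null(lin) || is.null(non)) {
    stop("need at least one grid in each family", call. = FALSE)
  }
  out <- matrix(NA_character_, nrow(ref$rate), ncol(ref$rate))
  both <- !is.na(lin) & !is.na(non)
  out[both & lin > non] <- "linear"
  out[both & non > lin] <- "nonlinear"
  out[both & lin == non] <- "equal"
  out[!is.na(lin) & is.na(non)] <- "linear"
  out[is.na(lin) & !is.na(non)] <- "nonlinear"
  out
}

#' Tidy export of a region grid
#'
#' @param grid A [region_heatmap()] result.
#' @param path Optional CSV path.
#' @return Data frame with one row per cell: indices, bin edges, count,
#'   rate.
#' @export
region_grid_table <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "region_grid"))
  n <- grid$n_bins
  df <- expand.grid(xlogp_bin = seq_len(n), mw_bin = seq_len(n))
  df$xlogp_lo <- grid$xlogp_edges[df$xlogp_bin]
  df$xlogp_hi <- grid$xlogp_edges[df$xlogp_bin + 1L]
  df$mw_lo <- grid$mw_edges[df$mw_bin]
  df$mw_hi <- grid$mw_edges[df$mw_bin + 1L]
  df$count <- grid$count[cbind(df$xlogp_bin, df$mw_bin)]
  df$rate <- grid$rate[cbind(df$xlogp_bin, df$mw_bin)]
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
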
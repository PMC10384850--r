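test_that("the AD box is the componentwise min/max of the training set", {
  pts <- data.frame(xlogp = c(-1.5, 0.2, 3.7), mw = c(120, 480, 305))
  box <- fit_ad_box(pts)
  expect_equal(box$xlogp_min, -1.5); expect_equal(box$xlogp_max, 3.7)
  expect_equal(box$mw_min, 120); expect_equal(box$mw_max, 480)
  # every training point is inside its own box, boundaries included
  expect_equal(flag_outside(box, pts)$fraction, 0)
  expect_false(flag_outside(box, data.frame(xlogp = 3.7, mw = 480))$outside)
  expect_true(flag_outside(box, data.frame(xlogp = 0, mw = 481))$outside)
  expect_error(fit_ad_box(pts[0, ]), "empty")
})

test_that("outside-AD fractions track the generator's outlier design", {
  ds <- generate_dataset(synthetic_config(1500, outlier_fraction = 0.01,
                                          fp_length = 32, seed = 14))
  labels <- stats::setNames(ds$label, ds$id)
  plan <- suppressWarnings(build_folds(labels, k = 5, seed = 14))
  rep_ <- ad_report(ds, plan)
  expect_equal(nrow(rep_$per_iteration), 5)
  # training points never fall outside their own AD; test fractions stay
  # within binomial reach of the designed outlier rate
  for (i in 1:5) {
    sp <- iteration_split(plan, i)
    box <- fit_ad_box(ds[match(sp$train, ds$id), ])
    expect_equal(flag_outside(box, ds[match(sp$train, ds$id), ])$fraction, 0)
  }
  expect_lt(rep_$mean_outside, 0.01 + 3 * sqrt(0.01 * 0.99 / 1275))
})

test_that("distance curves match hand arithmetic and their identities", {
  # four hand-placed points around a median at (0, 0)
  pts <- data.frame(xlogp = c(0, 3, 0, -3, 0), mw = c(0, 4, -4, -4, 4))
  d <- median_distances(pts)
  expect_equal(as.numeric(d), c(0, 5, 4, 5, 4))  # 3-4-5 triangles

  correct <- c(1, 0, 1, 1, 0)
  cur <- distance_curves(pts, correct, n_bins = 5, n_thresholds = 10)
  # thresholded curve at the largest threshold equals the global rate
  expect_equal(cur$thresholded$rate[10], mean(correct))
  expect_equal(cur$thresholded$count[10], 5)
  # binned rates: weighted average over bins recovers the global rate
  expect_equal(sum(cur$binned$rate * cur$binned$count) /
                 sum(cur$binned$count), mean(correct))

  # class histograms normalise to one
  cur2 <- distance_curves(pts, correct, labels = c(1, 0, 0, 1, 0),
                          hist_bins = 8)
  for (h in cur2$histograms) expect_equal(sum(h), 1)

  # single point at the median: zero distance, rate = its correctness
  one <- distance_curves(data.frame(xlogp = 1, mw = 2), 1)
  expect_equal(one$thresholded$rate[1], 1)
  expect_error(distance_curves(pts[0, ], numeric(0)), "empty")
})

test_that("region heatmaps aggregate correctness per chemical-space cell", {
  # all points in one cell: one occupied cell carrying the overall rate
  pts <- data.frame(xlogp = rep(1, 7), mw = rep(100, 7))
  g <- region_heatmap(pts, c(1, 1, 0, 1, 0, 1, 1))
  expect_equal(sum(!is.na(g$rate)), 1)
  expect_equal(sum(is.na(g$rate)), 899)
  expect_equal(g$rate[!is.na(g$rate)], 5 / 7)

  # uniformly correct predictions: every occupied cell at rate 1
  ds <- generate_dataset(synthetic_config(200, fp_length = 32, seed = 2))
  g2 <- region_heatmap(ds, rep(1, 200))
  expect_true(all(g2$rate[!is.na(g2$rate)] == 1))
  expect_equal(sum(g2$count), 200)

  # two clusters with known per-cluster rates land in their own cells
  pts3 <- data.frame(xlogp = c(rep(0, 4), rep(10, 4)),
                     mw = c(rep(100, 4), rep(900, 4)))
  g3 <- region_heatmap(pts3, c(1, 1, 0, 0, 1, 1, 1, 0), n_bins = 2)
  expect_equal(g3$rate[1, 1], 0.5)
  expect_equal(g3$rate[2, 2], 0.75)
  expect_true(is.na(g3$rate[1, 2]) && is.na(g3$rate[2, 1]))
  tab <- region_grid_table(g3)
  expect_equal(sum(tab$count), 8)
})

test_that("the superiority map compares technique families per cell", {
  pts <- data.frame(xlogp = c(0, 0, 10, 10), mw = c(100, 100, 900, 900))
  g_lin <- region_heatmap(pts, c(1, 1, 0, 0), n_bins = 2)
  g_non <- region_heatmap(pts, c(0, 0, 1, 1), n_bins = 2)
  g_tie <- region_heatmap(pts, c(1, 1, 0, 0), n_bins = 2)

  sup <- superiority_map(list(pca = g_lin, lle = g_non))
  expect_equal(sup[1, 1], "linear")
  expect_equal(sup[2, 2], "nonlinear")
  expect_true(all(is.na(sup[is.na(g_lin$rate) & is.na(g_non$rate)])))

  sup2 <- superiority_map(list(pca = g_lin, lle = g_tie))
  expect_equal(unique(sup2[!is.na(sup2)]), "equal")

  # uniformly better linear family
  g_best <- region_heatmap(pts, c(1, 1, 1, 1), n_bins = 2)
  g_worse <- region_heatmap(pts, c(0, 0, 0, 0), n_bins = 2)
  sup3 <- superiority_map(list(pca = g_best, ica = g_tie, ae = g_worse))
  expect_true(all(sup3[!is.na(sup3)] == "linear"))

  g_other <- region_heatmap(data.frame(xlogp = 0:3, mw = 0:3), rep(1, 4),
                            n_bins = 2)
  expect_error(superiority_map(list(pca = g_lin, ae = g_other)),
               "mismatched")
})
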
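test_that("grid cardinalities and orders are exactly as specified", {
  expect_length(enumerate_grid("ica"), 18)     # 2 x 9
  expect_length(enumerate_grid("ae"), 40)      # 8 x 5
  expect_length(enumerate_grid("lle"), 60)     # 5 x 12
  expect_length(enumerate_grid("isomap"), 120) # 12 x (1 + 9)
  expect_error(grid_spec("pca"), "arg")

  ica <- grid_spec("ica")
  expect_identical(ica$axis2, seq(200L, 1000L, by = 100L))
  ae <- grid_spec("ae")
  expect_identical(ae$axis1, as.integer(10 * 2^(0:7)))  # 10..1280 doubling
  expect_length(ae$axis1, 8)
  lle <- grid_spec("lle")
  expect_equal(lle$axis1, 10^seq(-6, -2))
  iso <- grid_spec("isomap")
  expect_identical(iso$axis1, seq(5L, 115L, by = 10L))
  # arnoldi states carry their iteration cap, lapack does not
  h <- iso$hyper[[which(iso$states$i2 == 4)[1]]]
  expect_identical(h$eigen_solver, "arnoldi")
  expect_identical(h$max_iter, 400L)
  expect_identical(iso$hyper[[1]]$eigen_solver, "lapack")
  # deterministic enumeration
  expect_identical(enumerate_grid("ica"), enumerate_grid("ica"))
})

test_that("optimum selection encodes best, tie-break and plateau rules", {
  mk <- function(M, D) list(mean_accuracy = M, dispersion = D)
  M <- matrix(0.6, 3, 4); D <- matrix(1, 3, 4)
  M[2, 3] <- 0.9
  sel <- select_optimum(mk(M, D))
  expect_equal(c(sel$i1, sel$i2), c(2, 3))
  expect_equal(sel$mean_accuracy, 0.9)

  # two equal maxima, unequal dispersion: lower dispersion wins
  M2 <- M; M2[1, 1] <- 0.9
  D2 <- D; D2[2, 3] <- 5; D2[1, 1] <- 2
  sel2 <- select_optimum(mk(M2, D2))
  expect_equal(c(sel2$i1, sel2$i2), c(1, 1))

  # plateau of three adjacent equal cells along one axis: middle cell
  M3 <- matrix(0.5, 3, 5); D3 <- matrix(1, 3, 5)
  M3[2, 2:4] <- 0.8
  sel3 <- select_optimum(mk(M3, D3))
  expect_equal(c(sel3$i1, sel3$i2), c(2, 3))

  expect_error(select_optimum(mk(matrix(NA_real_, 2, 2),
                                 matrix(NA_real_, 2, 2))), "no successful")
})

test_that("a small ica grid run fills every heatmap cell", {
  toy <- toy_tc_dataset(n = 120, fp_length = 64, seed = 7)
  plan <- build_folds(toy$labels, k = 5, seed = 7)
  spec <- grid_spec("ica")
  mlp <- mlp_config(hidden_layers = c(16, 16), max_epochs = 60, seed = 1)
  res <- suppressWarnings(
    run_grid(toy$space, toy$labels, plan, spec, dim = 15, mlp = mlp,
             seed = 5))
  expect_equal(dim(res$mean_accuracy), c(2, 9))
  expect_equal(dim(res$dispersion), c(2, 9))
  expect_false(any(is.na(res$mean_accuracy)))
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
  expect_true(all(res$dispersion >= 0, na.rm = TRUE))
  sel <- select_optimum(res)
  expect_true(sel$whiten_variant %in% c("arbitrary", "unit"))
  # heatmap shapes match the axes for every searched technique
  for (tech in c("ica", "ae", "lle", "isomap")) {
    gs <- grid_spec(tech)
    expect_equal(nrow(gs$states), length(gs$axis1) * length(gs$axis2))
  }
})

test_that("identical feature rows drive the classifier to constant predictions", {
  n <- 40
  feats <- matrix(0.7, n, n)
  y <- rep(c(0L, 1L), each = n / 2)
  fit <- fit_pca(feats, 3)
  Z <- project(fit, feats)
  clf <- train_mlp(Z, y, mlp_config(hidden_layers = c(8, 8), max_epochs = 30,
                                    seed = 2))
  pred <- predict_mlp(clf, Z)
  expect_length(unique(pred), 1)
  # accuracy then equals one of the two class prevalences
  rec <- metrics_record(pred, y)
  expect_true(rec$overall_accuracy %in% c(mean(y == 1), mean(y == 0)))
})
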
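test_that("pca recovers closed-form structure and preserves geometry", {
  # points on the line y = x: first component is (1,1)/sqrt(2) up to sign
  X <- cbind(seq(-2, 2, by = 0.5), seq(-2, 2, by = 0.5))
  m <- fit_pca(X, 1)
  expect_equal(abs(m$components[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  set.seed(1)
  Y <- matrix(rnorm(30 * 6), 30, 6)
  mf <- fit_pca(Y, 6)
  # projecting the column-mean row gives the zero vector
  expect_equal(as.numeric(project(mf, matrix(colMeans(Y), 1))),
               rep(0, 6), tolerance = 1e-12)
  # full-rank rotation preserves pairwise distances
  expect_equal(as.matrix(dist(project(mf, Y))), as.matrix(dist(Y)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # orthonormal components, non-increasing explained variance
  expect_equal(crossprod(mf$components), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(mf$explained_variance) <= 1e-12))
  expect_warning(fit_pca(Y, 12), "truncating")
})

test_that("kernel pca matches pca under a linear kernel and is self-consistent", {
  set.seed(2)
  X <- matrix(rnorm(35 * 8), 35, 8)
  kl <- fit_kpca(X, 4, kernel = "linear")
  pc <- fit_pca(X, 4)
  expect_lt(align_error(project(kl, X), project(pc, X)), 1e-8)

  kr <- fit_kpca(X, 4, kernel = "rbf")
  # double-centred kernel rows sum to zero
  n <- nrow(X)
  ones <- matrix(1 / n, n, n)
  Kc <- kr$K_train - ones %*% kr$K_train - kr$K_train %*% ones +
    ones %*% kr$K_train %*% ones
  expect_lt(max(abs(rowSums(Kc))), 1e-8)
  # projecting a training row reproduces its fitted score
  expect_lt(max(abs(project(kr, X[7, , drop = FALSE]) -
                      project(kr, X)[7, ])), 1e-8)
  # near-degenerate kernel: graceful warning, no crash
  expect_warning(fit_kpca(X, 10, kernel = "rbf", gamma = 1e-12),
                 "positive kernel eigenvalues")
})

test_that("rbf kernel pca beats pca on xor-structured fingerprints", {
  toy <- toy_tc_dataset(n = 120, fp_length = 64, seed = 31, mode = "xor")
  fps <- fingerprint_matrix(toy$dataset)
  y <- toy$dataset$label
  acc_pca <- linear_probe(project(fit_pca(fps, 10), fps), y, seed = 2)
  acc_kpca <- linear_probe(project(fit_kpca(fps, 10, kernel = "rbf"), fps),
                           y, seed = 2)
  expect_gt(acc_kpca, acc_pca)
})

test_that("fastica recovers independent sources from a known mixing", {
  qsardr:::with_seed(11, {
    S <- cbind(runif(2000, -1, 1), runif(2000, -1, 1))
    A <- matrix(c(1, 0.5, 0.4, 1.2), 2, 2)
  })
  X <- S %*% t(A)
  m <- fit_fastica(X, 2, max_iter = 500, tol = 1e-7, seed = 2)
  expect_true(m$converged)
  expect_lt(amari_index(m$unmixing %*% A), 0.1)
  # symmetric decorrelation leaves the rotation orthogonal
  expect_equal(m$W_rot %*% t(m$W_rot), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # unit-variance variant: recovered components have variance ~ 1
  mu <- fit_fastica(X, 2, whiten_variant = "unit", max_iter = 500,
                    tol = 1e-7, seed = 2)
  v <- apply(project(mu, X), 2, var)
  expect_equal(v, c(1, 1), tolerance = 0.01, ignore_attr = TRUE)
  expect_error(fit_fastica(X, 5), "rank")
})

test_that("lle weights are barycentric and the embedding is well posed", {
  # a point exactly on the segment between two neighbours: zero
  # reconstruction error with weights (1/2, 1/2)
  w <- qsardr:::lle_weights(c(0.5, 0.5), rbind(c(0, 0), c(1, 1)), 1e-9)
  expect_equal(w, c(0.5, 0.5), tolerance = 1e-6)

  sw <- swiss_roll(100, seed = 5)
  m <- fit_lle(sw, 2, n_neighbors = 10, reg = 1e-3)
  # every weight row sums to one (checked through the stored model by
  # re-deriving a row)
  i <- 17
  nbr <- qsardr:::knn_index(sw[i, , drop = FALSE], sw, 11)[1, ]
  nbr <- nbr[nbr != i][1:10]
  expect_equal(sum(qsardr:::lle_weights(sw[i, ], sw[nbr, ], 1e-3)), 1)
  # (I - W)'(I - W) is PSD: retained eigenvalues non-negative, constant
  # mode discarded
  expect_true(all(m$bottom_eigenvalues >= -1e-10))
  expect_lt(max(abs(colSums(m$embedding))), 1e-6)  # orthogonal to constant
  # out-of-sample projection of training rows stays close to the fitted
  # embedding
  expect_lt(max(abs(project(m, sw) - m$embedding)), 0.1)
  expect_error(fit_lle(sw, 2, n_neighbors = 100), "smaller")
  expect_error(fit_lle(sw, 2, n_neighbors = 5, reg = 0), "positive")
})

test_that("isomap recovers line geometry and manifold structure", {
  X <- cbind(0:10, 0)
  m <- fit_isomap(X, 1, n_neighbors = 2, eigen_solver = "lapack")
  # evenly spaced points on a line: geodesic = Euclidean, unit gaps kept
  expect_equal(m$geodesics[1, ], as.numeric(0:10), ignore_attr = TRUE)
  expect_equal(abs(diff(m$embedding[, 1])), rep(1, 10), tolerance = 1e-8)
  expect_lt(max(abs(project(m, X) - m$embedding)), 1e-8)

  sw <- swiss_roll(120, seed = 5)
  mi <- fit_isomap(sw, 2, n_neighbors = 8)
  mp <- fit_pca(sw, 2)
  expect_lt(residual_distance_error(mi$geodesics, mi$embedding),
            residual_distance_error(mi$geodesics, project(mp, sw)))

  # two separated clusters with small k: connectivity error with sizes
  clusters <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                    matrix(rnorm(20, 50, 0.1), 10, 2))
  expect_error(fit_isomap(clusters, 2, n_neighbors = 3),
               "disconnected.*component sizes", perl = TRUE)

  # iterative solver agrees with the dense one
  ma <- fit_isomap(sw, 2, n_neighbors = 8, eigen_solver = "arnoldi",
                   max_iter = 500)
  expect_lt(align_error(ma$embedding, mi$embedding), 1e-3)
})

test_that("autoencoder layer sizing follows the geometric series", {
  a1 <- ae_architecture(11268, 100, 1)
  expect_length(a1$layer_sizes, 3)
  expect_identical(a1$layer_sizes, c(11268, 100, 11268))
  a5 <- ae_architecture(11268, 100, 5)
  expect_length(a5$layer_sizes, 11)
  expect_identical(a5$layer_sizes[1], 11268)
  expect_identical(a5$layer_sizes[6], 100)
  expect_identical(a5$layer_sizes, rev(a5$layer_sizes))
  a2 <- ae_architecture(10000, 100, 2)
  expect_equal(a2$common_ratio, 10)
  expect_identical(a2$layer_sizes, c(10000, 1000, 100, 1000, 10000))
  expect_error(ae_architecture(100, 100, 2), "smaller")
})

test_that("autoencoder training reduces reconstruction loss", {
  qsardr:::with_seed(9, {
    Xa <- matrix(runif(60 * 30), 60, 30) %*% matrix(runif(30 * 30), 30) / 10
  })
  m <- ae_train(Xa, ae_architecture(30, 3, 1), epochs = 60, seed = 4)
  trace <- m$loss_trace
  expect_length(trace, 60)
  expect_lt(trace[60], trace[1])
  Z <- project(m, Xa)
  expect_equal(dim(Z), c(60, 3))
  # determinism
  m2 <- ae_train(Xa, ae_architecture(30, 3, 1), epochs = 60, seed = 4)
  expect_identical(project(m2, Xa), Z)
  expect_error(ae_train(Xa, ae_architecture(30, 3, 1), epochs = 0), "epochs")
  expect_error(ae_train(Xa[, 1:10], ae_architecture(30, 3, 1), epochs = 1),
               "architecture")
})

test_that("projection rejects dimension mismatches for every kind", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  models <- list(fit_pca(X, 3), fit_kpca(X, 3, "rbf"),
                 fit_fastica(X, 3, seed = 1, max_iter = 500),
                 fit_lle(X, 2, n_neighbors = 6),
                 fit_isomap(X, 2, n_neighbors = 6))
  for (m in models) {
    expect_error(project(m, X[, 1:5]), "columns")
  }
})

test_that("all six techniques match the frozen reference implementation", {
  X <- read_fixture("oracle_X40.csv")
  # spectra: eigen/singular structure to 1e-6, embeddings to 1e-4
  expect_lt(align_error(project(fit_pca(X, 5), X),
                        read_fixture("oracle_pca.csv")), 1e-6)
  expect_lt(align_error(project(fit_kpca(X, 5, "rbf"), X),
                        read_fixture("oracle_kpca_rbf.csv")), 1e-6)
  expect_lt(align_error(project(fit_kpca(X, 5, "sigmoid"), X),
                        read_fixture("oracle_kpca_sigmoid.csv")), 1e-6)
  ica <- fit_fastica(X, 4, whiten_variant = "unit", max_iter = 20000,
                     tol = 1e-12, seed = 1)
  expect_lt(align_error(project(ica, X), read_fixture("oracle_ica.csv"),
                        match_scale = TRUE), 1e-4)
  expect_lt(align_error(fit_lle(X, 2, n_neighbors = 8, reg = 1e-3)$embedding,
                        read_fixture("oracle_lle.csv")), 1e-4)
  expect_lt(align_error(fit_isomap(X, 3, n_neighbors = 8)$embedding,
                        read_fixture("oracle_isomap.csv")), 1e-4)
})

test_that("every technique keeps a linear-mode TC matrix separable at d=10", {
  toy <- toy_tc_dataset(n = 60, fp_length = 64, seed = 42)
  feats <- toy$space$matrix
  y <- toy$dataset$label
  for (kind in c("pca", "kpca_rbf", "kpca_sigmoid", "ica", "ae", "lle",
                 "isomap")) {
    fit <- suppressWarnings(reducer(kind)(feats, 10, seed = 3))
    Z <- project(fit, feats)
    expect_gt(linear_probe(Z, y, seed = 7), 0.5)
  }
})
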
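# shared helpers: fixture loading, embedding alignment, toy data builders

read_fixture <- function(name) {
  as.matrix(read.csv(test_path("fixtures", name), header = FALSE))
}

# max abs deviation after matching components by absolute correlation and
# flipping signs (embeddings are defined up to per-component sign and
# permutation); match_scale additionally normalises both sides to unit
# column sd, for representations defined only up to scale
align_error <- function(mine, ref, match_scale = FALSE) {
  stopifnot(ncol(mine) == ncol(ref))
  if (match_scale) {
    mine <- scale(mine, center = FALSE, scale = apply(mine, 2, sd))
    ref <- scale(ref, center = FALSE, scale = apply(ref, 2, sd))
  }
  C <- abs(suppressWarnings(cor(mine, ref)))
  C[is.na(C)] <- 0
  perm <- apply(C, 2, which.max)
  m2 <- mine[, perm, drop = FALSE]
  s <- sign(colSums(m2 * ref))
  s[s == 0] <- 1
  max(abs(sweep(m2, 2, s, "*") - ref))
}

# Amari performance index of P = W %*% A (0 for a perfect unmixing up to
# permutation/scale)
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * n * (n - 1))
}

# swiss-roll sample for the manifold-recovery checks
swiss_roll <- function(n = 120, seed = 5) {
  qsardr:::with_seed(seed, {
    t_ <- runif(n, 1.5, 4.5) * pi
    h <- runif(n, 0, 10)
    cbind(t_ * cos(t_), h, t_ * sin(t_))
  })
}

# residual distance error: 1 - squared correlation between a reference
# distance matrix and the pairwise distances of an embedding
residual_distance_error <- function(D, Y) {
  1 - cor(as.vector(D), as.vector(as.matrix(dist(Y))))^2
}

# small molecule set + its Tanimoto feature space, for downstream tests
toy_tc_dataset <- function(n = 60, fp_length = 64, seed = 42,
                           mode = "linear", flip_noise = 0.02) {
  cfg <- synthetic_config(n, mutagenic_fraction = 0.5,
                          fp_length = fp_length, flip_noise = flip_noise,
                          outlier_fraction = 0,
                          separability_mode = mode, seed = seed)
  ds <- generate_dataset(cfg)
  space <- tanimoto_matrix(fingerprint_matrix(ds), ids = ds$id)
  list(dataset = ds, space = space,
       labels = stats::setNames(ds$label, ds$id))
}

withr_local_tempfile <- function() tempfile(fileext = ".csv")

withr_local_tempfile_with <- function(text) {
  p <- tempfile(fileext = ".csv")
  writeLines(text, p)
  p
}
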
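#' Configuration for the synthetic mutagenicity dataset generator
#'
#' Bundles and validates the parameters of [generate_dataset()]. The
#' defaults emulate the statistical structure of a curated Ames
#' mutagenicity screening collection: roughly one mutagen per ten
#' non-mutagens (1,080 of 11,268 molecules at full scale), 2048-bit
#' circular fingerprints with class-informative block structure, and a
#' physicochemical cloud in XLogP/molecular-weight space whose Euclidean
#' distances from the median point are approximately exponentially
#' distributed, with a small fraction of far outliers.
#'
#' @param n_total Total number of molecules to generate.
#' @param mutagenic_fraction Fraction of molecules labelled mutagenic
#'   (default `1080/11268`, the full-scale class ratio).
#' @param fp_length Fingerprint length in bits (default 2048, >= 8).
#' @param n_prototypes_per_class Number of fingerprint prototypes per
#'   class in `"linear"` mode (default 3).
#' @param bit_density Fraction of on-bits in each prototype (default 0.05).
#' @param flip_noise Per-bit corruption probability applied independently
#'   to every copied prototype bit (default 0.02).
#' @param outlier_fraction Fraction of molecules placed as physicochemical
#'   outliers far outside the bulk cloud (default 0.002).
#' @param separability_mode `"linear"` (labels follow class prototypes;
#'   linearly separable fingerprints by construction) or `"xor"` (the
#'   label is the exclusive-or of membership in two prototype groups,
#'   non-linearly separable in prototype-membership space).
#' @param seed Integer seed; generation is fully deterministic given it.
#'
#' @return A list of class `"synthetic_config"`.
#' @seealso [generate_dataset()]
#' @export
synthetic_config <- function(n_total,
                             mutagenic_fraction = 1080 / 11268,
                             fp_length = 2048L,
                             n_prototypes_per_class = 3L,
                             bit_density = 0.05,
                             flip_noise = 0.02,
                             outlier_fraction = 0.002,
                             separability_mode = c("linear", "xor"),
                             seed = 1L) {
  n_total <- assert_count(n_total, "n_total")
  assert_scalar_in(mutagenic_fraction, "mutagenic_fraction", 0, 1,
                   open_lo = TRUE, open_hi = TRUE)
  fp_length <- assert_count(fp_length, "fp_length", min = 8L)
  n_prototypes_per_class <- assert_count(n_prototypes_per_class,
                                         "n_prototypes_per_class")
  assert_scalar_in(bit_density, "bit_density", 0, 1, TRUE, TRUE)
  assert_scalar_in(flip_noise, "flip_noise", 0, 1, TRUE, TRUE)
  assert_scalar_in(outlier_fraction, "outlier_fraction", 0, 1,
                   open_hi = TRUE)
  separability_mode <- match.arg(separability_mode)
  if (round(mutagenic_fraction * n_total) < 1) {
    stop("mutagenic_fraction * n_total rounds to zero mutagenic molecules",
         call. = FALSE)
  }
  if (fp_length * bit_density < 1) {
    stop("fp_length too small to host prototypes at this bit_density",
         call. = FALSE)
  }
  structure(
    list(n_total = n_total,
         mutagenic_fraction = mutagenic_fraction,
         fp_length = fp_length,
         n_prototypes_per_class = n_prototypes_per_class,
         bit_density = bit_density,
         flip_noise = flip_noise,
         outlier_fraction = outlier_fraction,
         separability_mode = separability_mode,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# physicochemical cloud constants: centre and per-axis anisotropy of the
# XLogP/MW cloud (MW scale >> XLogP scale gives the elongated shape), plus
# the mean radial distance of the bulk (exponential scale, in raw units
# dominated by g/mol).
PHYSCHEM <- list(xlogp_centre = 2.5, mw_centre = 290,
                 xlogp_weight = 1.6, mw_weight = 110,
                 radial_scale = 120,
                 outlier_inflation = c(5, 20))

#' Generate a seeded synthetic mutagenicity dataset
#'
#' Produces `n_total` molecule records with binary fingerprints, binary
#' mutagenicity labels and XLogP/MW physicochemical coordinates.
#'
#' Fingerprints copy one of a small set of random prototype bit templates
#' (drawn at `bit_density`) and then flip every bit independently with
#' probability `flip_noise`. In `"linear"` mode each class owns its own
#' prototypes, so a linear classifier on raw bits separates the classes
#' almost perfectly at low noise. In `"xor"` mode the fingerprint is the
#' concatenation of two half-length prototype blocks, each chosen from a
#' two-template group, and the label is the exclusive-or of the two group
#' memberships: no linear function of the membership indicators predicts
#' the label, giving a controlled non-linearly-separable stress test.
#'
#' Physicochemical coordinates are sampled radially: a distance drawn from
#' an exponential distribution is applied along a random direction whose
#' angular density is elongated along the MW axis, so the Euclidean
#' distance of each molecule from the cloud centre is exponential by
#' construction (and distances from the sample median point are
#' approximately so). A fraction `outlier_fraction` of molecules get their
#' radius inflated 5-20x, placing them far outside the bulk envelope.
#'
#' @param config A [synthetic_config()] object.
#' @return A `data.frame` with one row per molecule and columns `id`,
#'   `label` (1 = mutagenic), `xlogp`, `mw`, `fingerprint` (0/1 string of
#'   length `fp_length`), `prototype` (prototype identifier; in xor mode
#'   the two group memberships are also exposed as `proto_a`, `proto_b`)
#'   and `outlier` (logical ground truth).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_total
  n_pos <- as.integer(round(config$mutagenic_fraction * n))
  n_neg <- n - n_pos
  with_seed(config$seed, {
    label <- c(rep(1L, n_pos), rep(0L, n_neg))
    fp <- matrix(0L, nrow = n, ncol = config$fp_length)

    if (config$separability_mode == "linear") {
      n_proto <- config$n_prototypes_per_class
      protos <- lapply(seq_len(2L * n_proto), function(i) {
        as.integer(runif(config$fp_length) < config$bit_density)
      })
      # prototypes 1..n_proto belong to class 1, rest to class 0
      proto_id <- integer(n)
      proto_id[label == 1L] <- sample.int(n_proto, n_pos, replace = TRUE)
      proto_id[label == 0L] <- n_proto +
        sample.int(n_proto, n_neg, replace = TRUE)
      for (i in seq_len(n)) fp[i, ] <- protos[[proto_id[i]]]
      proto_a <- proto_b <- NULL
    } else {
      half <- config$fp_length %/% 2L
      group_a <- lapply(1:2, function(i)
        as.integer(runif(half) < config$bit_density))
      group_b <- lapply(1:2, function(i)
        as.integer(runif(config$fp_length - half) < config$bit_density))
      # choose memberships so that xor(u, v) reproduces the exact class
      # counts: assign u freely, then v = xor(u, label)
      u <- sample(0:1, n, replace = TRUE)
      v <- as.integer(xor(u == 1L, label == 1L))
      for (i in seq_len(n)) {
        fp[i, ] <- c(group_a[[u[i] + 1L]], group_b[[v[i] + 1L]])
      }
      proto_id <- 1L + u * 2L + v
      proto_a <- u
      proto_b <- v
    }

    flips <- matrix(runif(n * config$fp_length) < config$flip_noise,
                    nrow = n)
    fp <- abs(fp - as.integer(flips))  # xor with the flip mask

    # radial-exponential physicochemical cloud
    r <- rexp(n, rate = 1 / PHYSCHEM$radial_scale)
    n_out <- as.integer(round(config$outlier_fraction * n))
    outlier <- rep(FALSE, n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      outlier[idx] <- TRUE
      bulk_reach <- quantile(r, 0.99) + 6 * PHYSCHEM$radial_scale
      r[idx] <- bulk_reach * runif(n_out, PHYSCHEM$outlier_inflation[1],
                                   PHYSCHEM$outlier_inflation[2])
    }
    dir <- cbind(PHYSCHEM$xlogp_weight * rnorm(n),
                 PHYSCHEM$mw_weight * rnorm(n))
    dir <- dir / sqrt(rowSums(dir^2))
    xlogp <- PHYSCHEM$xlogp_centre + r * dir[, 1]
    mw <- PHYSCHEM$mw_centre + r * dir[, 2]
    # reflect displacements that would give a sub-CH4 mass: a mirrored
    # direction keeps the radial distance exact while masses stay physical
    low <- mw < 16
    mw[low] <- PHYSCHEM$mw_centre - r[low] * dir[low, 2]

    ord <- sample.int(n)  # interleave classes in the output order
    out <- data.frame(
      id = sprintf("mol%05d", seq_len(n)),
      label = label[ord],
      xlogp = xlogp[ord],
      mw = mw[ord],
      fingerprint = apply(fp[ord, , drop = FALSE], 1, paste0,
                          collapse = ""),
      prototype = proto_id[ord],
      outlier = outlier[ord],
      stringsAsFactors = FALSE)
    if (!is.null(proto_a)) {
      out$proto_a <- proto_a[ord]
      out$proto_b <- proto_b[ord]
    }
    attr(out, "config") <- config
    out
  })
}

#' Extract the fingerprint bit matrix from a dataset
#'
#' @param dataset A data frame with a `fingerprint` column of equal-length
#'   0/1 strings, as produced by [generate_dataset()] or [read_dataset()].
#' @return An integer matrix of dimension `nrow(dataset)` x fingerprint
#'   length, with `dataset$id` as row names.
#' @export
fingerprint_matrix <- function(dataset) {
  stopifnot(is.data.frame(dataset), "fingerprint" %in% names(dataset))
  lens <- unique(nchar(dataset$fingerprint))
  if (length(lens) != 1L) stop("fingerprints differ in length", call. = FALSE)
  m <- matrix(as.integer(
    unlist(strsplit(dataset$fingerprint, "", fixed = TRUE), use.names = FALSE)),
    nrow = nrow(dataset), byrow = TRUE)
  rownames(m) <- dataset$id
  m
}

#' Write / read the molecule-table CSV dialect
#'
#' The on-disk dialect is a plain CSV with columns `id`, `label`, `xlogp`,
#' `mw`, `fingerprint` (fingerprint as a 0/1 string). Extra generator
#' columns (`prototype`, `outlier`, ...) are preserved when present.
#'
#' @param dataset Data frame of molecule records.
#' @param path File path.
#' @return `read_dataset()` returns the data frame; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(all(c("id", "label", "xlogp", "mw", "fingerprint") %in%
                  names(dataset)))
  write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  hdr <- names(read.csv(path, nrows = 1))
  classes <- if ("fingerprint" %in% hdr) c(fingerprint = "character")
             else NA
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
  need <- c("id", "label", "xlogp", "mw", "fingerprint")
  if (!all(need %in% names(d))) {
    stop("dataset CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Ridge-logistic linear probe with balanced accuracy
#'
#' Fits an L2-regularised logistic regression on half the rows (seeded
#' split, stratified by class) and reports balanced accuracy on the other
#' half. Used as a separability diagnostic: high balanced accuracy means
#' the representation is (approximately) linearly separable.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1), one per row of `X`.
#' @param seed Seed for the split.
#' @param lambda Ridge penalty (default `1e-2`).
#' @return Balanced accuracy (mean of per-class accuracies) on the
#'   held-out half.
#' @export
linear_probe <- function(X, y, seed = 1L, lambda = 1e-2) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  with_seed(seed, {
    idx1 <- which(y == 1)
    idx0 <- which(y == 0)
    tr <- c(sample(idx1, ceiling(length(idx1) / 2)),
            sample(idx0, ceiling(length(idx0) / 2)))
  })
  te <- setdiff(seq_along(y), tr)
  # inverse-frequency class weights so imbalance does not mask
  # separability (the probe measures geometry, not prevalence)
  w <- ifelse(y[tr] == 1, 0.5 / mean(y[tr] == 1), 0.5 / mean(y[tr] == 0))
  fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                        weights = w, alpha = 0, lambda = lambda,
                        standardize = FALSE)
  p <- as.numeric(predict(fit, X[te, , drop = FALSE], type = "response"))
  pred <- as.integer(p >= 0.5)
  acc1 <- mean(pred[y[te] == 1] == 1)
  acc0 <- mean(pred[y[te] == 0] == 0)
  mean(c(acc1, acc0))
}
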
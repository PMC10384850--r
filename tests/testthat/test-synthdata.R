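test_that("class counts are exact and the total is preserved", {
  cfg <- synthetic_config(1128, mutagenic_fraction = 1080 / 11268, seed = 7)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds), 1128)
  expect_equal(sum(ds$label == 1), 108)
  expect_equal(sum(ds$label == 0), 1020)

  for (frac in c(0.1, 0.3333, 0.5)) {
    d2 <- generate_dataset(synthetic_config(200, mutagenic_fraction = frac,
                                            fp_length = 64, seed = 1))
    expect_equal(sum(d2$label == 1), round(frac * 200))
    expect_equal(nrow(d2), 200)
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(300, fp_length = 128, seed = 99)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  other <- synthetic_config(300, fp_length = 128, seed = 100)
  expect_false(identical(generate_dataset(cfg)$fingerprint,
                         generate_dataset(other)$fingerprint))
})

test_that("distances from the median point are approximately exponential", {
  ds <- generate_dataset(synthetic_config(1000, seed = 3))
  d <- median_distances(ds)
  rate <- log(2) / median(d)  # robust to the designed far outliers
  p <- suppressWarnings(stats::ks.test(d, "pexp", rate = rate))$p.value
  expect_gt(p, 0.01)
})

test_that("linear mode is linearly separable, xor mode is not", {
  lin <- generate_dataset(synthetic_config(400, mutagenic_fraction = 0.3,
                                           fp_length = 256,
                                           flip_noise = 0.02, seed = 21))
  acc_lin <- linear_probe(fingerprint_matrix(lin), lin$label, seed = 5)
  expect_gte(acc_lin, 0.9)

  xr <- generate_dataset(synthetic_config(400, mutagenic_fraction = 0.5,
                                          fp_length = 256,
                                          separability_mode = "xor",
                                          seed = 22))
  # membership in the two prototype groups: xor labels are not a linear
  # function of these indicators
  memb <- cbind(xr$proto_a, xr$proto_b)
  acc_xor <- linear_probe(memb, xr$label, seed = 5)
  expect_lte(acc_xor, 0.6)
})

test_that("designated outliers fall outside the bulk bounding box", {
  ds <- generate_dataset(synthetic_config(2000, outlier_fraction = 0.01,
                                          fp_length = 32, seed = 12))
  expect_equal(sum(ds$outlier), 20)
  bulk <- ds[!ds$outlier, ]
  box <- fit_ad_box(bulk)
  out <- flag_outside(box, ds)
  # every designed outlier is outside the bulk envelope, so the outside
  # fraction matches outlier_fraction within binomial error of the design
  expect_true(all(out$outside[ds$outlier]))
  expect_lt(abs(out$fraction - 0.01),
            0.01 + 3 * sqrt(0.01 * 0.99 / 2000))
  expect_true(all(ds$mw > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(100, mutagenic_fraction = 0), "mutagenic")
  expect_error(synthetic_config(100, mutagenic_fraction = 1.2), "mutagenic")
  expect_error(synthetic_config(100, fp_length = 4), "fp_length")
  expect_error(synthetic_config(100, mutagenic_fraction = 1e-4), "zero")
  expect_error(synthetic_config(100, fp_length = 8, bit_density = 0.01),
               "host prototypes")
  expect_error(synthetic_config(100, flip_noise = 1), "flip_noise")
})

test_that("the CSV dialect round-trips", {
  ds <- generate_dataset(synthetic_config(50, fp_length = 32, seed = 4))
  path <- withr_local_tempfile()
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$id, ds$id)
  expect_equal(back$label, ds$label)
  expect_equal(back$fingerprint, ds$fingerprint)
  expect_equal(back$xlogp, ds$xlogp, tolerance = 1e-12)
  expect_error(read_dataset(withr_local_tempfile_with("a,b\n1,2\n")),
               "columns")
})
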
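# A shared small open mixture (no closure): only target-band wavelengths
# carry reference information, so selector recovery is unambiguous.
baseline_spec <- open_mixture_spec()
baseline_ds <- make_split_ds(baseline_spec)

test_that("correlation ranking matches a brute-force oracle and handles
           signs and dead channels", {
  set.seed(51)
  m <- 30
  X <- matrix(rnorm(m * 5), m, 5)
  y <- rnorm(m)
  X[, 2] <- y            # |r| = 1
  X[, 4] <- -y           # |r| = 1 via absolute value
  X[, 5] <- 7            # constant -> r defined as 0
  ds <- spectra_dataset(X, 1:5, y)
  ds$role <- rep(c("calibration", "validation"), c(22, 8))
  res <- cc_select(ds, lv_cap = 3)
  expect_setequal(res$ranked_order[1:2], c(2, 4))
  expect_equal(res$ranked_order[5], 5)

  cal <- spectra_block(ds, "calibration")
  oracle <- abs(sapply(1:4, function(j) cor(cal$X[, j], cal$y)))
  expect_equal(abs(res$correlation[1:4]), oracle, tolerance = 1e-12)
  # without a threshold the kept count comes from forward accumulation
  expect_equal(res$rmsep_curve$rmsep[length(res$selected)],
               min(res$rmsep_curve$rmsep))
})

test_that("VIP thresholding keeps the informative band", {
  res <- vip_select(baseline_ds, lv_cap = 6)
  expect_equal(mean(res$vip^2), 1, tolerance = 1e-10)
  expect_lt(length(res$selected), ncol(baseline_ds$X))
  score <- recovery_score(res, baseline_spec)
  expect_gt(score$precision, 0.4)
  expect_error(vip_select(baseline_ds, threshold = 1e6), "threshold")
})

test_that("UVE keeps a noiseless informative variable and drops noise", {
  set.seed(61)
  m <- 24
  X <- cbind(seq_len(m) / m, matrix(rnorm(m * 5, 0, 1), m, 5))
  y <- 2 * X[, 1]
  ds <- spectra_dataset(X, 1:6, y)
  ds$role <- rep(c("calibration", "validation"), c(18, 6))
  res <- uve_select(ds, seed = 3, lv_cap = 3)
  expect_true(1 %in% res$selected)
  expect_false(all(2:6 %in% res$selected))

  # doubling the noise amplitude changes the cutoff, not the real stabilities
  res2 <- uve_select(ds, seed = 3, noise_amplitude = 2e-10, lv_cap = 3)
  expect_equal(res2$stability, res$stability, tolerance = 1e-6)

  # noise_multiplier -> infinity empties the kept set
  expect_error(uve_select(ds, seed = 3, noise_multiplier = 1e12, lv_cap = 3),
               "eliminated every wavelength")
})

test_that("CARS retention is monotone, deterministic, and recovers the
           informative band across seeds", {
  res <- cars_select(baseline_ds, n_runs = 30, seed = 5, lv_cap = 5)
  expect_true(all(diff(res$runs$n_retained) <= 0))
  expect_lt(length(res$selected), ncol(baseline_ds$X))

  replay <- cars_select(baseline_ds, n_runs = 30, seed = 5, lv_cap = 5)
  expect_identical(replay$selected, res$selected)
  expect_identical(replay$runs, res$runs)
  expect_error(cars_select(baseline_ds, n_runs = 1), "at least 2")

  scores <- lapply(1:10, function(s) {
    r <- cars_select(baseline_ds, n_runs = 30, seed = s, lv_cap = 5)
    recovery_score(r, baseline_spec)
  })
  recalls <- sapply(scores, function(s) s$recall)
  precisions <- sapply(scores, function(s) s$precision)
  expect_gte(median(recalls), 0.5) # most of the informative band survives
  chance <- sum(baseline_spec$informative_mask) / ncol(baseline_ds$X)
  expect_gt(mean(precisions), chance) # and enrichment beats chance
})

test_that("BIPLS eliminates a pure-noise interval first", {
  set.seed(71)
  spec <- open_mixture_spec(n_wavelengths = 60, n_samples = 36)
  ds <- make_split_ds(spec)
  # append a pure-noise block as the final interval's worth of columns
  noise_block <- matrix(rnorm(nrow(ds$X) * 10, 0, 0.05), nrow(ds$X), 10)
  ds_aug <- spectra_dataset(cbind(ds$X, noise_block),
                            c(ds$wavelengths, seq(1710, 1800, length.out = 10)),
                            ds$y, role = ds$role)
  res <- bipls_select(ds_aug, n_intervals = 7, lv_cap = 5)
  noise_cols <- 61:70
  expect_lt(length(intersect(res$selected, noise_cols)), 10)
  expect_false(all(noise_cols %in% res$selected))

  # interval partition arithmetic
  sizes <- lengths(bnmi:::make_intervals(70, 7))
  expect_true(all(abs(sizes - mean(sizes)) <= 1))
  expect_equal(sum(sizes), 70)
  expect_error(bipls_select(ds_aug, n_intervals = 1), "at least 2")
  expect_error(bipls_select(ds_aug, n_intervals = 1000), "may not exceed")
})

test_that("every selector emits a coherent selection_result on the shared
           fixture", {
  results <- list(
    cc_select(baseline_ds, lv_cap = 5),
    vip_select(baseline_ds, lv_cap = 5),
    uve_select(baseline_ds, seed = 2, lv_cap = 5),
    cars_select(baseline_ds, n_runs = 20, seed = 2, lv_cap = 5),
    bipls_select(baseline_ds, n_intervals = 8, lv_cap = 5)
  )
  n <- ncol(baseline_ds$X)
  for (res in results) {
    expect_s3_class(res, "selection_result")
    expect_true(length(res$selected) >= 1 && length(res$selected) < n)
    expect_setequal(res$ranked_order, seq_len(n))
    expect_equal(res$metrics$n_vars, length(res$selected))
    expect_equal(res$metrics$rpd * res$metrics$rmsep,
                 sd(spectra_block(baseline_ds, "validation")$y),
                 tolerance = 1e-8)
    td <- tidy(res)
    expect_equal(sum(td$selected), length(res$selected))
    gl <- glance(res)
    expect_equal(gl$method, res$method)
  }
})
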
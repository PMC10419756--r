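test_that("a noiseless single-factor system is recovered with one LV", {
  d <- tiny_linear_ds(m = 15, n = 1)
  m1 <- fit_pls(d$X, d$y, 1)
  expect_equal(unname(m1$beta), 2, tolerance = 1e-10)
  expect_equal(predict(m1, d$X), d$y, tolerance = 1e-10)

  # with extra orthogonal noise columns the first-column weight dominates
  d6 <- tiny_linear_ds(m = 30, n = 6)
  m6 <- fit_pls(d6$X, d6$y, 6)
  expect_equal(predict(m6, d6$X), d6$y, tolerance = 1e-8)
})

test_that("PLS at full rank reproduces least squares on random systems", {
  set.seed(101)
  for (i in 1:50) {
    m <- sample(8:16, 1)
    n <- sample(2:5, 1)
    X <- matrix(rnorm(m * n), m, n)
    y <- rnorm(m)
    model <- fit_pls(X, y, n)
    expect_equal(predict(model, X), ols_predict(X, y, X), tolerance = 1e-6)
  }
})

test_that("SIMPLS agrees with a textbook NIPALS implementation at every LV", {
  set.seed(55)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(20, 0, 0.2)
  for (a in 1:4) {
    model <- fit_pls(X, y, a)
    expect_equal(predict(model, X), nipals_predict(X, y, a, X),
                 tolerance = 1e-8)
  }
})

test_that("fit_pls validates its inputs", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_pls(X, rnorm(5), 0), "n_lv")
  expect_error(fit_pls(X, rnorm(5), 5), "n_lv")
  expect_error(fit_pls(X, rep(1, 5), 2), "zero-variance")
  m <- fit_pls(X, rnorm(5), 2)
  expect_error(predict(m, matrix(0, 1, 3)), "columns")
})

test_that("duplicating a column leaves full-rank predictions unchanged", {
  # the span of X is unchanged by duplicating a column, so at full rank the
  # least-squares limit (and hence the PLS fit) predicts identically
  d <- tiny_linear_ds(m = 25, n = 4, noise = 0.1)
  m1 <- fit_pls(d$X, d$y, 4)
  m2 <- fit_pls(cbind(d$X, d$X[, 1]), d$y, 4)
  expect_equal(predict(m2, cbind(d$X, d$X[, 1])), predict(m1, d$X),
               tolerance = 1e-6)
})

test_that("the LOOCV curve equals a naive rebuilt-fold oracle", {
  set.seed(77)
  X <- matrix(rnorm(14 * 5), 14, 5)
  y <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(14, 0, 0.3)
  curve <- loocv_curve(X, drop(y), 4)
  expect_equal(curve$rmsecv, naive_loocv(X, drop(y), 4), tolerance = 1e-8)
  expect_true(all(curve$rmsecv >= 0))

  # noiseless rank-1 system (X and y driven by one factor): the first LV
  # already predicts perfectly
  set.seed(78)
  t_score <- rnorm(12)
  X1 <- outer(t_score, c(1, 0.5, -0.3))
  expect_lt(loocv_curve(X1, 2 * t_score, 2)$rmsecv[1], 1e-8)
  expect_error(loocv_curve(X1, 2 * t_score, 20), "max_lv")
})

test_that("latent-variable selection rules behave as specified", {
  curve <- c(5, 3, 1, 1.0001)
  expect_equal(select_lv(curve, "global_min"), 3)
  expect_equal(select_lv(curve, "parsimonious", tol = 0.02), 3)
  expect_equal(select_lv(c(2, 1, 1), "global_min"), 2) # tie -> smaller LV
  expect_equal(select_lv(c(1.01, 1), "parsimonious", tol = 0.02), 1)
  expect_error(select_lv(numeric(0)), "empty")
})

test_that("calibration metrics reproduce the defining identities", {
  d <- tiny_linear_ds(m = 20, n = 3)
  cal <- list(X = d$X[1:14, ], y = d$y[1:14])
  val <- list(X = d$X[15:20, ], y = d$y[15:20])
  model <- fit_pls(cal$X, cal$y, 3) # full rank: exact on a noiseless system
  met <- calibration_metrics(model, cal, val)

  # noiseless system: perfect prediction
  expect_equal(met$r2_pred, 1, tolerance = 1e-10)
  expect_equal(met$rmsep, 0, tolerance = 1e-8)
  expect_equal(met$bias, 0, tolerance = 1e-8)
  # RPD identity by construction
  expect_equal(met$rpd * met$rmsep, sd(val$y), tolerance = 1e-6)

  # printed toy residuals: R^2 = 1 - 0.02/2 = 0.99
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.0)), 0.99)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")

  # divisor option: m (default) vs m-1
  expect_equal(rmse(c(0, 0), c(1, 1), "m"), 1)
  expect_equal(rmse(c(0, 0), c(1, 1), "m-1"), sqrt(2))
})

test_that("VIP scores satisfy their normalization and match an oracle", {
  d <- tiny_linear_ds(m = 25, n = 5, noise = 0.2)
  model <- fit_pls(d$X, d$y, 3)
  vip <- bnmi:::vip_scores(model)
  expect_equal(mean(vip^2), 1, tolerance = 1e-10)

  # from-scratch oracle via explicit score regressions
  ctr <- mean_center(d$X, d$y)
  TT <- ctr$Xc %*% model$weights
  ssy <- sapply(seq_len(ncol(TT)), function(a) {
    t <- TT[, a]
    (sum(ctr$yc * t) / sum(t^2))^2 * sum(t^2)
  })
  W <- model$weights
  oracle <- sqrt(ncol(d$X) *
                   colSums(t(W^2) / colSums(W^2) * ssy) / sum(ssy))
  expect_equal(unname(vip), unname(oracle), tolerance = 1e-8)

  # single informative variable, one LV: VIP concentrates to sqrt(n)
  d1 <- tiny_linear_ds(m = 20, n = 4)
  X1 <- cbind(d1$X[, 1], matrix(rnorm(20 * 3, 0, 1e-6), 20, 3))
  v1 <- bnmi:::vip_scores(fit_pls(X1, d1$y, 1))
  expect_equal(v1[1], sqrt(4), tolerance = 1e-3)
  expect_true(all(v1[2:4] < 0.01))
})

test_that("adding a pure-noise variable barely moves RMSEC", {
  set.seed(31)
  d <- tiny_linear_ds(m = 30, n = 4, noise = 0.1)
  base <- fit_pls(d$X, d$y, 2)
  noisy <- fit_pls(cbind(d$X, rnorm(30, 0, 0.01)), d$y, 2)
  r1 <- rmse(d$y, predict(base, d$X))
  r2 <- rmse(d$y, predict(noisy, cbind(d$X, rep(0, 30))))
  expect_lt(abs(r1 - r2), 0.05)
})
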
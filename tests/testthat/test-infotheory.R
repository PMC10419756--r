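test_that("equal-interval binning follows the width formula", {
  sc <- make_binning(c(2, 7, 12), 5)
  expect_equal(sc$bin_width, 2)
  expect_equal(sc$edges, c(2, 4, 6, 8, 10, 12))
  expect_equal(make_binning(c(0, 1), 10)$bin_width, 0.1)
  one <- make_binning(c(3, 9), 1)
  expect_equal(one$edges, c(3, 9))
  expect_error(make_binning(c(1, 2), 0), "positive integer")
  expect_error(make_binning(rep(2, 5), 4), "degenerate")
})

test_that("discretization is left-closed with a closed top edge", {
  sc <- make_binning(c(0, 1), 4)
  d <- discretize(c(0, 0.25, 0.5, 0.75, 1.0), sc)
  expect_equal(d$labels, c(0L, 1L, 2L, 3L, 3L))
  expect_error(discretize(c(-0.1, 0.5), sc), "out of binning range")
  expect_equal(discretize(c(-0.1, 1.4), sc, clamp = TRUE)$labels, c(0L, 3L))

  # histogram of labels equals a direct counting oracle
  set.seed(21)
  v <- runif(500)
  sc2 <- make_binning(v, 7)
  lab <- discretize(v, sc2)$labels
  counts_oracle <- sapply(0:6, function(k) {
    lo <- sc2$edges[k + 1]; hi <- sc2$edges[k + 2]
    if (k < 6) sum(v >= lo & v < hi) else sum(v >= lo & v <= hi)
  })
  expect_equal(tabulate(lab + 1L, 7), counts_oracle)
})

test_that("entropy matches closed forms and rejects invalid probabilities", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("conditional entropy obeys its closed forms and the chain rule", {
  expect_equal(conditional_entropy(joint_from_counts(diag(2))), 0)
  unif <- joint_from_counts(matrix(1, 2, 2))
  expect_equal(conditional_entropy(unif), 1)

  set.seed(17)
  for (i in 1:50) {
    counts <- matrix(rpois(12, 3), 3, 4)
    counts[1, 1] <- counts[1, 1] + 1 # non-empty
    j <- joint_from_counts(counts)
    chain <- joint_entropy_brute(counts) - entropy_brute(j$p_y)
    expect_equal(conditional_entropy(j), chain, tolerance = 1e-9)
  }
})

test_that("both mutual-information routes agree with the brute-force sum", {
  expect_equal(mutual_information(joint_from_counts(matrix(1, 2, 2))), 0)
  expect_equal(mutual_information(joint_from_counts(diag(2))), 1)

  j <- joint_from_counts(matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(mutual_information(j), mi_brute(matrix(c(2, 1, 1, 2), 2, 2)),
               tolerance = 1e-12)
  expect_equal(mutual_information(j), 0.0817, tolerance = 1e-3)

  set.seed(4)
  for (i in 1:200) {
    counts <- matrix(rpois(9, 2), 3, 3)
    if (sum(counts) == 0) counts[2, 2] <- 1
    j <- joint_from_counts(counts)
    mi1 <- mutual_information(j, "conditional")
    mi2 <- mutual_information(j, "double_sum")
    expect_equal(mi1, mi2, tolerance = 1e-9)
    expect_equal(mi1, mi_brute(counts), tolerance = 1e-9)
    expect_gte(mi1, 0)
  }
})

test_that("NMI is symmetric, bounded, and hits its analytic anchors", {
  set.seed(8)
  xv <- runif(60)
  x <- discretize(xv, make_binning(xv, 5))
  expect_equal(nmi(x, x), 1)
  u <- joint_from_counts(matrix(1, 2, 2))
  expect_equal(2 * mutual_information(u) /
                 (shannon_entropy(u$p_x) + shannon_entropy(u$p_y)), 0)

  for (i in 1:100) {
    a <- runif(40); b <- runif(40)
    da <- discretize(a, make_binning(a, sample(2:8, 1)))
    db <- discretize(b, make_binning(b, sample(2:8, 1)))
    v <- nmi(da, db)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, nmi(db, da))
  }

  # both series constant -> 0 by convention
  const <- structure(list(labels = rep(0L, 10), bin_count = 1L),
                     class = "discrete_series")
  expect_equal(nmi(const, const), 0)
  short <- structure(list(labels = 0L, bin_count = 1L),
                     class = "discrete_series")
  expect_error(nmi(x, short), "lengths differ")
})

test_that("NMI is invariant to per-variable affine transforms", {
  set.seed(13)
  x <- rnorm(80); y <- x + rnorm(80, 0, 0.3)
  B <- 8
  base <- nmi(discretize(x, make_binning(x, B)),
              discretize(y, make_binning(y, B)))
  for (a in c(0.5, 3)) {
    xt <- a * x + 2 # bin edges co-transform, assignments identical
    vt <- nmi(discretize(xt, make_binning(xt, B)),
              discretize(y, make_binning(y, B)))
    expect_equal(vt, base, tolerance = 1e-12)
  }
})

test_that("the NMI profile flags informative columns and survives dead ones", {
  set.seed(19)
  m <- 100
  y <- runif(m)
  X <- cbind(y, matrix(rnorm(m * 3), m, 3), rep(2, m))
  expect_warning(p <- nmi_profile(X, y, 10), "constant spectral column")
  expect_equal(p$nmi[1], 1)
  expect_equal(p$nmi[5], 0)
  # pure-noise columns sit at the finite-sample null level (approx. 0.19
  # for m = 100, B = 10), far below an informative column
  expect_true(all(p$nmi[2:4] < 0.3))
  expect_true(all(p$nmi[2:4] < p$nmi[1] - 0.5))

  # column loop equals the vectorized profile
  direct <- sapply(1:4, function(j) {
    nmi(discretize(X[, j], make_binning(X[, j], 10)),
        discretize(y, make_binning(y, 10)))
  })
  expect_equal(p$nmi[1:4], direct)
})
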
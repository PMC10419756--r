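# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (loops, normal equations,
# textbook NIPALS) so they share no code with the implementation under test.

# OLS coefficients by normal equations on centered data.
ols_predict <- function(X, y, newX) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  drop(sweep(newX, 2, mu) %*% beta) + mean(y)
}

# Textbook NIPALS PLS1 (deflation of X and y), coefficient vector for a LVs.
nipals_beta <- function(X, y, a) {
  mu <- colMeans(X)
  ybar <- mean(y)
  E <- sweep(X, 2, mu)
  f <- y - ybar
  W <- NULL; P <- NULL; q <- c()
  for (i in seq_len(a)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    qi <- sum(f * t) / tt
    E <- E - t %*% t(p)
    f <- f - qi * t
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qi)
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = drop(beta), mu = mu, ybar = ybar)
}

nipals_predict <- function(X, y, a, newX) {
  fit <- nipals_beta(X, y, a)
  drop(sweep(newX, 2, fit$mu) %*% fit$beta) + fit$ybar
}

# Naive LOOCV curve: every fold rebuilt from scratch through NIPALS.
naive_loocv <- function(X, y, max_lv) {
  m <- nrow(X)
  sse <- numeric(max_lv)
  for (k in seq_len(max_lv)) {
    for (i in seq_len(m)) {
      pred <- nipals_predict(X[-i, , drop = FALSE], y[-i], k,
                             X[i, , drop = FALSE])
      sse[k] <- sse[k] + (pred - y[i])^2
    }
  }
  sqrt(sse / m)
}

# Exhaustive-greedy Kennard-Stone written with plain loops.
ks_greedy_oracle <- function(X, n_cal) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  best_pair <- c(1, 2); best_d <- -1
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (D[i, j] > best_d) { best_d <- D[i, j]; best_pair <- c(i, j) }
    }
  }
  sel <- best_pair
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(m), sel)
    scores <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(scores)])
  }
  sort(sel)
}

# Brute-force mutual information in bits from a count table.
mi_brute <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  total
}

entropy_brute <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Joint entropy H(X, Y) from a count table.
joint_entropy_brute <- function(counts) entropy_brute(counts / sum(counts))

# A tiny deterministic dataset: y linear in the first column, the rest noise.
tiny_linear_ds <- function(m = 20, n = 6, seed = 42, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(m * n), m, n)
  y <- 2 * X[, 1] + rnorm(m, 0, noise)
  list(X = X, y = y)
}

# Small synthetic mixture without closure: only target bands carry the
# reference signal, convenient for baseline-selector recovery tests.
open_mixture_spec <- function(seed = 11, n_samples = 40, n_wavelengths = 80,
                              noise_sd = 0.002) {
  synthetic_spec(
    n_wavelengths = n_wavelengths,
    wavelength_range = c(1100, 1700),
    components = list(
      list(list(center = 1450, sigma = 40, amplitude = 1.0)),
      list(list(center = 1210, sigma = 35, amplitude = 0.7)),
      list(list(center = 1650, sigma = 35, amplitude = 0.6))
    ),
    target = 1,
    conc_ranges = list(c(0.1, 0.9), c(0.1, 0.9), c(0.1, 0.9)),
    closure = FALSE,
    noise_sd = noise_sd,
    n_samples = n_samples,
    seed = seed
  )
}

# Role-assigned dataset from a spec, deterministic KS 75/25 split.
make_split_ds <- function(spec, fraction = 0.75) {
  ks_assign(generate_dataset(spec), fraction)
}
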
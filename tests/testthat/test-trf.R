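test_that("the lagged design materializes the convolution", {
  env <- c(1, 2, 3, 4, 5)
  X0 <- lagged_design(env, fs = 1000, lags_ms = c(0, 0))
  expect_equal(X0[, 1], rep(1, 5))
  expect_equal(X0[, 2], env)

  imp <- c(1, 0, 0, 0, 0)
  Xi <- lagged_design(imp, fs = 1000, lags_ms = c(0, 3))
  expect_equal(unname(Xi[, -1]), diag(5)[, 1:4])

  x <- with_seed(1, stats::rnorm(300))
  k <- with_seed(2, stats::rnorm(21))
  X <- lagged_design(x, fs = 1000, lags_ms = c(0, 20))
  direct <- stats::convolve(x, rev(k), type = "open")[1:300]
  expect_equal(drop(X %*% c(0, k)), direct, tolerance = 1e-10)

  expect_error(lagged_design(x, 1000, c(10, 0)), "lag")
})

test_that("ridge solutions match closed forms and shrink", {
  X <- cbind(c(1, 2, 3)); attr(X, "lags_ms") <- 0
  expect_equal(fit_trf(X, c(2, 4, 6), 0, has_intercept = FALSE)$kernel, 2,
               tolerance = 1e-12)
  expect_equal(fit_trf(X, c(2, 4, 6), 14, has_intercept = FALSE)$kernel, 1,
               tolerance = 1e-12)

  Xn <- cbind(1, with_seed(4, matrix(stats::rnorm(200), 50, 4)))
  y <- with_seed(5, stats::rnorm(50))
  ols <- fit_trf(Xn, y, 0)$kernel
  huge <- fit_trf(Xn, y, 1e9)$kernel
  expect_lt(sqrt(sum(huge^2)), 1e-6 * sqrt(sum(ols^2)))

  sing <- cbind(1, 1:4, 1:4)
  expect_error(fit_trf(sing, stats::rnorm(4), 0), "lambda > 0")
})

test_that("fit_trf agrees with an SVD ridge oracle on random problems", {
  svd_ridge <- function(X, y, lambda) {
    # oracle: ridge via the singular-value decomposition, no intercept
    s <- svd(X)
    drop(s$v %*% ((s$d / (s$d^2 + lambda)) * crossprod(s$u, y)))
  }
  worst <- 0
  for (rep in 1:100) {
    n <- with_seed(rep, sample(30:500, 1))
    p <- with_seed(rep + 1000, sample(2:20, 1))
    X <- with_seed(rep + 2000, matrix(stats::rnorm(n * p), n, p))
    y <- with_seed(rep + 3000, stats::rnorm(n))
    lam <- 10^with_seed(rep + 4000, stats::runif(1, -2, 3))
    got <- fit_trf(X, y, lam, has_intercept = FALSE)$kernel
    want <- svd_ridge(X, y, lam)
    worst <- max(worst, max(abs(got - want)) / max(abs(want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("kernel norm is non-increasing in lambda", {
  X <- with_seed(9, matrix(stats::rnorm(400 * 12), 400, 12))
  y <- with_seed(10, stats::rnorm(400))
  norms <- vapply(default_lambda_grid(), function(l) {
    sqrt(sum(fit_trf(X, y, l, has_intercept = FALSE)$kernel^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("prediction scoring is the Fisher-z correlation", {
  X <- lagged_design(with_seed(11, stats::rnorm(500)), 100, c(0, 50))
  k <- with_seed(12, stats::rnorm(6))
  y <- drop(X %*% c(0.5, k))
  m <- structure(list(kernel = k, intercept = 0.5, lambda = 1,
                      lags_ms = attr(X, "lags_ms")), class = "trf_model")
  expect_equal(predict_score(m, X, y)$z, atanh(1 - 1e-12), tolerance = 1e-9)

  ynull <- with_seed(13, stats::rnorm(10000))
  Xn <- lagged_design(with_seed(14, stats::rnorm(10000)), 100, c(0, 0))
  mn <- structure(list(kernel = 1, intercept = 0, lambda = 0,
                       lags_ms = 0), class = "trf_model")
  expect_lt(abs(predict_score(mn, Xn, ynull)$z), 0.03)

  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(predict_score(m, X * 0, y), "constant")
})

test_that("averaging happens on the z scale, not the r scale", {
  rs <- c(0.9, -0.5)
  z_then_mean <- mean(atanh(rs))
  mean_then_z <- atanh(mean(rs))
  expect_false(isTRUE(all.equal(z_then_mean, mean_then_z)))
  # two synthetic test trials with exactly those correlations
  n <- 400
  base <- with_seed(20, stats::rnorm(n))
  mk_resp <- function(r, seed) {
    noise <- with_seed(seed, stats::rnorm(n))
    noise <- stats::resid(stats::lm(noise ~ base))
    r * stats::sd(noise) * base + noise * stats::sd(base) * sqrt(1 - r^2)
  }
  m <- structure(list(kernel = 1, intercept = 0, lambda = 0, lags_ms = 0),
                 class = "trf_model")
  envs <- list(base, base)
  resps <- list(mk_resp(0.9, 21), mk_resp(-0.5, 22))
  got <- score_trials(m, envs, resps, fs = 100, lags_ms = c(0, 0))
  expect_equal(got$z, mean(atanh(vapply(resps, function(y) {
    stats::cor(scale(base)[, 1], y - mean(y))
  }, numeric(1)))), tolerance = 1e-9)
})

test_that("cross-validated training finds signal and rejects noise", {
  fs <- 64
  k <- resample_fft(make_kernels("x", mode = "shared")$x$kernel, 33)
  envs <- lapply(1:8, function(i) {
    e <- abs(one_over_f_noise(320, 1, 300 + i)); e / max(e)
  })
  resps <- lapply(envs, function(e) {
    X <- lagged_design(scale(e)[, 1], fs)
    drop(X %*% c(0, k))
  })
  fit <- suppressWarnings(train_with_cv(envs, resps, fs, selection = "max"))
  expect_gt(fit$z, 3)
  expect_lte(fit$lambda, sort(default_lambda_grid())[9])  # <= grid median

  noise <- lapply(1:50, function(i) with_seed(700 + i, stats::rnorm(320)))
  nfit <- train_with_cv(envs[rep(1:8, length.out = 50)], noise, fs)
  expect_lt(abs(nfit$z), 0.05)

  single <- train_with_cv(envs, resps, fs, lambda_grid = 3.3)
  expect_identical(single$lambda, 3.3)
  expect_error(train_with_cv(envs, resps, fs, lambda_grid = numeric(0)),
               "empty")
})

test_that("cross-encoding builds the labeled grid and flags gaps", {
  fs <- 64
  envs <- lapply(1:6, function(i) {
    e <- abs(one_over_f_noise(320, 1, 40 + i)); e / max(e)
  })
  k <- with_seed(41, stats::rnorm(33) * exp(-(0:32) / 10))
  trials <- list()
  for (lab in c("a", "b")) {
    resps <- lapply(envs, function(e) {
      X <- lagged_design(scale(e)[, 1], fs)
      drop(X %*% c(0, k)) + with_seed(42, stats::rnorm(320, 0, 0.1))
    })
    trials[[lab]] <- list(envelopes = envs, responses = resps)
  }
  cm <- cross_encode(trials, fs)
  expect_identical(dim(cm$values), c(2L, 2L))
  expect_identical(rownames(cm$values), c("a", "b"))
  expect_error(cross_encode(list(list(envelopes = envs)), fs), "named")
  expect_error(cross_encode(list(a = list(envelopes = envs)), fs), "missing")
})

test_that("modulation-band encoding resolves the driving band", {
  fs <- 64
  edges <- modulation_band_edges()
  expect_identical(dim(edges), c(22L, 2L))
  expect_identical(unname(edges[1, ]), c(1, 3))
  expect_identical(unname(edges[22, ]), c(43, 45))

  envs <- lapply(1:10, function(i) {
    e <- abs(one_over_f_noise(640, 0.5, 500 + i)); e / max(e)
  })
  k <- resample_fft(make_kernels("x", mode = "shared")$x$kernel, 33)
  # response driven only by the 4-6 Hz component of the envelope
  resps <- lapply(envs, function(e) {
    fe <- bandpass_envelope(scale(e)[, 1], fs, c(4, 6), order = 2)
    X <- lagged_design(fe, fs)
    drop(X %*% c(0, k)) + with_seed(77, stats::rnorm(640, 0, 0.05))
  })
  small_edges <- cbind(lo = c(1, 3, 5, 7, 9), hi = c(3, 5, 7, 9, 11))
  grid <- modulation_band_encode(
    envs, list(theta = resps), fs, band_edges = small_edges,
    lambda_grid = 10^seq(-1, 4), matched_bands = list(theta = 2:3))
  expect_identical(dim(grid$grid), c(5L, 1L))
  peak <- which.max(grid$grid[, 1])
  expect_true(rownames(grid$grid)[peak] %in% c("3-5", "5-7"))
  expect_error(modulation_band_encode(envs, list(x = resps), fs = 8),
               "Nyquist")
})
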
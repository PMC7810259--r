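# small epochs: trials x channels x samples at 500 Hz, -3..+8 s frame
make_epochs <- function(n_trials = 3, n_channels = 4, fill = 0,
                        span = c(-2, 6)) {
  ns <- round((span[2] - span[1]) * 500)
  eeg_epochs(array(fill, dim = c(n_trials, n_channels, ns)), fs = 500,
             t0 = -span[1])
}

test_that("preprocessing removes DC, attenuates 60 Hz and baselines exactly", {
  ep <- make_epochs()
  t <- (seq_len(dim(ep$data)[3]) - 1) / 500 - 2
  for (i in 1:3) for (j in 1:4) {
    ep$data[i, j, ] <- 7 + sin(2 * pi * 60 * t) * (j == 1) +
      with_seed(i * 10 + j, stats::rnorm(length(t)))
  }
  pp <- preprocess_eeg(ep, average_reference = FALSE)
  bsel <- t >= -1 & t < 0
  for (i in 1:3) for (j in 1:4) {
    expect_lt(abs(mean(pp$data[i, j, bsel])), 1e-10)
  }
  # 60-Hz attenuation on a pure sinusoid epoch
  ep60 <- make_epochs(1, 1)
  ep60$data[1, 1, ] <- sin(2 * pi * 60 * t)
  pp60 <- preprocess_eeg(ep60, average_reference = FALSE)
  mid <- t > 0 & t < 4
  atten_db <- 10 * log10(mean(ep60$data[1, 1, mid]^2) /
                           mean(pp60$data[1, 1, mid]^2))
  expect_gt(atten_db, 20)
})

test_that("trials with non-finite samples are dropped", {
  ep <- make_epochs(3, 2, fill = 1)
  ep$data[2, 1, 5] <- NaN
  expect_message(pp <- preprocess_eeg(ep), "dropping 1")
  expect_equal(dim(pp$data)[1], 2)
})

test_that("the spatial filter finds single-channel sources and normalizes", {
  ep <- make_epochs(4, 5)
  t <- (seq_len(dim(ep$data)[3]) - 1) / 500 - 2
  bump <- exp(-(t - 0.25)^2 / (2 * 0.05^2))
  for (i in 1:4) ep$data[i, 3, ] <- bump
  filt <- fit_spatial_filter(ep)
  expect_equal(abs(filt$weights), c(0, 0, 1, 0, 0), tolerance = 1e-8)
  expect_equal(sum(filt$weights^2), 1, tolerance = 1e-12)
  expect_gt(filt$explained_variance_fraction, 0.99)
  # polarity flips project to a positive 150-350 ms mean
  comp <- apply_spatial_filter(ep, filt)
  sel <- t >= 0.15 & t <= 0.35
  expect_gt(mean(comp$data[1, sel]), 0)

  flat <- make_epochs(2, 3)
  expect_error(fit_spatial_filter(flat), "rank-deficient")
})

test_that("spatial projection is the weighted channel sum", {
  ep <- make_epochs(2, 3)
  for (i in 1:2) for (j in 1:3) {
    ep$data[i, j, ] <- with_seed(i * 7 + j, stats::rnorm(dim(ep$data)[3]))
  }
  onehot <- structure(list(weights = c(0, 1, 0), polarity = 1,
                           explained_variance_fraction = 1),
                      class = "spatial_filter")
  comp <- apply_spatial_filter(ep, onehot)
  expect_equal(comp$data[1, ], ep$data[1, 2, ], tolerance = 1e-12)
  onehot$polarity <- -1
  expect_equal(apply_spatial_filter(ep, onehot)$data[2, ],
               -ep$data[2, 2, ], tolerance = 1e-12)
  bad <- structure(list(weights = c(1, 0), polarity = 1),
                   class = "spatial_filter")
  expect_error(apply_spatial_filter(ep, bad), "channel")
})

test_that("projection beats the best single channel for a distributed source", {
  cfg <- simulation_config(n_channels = 12, n_trials = 6,
                           epoch_span = c(-1.5, 6))
  envs <- lapply(1:6, function(i) {
    e <- abs(one_over_f_noise(2500, 1.5, 600 + i)); e / max(e)
  })
  ks <- make_kernels("x", mode = "shared")
  topo <- make_topography(12)
  ep <- simulate_eeg(envs, ks, topo, cfg, trial_labels = rep("x", 6),
                     seed = 61)
  pp <- preprocess_eeg(ep)
  comp <- apply_spatial_filter(pp, fit_spatial_filter(pp))
  # ground-truth component of trial 1
  truth <- drop(topo %*% ep$data[1, , ])
  r_proj <- abs(stats::cor(comp$data[1, ], truth))
  r_best <- max(abs(apply(pp$data[1, , ], 1, stats::cor, y = truth)))
  expect_gte(r_proj, r_best)
})

test_that("band decomposition is selective, zero-phase and linear", {
  comp <- structure(list(data = matrix(0, 1, 2500), fs = 500, t0 = 1,
                         trial_meta = NULL), class = "component_signal")
  t <- (0:2499) / 500
  comp$data[1, ] <- sin(2 * pi * 5 * t)
  bd <- band_decompose(comp, neural_bands()[c("theta", "alpha")])
  mid <- 500:2000
  expect_gt(stats::var(bd$theta$data[1, mid]) /
              stats::var(comp$data[1, mid]), 0.9)
  expect_lt(stats::var(bd$alpha$data[1, mid]) /
              stats::var(comp$data[1, mid]), 0.1)

  zero <- comp; zero$data[] <- 0
  expect_identical(max(abs(band_decompose(zero)$full$data)), 0)

  # broadband pulse: zero-phase filtering leaves the peak at zero lag
  pulse <- comp; pulse$data[] <- 0; pulse$data[1, 1250] <- 1
  bp <- band_decompose(pulse, list(wide = c(1, 45)))$wide
  xc <- stats::ccf(drop(bp$data), drop(pulse$data), lag.max = 20,
                   plot = FALSE)
  expect_equal(xc$lag[which.max(abs(xc$acf))], 0)

  expect_error(band_decompose(comp, list(bad = c(0, 5))), "invalid")

  # spatial filtering and band filtering commute (both linear); checked in
  # the beta band, where the recursive filter arithmetic is well conditioned
  ep <- make_epochs(2, 3)
  for (i in 1:2) for (j in 1:3) {
    ep$data[i, j, ] <- with_seed(i + 10 * j, stats::rnorm(dim(ep$data)[3]))
  }
  filt <- structure(list(weights = c(0.6, 0.64, 0.48), polarity = 1),
                    class = "spatial_filter")
  a <- band_decompose(apply_spatial_filter(ep, filt),
                      list(beta = c(13, 30)))$beta$data
  epb <- ep
  for (i in 1:2) for (j in 1:3) {
    epb$data[i, j, ] <- bandpass_envelope(ep$data[i, j, ], 500, c(13, 30),
                                          order = 4)
  }
  b <- apply_spatial_filter(epb, filt)$data
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("evoked responses average, baseline and shrink with n", {
  ep <- make_epochs(3, 1)
  t <- (seq_len(dim(ep$data)[3]) - 1) / 500 - 2
  shape <- exp(-(t - 0.2)^2 / (2 * 0.04^2))
  for (i in 1:3) ep$data[i, 1, ] <- shape + 0.3
  comp <- structure(list(data = ep$data[, 1, ], fs = 500, t0 = 2,
                         trial_meta = NULL), class = "component_signal")
  ev <- evoked_response(comp, "onset")
  sel <- t >= -0.2 & t <= 0.5 + 1e-9
  base <- mean(shape[t >= -0.2 & t < 0])
  expect_equal(ev$response, shape[sel] - base, tolerance = 1e-9)
  expect_equal(ev$times[which.max(ev$response)], 0.2, tolerance = 0.002)

  short <- structure(list(data = matrix(0, 2, 100), fs = 500, t0 = 0.1,
                          trial_meta = NULL), class = "component_signal")
  expect_error(evoked_response(short, "offset"), "short")

  # averaging law: max |noise evoked| shrinks roughly as 1/sqrt(n)
  noise <- with_seed(77, matrix(stats::rnorm(1000 * 400), 1000, 400))
  nc <- function(n) {
    cs <- structure(list(data = noise[1:n, ], fs = 500, t0 = 0.3,
                         trial_meta = NULL), class = "component_signal")
    max(abs(evoked_response(cs, "onset", duration = 0.2,
                            window = c(-0.2, 0.4))$response))
  }
  ratio <- nc(250) / nc(1000)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("induced power normalizes to baseline and localizes bursts", {
  ns <- 500 * 7
  t <- (0:(ns - 1)) / 500 - 2
  comp <- structure(list(data = matrix(0, 2, ns), fs = 500, t0 = 2,
                         trial_meta = NULL), class = "component_signal")
  # stationary 10-Hz sinusoid: ~0 dB everywhere at 10 Hz
  for (i in 1:2) comp$data[i, ] <- sin(2 * pi * 10 * t)
  ip <- induced_power(comp, freqs = seq(2, 20, 2))
  mid <- ip$times > 0.5 & ip$times < 4
  expect_lt(abs(mean(ip$spectrogram[ip$freqs == 10, mid])), 0.1)
  # baseline normalization identity on the power scale
  bsel <- ip$times >= -1 & ip$times <= -0.75
  expect_equal(rowMeans(10^(ip$spectrogram[, bsel] / 10)),
               rep(1, length(ip$freqs)), tolerance = 1e-9)

  # burst only after onset: positive dB with the peak at the burst frequency
  burst <- comp
  for (i in 1:2) {
    burst$data[i, ] <- 0.05 * with_seed(i, stats::rnorm(ns)) +
      sin(2 * pi * 10 * t) * (t > 0 & t < 4.6)
  }
  ipb <- induced_power(burst, freqs = seq(2, 20, 2))
  expect_gt(mean(ipb$spectrogram[ipb$freqs == 10, mid]), 6)
  expect_equal(ipb$freqs[which.max(ipb$power_spectrum)], 10)

  # amplitude doubling after onset: +6.02 dB at the carrier frequency
  dbl <- comp
  for (i in 1:2) dbl$data[i, ] <- sin(2 * pi * 10 * t) * (1 + (t > 0))
  ipd <- induced_power(dbl, freqs = seq(2, 20, 2))
  expect_equal(mean(ipd$spectrogram[ipd$freqs == 10,
                                    ipd$times > 0.5 & ipd$times < 4.5]),
               20 * log10(2), tolerance = 0.2)

  shallow <- structure(list(data = matrix(0, 1, 200), fs = 500, t0 = 0.1,
                            trial_meta = NULL), class = "component_signal")
  expect_error(induced_power(shallow), "cover")
})
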
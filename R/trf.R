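#' Lagged design matrix for TRF estimation
#'
#' Row `t` holds the stimulus envelope at `t - lag` for each lag (zero
#' padded outside the trial; trials are never concatenated), with a leading
#' intercept column. Multiplying by a kernel reproduces the causal
#' convolution of the envelope with that kernel.
#'
#' @param envelope Numeric envelope already at the response sampling rate.
#' @param fs Sampling rate in Hz.
#' @param lags_ms Lag window in ms (default `c(0, 500)`); lags are every
#'   sample in the window.
#' @return Matrix (time x (1 + n_lags)) with attributes `lags_ms` (the lag
#'   grid) and `fs`.
#' @export
lagged_design <- function(envelope, fs, lags_ms = c(0, 500)) {
  lag_lo <- round(lags_ms[1] / 1000 * fs)
  lag_hi <- round(lags_ms[2] / 1000 * fs)
  if (lag_lo > lag_hi) stop("invalid lag window")
  lags <- lag_lo:lag_hi
  n <- length(envelope)
  X <- matrix(0, n, length(lags) + 1)
  X[, 1] <- 1
  for (j in seq_along(lags)) {
    L <- lags[j]
    if (L >= 0) {
      if (L < n) X[(L + 1):n, j + 1] <- envelope[1:(n - L)]
    } else {
      if (-L < n) X[1:(n + L), j + 1] <- envelope[(1 - L):n]
    }
  }
  attr(X, "lags_ms") <- lags / fs * 1000
  attr(X, "fs") <- fs
  X
}

ridge_penalty <- function(p) {
  M <- diag(p)
  M[1, 1] <- 0  # intercept unpenalized
  M
}

#' Fit a temporal response function by ridge regression
#'
#' Solves `(X'X + lambda M) k = X'y` where `X` is the lagged design, `y`
#' the neural response, and `M` the identity with a zero in the intercept
#' position, so the intercept is unpenalized.
#'
#' @param design Lagged design matrix from [lagged_design()] (or any
#'   matrix whose first column is the intercept).
#' @param response Numeric response aligned with the design rows.
#' @param lambda Ridge parameter `>= 0`.
#' @param has_intercept Whether column 1 is an unpenalized intercept
#'   (default TRUE).
#' @return A `trf_model`: `kernel` (per lag), `intercept`, `lambda`,
#'   `lags_ms`.
#' @export
fit_trf <- function(design, response, lambda, has_intercept = TRUE) {
  stopifnot(nrow(design) == length(response), lambda >= 0)
  p <- ncol(design)
  M <- if (has_intercept) ridge_penalty(p) else diag(p)
  A <- crossprod(design) + lambda * M
  b <- crossprod(design, response)
  beta <- tryCatch(drop(solve(A, b)), error = function(e) {
    stop("singular normal equations; use lambda > 0")
  })
  lags <- attr(design, "lags_ms")
  if (has_intercept) {
    structure(list(kernel = beta[-1], intercept = beta[1], lambda = lambda,
                   lags_ms = lags), class = "trf_model")
  } else {
    structure(list(kernel = beta, intercept = 0, lambda = lambda,
                   lags_ms = lags), class = "trf_model")
  }
}

#' Predict a response from a TRF and score it
#'
#' Prediction is `design %*% c(intercept, kernel)`; the score is the
#' Fisher z-transformed Pearson correlation between prediction and
#' observation.
#'
#' @param model A `trf_model`.
#' @param design Lagged design matrix of the test envelope.
#' @param response Observed response.
#' @return An `encoding_result`: `z`, `r`, `lambda_used`.
#' @export
predict_score <- function(model, design, response) {
  stopifnot(inherits(model, "trf_model"))
  pred <- drop(design %*% c(model$intercept, model$kernel))
  if (stats::sd(pred) == 0 || stats::sd(response) == 0) {
    stop("constant predicted or observed series; correlation undefined")
  }
  r <- stats::cor(pred, response)
  structure(list(z = fisher_z(r, warn = FALSE), r = r,
                 lambda_used = model$lambda),
            class = "encoding_result")
}

standardize_trial <- function(env, resp) {
  s <- stats::sd(env)
  env <- if (s > 0) (env - mean(env)) / s else env - mean(env)
  resp <- resp - mean(resp)
  list(env = env, resp = resp)
}

# center non-intercept columns so per-trial centering commutes with the
# linear model (zero-padded design edges otherwise leave per-trial offsets
# a single global intercept cannot absorb)
center_design <- function(X) {
  at <- attributes(X)
  X[, -1] <- sweep(X[, -1, drop = FALSE], 2,
                   colMeans(X[, -1, drop = FALSE]))
  attr(X, "lags_ms") <- at$lags_ms
  attr(X, "fs") <- at$fs
  X
}

#' Default ridge-parameter grid
#' @return Log-spaced grid `10^-2 .. 10^6` (17 points).
#' @export
default_lambda_grid <- function() 10^seq(-2, 6, length.out = 17)

#' Train a TRF with cross-validated ridge-parameter selection
#'
#' Envelopes are z-scored and responses centered per trial, the lagged
#' designs and their Gram matrices are precomputed, and for every lambda
#' in the grid the model is fitted on the training folds and scored
#' (Fisher z of the Pearson correlation) on the held-out fold:
#' leave-one-out over trials (the convention for the 60-trial AM types) or
#' 10-fold over segments (the convention for continuous speech). The
#' optimal lambda maximizes the mean held-out z; the returned model is
#' refitted on all trials at that lambda and the reported performance is
#' the held-out mean z.
#'
#' @param envelopes List of per-trial envelopes at the response rate.
#' @param responses List of per-trial responses (same lengths).
#' @param fs Sampling rate in Hz.
#' @param lambda_grid Candidate ridge parameters (default
#'   [default_lambda_grid()]).
#' @param scheme `"loo"` or `"kfold10"`.
#' @param lags_ms Lag window in ms (default `c(0, 500)`).
#' @param drop_initial_s Initial portion of every trial (in s) excluded
#'   from fitting and scoring (default 0). Design rows in the excluded
#'   window are removed after the lagged design is built, so kept rows
#'   still see the true stimulus history. Used to keep onset-evoked
#'   transients, which the stationary envelope kernel cannot explain, out
#'   of the regression.
#' @param selection `"max_1se"` (default) maximizes the held-out mean z but
#'   breaks plateau ties toward stronger regularization: among lambdas
#'   whose mean z lies within one standard error of the maximum, the
#'   largest lambda is chosen. A lambda ties with the maximum when its
#'   mean deficit is within one standard error of the paired fold-wise
#'   difference (fold scores are strongly correlated across lambdas, so
#'   the paired SE is the right yardstick) or below 0.01 z, a region of
#'   practical equivalence for prediction scores. The cross-validation
#'   curve is typically flat over several decades, where the prediction
#'   score cannot distinguish models but weakly regularized kernels are
#'   noisy. `"max"` takes the literal argmax.
#' @return List with `model` (refit at the optimal lambda), `z` (held-out
#'   mean), `per_fold_z`, `lambda`, `scheme`, `n_trials`.
#' @export
train_with_cv <- function(envelopes, responses, fs,
                          lambda_grid = default_lambda_grid(),
                          scheme = c("loo", "kfold10"),
                          lags_ms = c(0, 500),
                          drop_initial_s = 0,
                          selection = c("max_1se", "max")) {
  scheme <- match.arg(scheme)
  selection <- match.arg(selection)
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  n <- length(envelopes)
  stopifnot(n >= 2, length(responses) == n)
  prep <- precompute_trials(envelopes, responses, fs, lags_ms, drop_initial_s)
  folds <- if (scheme == "loo") as.list(seq_len(n)) else {
    split(seq_len(n), cut(seq_len(n), breaks = min(10, n), labels = FALSE))
  }
  p <- ncol(prep$X[[1]])
  M <- ridge_penalty(p)
  G_tot <- Reduce(`+`, prep$G)
  c_tot <- Reduce(`+`, prep$c)
  mean_z <- numeric(length(lambda_grid))
  fold_z <- matrix(NA_real_, length(lambda_grid), length(folds))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    for (fi in seq_along(folds)) {
      held <- folds[[fi]]
      G_tr <- G_tot - Reduce(`+`, prep$G[held])
      c_tr <- c_tot - Reduce(`+`, prep$c[held])
      beta <- drop(solve(G_tr + lam * M, c_tr))
      zs <- vapply(held, function(i) {
        pred <- drop(prep$X[[i]] %*% beta)
        if (stats::sd(pred) == 0) return(NA_real_)
        fisher_z(stats::cor(pred, prep$y[[i]]), warn = FALSE)
      }, numeric(1))
      fold_z[li, fi] <- mean(zs, na.rm = TRUE)
    }
    mean_z[li] <- mean(fold_z[li, ])
  }
  best <- which.max(mean_z)
  if (selection == "max_1se" && length(folds) >= 2) {
    eligible <- vapply(seq_along(lambda_grid), function(li) {
      d <- fold_z[best, ] - fold_z[li, ]
      mean(d) <= max(stats::sd(d) / sqrt(length(folds)), 0.01) + 1e-12
    }, logical(1))
    best <- which(eligible)[which.max(lambda_grid[eligible])]
  }
  lam <- lambda_grid[best]
  beta <- drop(solve(G_tot + lam * M, c_tot))
  model <- structure(list(kernel = beta[-1], intercept = beta[1],
                          lambda = lam, lags_ms = prep$lags_ms),
                     class = "trf_model")
  list(model = model, z = mean_z[best], per_fold_z = fold_z[best, ],
       lambda = lam, scheme = scheme, n_trials = n,
       grid_z = stats::setNames(mean_z, signif(lambda_grid, 3)))
}

precompute_trials <- function(envelopes, responses, fs, lags_ms,
                              drop_initial_s = 0) {
  X <- vector("list", length(envelopes))
  y <- vector("list", length(envelopes))
  G <- vector("list", length(envelopes))
  cc <- vector("list", length(envelopes))
  drop_n <- round(drop_initial_s * fs)
  for (i in seq_along(envelopes)) {
    st <- standardize_trial(as.numeric(envelopes[[i]]),
                            as.numeric(responses[[i]]))
    Xi <- lagged_design(st$env, fs, lags_ms)
    yi <- st$resp
    if (drop_n > 0) {
      keep <- (drop_n + 1):nrow(Xi)
      at <- attributes(Xi)
      Xi <- Xi[keep, , drop = FALSE]
      attr(Xi, "lags_ms") <- at$lags_ms
      attr(Xi, "fs") <- at$fs
      yi <- yi[keep]
    }
    Xi <- center_design(Xi)
    yi <- yi - mean(yi)
    X[[i]] <- Xi
    y[[i]] <- yi
    G[[i]] <- crossprod(Xi)
    cc[[i]] <- crossprod(Xi, yi)
  }
  list(X = X, y = y, G = G, c = cc, lags_ms = attr(X[[1]], "lags_ms"))
}

#' Score a fitted TRF on a set of test trials
#'
#' Applies the model (with its training lambda; no re-selection on test
#' data) to each test trial and averages the Fisher-z scores.
#'
#' @param model A `trf_model`.
#' @param envelopes,responses Test trials.
#' @param fs Sampling rate in Hz.
#' @param lags_ms Lag window (must match the model's).
#' @param drop_initial_s Initial trial portion excluded from scoring.
#' @return List with `z` (mean over trials) and `per_trial_z`.
#' @export
score_trials <- function(model, envelopes, responses, fs,
                         lags_ms = c(0, 500), drop_initial_s = 0) {
  drop_n <- round(drop_initial_s * fs)
  zs <- vapply(seq_along(envelopes), function(i) {
    st <- standardize_trial(as.numeric(envelopes[[i]]),
                            as.numeric(responses[[i]]))
    X <- lagged_design(st$env, fs, lags_ms)
    yi <- st$resp
    if (drop_n > 0) {
      keep <- (drop_n + 1):nrow(X)
      at <- attributes(X)
      X <- X[keep, , drop = FALSE]
      attr(X, "lags_ms") <- at$lags_ms
      yi <- yi[keep]
    }
    X <- center_design(X)
    predict_score(model, X, yi - mean(yi))$z
  }, numeric(1))
  list(z = mean(zs), per_trial_z = zs)
}

#' Cross-encoding matrix between stimulus classes
#'
#' Trains (or accepts) one TRF per class and scores every model on every
#' class's trials. Off-diagonal cells are the mean Fisher-z prediction
#' accuracy of one class's TRF applied to another class's trials; diagonal
#' cells are the class's own held-out (cross-validated) performance, the
#' upper bound for transfer.
#'
#' @param trials Named list (one entry per class) of lists with elements
#'   `envelopes` and `responses`.
#' @param fs Sampling rate in Hz.
#' @param lambda_grid Ridge grid for the per-class training.
#' @param scheme CV scheme for the diagonal (default `"loo"`).
#' @param lags_ms Lag window in ms.
#' @return A `cross_encoding_matrix`: `values` (train x test z matrix),
#'   `labels`, `models`, `cv` (per-class training results).
#' @export
cross_encode <- function(trials, fs, lambda_grid = default_lambda_grid(),
                         scheme = "loo", lags_ms = c(0, 500),
                         drop_initial_s = 0) {
  labels <- names(trials)
  if (is.null(labels) || any(labels == "")) stop("trials must be a named list")
  for (lb in labels) {
    if (is.null(trials[[lb]]$envelopes) || is.null(trials[[lb]]$responses)) {
      stop("missing envelopes/responses for class ", lb)
    }
  }
  cv <- lapply(trials, function(tr) {
    train_with_cv(tr$envelopes, tr$responses, fs, lambda_grid,
                  scheme = scheme, lags_ms = lags_ms,
                  drop_initial_s = drop_initial_s)
  })
  k <- length(labels)
  values <- matrix(NA_real_, k, k, dimnames = list(train = labels,
                                                   test = labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      values[i, j] <- if (i == j) cv[[i]]$z else {
        score_trials(cv[[i]]$model, trials[[j]]$envelopes,
                     trials[[j]]$responses, fs, lags_ms, drop_initial_s)$z
      }
    }
  }
  structure(list(values = values, labels = labels,
                 models = lapply(cv, `[[`, "model"), cv = cv),
            class = "cross_encoding_matrix")
}

#' Modulation-band edges, 1-45 Hz in 2-Hz steps
#' @return Matrix with columns `lo`, `hi` (22 bands).
#' @export
modulation_band_edges <- function() {
  lo <- seq(1, 43, by = 2)
  cbind(lo = lo, hi = lo + 2)
}

#' Neural-band by modulation-band resolved encoding
#'
#' Filters the stimulus envelopes into narrow modulation bands (2-Hz
#' steps, two-pass Butterworth of order 2) and repeats cross-validated TRF
#' training for every (modulation band x neural band) combination. Neural
#' bands are supplied as pre-filtered response sets (e.g. from
#' [band_decompose()]). Cells whose filtered envelope is degenerate
#' (zero variance) are returned as NA with a warning.
#'
#' @param envelopes List of per-trial envelopes at the working rate.
#' @param responses_by_band Named list (per neural band) of per-trial
#'   response lists.
#' @param fs Sampling rate in Hz.
#' @param band_edges Modulation-band edges (default
#'   [modulation_band_edges()]).
#' @param lambda_grid,scheme,lags_ms Passed to [train_with_cv()].
#' @param matched_bands Optional named list mapping each neural band to the
#'   modulation-band rows to average for the matched-band summary (default:
#'   modulation bands overlapping the neural band's passband).
#' @param neural_passbands Passbands of the neural bands (default
#'   [neural_bands()]), used for the matched-band summary.
#' @return List with `grid` (modulation bands x neural bands, mean held-out
#'   z), `band_edges`, and `matched` (per neural band, the mean over its
#'   matched modulation bands).
#' @export
modulation_band_encode <- function(envelopes, responses_by_band, fs,
                                   band_edges = modulation_band_edges(),
                                   lambda_grid = default_lambda_grid(),
                                   scheme = "loo", lags_ms = c(0, 500),
                                   matched_bands = NULL,
                                   neural_passbands = neural_bands()) {
  if (any(band_edges >= fs / 2)) stop("modulation band above the envelope Nyquist")
  nb <- nrow(band_edges)
  bands <- names(responses_by_band)
  grid <- matrix(NA_real_, nb, length(bands),
                 dimnames = list(paste0(band_edges[, 1], "-", band_edges[, 2]),
                                 bands))
  filt_envs <- vector("list", nb)
  for (m in seq_len(nb)) {
    fe <- lapply(envelopes, bandpass_envelope, fs = fs,
                 passband = band_edges[m, ], order = 2)
    if (any(vapply(fe, stats::sd, numeric(1)) == 0)) {
      warning("degenerate filtered envelope in band ",
              rownames(grid)[m], "; cell marked missing")
      next
    }
    filt_envs[[m]] <- fe
  }
  for (m in seq_len(nb)) {
    if (is.null(filt_envs[[m]])) next
    for (b in seq_along(bands)) {
      grid[m, b] <- train_with_cv(filt_envs[[m]], responses_by_band[[b]],
                                  fs, lambda_grid, scheme = scheme,
                                  lags_ms = lags_ms)$z
    }
  }
  centers <- rowMeans(band_edges)
  if (is.null(matched_bands)) {
    matched_bands <- lapply(neural_passbands[bands[bands %in% names(neural_passbands)]],
                            function(pb) {
                              which(band_edges[, 2] > pb[1] & band_edges[, 1] < pb[2])
                            })
  }
  matched <- vapply(names(matched_bands), function(nm) {
    mean(grid[matched_bands[[nm]], nm], na.rm = TRUE)
  }, numeric(1))
  list(grid = grid, band_edges = band_edges, band_centers = centers,
       matched = matched)
}
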
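#' Derive reproducible child seeds from a master seed
#'
#' Draws `n` distinct integer seeds from a master seed so that every
#' randomized component of a pipeline run is a pure function of one number.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed), n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(2147483645L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run an expression with a local RNG state
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal (positive-frequency content doubled,
#' negative frequencies zeroed); its modulus is the Hilbert envelope.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Fisher z-transform of a correlation, clipped away from |r| = 1
#'
#' @param r Correlation value(s).
#' @param clip Clip bound on |r| (default `1 - 1e-12`).
#' @param warn Warn when clipping occurs.
#' @return `atanh` of the clipped correlation.
#' @export
fisher_z <- function(r, clip = 1 - 1e-12, warn = TRUE) {
  out_of_range <- abs(r) > clip
  if (any(out_of_range, na.rm = TRUE) && warn) {
    warning("correlation at |r| ~ 1 clipped before Fisher z-transform")
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' Resample a band-limited signal by Fourier truncation
#'
#' Exact for signals whose content lies below the new Nyquist frequency;
#' used to bring acoustic envelopes and EEG component signals onto a common
#' working rate before TRF estimation.
#'
#' @param x Numeric vector.
#' @param n_new New length (same duration, new rate `n_new / n * fs`).
#' @return Numeric vector of length `n_new`.
#' @export
resample_fft <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  stopifnot(n_new >= 2)
  X <- stats::fft(x)
  keep <- floor(min(n, n_new) / 2)
  Y <- complex(real = numeric(n_new), imaginary = numeric(n_new))
  Y[1] <- X[1]
  if (keep >= 2) {
    Y[2:keep] <- X[2:keep]
    Y[(n_new - keep + 2):n_new] <- X[(n - keep + 2):n]
  }
  # split the shared Nyquist-edge bin symmetrically to keep the result real
  if (n_new < n && n_new %% 2 == 0) {
    Y[keep + 1] <- Re(X[keep + 1])
  } else if (n_new > n && n %% 2 == 0) {
    Y[keep + 1] <- X[keep + 1] / 2
    Y[n_new - keep + 1] <- Conj(X[keep + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * (n_new / n) / n_new
}

#' Hann taper of a given length
#' @param n Length.
#' @return Numeric vector.
#' @keywords internal
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' One-sided magnitude spectrum of a single envelope
#'
#' Demeans, applies a Hann taper, and returns `|FFT|` at nonnegative
#' frequencies. The taper suppresses leakage from strong low-frequency
#' modulation content that otherwise biases the high-frequency tail.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param taper `"hann"` (default) or `"none"`.
#' @return List with `frequencies` and `amplitudes`.
#' @export
magnitude_spectrum <- function(x, fs, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  amp <- Mod(stats::fft((x - mean(x)) * w))[1:(floor(n / 2) + 1)]
  list(frequencies = (0:floor(n / 2)) * fs / n, amplitudes = amp)
}
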
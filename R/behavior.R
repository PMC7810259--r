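#' Tone-detection sensitivity (d-prime) from yes/no responses
#'
#' Builds the two-by-two confusion table for one AM type (tone-present
#' trials are targets, tone-absent trials noise) and computes
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. If the table is
#' perfect (no misses and no false alarms) half an artificial incorrect
#' trial is added to the miss cell and to the false-alarm cell before the
#' rates are formed; a rate of exactly 0 or 1 after this correction is an
#' error.
#'
#' @param responses Data frame with logical columns `tone_present` and
#'   `reported_tone` (one row per trial of a single AM type), or the four
#'   counts via `hits`, `misses`, `false_alarms`, `correct_rejections`.
#' @param am_type Optional label carried into the result.
#' @param hits,misses,false_alarms,correct_rejections Alternative count
#'   interface (used when `responses` is missing).
#' @return A `dprime_result`: list with the (possibly half-integer) counts
#'   and `dprime`.
#' @export
dprime_from_responses <- function(responses = NULL, am_type = NA_character_,
                                  hits = NULL, misses = NULL,
                                  false_alarms = NULL,
                                  correct_rejections = NULL) {
  if (!is.null(responses)) {
    stopifnot(all(c("tone_present", "reported_tone") %in% names(responses)))
    tp <- as.logical(responses$tone_present)
    rp <- as.logical(responses$reported_tone)
    hits <- sum(tp & rp)
    misses <- sum(tp & !rp)
    false_alarms <- sum(!tp & rp)
    correct_rejections <- sum(!tp & !rp)
  }
  if (hits + misses < 1 || false_alarms + correct_rejections < 1) {
    stop("need at least one target and one noise trial")
  }
  if (misses == 0 && false_alarms == 0) {
    misses <- misses + 0.5
    hits <- hits - 0.5
    false_alarms <- false_alarms + 0.5
    correct_rejections <- correct_rejections - 0.5
  }
  hit_rate <- hits / (hits + misses)
  fa_rate <- false_alarms / (false_alarms + correct_rejections)
  if (hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)) {
    stop("hit or false-alarm rate of exactly 0 or 1; d-prime undefined")
  }
  structure(list(am_type = am_type, hits = hits, misses = misses,
                 false_alarms = false_alarms,
                 correct_rejections = correct_rejections,
                 hit_rate = hit_rate, fa_rate = fa_rate,
                 dprime = stats::qnorm(hit_rate) - stats::qnorm(fa_rate)),
            class = "dprime_result")
}

#' d-prime table for a multi-participant trial table
#'
#' @param trials Data frame with columns `participant_id`, `am_type`,
#'   `tone_present`, `reported_tone`.
#' @param on_boundary What to do with a participant-by-type cell whose hit
#'   or false-alarm rate sits exactly on 0 or 1 without qualifying for the
#'   perfect-table correction: `"error"` (default) or `"drop"` (cell
#'   excluded with a warning).
#' @return Data frame with one row per participant x am_type and columns
#'   `participant_id`, `am_type`, `dprime`.
#' @export
dprime_table <- function(trials, on_boundary = c("error", "drop")) {
  on_boundary <- match.arg(on_boundary)
  stopifnot(all(c("participant_id", "am_type", "tone_present",
                  "reported_tone") %in% names(trials)))
  rows <- lapply(split(trials, list(trials$participant_id, trials$am_type),
                       drop = TRUE), function(d) {
    dp <- if (on_boundary == "drop") {
      tryCatch(dprime_from_responses(d, am_type = d$am_type[1])$dprime,
               error = function(e) NA_real_)
    } else {
      dprime_from_responses(d, am_type = d$am_type[1])$dprime
    }
    data.frame(participant_id = d$participant_id[1], am_type = d$am_type[1],
               dprime = dp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$dprime)) {
    warning(sum(is.na(out$dprime)),
            " cell(s) with boundary rates dropped from the d-prime table")
    out <- out[!is.na(out$dprime), , drop = FALSE]
  }
  out
}

#' Correlation between d-prime and local SNR across AM types, per window
#'
#' For each participant and window size, computes the Pearson correlation
#' across AM types between the participant's d-prime values and the
#' type-mean local SNR at that window size, Fisher z-transforms the
#' correlations, and averages the z values across participants
#' (z-before-mean).
#'
#' @param dprimes Matrix participants x AM types of d-prime values
#'   (dimnames optional but columns must align with `snr`'s rows), or the
#'   data frame from [dprime_table()].
#' @param snr Matrix AM types x window sizes of mean local SNR in dB
#'   (e.g. the per-type mean over probed stimuli), with colnames the
#'   window sizes in ms.
#' @return List with `window_ms`, `mean_z` (across participants), `se_z`,
#'   and the per-participant `z` matrix (participants x windows).
#' @export
snr_behavior_correlation <- function(dprimes, snr) {
  if (is.data.frame(dprimes)) {
    types <- rownames(snr)
    if (is.null(types)) types <- sort(unique(dprimes$am_type))
    parts <- unique(dprimes$participant_id)
    m <- matrix(NA_real_, length(parts), length(types),
                dimnames = list(parts, types))
    for (i in seq_len(nrow(dprimes))) {
      m[as.character(dprimes$participant_id[i]), dprimes$am_type[i]] <-
        dprimes$dprime[i]
    }
    dprimes <- m
  }
  if (!is.null(rownames(snr)) && !is.null(colnames(dprimes))) {
    snr <- snr[colnames(dprimes), , drop = FALSE]
  }
  stopifnot(ncol(dprimes) == nrow(snr))
  if (anyNA(dprimes)) {
    keep <- stats::complete.cases(dprimes)
    warning(sum(!keep), " participant(s) with incomplete d-prime cells dropped")
    dprimes <- dprimes[keep, , drop = FALSE]
  }
  if (any(apply(dprimes, 1, stats::sd) == 0) || any(apply(snr, 2, stats::sd) == 0)) {
    stop("zero variance across AM types on one side of the correlation")
  }
  z <- matrix(NA_real_, nrow(dprimes), ncol(snr))
  for (p in seq_len(nrow(dprimes))) {
    for (w in seq_len(ncol(snr))) {
      z[p, w] <- fisher_z(stats::cor(dprimes[p, ], snr[, w]), warn = FALSE)
    }
  }
  window_ms <- suppressWarnings(as.numeric(colnames(snr)))
  if (all(is.na(window_ms))) window_ms <- seq_len(ncol(snr))
  list(window_ms = window_ms,
       mean_z = colMeans(z),
       se_z = apply(z, 2, stats::sd) / sqrt(nrow(z)),
       z = z)
}
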
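#' Label-shuffling permutation thresholds
#'
#' For condition-labeled, participant-wise statistics (rows = participants,
#' columns = conditions/cells), shuffles the cell labels independently
#' within each participant and summarizes each permuted dataset:
#'
#' * `median_summary` - per-cell median across participants, then the mean
#'   of those medians: one global statistic per permutation and one global
#'   threshold (the convention for the behavioral d-prime test).
#' * `mean_summary` - per-cell mean across participants: a per-cell
#'   permutation distribution and per-cell thresholds (the convention for
#'   the cross-encoding tests).
#'
#' Thresholds are the `ceil((1 - alpha) * (n_perm + 1))`-th order
#' statistics of the permutation distribution (one-sided; the `+ 1` counts
#' the observed dataset among the permutations, the exact-test convention,
#' so the flag rate under an exchangeable null is `<= alpha` and equals
#' `ceil`-rounded alpha at n_perm = 1000). Observed cell summaries (median
#' across participants for `median_summary`, mean for `mean_summary`)
#' exceeding the threshold are flagged.
#'
#' @param data Numeric matrix participants x cells (>= 2 each).
#' @param scheme `"median_summary"` or `"mean_summary"`.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param alphas One-sided alpha levels in (0, 0.5) (default
#'   `c(0.05, 0.01)`).
#' @param seed Integer seed for the shuffles.
#' @return A `permutation_null`: `thresholds` (matrix alphas x cells, or
#'   alphas x 1 for the global scheme), `observed` (per-cell summary),
#'   `flagged` (logical matrix alphas x cells), `n_perm`, `scheme`.
#' @export
permutation_threshold <- function(data, scheme = c("median_summary",
                                                   "mean_summary"),
                                  n_perm = 1000, alphas = c(0.05, 0.01),
                                  seed = 1) {
  scheme <- match.arg(scheme)
  data <- as.matrix(data)
  P <- nrow(data); C <- ncol(data)
  stopifnot(P >= 2, C >= 2)
  if (n_perm < 100) warning("n_perm < 100; thresholds will be coarse")
  if (any(alphas <= 0 | alphas >= 0.5)) stop("alphas must lie in (0, 0.5)")
  cells <- colnames(data)
  if (is.null(cells)) cells <- paste0("cell", seq_len(C))
  ord <- with_seed(seed, {
    matrix(vapply(seq_len(n_perm * P), function(i) sample.int(C),
                  integer(C)), nrow = C)
  })  # C x (n_perm * P): one shuffled label order per participant per perm
  if (scheme == "median_summary") {
    stat <- numeric(n_perm)
    perm_data <- matrix(0, P, C)
    for (k in seq_len(n_perm)) {
      for (p in seq_len(P)) {
        perm_data[p, ] <- data[p, ord[, (k - 1) * P + p]]
      }
      stat[k] <- mean(apply(perm_data, 2, stats::median))
    }
    qidx <- pmin(ceiling((1 - alphas) * (n_perm + 1)), n_perm)
    thr <- matrix(sort(stat)[qidx], length(alphas), 1,
                  dimnames = list(paste0("alpha_", alphas), "global"))
    observed <- apply(data, 2, stats::median)
  } else {
    stat <- matrix(0, n_perm, C)
    perm_data <- matrix(0, P, C)
    for (k in seq_len(n_perm)) {
      for (p in seq_len(P)) {
        perm_data[p, ] <- data[p, ord[, (k - 1) * P + p]]
      }
      stat[k, ] <- colMeans(perm_data)
    }
    qidx <- pmin(ceiling((1 - alphas) * (n_perm + 1)), n_perm)
    thr <- apply(stat, 2, function(col) sort(col)[qidx])
    if (length(alphas) == 1) thr <- matrix(thr, 1, C)
    dimnames(thr) <- list(paste0("alpha_", alphas), cells)
    observed <- colMeans(data)
  }
  names(observed) <- cells
  flagged <- matrix(FALSE, length(alphas), C,
                    dimnames = list(paste0("alpha_", alphas), cells))
  for (a in seq_along(alphas)) {
    flagged[a, ] <- observed > (if (ncol(thr) == 1) thr[a, 1] else thr[a, ])
  }
  structure(list(thresholds = thr, observed = observed, flagged = flagged,
                 n_perm = n_perm, scheme = scheme, alphas = alphas,
                 seed = seed, cell_labels = cells),
            class = "permutation_null")
}
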
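# Response preparation: PSTH binning, onset exclusion, reliability
# statistics (signal/noise power) and unit screening.

#' Bin spike times into a PSTH response
#'
#' Bins are half-open, 0-based: a spike at time t falls in bin
#' `floor(t / bin_ms)` (so a spike at exactly 25.0 ms falls in the second
#' bin). Empty trains are allowed and produce all-zero rows.
#'
#' @param spike_times Data frame with columns `trial` and `time_ms`, or a
#'   list of numeric spike-time vectors (one per trial).
#' @param n_bins Number of bins (stimulus chords).
#' @param bin_ms Bin duration, ms.
#' @param contrast Optional per-bin contrast labels.
#' @return A [unit_response()] with one row per trial.
#' @export
bin_psth <- function(spike_times, n_bins, bin_ms = 25, contrast = NULL) {
  if (is.data.frame(spike_times)) {
    stopifnot(all(c("trial", "time_ms") %in% names(spike_times)))
    trials <- split(spike_times$time_ms, spike_times$trial)
  } else {
    trials <- spike_times
  }
  total_ms <- n_bins * bin_ms
  counts <- t(vapply(trials, function(tt) {
    if (length(tt) > 0 && (any(tt < 0) || any(tt >= total_ms))) {
      stop("spike times must lie within [0, ", total_ms, ") ms")
    }
    tabulate(floor(tt / bin_ms) + 1L, nbins = n_bins)
  }, integer(n_bins)))
  unit_response(counts, bin_ms, contrast)
}

#' Exclude the onset window of a response or stimulus
#'
#' Removes the first `exclude_ms` worth of bins (default 500 ms), the
#' standard rule for discarding transient onset responses. Works on a
#' `unit_response` (drops count columns and labels) or a `drc_stimulus`
#' (drops chords). `exclude_ms = 0` is the identity.
#'
#' @param x A `unit_response` or `drc_stimulus`.
#' @param exclude_ms Window to remove, ms.
#' @return Object of the same class with the leading bins removed.
#' @export
exclude_onset <- function(x, exclude_ms = 500) {
  UseMethod("exclude_onset")
}

#' @export
exclude_onset.unit_response <- function(x, exclude_ms = 500) {
  k <- as.integer(round(exclude_ms / x$bin_ms))
  if (k == 0L) return(x)
  if (k >= ncol(x$counts)) stop("response is not longer than the exclusion window")
  x$counts <- x$counts[, -(seq_len(k)), drop = FALSE]
  x$contrast <- x$contrast[-(seq_len(k))]
  if (!is.null(x$state)) x$state <- x$state[-(seq_len(k))]
  x
}

#' @export
exclude_onset.drc_stimulus <- function(x, exclude_ms = 500) {
  k <- as.integer(round(exclude_ms / x$chord_ms))
  if (k == 0L) return(x)
  if (k >= nrow(x$levels)) stop("stimulus is not longer than the exclusion window")
  x$levels <- x$levels[-(seq_len(k)), , drop = FALSE]
  x$contrast_track <- x$contrast_track[-(seq_len(k))]
  x
}

#' Signal and noise power of a repeated response
#'
#' With N repeats and the time-power operator P(.) (population variance of a
#' vector across bins), the estimators are
#' `SP = (N * P(mean PSTH) - mean_n P(trial_n)) / (N - 1)` and
#' `NP = mean_n P(trial_n) - SP`, so the identity
#' `SP + NP = mean_n P(trial_n)` holds exactly on every input. SP is
#' unbiased for the power of the underlying PSTH; individual estimates may
#' be slightly negative and are preserved, not clamped.
#'
#' @param response A `unit_response` with at least 2 repeats.
#' @return List: `signal_power`, `noise_power`, `np_sp_ratio` (NA when
#'   SP <= 0), `mean_trial_power`, `n_repeats`.
#' @export
signal_noise_power <- function(response) {
  counts <- response$counts
  n <- nrow(counts)
  if (n < 2L) stop("signal/noise power requires at least 2 repeats")
  pow <- function(x) mean((x - mean(x))^2)
  p_trials <- apply(counts, 1, pow)
  p_bar <- mean(p_trials)
  p_sig <- pow(colMeans(counts))
  sp <- (n * p_sig - p_bar) / (n - 1)
  np <- p_bar - sp
  list(
    signal_power = sp,
    noise_power = np,
    np_sp_ratio = if (sp > 0) np / sp else NA_real_,
    mean_trial_power = p_bar,
    n_repeats = n
  )
}

#' Cross-validated linear prediction correlation
#'
#' Fits a separable STRF to the leading `train_frac` of the bins and returns
#' the Pearson correlation between the linear prediction and the
#' repeat-averaged response on the held-out remainder (the `cc_pred`
#' screening statistic).
#'
#' @param stimulus `drc_stimulus` or level matrix.
#' @param response `unit_response` or numeric PSTH.
#' @param train_frac Leading fraction used for fitting (default 0.9,
#'   contiguous blocks).
#' @inheritParams fit_separable_strf
#' @return List: `cc_pred`, the fitted `strf`.
#' @export
prediction_cc <- function(stimulus, response, train_frac = 0.9,
                          n_history = 10, ridge = 1e-3, exclude_ms = 500) {
  levels <- stimulus_levels(stimulus)
  y <- if (inherits(response, "unit_response")) psth_of(response) else response
  stopifnot(length(y) == nrow(levels))
  usable <- seq_along(y)
  if (exclude_ms > 0) {
    usable <- usable[-seq_len(round(exclude_ms / CHORD_MS))]
  }
  n_tr <- floor(length(usable) * train_frac)
  stopifnot(n_tr >= 1, n_tr < length(usable))
  train <- usable[seq_len(n_tr)]
  test <- usable[(n_tr + 1):length(usable)]
  x <- lagged_design(levels, n_history)
  sel <- rep(FALSE, length(y))
  sel[train] <- TRUE
  strf <- fit_strf_rows(x, y, sel, ncol(levels), n_history, ridge)
  z <- drop(x %*% as.numeric(outer(strf$k_f, strf$k_h))) + strf$bias
  cc <- suppressWarnings(stats::cor(z[test], y[test]))
  list(cc_pred = if (is.finite(cc)) cc else 0, strf = strf)
}

#' Screen units by reliability and prediction quality
#'
#' A unit is retained iff `NP/SP <= np_sp_max` (boundary inclusive; the
#' exclusion rule is strict `>`) and `cc_pred >= cc_min`. Units with
#' `SP <= 0` are excluded with reason `nonpositive_sp`. Lowering `np_sp_max`
#' never admits a previously excluded unit.
#'
#' @param stats Data frame with columns `unit`, `signal_power`,
#'   `noise_power`, `cc_pred`.
#' @param np_sp_max Maximum allowed NP/SP ratio (default 60).
#' @param cc_min Minimum cross-validated prediction correlation (default
#'   0.1).
#' @return The input with added columns `np_sp_ratio`, `retained`, `reason`
#'   ("" when retained).
#' @export
screen_units <- function(stats, np_sp_max = 60, cc_min = 0.1) {
  required <- c("unit", "signal_power", "noise_power", "cc_pred")
  stopifnot(all(required %in% names(stats)))
  ratio <- ifelse(stats$signal_power > 0,
                  stats$noise_power / stats$signal_power, NA_real_)
  reason <- character(nrow(stats))
  reason[stats$signal_power <= 0] <- "nonpositive_sp"
  bad_ratio <- !is.na(ratio) & ratio > np_sp_max
  reason[reason == "" & bad_ratio] <- "np_sp_above_max"
  bad_cc <- is.na(stats$cc_pred) | stats$cc_pred < cc_min
  reason[reason == "" & bad_cc] <- "cc_pred_below_min"
  stats$np_sp_ratio <- ratio
  stats$retained <- reason == ""
  stats$reason <- reason
  stats
}
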
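# Ground-truth synthetic units and observers.
#
# Every downstream stage (screening, STRF estimation, nonlinearity fitting,
# dynamics, neurometrics) is validated against populations generated here,
# where the STRF, the per-contrast sigmoid parameters, the adaptation time
# constant and the observer's JNDs are known exactly.

#' Ground-truth LN unit
#'
#' @param strf A `separable_strf`.
#' @param params_low,params_high [sigmoid_params()] in the low- and
#'   high-contrast steady states.
#' @param tau_ms Adaptation time constant, ms.
#' @return A `ground_truth_unit` (also a valid [adaptive_ln()] model).
#' @export
ground_truth_unit <- function(strf, params_low, params_high, tau_ms) {
  u <- adaptive_ln(strf, params_low, params_high, tau_ms)
  class(u) <- c("ground_truth_unit", class(u))
  u
}

#' Per-unit spike-count response
#'
#' Container for repeated responses in 25-ms bins aligned 1:1 with stimulus
#' chords.
#'
#' @param counts Integer matrix, repeats x bins.
#' @param bin_ms Bin duration (ms).
#' @param contrast Per-bin contrast labels (length = bins).
#' @param state Optional per-bin cortex-state labels.
#' @return A `unit_response`.
#' @export
unit_response <- function(counts, bin_ms = 25, contrast = NULL, state = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (is.null(contrast)) contrast <- rep(NA_character_, ncol(counts))
  stopifnot(length(contrast) == ncol(counts))
  structure(
    list(counts = counts, bin_ms = bin_ms, contrast = contrast, state = state),
    class = "unit_response"
  )
}

#' Repeat-averaged PSTH of a response
#' @param response A `unit_response`.
#' @return Mean spikes/bin across repeats, one value per bin.
#' @export
psth_of <- function(response) {
  stopifnot(inherits(response, "unit_response"))
  colMeans(response$counts)
}

#' Simulate Poisson responses of a ground-truth unit
#'
#' The rate is the adaptive LN prediction (sigmoid parameters interpolated by
#' the exponentially smoothed contrast state of the stimulus with the unit's
#' tau), clamped at zero, and spike counts are drawn independently per repeat
#' from a Poisson distribution in each 25-ms bin.
#'
#' @param unit A [ground_truth_unit()].
#' @param stimulus A `drc_stimulus` on the unit's frequency grid.
#' @param n_repeats Number of repeats.
#' @param seed RNG seed.
#' @return A `unit_response` with the true `rate` attached as an attribute.
#' @export
simulate_unit_response <- function(unit, stimulus, n_repeats, seed) {
  if (ncol(stimulus$levels) != length(unit$strf$k_f)) {
    stop("stimulus frequency grid does not match the unit's STRF")
  }
  rate <- pmax(0, adaptive_predict(unit, stimulus))
  n_bins <- length(rate)
  counts <- with_seed(seed, {
    matrix(stats::rpois(n_repeats * n_bins, rep(rate, each = n_repeats)),
           nrow = n_repeats)
  })
  out <- unit_response(counts, stimulus$chord_ms, stimulus$contrast_track)
  attr(out, "rate") <- rate
  out
}

# expected steady-state drive for a flat spectrogram at `level` dB/channel
flat_drive <- function(strf, level) {
  strf$bias + level * sum(strf$k_f) * sum(strf$k_h)
}

# decision-window drive operating point and slope per probe dB, measured on
# deterministic (zero-contrast-width) 2-AFC trials. Window bins see a
# mixture of probe and DRC-context drive through the temporal kernel, so
# both quantities are computed per bin and averaged with weights equal to
# each bin's level sensitivity: the operating point is centered where the
# level-responsive drive actually sits.
probe_drive_calibration <- function(strf, grid, reference_level = 70,
                                    mean_level = 40, extra_bins = 1) {
  flat <- contrast_regime(0, mean_level, "low")
  win_z <- function(target) {
    tr <- assemble_trial(grid, flat, reference_level, target, seed = 1)
    z <- predict_linear(strf, tr$levels)
    win <- decision_windows(tr, extra_bins)
    z[win$target]
  }
  z0 <- win_z(reference_level)
  z1 <- win_z(reference_level + 1)
  w <- pmax(z1 - z0, 0)
  if (sum(w) <= 0) {
    return(list(mean_drive = mean(z0), slope_per_db = 0))
  }
  list(
    mean_drive = sum(w * z0) / sum(w),
    slope_per_db = sum(w * w) / sum(w)
  )
}

# sd of the drive under i.i.d. uniform levels of width w (independent across
# tones and chords, so variances add over the full kernel)
drive_sd <- function(strf, width) {
  sqrt(sum(strf_kernel(strf)^2)) * width / sqrt(12)
}

#' Build a ground-truth population with a known compensation target
#'
#' Constructs `n_units` LN units whose spectral kernels (Gabor-like
#' Gaussians) tile the frequency grid, with difference-of-exponentials
#' temporal kernels, and whose sigmoid gains across the two contrast
#' conditions are set so that each unit's percent compensation equals
#' `compensation_target` (up to `jitter_pct` of Gaussian jitter). Complete
#' compensation (100%) makes the high-contrast gain half the low-contrast
#' gain under a contrast-width doubling; 0% leaves the gain unchanged. The
#' gain change is implemented through the sigmoid width d (shared y-range b),
#' and the x-offset c is placed at the drive produced by a flat spectrogram
#' at `operating_level` dB per channel (the DRC mean level by default, so
#' fits on DRC data sit on the informative part of the curve).
#'
#' @param n_units Number of units.
#' @param compensation_target Target percent compensation in `[0, 150]`.
#' @param grid Frequency grid the STRFs live on.
#' @param seed RNG seed (jitter and per-unit rate parameters).
#' @param jitter_pct SD of Gaussian jitter on the per-unit compensation
#'   target, percentage points.
#' @param tau_ms Time constants, recycled across units (deterministic
#'   assignment).
#' @param widths Contrast widths in dB, `c(low = , high = )`.
#' @param mean_level DRC mean level (dB SPL).
#' @param operating_level Channel level (dB) at which the sigmoid inflection
#'   sits; use the probe channel level for neurometric studies.
#' @param n_history Temporal kernel length in bins.
#' @param y_offset_ratio Ratio a_high / a_low (1 = no y-offset adaptation).
#' @param probe_width_db If given, the sigmoid is calibrated for the 2-AFC
#'   noise probes instead of `operating_level`: the inflection is placed at
#'   the mean decision-window drive of a reference trial and the low-contrast
#'   width d is set so the nonlinearity transitions over about this many dB
#'   of probe level, making the units level-monotone across the target
#'   range. If `NULL` (default) d is the DRC drive standard deviation,
#'   placing the dynamic range on the DRC drive distribution.
#' @param reference_level Reference probe level (dB SPL) used for the probe
#'   calibration.
#' @param t_rise,t_fall Rise and fall time constants (bins) of the
#'   difference-of-exponentials temporal kernel. Short values give compact
#'   kernels whose decision-window drive is dominated by the noise probe,
#'   the premise of the gain-to-JND consistency relation.
#' @return List of [ground_truth_unit()]s.
#' @export
make_population <- function(n_units, compensation_target = 100, grid,
                            seed = 1, jitter_pct = 0, tau_ms = 150,
                            widths = c(low = 20, high = 40), mean_level = 40,
                            operating_level = mean_level, n_history = 10,
                            y_offset_ratio = 1, probe_width_db = NULL,
                            reference_level = 70,
                            t_rise = 0.6, t_fall = 1.8) {
  stopifnot(compensation_target >= 0, compensation_target <= 150)
  n_f <- length(grid$frequencies)
  bf_channels <- round(seq(max(2, n_f * 0.15), min(n_f - 1, n_f * 0.85),
                           length.out = n_units))
  taus <- rep(tau_ms, length.out = n_units)
  h <- 0:(n_history - 1)
  ratio <- (widths[["high"]] - widths[["low"]]) / widths[["low"]]
  with_seed(seed, {
    lapply(seq_len(n_units), function(i) {
      sigma <- stats::runif(1, 1.5, 2.5)
      k_f <- exp(-(seq_len(n_f) - bf_channels[i])^2 / (2 * sigma^2))
      k_h <- exp(-h / t_fall) - exp(-h / t_rise)
      strf <- separable_strf(k_f, k_h, bias = 0)
      # scale spectral kernel so the low-contrast drive has unit sd
      sdz <- drive_sd(strf, widths[["low"]])
      strf$k_f <- strf$k_f / sdz
      comp_i <- compensation_target + stats::rnorm(1, 0, jitter_pct)
      comp_i <- max(comp_i, -50)
      gain_ratio <- 1 + comp_i / 100 * ratio # G_low / G_high
      b <- stats::runif(1, 2, 4)
      a <- stats::runif(1, 0.2, 0.6)
      if (is.null(probe_width_db)) {
        d_low <- 1 # = sd of the low-contrast DRC drive after rescaling
        cc <- flat_drive(strf, operating_level)
      } else {
        cal <- probe_drive_calibration(strf, grid, reference_level,
                                       mean_level)
        d_low <- probe_width_db * cal$slope_per_db
        cc <- cal$mean_drive
      }
      ground_truth_unit(
        strf,
        params_low = sigmoid_params(a, b, cc, d_low),
        params_high = sigmoid_params(a * y_offset_ratio, b, cc,
                                     d_low * gain_ratio),
        tau_ms = taus[i]
      )
    })
  })
}

#' True percent compensation of a ground-truth unit
#' @param unit A [ground_truth_unit()].
#' @param widths Contrast widths in dB.
#' @return Percent compensation implied by the unit's true gains.
#' @export
true_compensation <- function(unit, widths = c(low = 20, high = 40)) {
  percent_compensation(
    sigmoid_gain(unit$params_low), sigmoid_gain(unit$params_high),
    widths[["low"]], widths[["high"]]
  )
}

#' Simulate a 2-AFC observer session
#'
#' Simulates an ideal observer whose probability of responding "louder"
#' follows a cumulative Gaussian in target level around the reference, with
#' the 25--75% width of the curve equal to the stated JND
#' (sigma = JND / 1.349).
#'
#' @param jnd_low,jnd_high JNDs (dB) in the low- and high-contrast conditions.
#' @param levels Target levels (dB SPL) tested in each condition.
#' @param n_trials Trials per level per condition.
#' @param seed RNG seed.
#' @param reference_level Reference probe level (dB SPL).
#' @param participant Participant identifier carried in the table.
#' @return Data frame: `participant`, `contrast`, `target_level_db`, `n`,
#'   `k_louder`, with the reference level as an attribute.
#' @export
simulate_observer_session <- function(jnd_low, jnd_high, levels, n_trials,
                                      seed, reference_level = 60,
                                      participant = "sim01") {
  stopifnot(jnd_low > 0, jnd_high > 0, n_trials >= 1)
  jnd_factor <- stats::qnorm(0.75) - stats::qnorm(0.25) # 1.349
  grid_tbl <- expand.grid(
    contrast = c("low", "high"), target_level_db = levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sigma <- ifelse(grid_tbl$contrast == "low", jnd_low, jnd_high) / jnd_factor
  p <- stats::pnorm(grid_tbl$target_level_db, reference_level, sigma)
  k <- with_seed(seed, stats::rbinom(nrow(grid_tbl), n_trials, p))
  out <- data.frame(
    participant = participant,
    contrast = grid_tbl$contrast,
    target_level_db = grid_tbl$target_level_db,
    n = n_trials,
    k_louder = k
  )
  attr(out, "reference_level") <- reference_level
  out
}
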
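# Dynamic random chord (DRC) stimulus construction.
#
# All analysis operates on the dB-level matrix (chords x frequencies); audio
# rendering is deliberately out of scope. Chord duration is 25 ms throughout
# (including 5 ms on/off ramps, which only matter for audio, not analysis).

CHORD_MS <- 25
RAMP_MS <- 5

#' Logarithmic frequency grid
#'
#' Builds the tone-frequency grid of a DRC: frequencies logarithmically spaced
#' between `f_min` and `f_max` at `steps_per_octave` steps per octave,
#' inclusive of both endpoints. The octave span must be an integral number of
#' steps (e.g. 1--64 kHz at 1/4-octave spacing gives 25 frequencies).
#'
#' @param f_min,f_max Frequency range in Hz.
#' @param steps_per_octave Steps per octave (4 = quarter-octave spacing).
#' @return A `frequency_grid` with fields `f_min`, `f_max`, `steps_per_octave`,
#'   `frequencies`.
#' @examples
#' length(make_frequency_grid(1000, 64000, 4)$frequencies)  # 25
#' @export
make_frequency_grid <- function(f_min, f_max, steps_per_octave = 4) {
  stopifnot(f_min > 0, f_max >= f_min, steps_per_octave >= 1)
  span <- log2(f_max / f_min) * steps_per_octave
  if (abs(span - round(span)) > 1e-9 * max(1, abs(span))) {
    stop(
      "frequency range ", f_min, "-", f_max,
      " Hz does not span a whole number of 1/", steps_per_octave,
      "-octave steps (", format(span), " steps)"
    )
  }
  n <- as.integer(round(span)) + 1L
  freqs <- f_min * 2^((seq_len(n) - 1) / steps_per_octave)
  freqs[n] <- f_max
  structure(
    list(
      f_min = f_min, f_max = f_max,
      steps_per_octave = steps_per_octave,
      frequencies = freqs
    ),
    class = "frequency_grid"
  )
}

#' Contrast regime of a DRC
#'
#' A contrast regime is a uniform distribution of tone levels: mean level
#' `mean_level` (dB SPL) and full range `width` (dB). The width is the
#' stimulus "contrast" (20/40 dB in the mouse experiments, 10/30 dB in the
#' human experiments); draws lie in `mean_level +/- width/2`.
#'
#' @param width Full dB range of the uniform level distribution.
#' @param mean_level Mean tone level, dB SPL.
#' @param label Condition label (e.g. "low", "high"); defaults to
#'   `"<width>dB"`.
#' @return A `contrast_regime` list.
#' @export
contrast_regime <- function(width, mean_level = 40, label = NULL) {
  stopifnot(is.numeric(width), length(width) == 1L, width >= 0)
  if (is.null(label)) label <- paste0(format(width), "dB")
  structure(
    list(mean_level = mean_level, width = width, label = label),
    class = "contrast_regime"
  )
}

regime_bounds <- function(regime) {
  regime$mean_level + c(-0.5, 0.5) * regime$width
}

# shared constructor: draw a DRC from a named regime list and per-chord track
drc_from_track <- function(grid, regimes, track, seed,
                           chord_ms = CHORD_MS, level_matched = FALSE) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (inherits(regimes, "contrast_regime")) {
    regimes <- stats::setNames(list(regimes), regimes$label)
  }
  stopifnot(all(track %in% names(regimes)))
  n_chords <- length(track)
  n_freqs <- length(grid$frequencies)
  mu <- vapply(regimes, `[[`, numeric(1), "mean_level")[track]
  w <- vapply(regimes, `[[`, numeric(1), "width")[track]
  levels <- with_seed(seed, {
    u <- matrix(stats::runif(n_chords * n_freqs), nrow = n_chords)
    mu + (u - 0.5) * w
  })
  if (level_matched) {
    # rescale each chord's summed acoustic power to the common target
    # n_freqs * 10^(mean_level/10); exact equality across regimes by
    # construction (and a no-op for zero-width regimes)
    target_db <- 10 * log10(n_freqs) + unique(mu)
    if (length(target_db) != 1L) {
      stop("level matching requires a common mean level across regimes")
    }
    chord_db <- 10 * log10(rowSums(10^(levels / 10)))
    levels <- levels + (target_db - chord_db)
  }
  structure(
    list(
      levels = levels,
      chord_ms = chord_ms,
      ramp_ms = RAMP_MS,
      grid = grid,
      regimes = regimes,
      contrast_track = track,
      level_matched = level_matched,
      seed = seed
    ),
    class = "drc_stimulus"
  )
}

#' Generate a constant-contrast DRC
#'
#' Tone levels are drawn i.i.d. from the regime's uniform distribution, one
#' draw per tone per 25-ms chord. Identical `(grid, regime, n_chords, seed)`
#' give a bit-identical level matrix.
#'
#' @param grid A [make_frequency_grid()] grid.
#' @param regime A [contrast_regime()], or a named list of regimes together
#'   with a per-chord `track` of labels.
#' @param n_chords Number of 25-ms chords.
#' @param seed RNG seed.
#' @param track Optional per-chord character vector of regime labels (length
#'   `n_chords`); defaults to the single regime's label throughout.
#' @return A `drc_stimulus`: `levels` (chords x frequencies, dB SPL),
#'   `contrast_track`, `regimes`, timing metadata.
#' @export
generate_drc <- function(grid, regime, n_chords, seed, track = NULL) {
  stopifnot(n_chords >= 1)
  if (is.null(track)) {
    if (inherits(regime, "contrast_regime")) {
      track <- rep(regime$label, n_chords)
    } else {
      stop("`track` must be given when `regime` is a list of regimes")
    }
  }
  stopifnot(length(track) == n_chords)
  drc_from_track(grid, regime, track, seed)
}

#' Generate a switching-contrast DRC
#'
#' Contrast alternates between a low- and a high-width regime every
#' `epoch_s` seconds (2 s in the switching experiments), holding the mean
#' level fixed.
#'
#' @inheritParams generate_drc
#' @param width_low,width_high Uniform widths (dB) of the two regimes.
#' @param epoch_s Epoch duration in seconds; must be a whole number of chords.
#' @param total_s Total duration in seconds; must be a whole number of epochs.
#' @param mean_level Mean tone level, dB SPL.
#' @param start_high Start in the high-contrast state?
#' @return A `drc_stimulus` whose `contrast_track` alternates "low"/"high".
#' @export
generate_switching_drc <- function(grid, width_low = 20, width_high = 40,
                                   epoch_s = 2, total_s, seed,
                                   mean_level = 40, start_high = FALSE) {
  epoch_ms <- epoch_s * 1000
  if (abs(epoch_ms / CHORD_MS - round(epoch_ms / CHORD_MS)) > 1e-9) {
    stop("epoch duration must be a whole number of ", CHORD_MS, "-ms chords")
  }
  chords_per_epoch <- as.integer(round(epoch_ms / CHORD_MS))
  n_epochs <- total_s / epoch_s
  if (abs(n_epochs - round(n_epochs)) > 1e-9) {
    stop("total duration must be a whole number of epochs")
  }
  n_epochs <- as.integer(round(n_epochs))
  regimes <- list(
    low = contrast_regime(width_low, mean_level, "low"),
    high = contrast_regime(width_high, mean_level, "high")
  )
  states <- rep(c("low", "high"), length.out = n_epochs)
  if (start_high) states <- rep(c("high", "low"), length.out = n_epochs)
  track <- rep(states, each = chords_per_epoch)
  drc_from_track(grid, regimes, track, seed)
}

#' Generate a level-matched DRC
#'
#' Like [generate_drc()], but each chord's summed acoustic power
#' (sum of 10^(L/10) over tones) is rescaled to a common target after the
#' uniform draw, so per-chord overall level is identical across contrast
#' regimes (at the expense of exact per-tone level statistics). This is the
#' control for the small overall-level difference inherent to the dB-uniform
#' construction.
#'
#' @inheritParams generate_drc
#' @return A `drc_stimulus` with `level_matched = TRUE`.
#' @export
generate_level_matched_drc <- function(grid, regime, n_chords, seed,
                                       track = NULL) {
  stopifnot(n_chords >= 1)
  if (is.null(track)) {
    if (inherits(regime, "contrast_regime")) {
      track <- rep(regime$label, n_chords)
    } else {
      stop("`track` must be given when `regime` is a list of regimes")
    }
  }
  stopifnot(length(track) == n_chords)
  drc_from_track(grid, regime, track, seed, level_matched = TRUE)
}

#' Per-chord overall level of a DRC
#'
#' @param drc A `drc_stimulus`.
#' @return Numeric vector, per-chord total level 10*log10(sum 10^(L/10)), dB.
#' @export
chord_total_level <- function(drc) {
  10 * log10(rowSums(10^(drc$levels / 10)))
}

#' Expected overall-level difference between two contrast regimes
#'
#' Analytic diagnostic for the overall-level mismatch inherent to uniform
#' draws on the dB scale: the expected summed acoustic power of a chord under
#' a regime is n_freqs * E[10^(L/10)], with
#' E[10^(L/10)] = (10^(b/10) - 10^(a/10)) / ((b - a) ln(10)/10)
#' for L ~ Uniform(a, b). Returns the dB difference (second minus first).
#'
#' @param regime_a,regime_b Two [contrast_regime()]s.
#' @param grid Frequency grid (sets the number of tones; cancels in the
#'   difference but kept for the absolute levels).
#' @return List with per-regime expected total level (dB) and `difference_db`.
#' @export
expected_level_difference <- function(regime_a, regime_b, grid) {
  e_pow <- function(regime) {
    ab <- regime_bounds(regime)
    if (regime$width == 0) {
      return(10^(regime$mean_level / 10))
    }
    (10^(ab[2] / 10) - 10^(ab[1] / 10)) / ((ab[2] - ab[1]) * log(10) / 10)
  }
  n <- length(grid$frequencies)
  la <- 10 * log10(n * e_pow(regime_a))
  lb <- 10 * log10(n * e_pow(regime_b))
  list(total_level_a = la, total_level_b = lb, difference_db = lb - la)
}

#' Flat spectrogram block for a broadband noise probe
#'
#' Represents a broadband noise burst on the DRC frequency grid: every channel
#' is set to `level - 10*log10(n_freqs)` dB so the channel powers sum to the
#' stated total level. Needed to present the noise probes of the 2-AFC task
#' to STRF models.
#'
#' @param level Total noise level, dB SPL.
#' @param duration_ms Duration; must be a multiple of the 25-ms chord.
#' @param grid Frequency grid.
#' @return Matrix `duration_ms/25` x `n_freqs` of channel levels (dB SPL).
#' @export
noise_to_spectrogram <- function(level, duration_ms, grid) {
  stopifnot(duration_ms >= 0)
  if (abs(duration_ms / CHORD_MS - round(duration_ms / CHORD_MS)) > 1e-9) {
    stop("noise duration must be a multiple of the ", CHORD_MS, "-ms chord")
  }
  n_bins <- as.integer(round(duration_ms / CHORD_MS))
  n_freqs <- length(grid$frequencies)
  matrix(level - 10 * log10(n_freqs), nrow = n_bins, ncol = n_freqs)
}

#' Assemble one 2-AFC level-discrimination trial
#'
#' Builds the 1,950-ms trial of the level-discrimination task: 1000 ms DRC,
#' 100 ms broadband noise at the reference level, 250 ms DRC, 100 ms noise at
#' the target level, 500 ms DRC, all within one contrast regime. Returns the
#' full trial spectrogram plus the bin indices of the two noise probes.
#'
#' @param grid Frequency grid.
#' @param contrast A [contrast_regime()] for the flanking DRC.
#' @param reference_level,target_level Probe levels, dB SPL (human defaults
#'   60 and 52--68; model variant 70 and 62--78).
#' @param seed RNG seed for the DRC segments.
#' @return A `trial_stimulus`: `levels` (78 x n_freqs dB matrix), `segments`
#'   table, `reference_bins`, `target_bins` (1-based rows of `levels`),
#'   `contrast`, probe levels.
#' @export
assemble_trial <- function(grid, contrast, reference_level = 60,
                           target_level, seed) {
  stopifnot(inherits(contrast, "contrast_regime"))
  seg <- data.frame(
    kind = c("drc", "noise", "drc", "noise", "drc"),
    duration_ms = c(1000, 100, 250, 100, 500),
    level = c(NA, reference_level, NA, target_level, NA)
  )
  stopifnot(sum(seg$duration_ms) == 1950)
  n_bins_seg <- seg$duration_ms / CHORD_MS
  drc_bins <- sum(n_bins_seg[seg$kind == "drc"])
  drc <- generate_drc(grid, contrast, drc_bins, seed)
  blocks <- list()
  drc_used <- 0L
  for (i in seq_len(nrow(seg))) {
    nb <- n_bins_seg[i]
    if (seg$kind[i] == "drc") {
      blocks[[i]] <- drc$levels[drc_used + seq_len(nb), , drop = FALSE]
      drc_used <- drc_used + nb
    } else {
      blocks[[i]] <- noise_to_spectrogram(seg$level[i], seg$duration_ms[i], grid)
    }
  }
  levels <- do.call(rbind, blocks)
  starts <- cumsum(c(0, n_bins_seg))[seq_len(nrow(seg))]
  ref_bins <- starts[2] + seq_len(n_bins_seg[2])
  tgt_bins <- starts[4] + seq_len(n_bins_seg[4])
  structure(
    list(
      levels = levels,
      segments = seg,
      chord_ms = CHORD_MS,
      grid = grid,
      contrast = contrast,
      reference_level = reference_level,
      target_level = target_level,
      reference_bins = ref_bins,
      target_bins = tgt_bins,
      total_ms = sum(seg$duration_ms),
      seed = seed
    ),
    class = "trial_stimulus"
  )
}

#' Duration of a DRC in bins
#' @param drc A `drc_stimulus`.
#' @return Integer number of 25-ms chords.
#' @export
n_chords <- function(drc) nrow(drc$levels)

# 0/1 contrast indicator per chord: 1 for the widest regime, 0 otherwise.
# With a single regime the indicator is 1 iff its label is "high".
contrast_indicator <- function(drc) {
  widths <- vapply(drc$regimes, `[[`, numeric(1), "width")
  if (length(widths) == 1L) {
    return(rep(as.numeric(names(widths) == "high"), n_chords(drc)))
  }
  high_label <- names(widths)[which.max(widths)]
  as.numeric(drc$contrast_track == high_label)
}
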
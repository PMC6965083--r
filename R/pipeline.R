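# End-to-end orchestration: simulate -> screen -> fit -> dynamics ->
# neurometric -> report. Every stochastic stage derives its seed from the
# single config seed, so a config determines the whole run.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. Round-trips losslessly
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param n_units Number of synthetic units.
#' @param compensation_target Ground-truth percent compensation.
#' @param jitter_pct SD of per-unit jitter on the target (percentage
#'   points).
#' @param tau_ms Ground-truth time constants, recycled across units.
#' @param f_min,f_max,steps_per_octave Frequency grid.
#' @param widths Contrast widths (dB), named low/high.
#' @param mean_level DRC mean level, dB SPL.
#' @param drc_s Duration (s) of the constant-contrast DRC per condition.
#' @param n_repeats Repeats per stimulus.
#' @param exclude_ms Onset exclusion window, ms.
#' @param np_sp_max,cc_min Screening thresholds.
#' @param n_history,ridge STRF fit settings.
#' @param train_frac Train fraction for cross-validated statistics.
#' @param tau_bounds Adaptive-fit tau bounds, ms.
#' @param switch_total_s,switch_epoch_s Switching-stimulus durations (s).
#' @param switch_repeats Repeats of the switching stimulus.
#' @param dynamics_units Number of units carried into the dynamics stage
#'   (`0` = all retained units).
#' @param neuro_trials,neuro_runs Neurometric simulation sizes.
#' @param neuro_reference,neuro_targets Neurometric probe levels, dB SPL.
#' @param stages Which stages to run, a subset of
#'   `c("screen", "nonlin", "dynamics", "neurometric")`.
#' @param n_boot Bootstrap resamples for summary CIs.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A `run_config`.
#' @export
run_config <- function(n_units = 50, compensation_target = 100,
                       jitter_pct = 0, tau_ms = 150,
                       f_min = 1000, f_max = 64000, steps_per_octave = 4,
                       widths = c(low = 20, high = 40), mean_level = 40,
                       drc_s = 40, n_repeats = 20, exclude_ms = 500,
                       np_sp_max = 60, cc_min = 0.1,
                       n_history = 10, ridge = 1e-3, train_frac = 0.9,
                       tau_bounds = c(1, 700),
                       switch_total_s = 40, switch_epoch_s = 2,
                       switch_repeats = 40, dynamics_units = 0,
                       neuro_trials = 500, neuro_runs = 25,
                       neuro_reference = 70,
                       neuro_targets = seq(62, 78, by = 2),
                       stages = c("screen", "nonlin"),
                       n_boot = 10000, seed = 1, out_dir = NULL) {
  widths <- unlist(widths)
  stopifnot(all(c("low", "high") %in% names(widths)))
  structure(
    list(
      n_units = n_units, compensation_target = compensation_target,
      jitter_pct = jitter_pct, tau_ms = tau_ms,
      f_min = f_min, f_max = f_max, steps_per_octave = steps_per_octave,
      widths = widths, mean_level = mean_level,
      drc_s = drc_s, n_repeats = n_repeats, exclude_ms = exclude_ms,
      np_sp_max = np_sp_max, cc_min = cc_min,
      n_history = n_history, ridge = ridge, train_frac = train_frac,
      tau_bounds = unlist(tau_bounds),
      switch_total_s = switch_total_s, switch_epoch_s = switch_epoch_s,
      switch_repeats = switch_repeats, dynamics_units = dynamics_units,
      neuro_trials = neuro_trials, neuro_runs = neuro_runs,
      neuro_reference = neuro_reference,
      neuro_targets = unlist(neuro_targets),
      stages = stages, n_boot = n_boot, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

# concatenate two constant-contrast DRCs into one pseudo-stimulus; bins whose
# lagged history crosses a segment boundary are handled by the segment-aware
# exclusion mask below
concat_drc <- function(drc_list) {
  structure(
    list(
      levels = do.call(rbind, lapply(drc_list, `[[`, "levels")),
      chord_ms = drc_list[[1]]$chord_ms,
      ramp_ms = drc_list[[1]]$ramp_ms,
      grid = drc_list[[1]]$grid,
      regimes = do.call(c, lapply(drc_list, `[[`, "regimes")),
      contrast_track = do.call(c, lapply(drc_list, `[[`, "contrast_track")),
      level_matched = FALSE,
      seed = drc_list[[1]]$seed,
      segment_bins = vapply(drc_list, n_chords, integer(1))
    ),
    class = "drc_stimulus"
  )
}

segment_mask <- function(segment_bins, exclude_bins) {
  unlist(lapply(segment_bins, function(n) {
    c(rep(FALSE, min(exclude_bins, n)), rep(TRUE, max(0, n - exclude_bins)))
  }))
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Executes the configured stages in order: stimulus + population
#' simulation; reliability screening (SP/NP and cross-validated prediction);
#' combined-STRF + per-condition sigmoid fitting with compensation and
#' y-offset metrics; adaptive-LN dynamics on switching-contrast data; and
#' the neurometric behavioral prediction. Identical configs (same seed)
#' produce identical results.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: `units` (per-unit table), `screening`,
#'   `dynamics` (when run), `neurometric` (when run), and a `summary` list
#'   (median compensation with bootstrap CI, median y-offset change, median
#'   tau, fraction tau-improved, predicted perceptual compensation, counts).
#'   When `config$out_dir` is set, result tables, `summary.json` and a run
#'   log are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  grid <- make_frequency_grid(config$f_min, config$f_max,
                              config$steps_per_octave)
  say("pipeline: ", config$n_units, " units, compensation target ",
      config$compensation_target, "%, seed ", config$seed)

  units <- make_population(
    config$n_units, config$compensation_target, grid,
    seed = child_seed(config$seed, 1), jitter_pct = config$jitter_pct,
    tau_ms = config$tau_ms, widths = config$widths,
    mean_level = config$mean_level, n_history = config$n_history
  )
  n_chords_per <- as.integer(round(config$drc_s * 1000 / CHORD_MS))
  regimes <- list(
    low = contrast_regime(config$widths[["low"]], config$mean_level, "low"),
    high = contrast_regime(config$widths[["high"]], config$mean_level, "high")
  )
  drcs <- list(
    low = generate_drc(grid, regimes$low, n_chords_per,
                       child_seed(config$seed, 2)),
    high = generate_drc(grid, regimes$high, n_chords_per,
                        child_seed(config$seed, 3))
  )
  stim <- concat_drc(drcs)
  exclude_bins <- as.integer(round(config$exclude_ms / CHORD_MS))
  mask <- segment_mask(stim$segment_bins, exclude_bins)

  responses <- lapply(seq_along(units), function(i) {
    lo <- simulate_unit_response(units[[i]], drcs$low, config$n_repeats,
                                 child_seed(config$seed, 100 + i))
    hi <- simulate_unit_response(units[[i]], drcs$high, config$n_repeats,
                                 child_seed(config$seed, 200 + i))
    unit_response(cbind(lo$counts, hi$counts), CHORD_MS,
                  c(lo$contrast, hi$contrast))
  })

  unit_tbl <- data.frame(unit = seq_along(units))
  unit_tbl$true_compensation <- vapply(units, true_compensation,
                                       numeric(1), widths = config$widths)

  screening <- NULL
  if ("screen" %in% config$stages) {
    say("screening: NP/SP <= ", config$np_sp_max, ", cc_pred >= ",
        config$cc_min)
    stats_tbl <- do.call(rbind, lapply(seq_along(units), function(i) {
      resp <- responses[[i]]
      kept <- unit_response(resp$counts[, mask, drop = FALSE], CHORD_MS,
                            resp$contrast[mask])
      snp <- signal_noise_power(kept)
      cc <- prediction_cc(stim, resp, train_frac = config$train_frac,
                          n_history = config$n_history, ridge = config$ridge,
                          exclude_ms = config$exclude_ms)$cc_pred
      data.frame(unit = i, signal_power = snp$signal_power,
                 noise_power = snp$noise_power, cc_pred = cc)
    }))
    screening <- screen_units(stats_tbl, config$np_sp_max, config$cc_min)
    say("retained ", sum(screening$retained), "/", nrow(screening), " units")
  } else {
    screening <- data.frame(unit = seq_along(units), retained = TRUE)
  }
  retained <- screening$unit[screening$retained]

  fitted_models <- list()
  if ("nonlin" %in% config$stages && length(retained) > 0) {
    say("fitting combined STRFs and per-condition nonlinearities")
    x_full <- lagged_design(stim$levels, config$n_history)
    res <- lapply(retained, function(i) {
      y <- psth_of(responses[[i]])
      strf <- fit_strf_rows(x_full, y, mask, ncol(stim$levels),
                            config$n_history, config$ridge)
      z <- drop(x_full %*% as.numeric(outer(strf$k_f, strf$k_h))) + strf$bias
      fc <- fit_conditions(z[mask], y[mask], stim$contrast_track[mask],
                           widths = config$widths)
      pl <- fc$fits[fc$fits$contrast == "low", ]
      ph <- fc$fits[fc$fits$contrast == "high", ]
      model <- if (nrow(pl) == 1 && nrow(ph) == 1) {
        adaptive_ln(strf,
                    sigmoid_params(pl$a, max(pl$b, 0), pl$c, pl$d),
                    sigmoid_params(ph$a, max(ph$b, 0), ph$c, ph$d),
                    tau_ms = 1)
      } else {
        NULL
      }
      list(
        row = data.frame(
          unit = i,
          compensation = fc$summary$compensation,
          y_offset_change = fc$summary$y_offset_change,
          gain_low = if (nrow(pl) == 1) pl$gain else NA_real_,
          gain_high = if (nrow(ph) == 1) ph$gain else NA_real_
        ),
        model = model
      )
    })
    nl_tbl <- do.call(rbind, lapply(res, `[[`, "row"))
    unit_tbl <- merge(unit_tbl, nl_tbl, by = "unit", all.x = TRUE)
    fitted_models <- Filter(Negate(is.null), lapply(res, `[[`, "model"))
  }

  dynamics_tbl <- NULL
  if ("dynamics" %in% config$stages && length(retained) > 0) {
    n_dyn <- if (config$dynamics_units > 0) {
      min(config$dynamics_units, length(retained))
    } else {
      length(retained)
    }
    dyn_units <- retained[seq_len(n_dyn)]
    say("dynamics: fitting adaptive LN to ", n_dyn,
        " units on switching-contrast data")
    sw <- generate_switching_drc(
      grid, config$widths[["low"]], config$widths[["high"]],
      config$switch_epoch_s, config$switch_total_s,
      child_seed(config$seed, 4), config$mean_level
    )
    dynamics_tbl <- do.call(rbind, lapply(dyn_units, function(i) {
      resp <- simulate_unit_response(units[[i]], sw, config$switch_repeats,
                                     child_seed(config$seed, 300 + i))
      sel <- model_selection(sw, resp, tau_bounds = config$tau_bounds,
                             exclude_ms = config$exclude_ms,
                             n_history = config$n_history,
                             ridge = config$ridge)
      data.frame(
        unit = i, true_tau = units[[i]]$tau_ms,
        tau_ms = sel$model$tau_ms,
        cap_hit = sel$model$fit$cap_hit,
        cc_single = sel$cc[["single"]],
        cc_two_state = sel$cc[["two_state"]],
        cc_adaptive = sel$cc[["adaptive"]],
        contrast_dependent_better = sel$contrast_dependent_better,
        tau_improves = sel$tau_improves
      )
    }))
  }

  neuro <- NULL
  if ("neurometric" %in% config$stages && length(fitted_models) > 0) {
    say("neurometric: ", config$neuro_runs, " runs x ",
        config$neuro_trials, " trials/level")
    ncfg <- neurometric_config(
      reference_level = config$neuro_reference,
      target_levels = config$neuro_targets,
      n_trials_per_level = config$neuro_trials,
      n_runs = config$neuro_runs,
      widths = config$widths, mean_level = config$mean_level,
      seed = child_seed(config$seed, 5)
    )
    neuro <- predict_perceptual_adaptation(fitted_models, grid, ncfg)
  }

  boot_seed <- child_seed(config$seed, 6)
  comp_ci <- if ("nonlin" %in% config$stages && length(retained) > 0) {
    median_ci(unit_tbl$compensation, n_boot = config$n_boot, seed = boot_seed)
  } else {
    list(median = NA_real_, ci = c(NA_real_, NA_real_), n = 0L)
  }
  yoff_med <- if ("nonlin" %in% config$stages && length(retained) > 0) {
    stats::median(unit_tbl$y_offset_change, na.rm = TRUE)
  } else {
    NA_real_
  }
  tau_med <- NA_real_
  frac_tau <- NA_real_
  if (!is.null(dynamics_tbl) && nrow(dynamics_tbl) > 0) {
    adapting <- dynamics_tbl[dynamics_tbl$contrast_dependent_better, ]
    tau_med <- if (nrow(adapting) > 0) stats::median(adapting$tau_ms) else
      NA_real_
    frac_tau <- mean(dynamics_tbl$tau_improves)
  }
  summary <- list(
    n_units = config$n_units,
    n_retained = length(retained),
    median_compensation = comp_ci$median,
    compensation_ci = comp_ci$ci,
    median_y_offset_change = yoff_med,
    median_tau_ms = tau_med,
    fraction_tau_improves = frac_tau,
    predicted_perceptual_compensation =
      if (is.null(neuro)) NA_real_ else neuro$mean_compensation,
    predicted_perceptual_ci =
      if (is.null(neuro)) c(NA_real_, NA_real_) else neuro$ci
  )
  say("median compensation: ", format(summary$median_compensation))

  result <- structure(
    list(
      config = config, units = unit_tbl, screening = screening,
      dynamics = dynamics_tbl, neurometric = neuro, summary = summary,
      log = log_lines
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result)
  result
}

write_pipeline_result <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(result$config$out_dir, f)
  utils::write.csv(result$units, out("units.csv"), row.names = FALSE)
  utils::write.csv(result$screening, out("screening.csv"), row.names = FALSE)
  if (!is.null(result$dynamics)) {
    utils::write.csv(result$dynamics, out("dynamics.csv"), row.names = FALSE)
  }
  if (!is.null(result$neurometric)) {
    utils::write.csv(result$neurometric$runs, out("neurometric_runs.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(result$log, out("log.txt"))
  invisible(result)
}
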
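# Psychometric analysis of 2-AFC level discrimination and the neurometric
# model predicting psychometric curves from populations of LN units.

#' Fit a 2-AFC psychometric function
#'
#' Maximum-likelihood fit of a psychometric curve
#' `P(louder) = guess + (1 - guess - lapse) * F((x - m)/s)` to binomial
#' response counts, with `F` the cumulative Gaussian (default) or the
#' logistic. Guess and lapse rates are estimated jointly within
#' `[0, gl_max]` by default, or held fixed when given as numbers. The JND is
#' the dB difference between the 25% and 75% points of the fitted curve.
#'
#' @param levels Target levels (dB SPL), at least 4 distinct values.
#' @param k Number of "louder" responses per level.
#' @param n Number of trials per level (scalar or vector).
#' @param guess,lapse Guess and lapse rates; `NULL` (default) = estimated,
#'   a number = fixed at that value.
#' @param link Curve family: `"probit"` (cumulative Gaussian) or
#'   `"logistic"`.
#' @param gl_max Upper bound for estimated guess/lapse rates.
#' @return A `psychometric_fit`: `location`, `width` (scale parameter, dB),
#'   `jnd` (dB), `guess`, `lapse`, `prop` (per-level observed proportions),
#'   `at_bound` flag, and `predict(x)` giving the fitted curve.
#' @export
fit_psychometric <- function(levels, k, n, guess = NULL, lapse = NULL,
                             link = c("probit", "logistic"), gl_max = 0.1) {
  stopifnot(length(unique(levels)) >= 4)
  link <- match.arg(link)
  fcdf <- if (link == "probit") stats::pnorm else stats::plogis
  fq <- if (link == "probit") stats::qnorm else stats::qlogis
  n <- rep(n, length.out = length(levels))
  stopifnot(length(k) == length(levels), all(k >= 0), all(k <= n))
  span <- diff(range(levels))
  free_g <- is.null(guess)
  free_l <- is.null(lapse)
  # unconstrained parameterisation: (m, log s[, logit-ish g, l])
  unpack <- function(theta) {
    i <- 2L
    g <- if (free_g) stats::plogis(theta[i <- i + 1L]) * gl_max else guess
    l <- if (free_l) stats::plogis(theta[i <- i + 1L]) * gl_max else lapse
    list(m = theta[1], s = exp(theta[2]), g = g, l = l)
  }
  nll <- function(theta) {
    p0 <- unpack(theta)
    p <- p0$g + (1 - p0$g - p0$l) * fcdf((levels - p0$m) / p0$s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  prop <- k / n
  m0 <- if (any(prop <= 0.5) && any(prop >= 0.5)) {
    stats::approx(prop + seq_along(prop) * 1e-9, levels, xout = 0.5,
                  rule = 2)$y
  } else {
    stats::median(levels)
  }
  extra0 <- c(if (free_g) -4, if (free_l) -4)
  best <- NULL
  for (s0 in span * c(0.05, 0.15, 0.5)) {
    fit <- tryCatch(
      stats::optim(c(m0, log(s0), extra0), nll, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed")
  pb <- unpack(best$par)
  # 25%/75% points on the full curve (guess/lapse included)
  qpt <- function(p) {
    pp <- (p - pb$g) / (1 - pb$g - pb$l)
    pb$m + pb$s * fq(pp)
  }
  at_bound <- all(prop <= pb$g + 1e-9) || all(prop >= 1 - pb$l - 1e-9) ||
    pb$s > span * 100 || pb$s < span * 1e-6
  structure(
    list(
      location = pb$m, width = pb$s, jnd = qpt(0.75) - qpt(0.25),
      guess = pb$g, lapse = pb$l, link = link,
      levels = levels, prop = prop, n = n,
      at_bound = at_bound,
      predict = function(x) {
        pb$g + (1 - pb$g - pb$l) * fcdf((x - pb$m) / pb$s)
      }
    ),
    class = "psychometric_fit"
  )
}

#' Behavioral percent compensation from JNDs
#'
#' Discrimination sensitivity is taken as inversely proportional to the JND,
#' so the effective gain per condition is `1/JND` and gain compensation
#' ([percent_compensation()]) applies directly.
#'
#' @param jnd_low,jnd_high JNDs (dB) in the two contrast conditions.
#' @param c_low,c_high Contrast widths (dB).
#' @return Percent compensation.
#' @export
behavioral_compensation <- function(jnd_low, jnd_high, c_low = 10,
                                    c_high = 30) {
  stopifnot(jnd_low > 0, jnd_high > 0)
  percent_compensation(1 / jnd_low, 1 / jnd_high, c_low, c_high)
}

#' Per-participant JND analysis of a 2-AFC response table
#'
#' Fits a psychometric curve per participant and contrast condition, and
#' summarises the JND change and compensation across participants. Because
#' group aggregation can be done two ways, both are returned: the mean of
#' per-participant compensations, and the compensation computed from the
#' mean JNDs.
#'
#' @param tbl Data frame with columns `participant`, `contrast`
#'   ("low"/"high"), `target_level_db`, `n`, `k_louder` (as produced by
#'   [simulate_observer_session()]).
#' @param widths Contrast widths (dB), default the human 10/30 design.
#' @return List: `per_participant` data frame (jnd_low, jnd_high,
#'   jnd_change_pct, compensation), `mean_jnd_change_pct`,
#'   `mean_compensation`, `compensation_of_mean_jnds`.
#' @export
estimate_jnd_table <- function(tbl, widths = c(low = 10, high = 30)) {
  need <- c("participant", "contrast", "target_level_db", "n", "k_louder")
  stopifnot(all(need %in% names(tbl)))
  parts <- unique(tbl$participant)
  rows <- lapply(parts, function(p) {
    jnds <- vapply(c("low", "high"), function(cond) {
      sub <- tbl[tbl$participant == p & tbl$contrast == cond, ]
      fit_psychometric(sub$target_level_db, sub$k_louder, sub$n)$jnd
    }, numeric(1))
    data.frame(
      participant = p, jnd_low = jnds[["low"]], jnd_high = jnds[["high"]],
      jnd_change_pct = percent_change(jnds[["high"]], jnds[["low"]]),
      compensation = behavioral_compensation(
        jnds[["low"]], jnds[["high"]], widths[["low"]], widths[["high"]]
      )
    )
  })
  pp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(
    per_participant = pp,
    mean_jnd_change_pct = mean(pp$jnd_change_pct),
    mean_compensation = mean(pp$compensation),
    compensation_of_mean_jnds = behavioral_compensation(
      mean(pp$jnd_low), mean(pp$jnd_high), widths[["low"]], widths[["high"]]
    )
  )
}

#' Neurometric simulation configuration
#'
#' @param reference_level Reference probe level, dB SPL (70 in the model
#'   variant of the task).
#' @param target_levels Target probe levels, dB SPL (62--78).
#' @param n_trials_per_level Simulated trials per level per contrast (500).
#' @param n_runs Number of repeated psychometric estimations (25).
#' @param widths Contrast widths (dB) of the flanking DRCs.
#' @param mean_level DRC mean level, dB SPL.
#' @param decision_extra_bins Bins appended after each 100-ms noise probe to
#'   capture response latency (default 1).
#' @param seed RNG seed.
#' @return A `neurometric_config` list.
#' @export
neurometric_config <- function(reference_level = 70,
                               target_levels = seq(62, 78, by = 2),
                               n_trials_per_level = 500, n_runs = 25,
                               widths = c(low = 20, high = 40),
                               mean_level = 40, decision_extra_bins = 1,
                               seed = 1) {
  stopifnot(n_trials_per_level >= 1, n_runs >= 1,
            min(target_levels) <= reference_level,
            max(target_levels) >= reference_level)
  structure(
    list(
      reference_level = reference_level, target_levels = target_levels,
      n_trials_per_level = n_trials_per_level, n_runs = n_runs,
      widths = widths, mean_level = mean_level,
      decision_extra_bins = decision_extra_bins, seed = seed
    ),
    class = "neurometric_config"
  )
}

# decision windows: probe bins plus trailing latency bins, clipped to trial
decision_windows <- function(trial, extra_bins) {
  n <- nrow(trial$levels)
  ref <- c(trial$reference_bins,
           max(trial$reference_bins) + seq_len(extra_bins))
  tgt <- c(trial$target_bins, max(trial$target_bins) + seq_len(extra_bins))
  list(reference = ref[ref <= n], target = tgt[tgt <= n])
}

# stack all units' full kernels into a (F*H) x n_units matrix + bias vector,
# so one lagged design multiply yields every unit's drive
population_kernels <- function(models, n_history) {
  kf <- vapply(models, function(m) {
    k <- strf_kernel(m$strf)
    if (ncol(k) < n_history) {
      k <- cbind(k, matrix(0, nrow(k), n_history - ncol(k)))
    }
    as.numeric(k[, seq_len(n_history)])
  }, numeric(length(models[[1]]$strf$k_f) * n_history))
  list(
    k = kf,
    bias = vapply(models, function(m) m$strf$bias, numeric(1)),
    n_history = n_history
  )
}

# summed-population Poisson counts in both decision windows for one trial
trial_counts <- function(models, kern, trial, contrast_label, extra_bins) {
  x <- lagged_design(trial$levels, kern$n_history)
  z <- sweep(x %*% kern$k, 2, kern$bias, "+") # bins x units
  win <- decision_windows(trial, extra_bins)
  rates <- vapply(seq_along(models), function(j) {
    p <- if (contrast_label == "low") models[[j]]$params_low else
      models[[j]]$params_high
    r <- pmax(0, sigmoid(z[, j], p))
    c(sum(r[win$reference]), sum(r[win$target]))
  }, numeric(2))
  c(
    reference = sum(stats::rpois(ncol(rates), rates[1, ])),
    target = sum(stats::rpois(ncol(rates), rates[2, ]))
  )
}

#' Simulate one neurometric 2-AFC trial
#'
#' Predicts every unit's rate during the two noise probes of a trial with
#' the contrast-appropriate sigmoid on the STRF drive, draws Poisson counts,
#' sums them across units within each probe's decision window, and decides
#' "louder" when the target window total exceeds the reference window total
#' (ties broken by a fair coin).
#'
#' @param models Non-empty list of LN models, each with `strf`,
#'   `params_low`, `params_high` (e.g. [ground_truth_unit()]s or fitted
#'   [adaptive_ln()] models).
#' @param trial A [assemble_trial()] stimulus.
#' @param seed RNG seed.
#' @param decision_extra_bins Latency bins after each probe.
#' @return `"louder"` or `"quieter"`.
#' @export
simulate_neurometric_trial <- function(models, trial, seed,
                                       decision_extra_bins = 1) {
  if (length(models) == 0L) stop("at least one unit model is required")
  kern <- population_kernels(models, models[[1]]$strf$n_history)
  label <- trial$contrast$label
  if (!label %in% c("low", "high")) {
    stop("trial contrast regime must be labelled 'low' or 'high'")
  }
  with_seed(seed, {
    counts <- trial_counts(models, kern, trial, label, decision_extra_bins)
    decide_louder(counts[["reference"]], counts[["target"]])
  })
}

decide_louder <- function(ref, tgt) {
  if (tgt > ref) return("louder")
  if (tgt < ref) return("quieter")
  if (stats::runif(1) < 0.5) "louder" else "quieter"
}

#' Predicted psychometric curves and compensation from a neural population
#'
#' The full neurometric simulation: for each run, `n_trials_per_level`
#' trials are simulated at every target level in each contrast condition
#' (each trial a fresh DRC-flanked probe pair), a psychometric curve is
#' fitted per contrast, and the behavioral compensation is computed from the
#' two JNDs. Runs whose psychometric fit lands at a bound are flagged and
#' excluded from the summary.
#'
#' @param models List of LN unit models (see
#'   [simulate_neurometric_trial()]); all on the same frequency grid.
#' @param grid The stimulus frequency grid.
#' @param config A [neurometric_config()].
#' @return List: `runs` data frame (run, jnd_low, jnd_high, compensation,
#'   ok), `mean_compensation`, `ci` (bootstrap 95%), `psychometrics` of the
#'   first run.
#' @export
predict_perceptual_adaptation <- function(models, grid, config) {
  stopifnot(length(models) >= 1, inherits(config, "neurometric_config"))
  kern <- population_kernels(models, models[[1]]$strf$n_history)
  extra <- config$decision_extra_bins
  regimes <- list(
    low = contrast_regime(config$widths[["low"]], config$mean_level, "low"),
    high = contrast_regime(config$widths[["high"]], config$mean_level, "high")
  )
  runs <- vector("list", config$n_runs)
  first_fits <- NULL
  for (r in seq_len(config$n_runs)) {
    run_seed <- child_seed(config$seed, r)
    res <- with_seed(run_seed, {
      jnds <- c(low = NA_real_, high = NA_real_)
      fits <- list()
      ok <- TRUE
      for (cond in c("low", "high")) {
        k_louder <- integer(length(config$target_levels))
        for (li in seq_along(config$target_levels)) {
          lev <- config$target_levels[li]
          n_louder <- 0L
          for (tr in seq_len(config$n_trials_per_level)) {
            trial <- assemble_trial(
              grid, regimes[[cond]], config$reference_level, lev,
              seed = floor(stats::runif(1) * 2^31)
            )
            counts <- trial_counts(models, kern, trial, cond, extra)
            if (decide_louder(counts[["reference"]],
                              counts[["target"]]) == "louder") {
              n_louder <- n_louder + 1L
            }
          }
          k_louder[li] <- n_louder
        }
        fit <- fit_psychometric(config$target_levels, k_louder,
                                config$n_trials_per_level)
        fits[[cond]] <- fit
        jnds[[cond]] <- fit$jnd
        if (fit$at_bound || !is.finite(fit$jnd) || fit$jnd <= 0) ok <- FALSE
      }
      list(jnds = jnds, fits = fits, ok = ok)
    })
    comp <- if (res$ok) {
      behavioral_compensation(res$jnds[["low"]], res$jnds[["high"]],
                              config$widths[["low"]], config$widths[["high"]])
    } else {
      NA_real_
    }
    runs[[r]] <- data.frame(
      run = r, jnd_low = res$jnds[["low"]], jnd_high = res$jnds[["high"]],
      compensation = comp, ok = res$ok
    )
    if (r == 1L) first_fits <- res$fits
  }
  runs <- do.call(rbind, c(runs, list(make.row.names = FALSE)))
  mc <- mean_ci(runs$compensation[runs$ok], seed = child_seed(config$seed, 0))
  list(
    runs = runs,
    mean_compensation = mc$mean,
    ci = mc$ci,
    psychometrics = first_fits
  )
}
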
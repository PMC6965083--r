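# Contrast-dependent sigmoid output nonlinearities and gain metrics.
#
# The output nonlinearity maps the STRF drive z_t to a firing rate
#   y_hat = a + b / (1 + exp(-(z - c)/d))
# with a = y-offset (spikes/bin), b = y-range, c = x-offset, d = width; the
# gain is the slope at the inflection point, b/(4d). Contrast gain control is
# quantified as % compensation of the gain for a change in stimulus contrast
# width, where 100% compensation means the gain halves when contrast doubles.

#' Sigmoid nonlinearity parameters
#'
#' @param a y-offset (spikes/bin).
#' @param b y-range (spikes/bin); must be >= 0 (identifiability: sign flips
#'   of (b, d) give identical curves).
#' @param c x-offset (drive units).
#' @param d width (drive units); must be > 0.
#' @return A `sigmoid_params` with derived field `gain = b/(4d)`.
#' @export
sigmoid_params <- function(a, b, c, d) {
  stopifnot(b >= 0, d > 0, is.finite(a), is.finite(c))
  structure(
    list(a = a, b = b, c = c, d = d, gain = b / (4 * d)),
    class = "sigmoid_params"
  )
}

#' Sigmoid gain
#' @param params A `sigmoid_params`.
#' @return The slope at the inflection point, `b/(4d)` (spikes/bin per drive
#'   unit).
#' @export
sigmoid_gain <- function(params) params$b / (4 * params$d)

#' Evaluate the sigmoid nonlinearity
#'
#' Overflow-safe: uses `plogis` for the logistic term.
#'
#' @param z Drive values.
#' @param params A `sigmoid_params` (or list with a, b, c, d).
#' @return Firing rate `a + b/(1 + exp(-(z - c)/d))`, spikes/bin.
#' @export
sigmoid <- function(z, params) {
  stopifnot(params$d > 0)
  params$a + params$b * stats::plogis((z - params$c) / params$d)
}

# SSE objective and analytic gradient for the sigmoid fit
sigmoid_sse <- function(theta, z, y) {
  s <- stats::plogis((z - theta[3]) / theta[4])
  r <- theta[1] + theta[2] * s
  sum((r - y)^2)
}

sigmoid_sse_grad <- function(theta, z, y) {
  u <- (z - theta[3]) / theta[4]
  s <- stats::plogis(u)
  e <- theta[1] + theta[2] * s - y
  sp <- s * (1 - s)
  c(
    2 * sum(e),
    2 * sum(e * s),
    -2 * theta[2] / theta[4] * sum(e * sp),
    -2 * theta[2] / theta[4] * sum(e * sp * u)
  )
}

#' Fit a sigmoid output nonlinearity by least squares
#'
#' Minimises the squared error between `sigmoid(z)` and `y` over (a, b, c, d)
#' with the constraints b >= 0, d > 0. A deterministic multi-start grid is
#' used: c initialised at the z quantiles 0.1 .. 0.9 and d over decades of
#' the standard deviation of z; the best start wins. The fit is fully
#' deterministic; `seed` is accepted for interface stability but unused.
#'
#' @param z Linear drive (length >= 50, non-constant).
#' @param y Observed rates, spikes/bin.
#' @param seed Unused; the multi-start grid is deterministic.
#' @param c_quantiles Quantiles of `z` used to initialise `c`.
#' @param d_factors Multiples of `sd(z)` used to initialise `d`.
#' @param maxit Iteration cap per start.
#' @return A `sigmoid_params` with fit info in `$fit` (`sse`, `converged`,
#'   `degenerate`).
#' @export
fit_sigmoid <- function(z, y, seed = NULL,
                        c_quantiles = seq(0.1, 0.9, by = 0.1),
                        d_factors = c(0.1, 1, 10), maxit = 500) {
  stopifnot(length(z) == length(y), length(z) >= 50)
  sdz <- stats::sd(z)
  if (!is.finite(sdz) || sdz == 0) stop("z is constant; sigmoid fit undefined")
  if (stats::sd(y) == 0) {
    out <- sigmoid_params(a = y[1], b = 0, c = stats::median(z), d = sdz)
    out$fit <- list(sse = 0, converged = TRUE, degenerate = TRUE)
    return(out)
  }
  a0 <- stats::quantile(y, 0.05, names = FALSE)
  b0 <- max(stats::quantile(y, 0.95, names = FALSE) - a0, 1e-3)
  d_min <- sdz * 1e-4
  lower <- c(-Inf, 0, -Inf, d_min)
  best <- NULL
  for (cq in stats::quantile(z, c_quantiles, names = FALSE)) {
    for (df in d_factors) {
      fit <- tryCatch(
        stats::optim(
          c(a0, b0, cq, sdz * df), sigmoid_sse, sigmoid_sse_grad,
          z = z, y = y, method = "L-BFGS-B", lower = lower,
          control = list(maxit = maxit)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) stop("sigmoid fit failed from every start")
  th <- best$par
  out <- sigmoid_params(a = th[1], b = th[2], c = th[3], d = max(th[4], d_min))
  out$fit <- list(
    sse = best$value, converged = best$convergence == 0, degenerate = FALSE
  )
  out
}

#' Percent compensation of gain for a contrast change
#'
#' `100 * C_low (G_low - G_high) / (G_high (C_high - C_low))`, where C are
#' the uniform-distribution dB widths of the two contrast conditions and G
#' the sigmoid gains. 100% compensation corresponds to a halving of gain when
#' the contrast doubles; 0% to no gain change. Invariant to common rescaling
#' of both gains.
#'
#' @param g_low,g_high Gains in the low- and high-contrast conditions.
#' @param c_low,c_high Contrast widths (dB) of the two conditions.
#' @return Percent compensation; `NA` (with a warning) if `g_high <= 0`.
#' @examples
#' percent_compensation(2, 1, 20, 40) # 100
#' @export
percent_compensation <- function(g_low, g_high, c_low, c_high) {
  stopifnot(c_high != c_low)
  if (!is.finite(g_high) || g_high <= 0) {
    warning("undefined compensation: g_high <= 0")
    return(NA_real_)
  }
  c_low * (g_low - g_high) / (g_high * (c_high - c_low)) * 100
}

#' Percent change between conditions
#'
#' `100 * (v_high - v_low) / v_low`: the change in the high-contrast value
#' relative to the low-contrast value (used e.g. for y-offset adaptation).
#'
#' @param v_high,v_low Values in the high- and low-contrast conditions.
#' @return Percent change; `NA` (with a warning) if `v_low == 0`.
#' @export
percent_change <- function(v_high, v_low) {
  if (!is.finite(v_low) || v_low == 0) {
    warning("undefined percent change: v_low is zero")
    return(NA_real_)
  }
  (v_high - v_low) / v_low * 100
}

#' Fit per-condition output nonlinearities on a shared drive
#'
#' Fits one sigmoid per condition to the bins belonging to that condition,
#' on a single shared linear drive (one overall STRF). For a two-condition
#' contrast design the summary carries the Eq.-style gain compensation and
#' the y-offset percent change; for a contrast x cortex-state design (four
#' conditions) the per-state metrics plus the silencing effect (% gain change
#' with cortex silenced minus % gain change with cortex intact) are returned.
#'
#' @param z Shared linear drive per bin.
#' @param y Observed rate per bin (spikes/bin).
#' @param contrast Per-bin contrast labels ("low"/"high").
#' @param state Optional per-bin cortex-state labels (e.g. "on"/"off").
#' @param widths Named contrast widths in dB, `c(low = , high = )`.
#' @param min_bins Conditions with fewer bins are excluded with a flag.
#' @return List: `fits` (data frame of per-condition a, b, c, d, gain,
#'   n_bins), `summary` (compensation, y-offset change, and silencing effect
#'   when `state` is given), `excluded` condition labels.
#' @export
fit_conditions <- function(z, y, contrast, state = NULL,
                           widths = c(low = 20, high = 40), min_bins = 50) {
  stopifnot(length(z) == length(y), length(contrast) == length(y))
  if (is.null(state)) state <- rep("all", length(y))
  key <- interaction(contrast, state, drop = TRUE, sep = "|")
  fits <- list()
  excluded <- character(0)
  for (k in levels(key)) {
    idx <- key == k
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (sum(idx) < min_bins) {
      excluded <- c(excluded, k)
      next
    }
    p <- fit_sigmoid(z[idx], y[idx])
    fits[[k]] <- data.frame(
      contrast = parts[1], state = parts[2],
      a = p$a, b = p$b, c = p$c, d = p$d, gain = p$gain,
      n_bins = sum(idx)
    )
  }
  fits <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  states <- unique(fits$state)
  per_state <- lapply(states, function(s) {
    lo <- fits[fits$contrast == "low" & fits$state == s, ]
    hi <- fits[fits$contrast == "high" & fits$state == s, ]
    if (nrow(lo) != 1 || nrow(hi) != 1) {
      return(list(compensation = NA_real_, y_offset_change = NA_real_,
                  gain_change = NA_real_))
    }
    list(
      compensation = percent_compensation(
        lo$gain, hi$gain, widths[["low"]], widths[["high"]]
      ),
      y_offset_change = percent_change(hi$a, lo$a),
      gain_change = percent_change(hi$gain, lo$gain)
    )
  })
  names(per_state) <- states
  summary <- list(per_state = per_state)
  if (length(states) == 1L) {
    summary$compensation <- per_state[[1]]$compensation
    summary$y_offset_change <- per_state[[1]]$y_offset_change
  }
  if (all(c("on", "off") %in% states)) {
    summary$silencing_effect <-
      per_state[["off"]]$gain_change - per_state[["on"]]$gain_change
  }
  list(fits = fits, summary = summary, excluded = excluded)
}
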
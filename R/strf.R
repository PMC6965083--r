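# Separable spectro-temporal receptive fields (STRFs).
#
# A separable STRF factorises the full kernel k_fh into a spectral kernel k_f
# (one weight per frequency channel) and a temporal kernel k_h (one weight
# per 25-ms history bin, h = 0 .. n_history-1), k_fh = k_f %o% k_h, plus a
# bias. Canonical form: k_h has unit L2 norm and a non-negative peak; scale
# and sign are carried by k_f, making the factorisation unique.

#' Separable STRF
#'
#' @param k_f Spectral kernel, one weight per frequency channel.
#' @param k_h Temporal kernel, one weight per 25-ms history bin (h = 0 is the
#'   current chord; strictly causal).
#' @param bias Output offset (drive units, spikes/bin for a linear model).
#' @param canonical If `TRUE` (default), return in canonical form.
#' @return A `separable_strf`.
#' @export
separable_strf <- function(k_f, k_h, bias = 0, canonical = TRUE) {
  stopifnot(length(k_f) >= 1, length(k_h) >= 1, is.finite(bias))
  s <- structure(
    list(
      k_f = as.numeric(k_f), k_h = as.numeric(k_h), bias = bias,
      n_history = length(k_h)
    ),
    class = "separable_strf"
  )
  if (canonical) canonicalize_strf(s) else s
}

#' Canonicalize a separable STRF
#'
#' Rescales so the temporal kernel has unit L2 norm and its largest-magnitude
#' element is positive; the scale and sign move into the spectral kernel.
#' Idempotent; predictions are unchanged.
#'
#' @param strf A `separable_strf`.
#' @return The canonical `separable_strf`.
#' @export
canonicalize_strf <- function(strf) {
  nrm <- sqrt(sum(strf$k_h^2))
  if (nrm == 0) {
    strf$k_f <- strf$k_f * 0
    return(strf)
  }
  k_h <- strf$k_h / nrm
  k_f <- strf$k_f * nrm
  if (k_h[which.max(abs(k_h))] < 0) {
    k_h <- -k_h
    k_f <- -k_f
  }
  strf$k_f <- k_f
  strf$k_h <- k_h
  strf
}

#' Full STRF kernel
#' @param strf A `separable_strf`.
#' @return Matrix n_freqs x n_history, `k_f %o% k_h`.
#' @export
strf_kernel <- function(strf) outer(strf$k_f, strf$k_h)

# T x (F*H) lagged design matrix, column order f fastest within h.
# History beyond the stimulus start is padded by replicating the first chord
# (neutral continuation of the stationary stimulus statistics).
lagged_design <- function(levels, n_history) {
  n_t <- nrow(levels)
  out <- matrix(0, n_t, ncol(levels) * n_history)
  for (h in seq_len(n_history) - 1L) {
    rows <- pmax(1L, seq_len(n_t) - h)
    out[, h * ncol(levels) + seq_len(ncol(levels))] <- levels[rows, , drop = FALSE]
  }
  out
}

stimulus_levels <- function(stimulus) {
  if (inherits(stimulus, c("drc_stimulus", "trial_stimulus"))) {
    return(stimulus$levels)
  }
  stopifnot(is.matrix(stimulus))
  stimulus
}

#' Linear drive predicted by a separable STRF
#'
#' Computes the causal linear prediction
#' `z_t = bias + sum_f sum_h k_f(f) k_h(h) L(t-h, f)`.
#'
#' @param strf A `separable_strf`.
#' @param stimulus A `drc_stimulus`, `trial_stimulus`, or dB-level matrix
#'   (time x frequency).
#' @return Numeric vector `z_t`, one value per chord.
#' @export
predict_linear <- function(strf, stimulus) {
  levels <- stimulus_levels(stimulus)
  if (inherits(stimulus, c("drc_stimulus", "trial_stimulus")) &&
      ncol(levels) != length(strf$k_f)) {
    stop("stimulus frequency grid does not match the STRF's spectral kernel")
  }
  stopifnot(ncol(levels) == length(strf$k_f))
  x <- lagged_design(levels, strf$n_history)
  drop(x %*% as.numeric(outer(strf$k_f, strf$k_h))) + strf$bias
}

# ridge-regularised LS solve of y ~ X (intercept unpenalised)
ridge_ls <- function(x, y, ridge) {
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  xtx <- crossprod(xc)
  lambda <- ridge * mean(diag(xtx))
  if (lambda > 0) xtx <- xtx + diag(lambda, ncol(x))
  beta <- tryCatch(
    solve(xtx, crossprod(xc, y - ym)),
    error = function(e) {
      # rank-deficient design: fall back to a stronger ridge
      warning("rank-deficient design; using ridge fallback")
      solve(xtx + diag(mean(diag(xtx)) * 1e-2 + 1e-12, ncol(x)),
            crossprod(xc, y - ym))
    }
  )
  list(beta = drop(beta), bias = ym - sum(xm * beta))
}

#' Fit a separable STRF by alternating least squares
#'
#' Maximum-likelihood fit under a Gaussian noise model (squared prediction
#' error), alternating closed-form updates of the spectral and temporal
#' kernels until the relative change in training error falls below `tol` or
#' `max_iter` iterations. A small ridge penalty (relative to the design norm)
#' keeps the subproblems well conditioned; this deviates slightly from pure
#' maximum likelihood and is configurable.
#'
#' @param stimulus `drc_stimulus` or dB-level matrix (time x frequency).
#' @param psth Numeric response vector (mean spikes/bin across repeats), or a
#'   `unit_response` (its repeat-averaged PSTH is used).
#' @param n_history History length in 25-ms bins (default 10 = 250 ms).
#' @param ridge Relative ridge penalty (default 1e-3).
#' @param max_iter,tol Convergence controls.
#' @param exclude_ms Initial response window to exclude from the fit (the
#'   onset-exclusion rule; the stimulus history of retained bins is kept).
#' @return A canonical `separable_strf` with fit diagnostics in
#'   `$fit` (`train_mse` trace, `iterations`, `converged`).
#' @export
fit_separable_strf <- function(stimulus, psth, n_history = 10, ridge = 1e-3,
                               max_iter = 200, tol = 1e-6, exclude_ms = 0) {
  levels <- stimulus_levels(stimulus)
  if (inherits(psth, "unit_response")) psth <- psth_of(psth)
  stopifnot(length(psth) == nrow(levels), n_history >= 1)
  n_t <- nrow(levels)
  n_f <- ncol(levels)
  keep <- seq_len(n_t)
  if (exclude_ms > 0) {
    drop_bins <- as.integer(round(exclude_ms / CHORD_MS))
    stopifnot(drop_bins < n_t)
    keep <- (drop_bins + 1L):n_t
  }
  x <- lagged_design(levels, n_history)[keep, , drop = FALSE]
  y <- psth[keep]
  if (all(y == 0)) {
    out <- separable_strf(rep(0, n_f), c(1, rep(0, n_history - 1L)), 0)
    out$fit <- list(train_mse = 0, iterations = 0L, converged = TRUE)
    return(out)
  }
  # x reshaped views: columns are f within h
  x3 <- array(x, dim = c(length(keep), n_f, n_history))
  k_h <- exp(-(seq_len(n_history) - 1) / 2)
  k_h <- k_h / sqrt(sum(k_h^2))
  bias <- mean(y)
  k_f <- rep(0, n_f)
  mse <- rep(NA_real_, max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  tfm <- matrix(x, nrow = length(keep) * n_f) # (T*F) x H
  for (it in seq_len(max_iter)) {
    u <- matrix(tfm %*% k_h, nrow = length(keep)) # T x F
    sol_f <- ridge_ls(u, y, ridge)
    k_f <- sol_f$beta
    v <- apply(x3, 3, function(m) m %*% k_f) # T x H
    sol_h <- ridge_ls(v, y, ridge)
    k_h <- sol_h$beta
    bias <- sol_h$bias
    pred <- drop(v %*% k_h) + bias
    mse[it] <- mean((y - pred)^2)
    if (is.finite(prev) && abs(prev - mse[it]) <= tol * max(prev, 1e-12)) {
      converged <- TRUE
      prev <- mse[it]
      break
    }
    prev <- mse[it]
  }
  out <- separable_strf(k_f, k_h, bias)
  out$fit <- list(
    train_mse = mse[seq_len(it)], iterations = it, converged = converged
  )
  out
}

# linear interpolation FWHM of a sampled kernel around its peak.
# Returns width in sample units plus a truncation flag when the half-max is
# never crossed on one side (width then extends to the kernel edge).
fwhm_samples <- function(k) {
  m <- which.max(k)
  peak <- k[m]
  if (peak <= 0) {
    return(list(width = NA_real_, truncated = NA, valid = FALSE))
  }
  half <- peak / 2
  truncated <- FALSE
  # rightward crossing
  right <- length(k) - m
  if (m < length(k)) {
    for (i in (m + 1):length(k)) {
      if (k[i] < half) {
        right <- (i - 1 - m) + (k[i - 1] - half) / (k[i - 1] - k[i])
        break
      }
      if (i == length(k)) truncated <- TRUE
    }
  } else if (length(k) > 1) {
    truncated <- TRUE
  }
  left <- m - 1
  if (m > 1) {
    for (i in (m - 1):1) {
      if (k[i] < half) {
        left <- (m - i - 1) + (k[i + 1] - half) / (k[i + 1] - k[i])
        break
      }
      if (i == 1) truncated <- TRUE
    }
  } else if (length(k) > 1) {
    truncated <- TRUE
  }
  if (length(k) == 1L) {
    # single-sample kernel: one-bin floor
    return(list(width = 1, truncated = FALSE, valid = TRUE))
  }
  list(width = left + right, truncated = truncated, valid = TRUE)
}

#' Extract STRF tuning parameters
#'
#' Best frequency (BF) is the grid frequency at the largest value of the
#' spectral kernel; frequency bandwidth (fBW) is the full-width half-maximum
#' of the spectral kernel in octaves (linear interpolation between channels);
#' temporal bandwidth (tBW) is the FWHM of the temporal kernel in ms (with a
#' one-bin floor at the 25-ms resolution); max weight is the largest value of
#' the full kernel.
#'
#' @param strf A canonical `separable_strf`.
#' @param grid The stimulus [make_frequency_grid()].
#' @return List: `best_frequency` (Hz), `freq_bandwidth` (octaves),
#'   `temporal_bandwidth` (ms), `max_weight`, plus truncation/validity flags.
#' @export
extract_strf_params <- function(strf, grid) {
  strf <- canonicalize_strf(strf)
  stopifnot(length(strf$k_f) == length(grid$frequencies))
  if (max(strf$k_f) <= 0) {
    return(list(
      best_frequency = NA_real_, freq_bandwidth = NA_real_,
      temporal_bandwidth = NA_real_, max_weight = NA_real_,
      valid = FALSE, fbw_truncated = NA, tbw_truncated = NA
    ))
  }
  ff <- fwhm_samples(strf$k_f)
  ft <- fwhm_samples(strf$k_h)
  tbw <- if (ft$valid) max(ft$width, 1) * CHORD_MS else NA_real_
  list(
    best_frequency = grid$frequencies[which.max(strf$k_f)],
    freq_bandwidth = ff$width / grid$steps_per_octave,
    temporal_bandwidth = tbw,
    max_weight = max(strf_kernel(strf)),
    valid = TRUE,
    fbw_truncated = isTRUE(ff$truncated),
    tbw_truncated = isTRUE(ft$truncated)
  )
}

#' Compare a combined STRF against per-condition STRFs
#'
#' Fits (i) a single STRF to all conditions and (ii) one STRF per condition,
#' each on the first `train_frac` of that condition's bins, and evaluates the
#' cross-validated prediction correlation (`cc_pred`) within condition on the
#' held-out bins. Returns per-condition correlations for both schemes and
#' their paired differences.
#'
#' @param stimulus `drc_stimulus` or level matrix.
#' @param response A `unit_response` whose per-bin `contrast` labels define
#'   the conditions (at least 2 required).
#' @param train_frac Fraction of each condition's bins used for training
#'   (contiguous leading block; default 0.9).
#' @inheritParams fit_separable_strf
#' @return List: `per_condition` data frame (condition, cc_combined,
#'   cc_split), `difference` (combined minus split, per condition).
#' @export
compare_combined_vs_split <- function(stimulus, response, train_frac = 0.9,
                                      n_history = 10, ridge = 1e-3,
                                      exclude_ms = 0) {
  levels <- stimulus_levels(stimulus)
  y <- psth_of(response)
  cond <- response$contrast
  stopifnot(length(y) == nrow(levels), length(cond) == length(y))
  conds <- unique(cond)
  if (length(conds) < 2L) {
    stop("at least two conditions are required to compare fitting schemes")
  }
  keep <- rep(TRUE, length(y))
  if (exclude_ms > 0) keep[seq_len(round(exclude_ms / CHORD_MS))] <- FALSE
  train <- rep(FALSE, length(y))
  test <- rep(FALSE, length(y))
  for (cc in conds) {
    idx <- which(cond == cc & keep)
    n_tr <- floor(length(idx) * train_frac)
    if (n_tr < 1 || n_tr >= length(idx)) {
      stop("insufficient data in condition '", cc, "' for a train/test split")
    }
    train[idx[seq_len(n_tr)]] <- TRUE
    test[idx[(n_tr + 1):length(idx)]] <- TRUE
  }
  mask_fit <- function(sel) {
    yy <- y
    yy[!sel] <- NA
    # fit on selected bins only: subset the design through a weighted trick
    # (drop rows); lagged design is built on the full stimulus so history is
    # preserved for every retained bin
    x <- lagged_design(levels, n_history)
    fit_strf_rows(x, y, sel, ncol(levels), n_history, ridge)
  }
  fit_all <- mask_fit(train)
  res <- data.frame(
    condition = conds, cc_combined = NA_real_, cc_split = NA_real_
  )
  x_full <- lagged_design(levels, n_history)
  for (i in seq_along(conds)) {
    sel_tr <- train & cond == conds[i]
    sel_te <- test & cond == conds[i]
    fit_c <- fit_strf_rows(x_full, y, sel_tr, ncol(levels), n_history, ridge)
    z_all <- drop(x_full %*% as.numeric(outer(fit_all$k_f, fit_all$k_h))) + fit_all$bias
    z_c <- drop(x_full %*% as.numeric(outer(fit_c$k_f, fit_c$k_h))) + fit_c$bias
    res$cc_combined[i] <- stats::cor(z_all[sel_te], y[sel_te])
    res$cc_split[i] <- stats::cor(z_c[sel_te], y[sel_te])
  }
  list(per_condition = res, difference = res$cc_combined - res$cc_split)
}

# alternating separable fit on a row subset of a prebuilt lagged design
fit_strf_rows <- function(x, y, sel, n_f, n_history, ridge,
                          max_iter = 200, tol = 1e-6) {
  xs <- x[sel, , drop = FALSE]
  ys <- y[sel]
  x3 <- array(xs, dim = c(nrow(xs), n_f, n_history))
  tfm <- matrix(xs, nrow = nrow(xs) * n_f)
  k_h <- exp(-(seq_len(n_history) - 1) / 2)
  k_h <- k_h / sqrt(sum(k_h^2))
  prev <- Inf
  k_f <- rep(0, n_f)
  bias <- mean(ys)
  for (it in seq_len(max_iter)) {
    u <- matrix(tfm %*% k_h, nrow = nrow(xs))
    sol_f <- ridge_ls(u, ys, ridge)
    k_f <- sol_f$beta
    v <- apply(x3, 3, function(m) m %*% k_f)
    sol_h <- ridge_ls(v, ys, ridge)
    k_h <- sol_h$beta
    bias <- sol_h$bias
    mse <- mean((ys - drop(v %*% k_h) - bias)^2)
    if (is.finite(prev) && abs(prev - mse) <= tol * max(prev, 1e-12)) break
    prev <- mse
  }
  separable_strf(k_f, k_h, bias)
}
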
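# Contrast-state filtering and the adaptive contrast-dependent LN model

test_that("the smoothed contrast state has the stated limits and bounds", {
  # constant contrast: state pinned at the indicator value
  expect_equal(contrast_filter(rep(1, 50), tau_ms = 100), rep(1, 50))
  expect_equal(contrast_filter(rep(0, 50), tau_ms = 100), rep(0, 50))

  # tau -> 0: instantaneous tracking
  c_t <- rep(c(0, 1), each = 40)
  expect_equal(contrast_filter(c_t, tau_ms = 0.5), c_t, tolerance = 1e-9)

  # step response reaches 1 - exp(-1) about tau after the switch
  s <- contrast_filter(c_t, tau_ms = 100)
  # 4 bins (100 ms) after the 0 -> 1 step at bin 41
  expect_lt(abs(s[44] - 0.632), 0.08)

  # bounded in [0, 1] for arbitrary tracks and taus
  set.seed(1)
  for (tau in c(5, 60, 700)) {
    s <- contrast_filter(rbinom(200, 1, 0.5), tau)
    expect_all_within(s, 0, 1)
  }
})

test_that("adaptive predictions reduce to static LN at the fixed points", {
  g <- test_grid()
  u <- test_unit(seed = 2, tau_ms = 150)
  # equal parameter sets: prediction independent of tau and track
  u_eq <- u
  u_eq$params_high <- u_eq$params_low
  sw <- generate_switching_drc(g, 20, 40, 2, 8, seed = 3)
  z <- predict_linear(u_eq$strf, sw)
  expect_equal(adaptive_predict(u_eq, sw), sigmoid(z, u_eq$params_low))

  # constant high contrast equals the static high-contrast prediction
  dh <- generate_drc(g, contrast_regime(40, 40, "high"), 200, seed = 4)
  expect_equal(adaptive_predict(u, dh),
               sigmoid(predict_linear(u$strf, dh), u$params_high))

  # brute-force per-bin oracle on a switching stimulus
  s <- contrast_filter(as.numeric(sw$contrast_track == "high"), u$tau_ms)
  zz <- predict_linear(u$strf, sw)
  ref <- vapply(seq_along(zz), function(t) {
    pars <- list(
      a = u$params_low$a + (u$params_high$a - u$params_low$a) * s[t],
      b = u$params_low$b + (u$params_high$b - u$params_low$b) * s[t],
      c = u$params_low$c + (u$params_high$c - u$params_low$c) * s[t],
      d = u$params_low$d + (u$params_high$d - u$params_low$d) * s[t]
    )
    sigmoid(zz[t], pars)
  }, numeric(1))
  expect_equal(adaptive_predict(u, sw), ref)
})

test_that("as tau shrinks the adaptive model matches the instantaneous one", {
  g <- test_grid()
  u <- test_unit(seed = 5, tau_ms = 1)
  sw <- generate_switching_drc(g, 20, 40, 2, 8, seed = 6)
  r_adapt <- adaptive_predict(u, sw)
  c_t <- as.numeric(sw$contrast_track == "high")
  z <- predict_linear(u$strf, sw)
  r_low <- sigmoid(z, u$params_low)
  r_high <- sigmoid(z, u$params_high)
  r_inst <- ifelse(c_t == 1, r_high, r_low)
  expect_lt(max(abs(r_adapt - r_inst)), 1e-9)
})

test_that("adaptive fits recover the time constant from switching data", {
  g <- test_grid()
  sw <- generate_switching_drc(g, 20, 40, 2, 40, seed = 7)
  for (tau_true in c(150, 400)) {
    u <- test_unit(seed = round(tau_true), tau_ms = tau_true)
    r <- simulate_unit_response(u, sw, 40, seed = round(tau_true) + 1)
    fit <- fit_adaptive_ln(sw, r)
    expect_lt(abs(fit$tau_ms - tau_true) / tau_true, 0.3)
    expect_false(fit$fit$cap_hit)
  }
})

test_that("tau estimation error shrinks with repeat count", {
  g <- test_grid()
  sw <- generate_switching_drc(g, 20, 40, 2, 40, seed = 8)
  tau_true <- 200
  err_at <- function(n_rep) {
    errs <- vapply(1:3, function(i) {
      u <- test_unit(seed = 60 + i, tau_ms = tau_true)
      r <- simulate_unit_response(u, sw, n_rep, seed = 70 + i)
      abs(fit_adaptive_ln(sw, r)$tau_ms - tau_true)
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(40), err_at(10) + 15) # allow small Monte-Carlo slack
})

test_that("identical parameter sets make tau unidentifiable but harmless", {
  g <- test_grid()
  u <- test_unit(seed = 9)
  u$params_high <- u$params_low
  sw <- generate_switching_drc(g, 20, 40, 2, 20, seed = 10)
  r <- simulate_unit_response(u, sw, 20, seed = 11)
  fit <- fit_adaptive_ln(sw, r)
  # the fit is flagged and prediction quality is unaffected by tau
  expect_true(fit$fit$tau_unidentifiable)
  alt <- fit
  alt$tau_ms <- 600
  cc1 <- cor(adaptive_predict(fit, sw), psth_of(r))
  cc2 <- cor(adaptive_predict(alt, sw), psth_of(r))
  expect_lt(abs(cc1 - cc2), 0.02)

  # a genuinely adapting unit is not flagged
  u2 <- test_unit(seed = 12, tau_ms = 200)
  r2 <- simulate_unit_response(u2, sw, 20, seed = 13)
  expect_false(fit_adaptive_ln(sw, r2)$fit$tau_unidentifiable)
})

test_that("model selection flags adapting units and spares non-adapting ones", {
  g <- test_grid()
  sw <- generate_switching_drc(g, 20, 40, 2, 40, seed = 12)
  run_flags <- function(pop, seed0) {
    vapply(seq_along(pop), function(i) {
      r <- simulate_unit_response(pop[[i]], sw, 40, seed = seed0 + i)
      m <- model_selection(sw, r)
      c(m$contrast_dependent_better, m$tau_improves)
    }, logical(2))
  }
  # slow-adapting truth: both flags raised in the majority
  slow <- run_flags(make_population(4, 100, g, seed = 13, tau_ms = 400), 80)
  expect_gte(sum(slow[1, ]), 3)
  expect_gte(sum(slow[2, ]), 3)

  # non-adapting truth: the contrast-dependence flag stays down mostly
  none <- run_flags(make_population(4, 0, g, seed = 14), 90)
  expect_lte(sum(none[1, ]), 1)

  # adaptation completed within one chord: tau rarely helps
  fast <- run_flags(make_population(4, 100, g, seed = 15, tau_ms = 5), 95)
  expect_gte(sum(fast[1, ]), 3) # contrast dependence is real
  expect_lt(sum(fast[2, ]), sum(slow[2, ])) # but tau adds less than for slow
})
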
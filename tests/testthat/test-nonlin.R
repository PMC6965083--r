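# Sigmoid nonlinearities, gain and compensation metrics

test_that("the sigmoid has the stated midpoint, asymptotes and slope", {
  p <- sigmoid_params(a = 1, b = 4, c = 2, d = 0.5)
  expect_equal(sigmoid(2, p), 1 + 2) # midpoint a + b/2
  expect_equal(sigmoid(1e6, p), 5) # upper asymptote a + b
  expect_equal(sigmoid(-1e6, p), 1) # lower asymptote a
  # overflow-safe far into both tails
  expect_true(is.finite(sigmoid(1e12, p)) && is.finite(sigmoid(-1e12, p)))

  # slope at the inflection equals b/(4d)
  p2 <- sigmoid_params(a = 0, b = 4, c = 0, d = 1)
  h <- 1e-6
  slope <- (sigmoid(h, p2) - sigmoid(-h, p2)) / (2 * h)
  expect_equal(slope, 1, tolerance = 1e-6)
  expect_equal(sigmoid_gain(p2), 1)
})

test_that("sigmoid fitting recovers parameters and handles degenerate input", {
  set.seed(1)
  z <- rnorm(2000)
  p_true <- sigmoid_params(0.4, 3, 0.3, 0.7)

  # noiseless self-consistency to 1e-4 relative
  fit <- fit_sigmoid(z, sigmoid(z, p_true))
  for (nm in c("a", "b", "c", "d")) {
    expect_lt(abs(fit[[nm]] - p_true[[nm]]) / abs(p_true[[nm]]), 1e-4)
  }

  # constant responses: a ~ y, b ~ 0, flagged
  fitc <- fit_sigmoid(z, rep(3, 2000))
  expect_equal(fitc$a, 3)
  expect_equal(fitc$b, 0)
  expect_true(fitc$fit$degenerate)

  # Poisson noise at 1e4 bins: gain within 5%
  set.seed(2)
  z2 <- rnorm(1e4)
  y2 <- rpois(1e4, pmax(0, sigmoid(z2, p_true)))
  fit2 <- fit_sigmoid(z2, y2)
  expect_lt(abs(fit2$gain - p_true$gain) / p_true$gain, 0.05)

  expect_error(fit_sigmoid(rep(1, 100), rpois(100, 1)), "constant")
})

test_that("gain compensation identities are floating-point exact", {
  expect_identical(percent_compensation(2, 1, 20, 40), 100)
  expect_identical(percent_compensation(1.5, 1.5, 20, 40), 0)
  expect_equal(percent_compensation(1.5, 1, 20, 40), 50)
  # invariance to common gain rescaling
  expect_equal(percent_compensation(2e-3, 1e-3, 20, 40), 100)
  expect_true(is.na(suppressWarnings(percent_compensation(1, 0, 20, 40))))

  expect_equal(percent_change(1.5, 1), 50)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(0.815, 1), -18.5)
  expect_true(is.na(suppressWarnings(percent_change(1, 0))))
})

test_that("fitted gain is invariant to affine rescaling of the drive", {
  set.seed(3)
  z <- rnorm(3000)
  p_true <- sigmoid_params(0.5, 3, 0, 1)
  y <- sigmoid(z, p_true)
  g1 <- fit_sigmoid(z, y)$gain
  g2 <- fit_sigmoid(5 * z + 2, y)$gain
  # c, d absorb the affine map; gain in original units scales by 1/5
  expect_equal(g2 * 5, g1, tolerance = 1e-3)
})

test_that("per-condition fits recover contrast metrics from populations", {
  g <- test_grid()
  regs <- mouse_regimes()
  dl <- generate_drc(g, regs$low, 1200, seed = 1)
  dh <- generate_drc(g, regs$high, 1200, seed = 2)
  levels_all <- rbind(dl$levels, dh$levels)
  track <- c(dl$contrast_track, dh$contrast_track)
  mask <- rep(c(rep(FALSE, 20), rep(TRUE, 1180)), 2)

  run_unit <- function(u, i) {
    lo <- simulate_unit_response(u, dl, 20, seed = 100 + i)
    hi <- simulate_unit_response(u, dh, 20, seed = 200 + i)
    y <- c(psth_of(lo), psth_of(hi))
    strf <- fit_separable_strf(levels_all, y)
    z <- predict_linear(strf, levels_all)
    fit_conditions(z[mask], y[mask], track[mask])
  }

  # 100% compensation truth
  pop <- make_population(8, 100, g, seed = 3)
  comps <- vapply(seq_along(pop), function(i) {
    run_unit(pop[[i]], i)$summary$compensation
  }, numeric(1))
  expect_lt(abs(median(comps) - 100), 10)

  # y-offset adaptation, truth a_high = 0.8 a_low: ~ -20% change
  popy <- lapply(seq_len(8), function(i) {
    u <- make_population(8, 100, g, seed = 4)[[i]]
    u$params_low <- sigmoid_params(1.5, 3, u$params_low$c, u$params_low$d)
    u$params_high <- sigmoid_params(1.2, 3, u$params_high$c, u$params_high$d)
    u
  })
  yoffs <- vapply(seq_along(popy), function(i) {
    run_unit(popy[[i]], 50 + i)$summary$y_offset_change
  }, numeric(1))
  expect_lt(abs(median(yoffs) - (-20)), 10)
})

test_that("four-condition designs yield a zero silencing effect when identical", {
  set.seed(5)
  z <- rnorm(4000)
  p <- sigmoid_params(0.5, 3, 0, 1)
  y <- sigmoid(z, p)
  contrast <- rep(c("low", "high"), 2000)
  state <- rep(c("on", "off"), each = 2000)
  fc <- fit_conditions(z, y, contrast, state)
  expect_equal(nrow(fc$fits), 4)
  expect_lt(abs(fc$summary$silencing_effect), 1)
  # conditions with too few bins are excluded with a flag
  fc2 <- fit_conditions(z[1:120], y[1:120], contrast[1:120],
                        c(rep("on", 100), rep("off", 20)))
  expect_true(length(fc2$excluded) > 0)
})
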
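# PSTH binning, onset exclusion, reliability statistics, screening

test_that("spikes fall into half-open 25-ms bins", {
  r <- bin_psth(list(c(30)), n_bins = 4)
  expect_equal(as.numeric(r$counts), c(0, 1, 0, 0))
  # boundary spike at exactly 25.0 ms goes to the second bin
  r2 <- bin_psth(list(c(25.0)), n_bins = 4)
  expect_equal(as.numeric(r2$counts), c(0, 1, 0, 0))
  # empty trains give all-zero rows
  r3 <- bin_psth(list(numeric(0), c(0, 10, 99.9)), n_bins = 4)
  expect_equal(rowSums(r3$counts), c(0, 3))
  expect_error(bin_psth(list(c(100)), n_bins = 4), "within")
  # uniform 40 Hz train over 10 s -> 1 spike/bin
  r4 <- bin_psth(list(seq(0, 9999.9, by = 25)), n_bins = 400)
  expect_equal(mean(r4$counts), 1.0)
})

test_that("onset exclusion removes the leading window from both sides", {
  counts <- matrix(rpois(2 * 1600, 1), nrow = 2)
  r <- unit_response(counts, contrast = rep("low", 1600))
  r2 <- exclude_onset(r, 500)
  expect_equal(ncol(r2$counts), 1580)
  expect_equal(r2$counts, counts[, -(1:20)])
  # 5-s trials lose the same 20 bins
  r5 <- unit_response(matrix(0, 2, 200))
  expect_equal(ncol(exclude_onset(r5, 500)$counts), 180)
  # identity at zero and rejection when too short
  expect_identical(exclude_onset(r, 0), r)
  expect_error(exclude_onset(unit_response(matrix(0, 2, 10)), 500), "longer")
  # stimulus side
  d <- generate_drc(test_grid(), contrast_regime(20, 40, "low"), 100,
                    seed = 1)
  d2 <- exclude_onset(d, 500)
  expect_equal(nrow(d2$levels), 80)
  expect_equal(d2$levels, d$levels[-(1:20), ])
})

test_that("signal/noise power estimator identities hold exactly", {
  # identical repeats: NP = 0, SP = power of a single trial
  trial <- rpois(200, 2)
  r <- unit_response(rbind(trial, trial, trial))
  snp <- signal_noise_power(r)
  pow <- function(x) mean((x - mean(x))^2)
  expect_equal(snp$noise_power, 0)
  expect_equal(snp$signal_power, pow(trial))

  # SP + NP = mean trial power on arbitrary inputs
  set.seed(1)
  for (i in 1:10) {
    counts <- matrix(rpois(5 * 100, runif(1, 0.5, 3)), nrow = 5)
    s <- signal_noise_power(unit_response(counts))
    expect_equal(s$signal_power + s$noise_power,
                 mean(apply(counts, 1, pow)))
  }
  expect_error(signal_noise_power(unit_response(matrix(0, 1, 10))),
               "repeats")
})

test_that("SP is invariant to trial order and unbiased in simulation", {
  set.seed(2)
  counts <- matrix(rpois(6 * 300, 1.5), nrow = 6)
  s1 <- signal_noise_power(unit_response(counts))
  s2 <- signal_noise_power(unit_response(counts[sample(6), ]))
  expect_equal(s1$signal_power, s2$signal_power)

  # flat-rate responses: SP -> 0 on average (signed estimates preserved)
  set.seed(3)
  sps <- replicate(300, {
    signal_noise_power(
      unit_response(matrix(rpois(4 * 100, 2), nrow = 4))
    )$signal_power
  })
  expect_true(any(sps < 0)) # negative estimates are not clamped
  expect_lt(abs(mean(sps)), 3 * sd(sps) / sqrt(length(sps)))

  # Poisson counts around a structured PSTH: SP -> power of the true PSTH
  set.seed(4)
  rate <- 1.5 + sin(seq_len(400) / 5)
  pow <- function(x) mean((x - mean(x))^2)
  sps2 <- replicate(100, {
    counts <- matrix(rpois(10 * 400, rep(rate, each = 10)), nrow = 10)
    signal_noise_power(unit_response(counts))$signal_power
  })
  expect_lt(abs(mean(sps2) - pow(rate)), 4 * sd(sps2) / sqrt(length(sps2)))
})

test_that("screening applies the NP/SP and cc_pred rules with reasons", {
  stats <- data.frame(
    unit = 1:5,
    signal_power = c(1, 1, 1, 0, 1),
    noise_power = c(60, 61, 5, 5, 5),
    cc_pred = c(0.5, 0.5, 0.09, 0.5, 0.5)
  )
  out <- screen_units(stats)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$reason[2], "np_sp_above_max") # strict > 60 excludes
  expect_equal(out$reason[3], "cc_pred_below_min") # < 0.1 excludes
  expect_equal(out$reason[4], "nonpositive_sp")

  # monotonicity: lowering the threshold never admits an excluded unit
  for (thr in c(60, 30, 10, 0)) {
    prev <- screen_units(stats, np_sp_max = thr)$retained
    tighter <- screen_units(stats, np_sp_max = thr / 2)$retained
    expect_true(all(prev | !tighter))
  }
})

test_that("cross-validated prediction correlation screens real structure", {
  g <- test_grid()
  u <- test_unit(seed = 10)
  d <- generate_drc(g, contrast_regime(20, 40, "low"), 3200, seed = 11)
  r <- simulate_unit_response(u, d, 10, seed = 12)
  cc <- prediction_cc(d, r)$cc_pred
  expect_gt(cc, 0.5)
  # shuffled responses carry no predictable structure: held-out cc is chance
  # level, far below both the real unit's cc and the screening threshold
  set.seed(13)
  shuf <- unit_response(r$counts[, sample(ncol(r$counts))])
  cc_shuf <- prediction_cc(d, shuf)$cc_pred
  expect_lt(cc_shuf, 0.15)
  expect_lt(cc_shuf, cc / 2)
})
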
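# Separable STRF fitting and parameter extraction

test_that("canonical form is unique, idempotent and prediction-invariant", {
  strf <- separable_strf(c(1, 2, 3), c(-2, -1, 0.5), bias = 0.3,
                         canonical = FALSE)
  can <- canonicalize_strf(strf)
  expect_equal(sqrt(sum(can$k_h^2)), 1)
  expect_gt(can$k_h[which.max(abs(can$k_h))], 0)
  expect_equal(canonicalize_strf(can), can)
  expect_equal(strf_kernel(can), strf_kernel(strf))

  # predictions invariant to how scale is split between the kernels
  g <- test_grid()
  d <- generate_drc(g, contrast_regime(20, 40, "low"), 100, seed = 1)
  a <- separable_strf(rnorm(13), rnorm(5), bias = 0.1)
  b <- a
  b$k_f <- a$k_f * 4
  b$k_h <- a$k_h / 4
  expect_equal(predict_linear(a, d), predict_linear(canonicalize_strf(b), d))
})

test_that("linear prediction matches a brute-force convolution oracle", {
  g <- test_grid()
  d <- generate_drc(g, contrast_regime(20, 40, "low"), 60, seed = 2)
  set.seed(3)
  strf <- separable_strf(rnorm(13), rnorm(4), bias = 0.5)
  z <- predict_linear(strf, d)
  # naive double loop with first-row edge padding
  k <- strf_kernel(strf)
  z_ref <- vapply(seq_len(60), function(t) {
    acc <- strf$bias
    for (h in 0:3) {
      row <- max(1, t - h)
      acc <- acc + sum(k[, h + 1] * d$levels[row, ])
    }
    acc
  }, numeric(1))
  expect_equal(z, z_ref)

  # identity-like kernel returns one channel's level track
  strf_id <- separable_strf(c(rep(0, 6), 1, rep(0, 6)), 1, bias = 0)
  expect_equal(predict_linear(strf_id, d), d$levels[, 7])

  # doubling weights doubles the drive around the bias
  strf2 <- strf
  strf2$k_f <- strf$k_f * 2
  expect_equal(predict_linear(strf2, d) - strf$bias,
               2 * (z - strf$bias))

  wrong_grid <- generate_drc(make_frequency_grid(1000, 4000, 4),
                             contrast_regime(20, 40, "low"), 10, seed = 1)
  expect_error(predict_linear(strf, wrong_grid), "grid")
})

test_that("alternating fit recovers kernels and never increases error", {
  g <- test_grid()
  u <- test_unit(seed = 4)
  d <- generate_drc(g, contrast_regime(20, 40, "low"), 1600, seed = 5)

  # noiseless: near-exact recovery
  z <- predict_linear(u$strf, d)
  fit0 <- fit_separable_strf(d, z)
  expect_gt(abs(cor(fit0$k_f, u$strf$k_f)), 0.999)
  expect_gt(abs(cor(fit0$k_h, u$strf$k_h)), 0.999)

  # Poisson noise, 20 repeats, 40 s: correlation >= 0.9
  r <- simulate_unit_response(u, d, 20, seed = 6)
  fit <- fit_separable_strf(d, psth_of(r), exclude_ms = 500)
  expect_gt(cor(as.numeric(strf_kernel(fit)),
                as.numeric(strf_kernel(u$strf))), 0.9)

  # training error is non-increasing across iterations
  mse <- fit$fit$train_mse
  expect_true(all(diff(mse) <= 1e-6 * mse[1]))

  # all-zero responses give a zero kernel and zero bias
  fitz <- fit_separable_strf(d, rep(0, 1600))
  expect_true(all(fitz$k_f == 0))
  expect_equal(fitz$bias, 0)
})

test_that("BF is recovered within one grid step across a population", {
  g <- test_grid()
  pop <- make_population(12, 100, g, seed = 7)
  d <- generate_drc(g, contrast_regime(20, 40, "low"), 800, seed = 8)
  err_steps <- vapply(seq_along(pop), function(i) {
    r <- simulate_unit_response(pop[[i]], d, 10, seed = 20 + i)
    fit <- fit_separable_strf(d, psth_of(r), exclude_ms = 500)
    est <- extract_strf_params(fit, g)$best_frequency
    true <- extract_strf_params(pop[[i]]$strf, g)$best_frequency
    abs(log2(est / true)) * g$steps_per_octave
  }, numeric(1))
  expect_lte(median(err_steps), 1)
})

test_that("tuning parameters follow closed-form oracles", {
  g <- make_frequency_grid(1000, 64000, 4)
  # Gaussian spectral kernel, sigma = 2 channels on a 1/4-octave grid
  k_f <- exp(-(1:25 - 12)^2 / (2 * 2^2))
  strf <- separable_strf(k_f, c(0.2, 1, 0.4), bias = 0)
  p <- extract_strf_params(strf, g)
  expect_equal(p$best_frequency, g$frequencies[12])
  fwhm_gauss <- 2 * sqrt(2 * log(2)) * 2 * 0.25 # 2.355 sigma in octaves
  expect_lt(abs(p$freq_bandwidth - fwhm_gauss), 0.05)

  # single-bin temporal kernel floors at one bin (25 ms)
  strf1 <- separable_strf(k_f, 1, bias = 0)
  expect_equal(extract_strf_params(strf1, g)$temporal_bandwidth, 25)

  # scaling leaves BF and bandwidths unchanged, scales max weight
  strf3 <- strf
  strf3$k_f <- strf$k_f * 3
  p3 <- extract_strf_params(strf3, g)
  expect_equal(p3$best_frequency, p$best_frequency)
  expect_equal(p3$freq_bandwidth, p$freq_bandwidth)
  expect_equal(p3$temporal_bandwidth, p$temporal_bandwidth)
  expect_equal(p3$max_weight, 3 * p$max_weight)

  # non-positive spectral peak: parameters undefined and flagged
  neg <- separable_strf(-k_f, c(0.2, 1, 0.4), bias = 0, canonical = FALSE)
  pn <- extract_strf_params(neg, g)
  expect_false(pn$valid)
  expect_true(is.na(pn$best_frequency))
})

test_that("combined vs split STRFs rank correctly for shared and distinct truths", {
  g <- test_grid()
  regs <- mouse_regimes()
  track <- rep(rep(c("low", "high"), each = 100), 8)
  d <- generate_drc(g, regs, 1600, seed = 9, track = track)

  # shared truth: combined fit at least as good on average
  u <- test_unit(seed = 10)
  r <- simulate_unit_response(u, d, 6, seed = 11)
  res <- compare_combined_vs_split(d, r, exclude_ms = 500)
  expect_gte(mean(res$difference), -0.02)

  # distinct truths per condition: split wins clearly
  u2 <- test_unit(seed = 12)
  u2$strf$k_f <- rev(u2$strf$k_f) # orthogonal-ish spectral kernel
  z1 <- predict_linear(u$strf, d)
  z2 <- predict_linear(u2$strf, d)
  y <- ifelse(d$contrast_track == "low", z1, z2)
  y <- pmax(0, y - quantile(y, 0.3))
  rr <- unit_response(matrix(round(y), nrow = 1), contrast = d$contrast_track)
  rr$counts <- rbind(rr$counts, rr$counts)
  res2 <- compare_combined_vs_split(d, rr, exclude_ms = 500)
  expect_lt(mean(res2$difference), 0)

  # a single condition is rejected
  d1 <- generate_drc(g, regs$low, 200, seed = 13)
  r1 <- simulate_unit_response(u, d1, 2, seed = 14)
  expect_error(compare_combined_vs_split(d1, r1), "two conditions")
})
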
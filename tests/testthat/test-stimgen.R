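# DRC stimulus construction

test_that("frequency grids span whole octave steps inclusively", {
  g <- make_frequency_grid(1000, 64000, 4)
  expect_length(g$frequencies, 25)
  expect_equal(g$frequencies[1], 1000)
  expect_equal(g$frequencies[25], 64000)
  # constant ratio between neighbours
  expect_equal(diff(log2(g$frequencies)), rep(0.25, 24))

  expect_length(make_frequency_grid(150, 19200, 4)$frequencies, 29)
  expect_equal(make_frequency_grid(1000, 1000, 4)$frequencies, 1000)
  expect_error(make_frequency_grid(1000, 3000, 4), "octave")
})

test_that("DRC levels are uniform draws within the regime bounds", {
  g <- test_grid()
  low <- contrast_regime(20, 40, "low")
  d <- generate_drc(g, low, 1000, seed = 1)
  expect_all_within(d$levels, 30, 50)
  expect_equal(dim(d$levels), c(1000, 13))

  # zero width collapses to the mean level exactly
  d0 <- generate_drc(g, contrast_regime(0, 40, "low"), 10, seed = 1)
  expect_true(all(d0$levels == 40))

  # Monte-Carlo mean over 10,000 high-contrast chords
  hi <- generate_drc(g, contrast_regime(40, 40, "high"), 10000, seed = 2)
  se <- 40 / sqrt(12) / sqrt(length(hi$levels))
  expect_lt(abs(mean(hi$levels) - 40), 3 * se)

  # determinism: identical seed => identical matrix
  expect_identical(generate_drc(g, low, 50, seed = 7)$levels,
                   generate_drc(g, low, 50, seed = 7)$levels)
  expect_false(identical(generate_drc(g, low, 50, seed = 7)$levels,
                         generate_drc(g, low, 50, seed = 8)$levels))
})

test_that("drawn levels pass a KS test against the stated uniform", {
  g <- test_grid()
  d <- generate_drc(g, contrast_regime(40, 40, "high"), 7700, seed = 3)
  x <- as.numeric(d$levels)[seq_len(1e5)]
  ks <- suppressWarnings(stats::ks.test(x, "punif", 20, 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("switching DRCs alternate regimes on whole-chord epochs", {
  g <- test_grid()
  sw <- generate_switching_drc(g, 20, 40, epoch_s = 2, total_s = 8, seed = 1)
  expect_equal(n_chords(sw), 320)
  r <- rle(sw$contrast_track)
  expect_equal(r$lengths, rep(80, 4)) # 2000 / 25 = 80 chords per epoch
  expect_equal(r$values, c("low", "high", "low", "high"))
  expect_error(generate_switching_drc(g, 20, 40, epoch_s = 0.0301,
                                      total_s = 0.0602, seed = 1),
               "whole number")
})

test_that("equal-width switching regimes have matching level distributions", {
  g <- test_grid()
  sw <- generate_switching_drc(g, 30, 30, epoch_s = 2, total_s = 40, seed = 4)
  lo <- as.numeric(sw$levels[sw$contrast_track == "low", ])
  hi <- as.numeric(sw$levels[sw$contrast_track == "high", ])
  ks <- suppressWarnings(stats::ks.test(lo, hi))
  expect_gt(ks$p.value, 0.01)
})

test_that("level-matched DRCs equalise per-chord total power", {
  g <- test_grid()
  regs <- mouse_regimes()
  track <- rep(c("low", "high"), 100)
  lm <- generate_level_matched_drc(g, regs, 200, seed = 5, track = track)
  tot <- chord_total_level(lm)
  expect_lt(diff(range(tot)), 0.1)

  # unmatched mouse regimes have a positive expected total-level difference
  diag <- expected_level_difference(regs$low, regs$high, g)
  expect_gt(diag$difference_db, 0)

  # zero-width: matched and unmatched generators agree exactly
  r0 <- contrast_regime(0, 40, "low")
  expect_equal(generate_level_matched_drc(g, r0, 20, seed = 6)$levels,
               generate_drc(g, r0, 20, seed = 6)$levels)
})

test_that("2-AFC trials assemble to 1,950 ms with interleaved noise probes", {
  g <- make_frequency_grid(150, 19200, 4)
  tr <- assemble_trial(g, contrast_regime(10, 40, "low"),
                       reference_level = 60, target_level = 64, seed = 1)
  expect_equal(tr$total_ms, 1950)
  expect_equal(sum(tr$segments$duration_ms), 1950)
  expect_equal(nrow(tr$levels), 78)
  expect_equal(tr$segments$kind, c("drc", "noise", "drc", "noise", "drc"))
  # probes sit after 1000 ms and after 1350 ms
  expect_equal(tr$reference_bins, 41:44)
  expect_equal(tr$target_bins, 55:58)
  # equal probe levels are a valid trial
  tr2 <- assemble_trial(g, contrast_regime(10, 40, "low"), 60, 60, seed = 2)
  expect_equal(tr2$reference_level, tr2$target_level)
})

test_that("noise blocks carry the stated total level split across channels", {
  g <- make_frequency_grid(1000, 64000, 4)
  blk <- noise_to_spectrogram(70, 100, g)
  expect_equal(dim(blk), c(4, 25))
  expect_equal(unique(as.numeric(blk)), 70 - 10 * log10(25))
  # channel powers sum back to the stated total
  expect_equal(10 * log10(sum(10^(blk[1, ] / 10))), 70)
  expect_equal(nrow(noise_to_spectrogram(70, 0, g)), 0)
  expect_error(noise_to_spectrogram(70, 30, g), "multiple")
})
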
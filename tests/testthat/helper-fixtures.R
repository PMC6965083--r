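# Shared fixtures. Most tests use a reduced grid (1-8 kHz, quarter-octave,
# 13 channels) to keep simulations light; grid-size assertions use the full
# mouse/human grids.

test_grid <- function() make_frequency_grid(1000, 8000, 4)

mouse_regimes <- function() {
  list(
    low = contrast_regime(20, 40, "low"),
    high = contrast_regime(40, 40, "high")
  )
}

# a single well-behaved unit on the test grid
test_unit <- function(seed = 1, tau_ms = 150, compensation = 100, ...) {
  make_population(1, compensation, test_grid(), seed = seed,
                  tau_ms = tau_ms, ...)[[1]]
}

expect_all_within <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              info = sprintf("range [%g, %g] outside [%g, %g]",
                             min(x), max(x), lo, hi))
}
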
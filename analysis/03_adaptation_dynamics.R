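#!/usr/bin/env Rscript
# Adaptation time-constant estimation on switching-contrast DRCs: recovery
# of known taus, the 700-ms estimation ceiling, and model selection
# (contrast dependence, tau improvement). Writes results/dynamics.csv.
#
# Findings: taus of 50-400 ms are recovered within ~30% from 40-repeat
# switching data; a 2000-ms truth pins the estimate at the 700-ms cap; and
# cross-validated model selection flags adapting units while leaving
# non-adapting ones mostly unflagged.

suppressMessages(library(contrastLN))

grid <- make_frequency_grid(1000, 64000, 4)
sw <- generate_switching_drc(grid, 20, 40, epoch_s = 2, total_s = 40,
                             seed = 301)

cases <- data.frame(
  tau_true = c(50, 150, 400, 2000, 150),
  compensation = c(100, 100, 100, 100, 0)
)
rows <- lapply(seq_len(nrow(cases)), function(i) {
  u <- make_population(1, cases$compensation[i], grid,
                       seed = 310 + i, tau_ms = cases$tau_true[i])[[1]]
  r <- simulate_unit_response(u, sw, 40, seed = 320 + i)
  sel <- model_selection(sw, r)
  data.frame(
    tau_true = cases$tau_true[i],
    compensation_true = cases$compensation[i],
    tau_est = sel$model$tau_ms,
    cap_hit = sel$model$fit$cap_hit,
    cc_single = sel$cc[["single"]],
    cc_two_state = sel$cc[["two_state"]],
    cc_adaptive = sel$cc[["adaptive"]],
    contrast_dependent_better = sel$contrast_dependent_better,
    tau_improves = sel$tau_improves
  )
})
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/dynamics.csv", row.names = FALSE)
print(out, row.names = FALSE)
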
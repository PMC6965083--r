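# contrastLN

Contrast gain control in linear–nonlinear (LN) auditory neuron models:
stimulus synthesis, ground-truth simulation, model fitting, adaptation
dynamics, and neurometric prediction of 2-AFC level-discrimination
behavior.

## The problem

Auditory neurons adapt to the *contrast* of their acoustic environment —
the spread of sound levels around the mean. When contrast doubles, many
neurons in the auditory midbrain, thalamus and cortex roughly halve the
gain of their input–output function, stabilising their firing-rate code
across environments, and human level-discrimination thresholds shift in a
matching way. `contrastLN` is a workflow package for quantifying this
adaptation with LN encoding models, for researchers in auditory systems
neuroscience and psychophysics. Since electrophysiological recordings of
this kind are rarely public, every stage is validated on synthetic
populations with known ground truth; the generators are first-class,
tested code.

## The model

Stimuli are dynamic random chords (DRCs): 25-ms chords of tones on a
log-frequency grid, each tone's level drawn uniformly on the dB scale.
The contrast condition is the width *C* of that uniform distribution
(e.g. 20 dB low vs 40 dB high around a fixed 40 dB SPL mean).

Each unit is modelled as a separable STRF plus a sigmoid output
nonlinearity on the linear drive *z_t*:

    z_t = bias + sum_{f,h} k_f(f) k_h(h) L(t-h, f)
    y_t = a + b / (1 + exp(-(z_t - c)/d)),     gain G = b/(4d)

with one sigmoid per contrast condition on a shared drive. Contrast gain
control is reported as percent compensation,

    % compensation = 100 * C_low (G_low - G_high) / (G_high (C_high - C_low)),

so 100% means the gain halves when the contrast doubles and 0% means no
change. For switching-contrast stimuli, the sigmoid parameters relax
between their per-contrast values according to an exponentially smoothed
contrast history with time constant τ (bounded at 700 ms, the longest
value estimable from 2-s switching epochs). A neurometric model predicts
2-AFC behavior by summing Poisson spike counts of a model population
during noise probes embedded in DRCs, fitting psychometric curves, and
converting JNDs to behavioral compensation via sensitivity = 1/JND.

## Worked example

Simulate a 10-unit population built with 100% compensation, screen it,
fit combined STRFs and per-condition sigmoids, and summarise:

```r
library(contrastLN)
cfg <- run_config(n_units = 10, compensation_target = 100, drc_s = 40,
                  n_repeats = 20, n_boot = 2000, seed = 7)
res <- run_pipeline(cfg)
#> pipeline: 10 units, compensation target 100%, seed 7
#> screening: NP/SP <= 60, cc_pred >= 0.1
#> retained 10/10 units
#> fitting combined STRFs and per-condition nonlinearities
#> median compensation: 100.0136

res$summary$median_compensation
#> [1] 100.0136        # 95% bootstrap CI 90.7-108.1
head(res$units, 3)
#>   unit true_compensation compensation y_offset_change gain_low gain_high
#> 1    1               100    100.36721       -3.893636 2.000266 0.9983002
#> 2    2               100     86.63925       48.061103 1.943981 1.0415715
#> 3    3               100    110.58502      -18.253919 2.077360 0.9864710
```

All ten synthetic units pass the reliability screen (noise-to-signal
power ratio NP/SP ≤ 60 and cross-validated prediction correlation
≥ 0.1); the fitted low-contrast gains are close to 2 and the
high-contrast gains close to 1 — the generative halving — so the median
recovered compensation is 100% with per-unit estimation noise of about
±10 percentage points at this data size.

The numbered scripts under `analysis/` run the full set of studies the
package supports (stimulus design diagnostics, population recovery at
several compensation targets, adaptation-dynamics estimation with the
700-ms cap, psychometric JND recovery, and neurometric behavioral
prediction), each writing its tables under `results/`.

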
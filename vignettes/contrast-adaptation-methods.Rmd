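---
title: "Models and methods for auditory contrast gain control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for auditory contrast gain control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contrastLN)
```

## The scientific problem

Auditory neurons adapt their input–output functions to the statistics of
recent stimulation. One well-studied form is *contrast gain control*: when
the spread (contrast) of sound levels in the environment doubles, many
neurons roughly halve the gain of their response function, keeping firing
rates informative across acoustic environments. `contrastLN` provides a
complete, tested workflow for studying this phenomenon with
linear–nonlinear (LN) encoding models: stimulus synthesis, ground-truth
simulation, reliability screening, model fitting, adaptation-dynamics
estimation, and the prediction of perceptual (2-AFC level discrimination)
consequences from populations of model neurons.

Because real recordings are not bundled with the package, every stage is
validated against synthetic data with known ground truth; the synthetic
generators are first-class, tested code, not ad-hoc fixtures.

## Stimuli

The workhorse stimulus is the dynamic random chord (DRC): a sequence of
25-ms chords, each a superposition of pure tones on a logarithmic frequency
grid (25 tones from 1–64 kHz at quarter-octave spacing for the mouse
design; 29 tones from 150 Hz–19.2 kHz for the human design). Each tone's
level is drawn independently and uniformly on the dB scale. The *contrast*
of a DRC is the full width of that uniform distribution — 20 dB (low) vs
40 dB (high) in the mouse design, 10 vs 30 dB in the human design — around
a fixed 40 dB SPL mean, so mean level is constant while level variability
changes.

All analysis operates on the dB-level matrix (chords × frequencies); audio
rendering (tone synthesis, 5-ms ramps) is deliberately out of scope since
the models never see waveforms.

Because the mean of `10^(L/10)` under a dB-uniform distribution grows with
the distribution's width, high-contrast DRCs are overall more intense than
low-contrast ones. The package does not hard-code any measured difference
(what a sound-level meter reports depends on the playback and measurement
chain); `expected_level_difference()` computes the analytic power-sum
value (≈7.0 dB for 20/40 widths, ≈5.7 dB for 10/30) and
`generate_level_matched_drc()` implements the control variant that
rescales every chord's summed power to a common target, equalising overall
level at the cost of exact per-tone level statistics (the two generators
coincide for zero-width regimes).

`generate_switching_drc()` alternates the contrast every 2 s (configurable
in whole chords) for adaptation-dynamics experiments, and
`assemble_trial()` builds the 1,950-ms 2-AFC trial: 1000 ms DRC, 100 ms
broadband noise (reference), 250 ms DRC, 100 ms noise (target), 500 ms
DRC. Noise probes enter the models as flat spectrogram blocks at
`level − 10·log10(n_channels)` per channel so channel powers sum to the
nominal level.

## The encoding model

Each unit is an LN model. The linear stage is a separable
spectro-temporal receptive field (STRF): `k_fh = k_f ⊗ k_h` with a
spectral kernel `k_f` over frequency channels and a temporal kernel `k_h`
over 25-ms history bins, applied causally to the dB spectrogram to give a
drive `z_t`. Separability keeps the parameter count low enough for
limited data. The factorisation is made unique by a canonical form
(`k_h` unit-norm with positive peak; scale and sign in `k_f`).

Fitting is maximum likelihood under Gaussian noise, i.e. least squares,
by alternating closed-form updates of `k_f` and `k_h` (each subproblem is
linear) until the relative change in training error drops below `1e-6` or
200 iterations. A small ridge penalty (`1e-3` relative to the design
norm) keeps the subproblems conditioned; this is a documented deviation
from pure maximum likelihood and is configurable. History length defaults
to 10 bins (250 ms). Stimulus history before the first chord is padded by
replicating the first chord, and fits exclude the first 500 ms of each
stimulus segment (the standard onset-exclusion rule), so the padding never
influences retained bins in practice.

Tuning parameters are read off the canonical kernels: best frequency (BF)
at the spectral kernel's maximum; frequency bandwidth (fBW) as its
full-width half-maximum in octaves with linear interpolation between
channels; temporal bandwidth (tBW) as the temporal kernel's FWHM in ms
with a one-bin (25 ms) floor; and the maximum weight of the full kernel.
When the half-max is never crossed on one side the bandwidth truncates at
the kernel edge and is flagged rather than extrapolated.

The output stage is a four-parameter sigmoid applied to the shared drive:

    y = a + b / (1 + exp(-(z - c)/d))

with y-offset `a`, y-range `b`, x-offset `c`, width `d`, and gain
`b/(4d)` (the slope at the inflection). Fitting minimises squared error
with a deterministic multi-start over `c` (drive quantiles 0.1–0.9) and
`d` (decades of the drive SD), under the identifiability constraints
`b ≥ 0`, `d > 0` (sign flips of `(b, d)` produce identical curves, so the
constraint loses no generality). Squared error rather than Poisson
likelihood keeps the static fits consistent with the dynamic model's
objective below.

Contrast gain control is quantified per unit by fitting one sigmoid per
contrast condition on a single shared drive (one combined STRF) and
comparing gains:

    % compensation = 100 · C_low (G_low − G_high) / (G_high (C_high − C_low))

where `C` are the contrast widths in dB. 100% means the gain halves under
a width doubling; 0% means no change; the measure is exact for these
identities in floating point and invariant to common gain rescaling.
Changes in other parameters (notably the y-offset `a`, the subtractive
adaptation component) are reported as plain percent change
`100·(V_high − V_low)/V_low`. Four-condition designs (contrast ×
cortex-state) reuse the same machinery and report the silencing effect as
the % gain change with cortex silenced minus the % gain change with
cortex intact.

## Reliability screening

Units are screened before modelling. With N repeats and the time-power
operator P(·) (population variance across bins), signal and noise power
are estimated as

    SP = (N · P(mean PSTH) − mean_n P(trial_n)) / (N − 1)
    NP = mean_n P(trial_n) − SP

so `SP + NP` equals the mean per-trial power as an exact algebraic
identity, `NP = 0` for identical repeats, and SP is unbiased for the true
PSTH power (individual estimates may be slightly negative and are
preserved, not clamped — clamping would bias population summaries). Units
with `NP/SP > 60` are excluded, as are units whose cross-validated linear
prediction correlation (`cc_pred`, fitted on the leading 90% of bins,
evaluated on the held-out remainder) falls below 0.1. Both thresholds are
configurable; the boundary is inclusive (`NP/SP = 60` is retained)
because the exclusion rule is a strict inequality.

## Adaptation dynamics

To estimate how fast the nonlinearity re-adapts after a contrast switch,
the sigmoid parameters are allowed to relax between their low- and
high-contrast values according to an exponentially weighted history of the
stimulus contrast. The per-chord contrast indicator `C_t` (0 = low,
1 = high) is filtered with a causal exponential kernel of time constant τ,
normalised to unit mass over a horizon where the residual kernel mass is
below `1e-4`, giving a smoothed state `s_t ∈ [0, 1]`; each parameter is
then `p_t = p_low + (p_high − p_low)·s_t`. This normalised
exponential-moving-average reading is the only one under which parameters
converge exactly to their steady-state values under sustained contrast,
which the model requires. Pre-stimulus history is initialised to the
first epoch's state to avoid onset transients from an arbitrary zero
state.

The full model — eight sigmoid parameters (four per contrast) plus one
shared τ, with the STRF fixed across conditions — is fitted to
switching-contrast data by gradient-based minimisation (L-BFGS-B) of the
squared error, initialised from static sigmoids fitted on the last second
of each 2-s epoch, with multi-start over τ ∈ {10, 50, 200, 600} ms. τ is
optimised on the log scale (so the finite-difference gradient resolves it
equally well at 10 and 700 ms) and bounded in [1, 700] ms: 700 ms is the
longest value reliably estimable from 2-s epochs, and fits whose truth
lies beyond pin at the cap (flagged via `cap_hit`); 1 ms is effectively
instantaneous at 25-ms bins. When the two parameter sets coincide τ has
no effect on predictions and is flagged unidentifiable.

Model selection uses 5-fold cross-validation on contiguous blocks,
comparing a single contrast-independent sigmoid, an instantaneous
two-state model, and the τ-augmented model by fold-averaged held-out
correlation. Fold averaging matters: with a single split the comparison
between near-equivalent models is a coin flip, whereas averaging lets the
(real, small) overfitting penalty of the richer model dominate for
non-adapting units. τ is interpreted only for units where the two-state
model beats the single sigmoid.

## Psychophysics and the neurometric model

2-AFC level discrimination is summarised by a psychometric curve
(probability of "louder" vs target level). The package fits
`P = guess + (1 − guess − lapse)·F((x − m)/s)` by maximum likelihood, with
`F` a cumulative Gaussian by default and the guess/lapse rates estimated
within [0, 0.1]. The JND is the dB difference between the curve's 25% and
75% points. The cumulative-Gaussian default is deliberate: simulated
observers are cumulative-Gaussian by construction, and a logistic family
with fixed small guess/lapse under-estimates their JND by ~10% even in
the infinite-data limit (the fixed asymptotes force a steeper core), so
the Gaussian link is required for the JND consistency property
(`fitted JND → 1.349σ`) to hold. The logistic family and fixed rates
remain available through arguments.

Discrimination sensitivity is taken as `1/JND`, so behavioral
compensation across contrast conditions uses the same formula as neural
gain compensation. Group tables are aggregated both ways — mean of
per-participant compensations, and compensation of mean JNDs — because
the two differ in general and the choice is a reporting convention.

The neurometric model predicts this behavior from a population of LN
units: for each simulated trial, each unit's rate during the two noise
probes is predicted with the contrast-appropriate sigmoid on the STRF
drive, Poisson spike counts are drawn and summed across units over a
decision window (the 4 probe bins plus 1 following bin for response
latency; configurable), and the trial is called "louder" when the target
window total exceeds the reference total, ties broken by a fair coin
(a deterministic tie rule would bias the curve at threshold). Units are
weighted equally. Repeating this per level and contrast yields
psychometric curves, JNDs, and a predicted behavioral compensation;
repeated runs give its spread.

## The synthetic populations

`make_population()` builds ground-truth units whose recovery validates
the whole chain: Gabor-like Gaussian spectral kernels (σ ≈ 2 channels)
tiling the grid, difference-of-exponentials temporal kernels, and
per-contrast sigmoids constructed so each unit's true compensation equals
a requested target (the gain change is carried by the width `d`, with the
y-range `b` shared; `a`, `b` and the spectral σ vary across units).
Baseline rates (~0.2–0.6 spikes/bin y-offset, 2–4 spikes/bin range) are
typical of midbrain/thalamic units at 25-ms resolution. Time constants
and best frequencies are assigned by deterministic recycling/tiling so
population structure does not depend on draw order. Rates are clamped at
zero before Poisson draws (fitted sigmoids can dip below zero; Poisson
rates cannot).

Two operating-point conventions exist because the DRC drive and the noise
probe drive occupy different parts of the drive axis (probes are ~16 dB
per channel louder than the DRC mean). For encoding-recovery studies the
sigmoid inflection sits on the DRC drive distribution (`operating_level =
40`, width = drive SD). For neurometric studies (`probe_width_db`) the
inflection and width are calibrated on deterministic zero-width trials to
the decision-window drive, weighting window bins by their level
sensitivity, so the population is level-monotone across the target range;
compact temporal kernels (`t_fall ≈ 0.5` bins) keep the window drive
probe-dominated, which is the premise of the clean gain→JND mapping
(`d` doubling ⇒ JND doubling ⇒ 100% compensation). With long kernels the
windows mix probe and DRC context and the predicted compensation is
systematically compressed below the neural value — an informative effect
in itself, but not the consistency property under test.

## What the synthetic data do not emulate

Simulated units are exactly LN-Poisson: no spike-history dependence,
no across-unit correlation, no slow drift, no non-separable receptive
fields, and contrast adaptation follows a single shared exponential.
Passing recovery tests therefore shows the estimators are correct and
well-calibrated for the model class, not that real neurons are described
exhaustively by it. Statistics computed from real recordings (median
compensation by brain area, τ medians, silencing effects) are outside the
package's scope; the workflow computes them when given data in the
documented formats.

## Numerical choices and problem sizes

Defaults throughout: 25-ms bins; 500-ms onset exclusion; 90/10 contiguous
train/test splits; STRF history 10 bins with relative ridge `1e-3`;
sigmoid multi-start over 9 c-quantiles × 3 d-decades; τ bounds [1, 700] ms
with 4 starts; bootstrap CIs with 10,000 resamples (fewer in the shipped
analyses). The shipped analyses and tests use 40-s stimuli with 10–40
repeats, populations of 4–50 units, and neurometric runs of ~100–150
trials per level — sizes at which every recovery property in the test
suite resolves clearly while the whole suite stays quick on a laptop.

## Known limitations

- One shared τ for all four sigmoid parameters; per-parameter time
  constants are not modelled.
- The separable STRF cannot represent frequency sweeps; deliberately so.
- The neurometric decision rule is a plain summed-count comparison with
  equal unit weighting; no optimal decoding.
- `cc_pred` uses the linear prediction, so strongly nonlinear units pass
  the screen only insofar as their linear component predicts.
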
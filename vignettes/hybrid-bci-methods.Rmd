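---
title: "Decoding a ternary hybrid EEG-NIRS BCI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a ternary hybrid EEG-NIRS BCI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridbci)
```

## The decoding problem

A hybrid brain-computer interface records two complementary views of the
same mental activity: EEG (scalp potentials, millisecond resolution,
sensitive to oscillatory power changes) and NIRS (cortical hemodynamics via
light attenuation at several wavelengths, resolution of seconds, sensitive
to metabolic demand). The decoder in this package discriminates three task
classes — mental arithmetic (MA), motor imagery (MI), and the idle state
(IS) — from simultaneous recordings: 21 EEG electrodes over frontal and
central areas at a working rate of 200 Hz, and 16 NIRS source-detector
channels over the prefrontal cortex at 13.3 Hz. The physiological rationale
is spatial: MI desynchronizes sensorimotor rhythms over central areas
(ERD), while MA drives prefrontal activation that NIRS sees as an increase
in oxygenated hemoglobin (HbO) with a smaller opposite-signed change in
deoxygenated hemoglobin (HbR). Neither modality separates all three classes
well on its own; their fusion can.

## Signal conditioning

**EEG.** Recordings above the working rate are downsampled with a
linear-phase windowed-sinc (Blackman) anti-alias low-pass (cutoff at 0.475
of the target rate, ~74 dB stopband) before resampling onto the target
grid; event onsets are rescaled and rounded to the nearest sample, ties
toward zero. The broadband filter is a 6th-order Butterworth band-pass,
0.1–50 Hz. All Butterworth filters in the package are designed in
zero-pole-gain form and applied as cascaded second-order sections, because
a transfer-function (polynomial) realization is numerically singular at
edges far below the sampling rate — most severely for the hemodynamic band
(0.01 Hz at 13.3 Hz sampling). "Zero-phase" is read the standard way: the
6th-order design is run forward and backward, cancelling group delay and
squaring the magnitude response. Reflective padding sized from the slowest
filter pole (nine time constants) suppresses edge transients.

Ocular artifacts are removed by a pluggable strategy whose default
regresses every EEG channel on the vertical EOG channel by least squares
and keeps the residual; the interface accepts drop-in replacements (for
example an ICA-based remover) as a function of the EEG and EOG matrices.
Epochs span [-5, 25) s around task onset.

**NIRS.** Optical densities at 780/805/830 nm convert to (HbR, HbO)
concentration changes through the modified Beer-Lambert law with the fixed
2x3 coefficient matrix returned by `mbll_coefficients()` (unit pathlength,
so the output unit is mM·cm). The chromophore order (HbR, HbO) is fixed
everywhere to prevent silent channel swaps. The hemoglobin traces are
band-passed at 0.01–0.09 Hz *before* epoching (the filter's memory at
0.01 Hz is on the order of 100 s, so filtering epochs would be
transient-dominated), then epoched at [-5, 25) s and baseline-corrected by
subtracting each trial's mean over [-1, 0) s. At 13.3 Hz the half-open
30 s window holds floor(30 x 13.3) = 399 samples; window discretization is
half-open with floor rounding throughout.

## Features

**EEG: filter-bank common spatial patterns.** Within each band of the bank
(theta 4–8, alpha 8–13, beta 13–30 Hz), per-trial spatial covariances over
the 0–10 s task window are trace-normalized (making features robust to
global amplitude scale) and averaged per class. CSP solves the generalized
eigenproblem of the two class covariances by whitening their sum; the
projection jointly diagonalizes both classes, and component *j* carries an
eigenvalue score equal to the class-A variance fraction
$\lambda_j \in [0,1]$ (class-B fraction $1-\lambda_j$). A small ridge
($10^{-10}$ times the mean diagonal) guards the rank deficiency that EOG
regression can introduce. The first three and last three components by
score are kept, and each trial contributes the log-variance of the six
projections per band: 6 x 3 = 18 features. Filters are refit inside every
training fold — never on test trials.

**NIRS: temporal means.** For each channel and chromophore, the mean of
the baseline-corrected trace in the 5–10 s and 10–15 s windows (placed for
the hemodynamic delay): 16 x 2 x 2 = 64 features, ordered channel-major,
then chromophore, then window. Slope and variance features are deliberately
not implemented.

## Classification

Each binary problem of the one-versus-one decomposition (MA-MI, MA-IS,
MI-IS) gets an EEG and a NIRS base classifier: linear discriminant analysis
with the pooled covariance replaced by the shrunken estimate
$(1-\lambda)\Sigma + \lambda \nu I$. The intensity $\lambda$ is the
analytic Ledoit-Wolf/Schäfer-Strimmer estimate clipped to $[0,1]$. The
target is scaled by $\nu$, the average feature variance, because the
literal identity target is dimensionally brittle when features are not
standardized (log-variances and mM·cm means live on different scales); for
standardized features the two coincide, and the literal target remains
available via `target = "identity"`.

The meta-classifier stacks the two base decision values per binary problem
into a 2-vector, each standardized by its training-fold spread so the
modalities enter on equal scale, and fits another shrinkage LDA.
Critically, the decisions used to *train* the meta stage are produced by
5-fold inner cross-validation within the training fold (base classifiers
refit per inner split, spatial filters from the outer training fold):
resubstitution decisions are optimistically compressed and provably bias
stacking toward the stronger-looking base model.

The final label is the majority over the three binary votes; the 1-1-1
cycle is broken by the largest absolute decision value backing each vote,
with canonical class order (MA, MI, IS) as the deterministic last resort.
Unimodal (EEG-only, NIRS-only) baselines vote on the base decisions
without the meta stage.

Evaluation is repeated stratified cross-validation, by default 10 x
10-fold: with 30 trials per class, each fold holds exactly 3 test trials
per class. No statistic of any test trial (covariances, shrinkage targets,
class means, scalings) enters any fitted parameter.

## Metrics

The information transfer rate in bits/min for an N-class task with
accuracy $p$ and trial length $\tau$ seconds is
$\frac{60}{\tau}[\log_2 N + p\log_2 p + (1-p)\log_2\frac{1-p}{N-1}]$,
with $p\log_2 p := 0$ at $p = 0$. It is zero exactly at chance and
increasing in $p$ above chance. The trial length is a reporting choice;
the pipeline reports $\tau = 10$ s (the task period), and the CLI takes
$\tau$ explicitly.

Event-related spectral perturbation maps use a short-time Fourier
transform (1 s Hann window, 90% overlap — the simplest estimator that
resolves band-level ERD at this timescale; the estimator is pluggable),
averaged over trials and a channel group, in dB relative to the mean
baseline power per frequency over [-4, -3) s.

## The synthetic-session generator

No per-trial recordings are distributable with the method, so the package
carries a generator that emulates the study conditions: 30 trials per
class in one globally randomized order, 10 s tasks, 16–18 s uniform
inter-trial breaks, 21 EEG + 1 EOG channels at 200 Hz (a 2048 Hz mode
exists to exercise the downsampler), 16 NIRS channels at 13.3 Hz.

**EEG model.** 1/f background noise plus region-specific band-limited
rhythms (shared regional source plus per-channel component). During task
windows the rhythm amplitude is multiplied by a class- and band-specific
factor with 0.5 s raised-cosine ramps — factors below 1 model ERD, the
simplest mechanism that reproduces task-locked band-power maps. Blinks are
stereotyped raised-cosine transients on the EOG channel, mixed into
frontal channels with fixed gains. Two nuisance processes make single
trials realistically hard: a slow log-amplitude wander of each rhythm
(log-sd 0.4) and per-trial jitter of the modulation depth (log-sd 0.3).
The wander is band-limited to 0.02–0.1 Hz: amplitude autocorrelation on
session timescales (minutes) would correlate by chance with the fixed
label sequence and lift even a null session above chance — a genuine
experimental confound, but one that would make a null decoding test
meaningless.

**NIRS model.** Class responses are task boxcars convolved with a
double-gamma hemodynamic response (peak 6 s, undershoot 16 s), scaled by a
per-class peak HbO amplitude and a fixed per-channel spatial gain, with
HbR = -HbO/3 (opposite sign, smaller magnitude). Defaults: MA 0.040,
MI 0.012, IS 0 mM·cm — prefrontal optodes see mental arithmetic strongly,
motor imagery weakly, idling not at all. Nuisances: Mayer (~0.1 Hz),
respiratory (~0.25 Hz) and cardiac (~1.1 Hz) oscillations, white noise,
per-trial gain jitter, and band-limited (0.01–0.1 Hz) vasomotor noise that
deliberately overlaps the analysis band (out-of-band noise would be
removed by the filter and teach us nothing). The latent (HbR, HbO) pair is
mapped to three optical densities through the Moore-Penrose pseudoinverse
of the Beer-Lambert matrix, so the conversion stage recovers the latent
hemodynamics exactly — a self-consistency the tests exploit.

Default effect sizes were chosen once to place one synthetic subject in
the regime the method is known to operate in — EEG somewhat stronger than
prefrontal-only NIRS, hybrid best, all well above chance; they are
physiologically plausible magnitudes (30–50% ERD, tens of µM·cm
hemodynamic responses), not measured constants. Accuracies vary by several
points across generator seeds, like subjects do. Named presets bound the
operating range: `strong` (a well-separable subject), `null` (no
class-dependent modulation anywhere — decoding must sit in the 90-trial
binomial 95% interval around 1/3), and `complementary` (EEG carries mainly
the MI contrast, NIRS mainly the MA contrast, so fusion must beat either
modality alone).

What passing tests on synthetic sessions do **not** show: robustness to
real-data pathologies the generator omits — electrode/optode artifacts and
drifts beyond the modeled ones, movement, volume conduction with realistic
spatial mixing, inter-subject variability, non-stationarity across a
session beyond amplitude wander. The generator validates the machinery,
not the physiology.

## Numerical and design notes

* **Time convention.** Onset = 0; sample *k* covers
  $[k/\text{rate}, (k+1)/\text{rate})$; every window is half-open.
  Event-onset resampling rounds to the nearest sample, ties toward zero.
* **Container.** Sessions are stored one-per-file as versioned serialized
  lists (rate and unit attributes, channel table, event table, data
  matrix) with validated, field-by-field reads; events export to TSV.
* **Determinism.** All stochastic stages draw from a private, restored
  RNG state seeded from configuration; identical configurations give
  bit-identical sessions, folds, and results.
* **Leakage canary.** The cross-validation leakage contract is tested by
  relabeling a strongly decodable session with labels *balanced against
  the true classes* (each true class receives each new label equally
  often). A plain random permutation is the weaker canary: its chance 3x3
  contingency with the true labels is learnable structure on decodable
  data (expected accuracy ≈ 0.41 here), whereas the balanced relabeling
  leaves exactly nothing to learn, so any above-chance result would
  indict the pipeline.
* **Problem sizes.** Tests run single synthetic subjects (90 trials) with
  the full 10 x 10-fold protocol for the headline checks and 2–3
  repetitions where only means are needed; the fusion property is
  averaged over 10 generator seeds.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)
res
#> <bci_result> config dfd08920
#>   eeg      84.2 +/-  1.5 %   ITR 4.79 bits/min
#>   nirs     73.9 +/-  3.0 %   ITR 2.97 bits/min
#>   hybrid   87.1 +/-  2.0 %   ITR 5.41 bits/min
```

One synthetic subject under default conditions, full 10 x 10-fold
protocol. The hybrid decoder beats both unimodal baselines; the ITR column
converts each accuracy at the 10 s task length.
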
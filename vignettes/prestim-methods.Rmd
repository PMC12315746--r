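---
title: "Methods: pre-stimulus power, ERS/ERD, and causal mediation on synthetic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-stimulus power, ERS/ERD, and causal mediation on synthetic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prestim)
```

## Scientific background

During incremental sequence learning, two event-related EEG signatures
track learning: mid-frontal theta power increases after stimulus onset
(event-related synchronization, ERS) and parietal alpha power decreases
(event-related desynchronization, ERD). Both are conventionally measured
against a pre-stimulus baseline. That convention hides a confound: if the
*pre-stimulus* power level itself drifts across sequence repetitions —
which it does, as attention and anticipation change with learning — then a
per-repetition baseline correction silently folds the pre-stimulus change
into the "post-stimulus" effect. A repetition-related change in baseline
power and a repetition-related change in the evoked response become
indistinguishable.

`prestim` implements the full analysis chain needed to study this problem
quantitatively on synthetic data with known ground truth:

1. a synthetic multi-subject EEG generator with controlled aperiodic
   (1/f) background, subject-specific alpha oscillations and theta bursts;
2. sliding-window time-frequency decomposition;
3. spectral parameterization into aperiodic + oscillatory components;
4. individual alpha frequency (IAF) detection and IAF-relative bands;
5. the two baseline-correction schemes and the pre-stimulus activity term;
6. a calibrated simulation of the conflation problem;
7. behavioral scoring for the sequence-learning task; and
8. causal mediation analysis (ACME/ADE) on linear mixed models.

## Baseline schemes and the pre-stimulus term

All power quantities below are aperiodic-adjusted log10 power. For subject
*s*, sequence *q* and repetition *r*, let `post(s,q,r)` be the
post-stimulus window power and `base(s,q,r)` the baseline-window
(−500..−250 ms) power.

* **Per-repetition scheme** (the conventional ERD/ERS measure):
  `ers_erd_rep = post − base`.
* **Average baseline**: `avg_base(s,q) = mean_r base(s,q,r)`.
* **Pre-stimulus activity**: `prestim = base − avg_base`; by construction
  it has zero mean over the repetitions of a sequence, making it a
  centered mediator.
* **Per-subject scheme**: `ers_erd_subj = post − avg_base`.

These satisfy the exact identity

```
ers_erd_subj = ers_erd_rep + prestim
```

which the package enforces to better than 1e−12 and the test suite checks
on every generated band-power table (`prestim_and_subject_scheme()`).

## The conflation simulation

`build_scenarios()` constructs a reference repetition-1 curve (flat
pre-stimulus level, raised-cosine post-stimulus dip) and four repetition-2
variants with level deltas, for pre/post magnitudes `(mp, mq)`:

| scenario | pre delta | post delta |
|----------|-----------|------------|
| A        | `mp + mq` | 0          |
| B        | 0         | `−(mp+mq)` |
| C        | `mp`      | `−mq`      |
| D        | `−mp`     | `−(2mp+mq)`|

The calibration is that all four share the same post-minus-pre shift
`d = −(mp + mq)`. Under per-repetition correction every variant's
corrected curve reduces algebraically to `dip + d·ramp` — the four
scenarios are *identical* and the scheme cannot tell a pre-stimulus
increase from a post-stimulus decrease. Under the per-subject scheme the
corrected pre-stimulus level equals `pre_delta / 2`, so the four scenarios
separate strictly. (In floating-point arithmetic the per-repetition
identity holds to one ulp; the tests bound it at 1e−12.)

## Synthetic EEG generation

`generate_epochs()` sums, per epoch and channel:

* **Aperiodic background**: Gaussian white noise shaped in the frequency
  domain with amplitude `10^(offset/2) · f^(−exponent/2)`, giving a power
  spectral density proportional to `10^offset · f^(−exponent)` — exact
  control of the aperiodic truth (`powerlaw_noise()`).
* **Alpha**: a sinusoid at the subject's drawn IAF on parietal channels,
  with pre- and post-onset amplitudes set per repetition (100 ms
  raised-cosine crossfade at onset). Repetition-dependent amplitude
  vectors implement learning-related drift of pre-stimulus power.
* **Theta burst**: a Hanning-windowed burst at `IAF − 5` Hz on mid-frontal
  channels, centered 250 ms post-onset.

Subject IAFs are drawn per group from truncated normal distributions
(defaults near 10.5/10.2 Hz, truncated to 7.5–13.5 Hz) so every simulated
subject has a detectable peak. All generators are deterministic functions
of the config seed.

Default cohort sizes (20 subjects per group, desk-scale montages) are
package choices made so the full pipeline runs in minutes on one CPU; they
are not claims about required sample sizes.

## Time-frequency decomposition

`sliding_tfr()` uses a 500 ms Hanning window stepped in 50 ms increments
(window centers −500..900 ms), zero-padded to a 0.2 Hz frequency grid
(1–40 Hz). Power is `|FFT|² / (Σw)²`, so a unit-amplitude sinusoid yields
0.25 linear power at its bin; values are floored at the machine epsilon
before log10. A multitaper (DPSS) estimator would lower variance at fixed
bandwidth, but a single Hanning taper keeps the estimator identical to the
high-resolution Welch estimator used for IAF detection
(`long_segment_spectrum()`: 5 s Hanning segments, 50% overlap) and is
fully reproducible without extra dependencies; this deviation is
deliberate and documented here.

## Spectral parameterization

`fit_spectrum()` decomposes a log-power spectrum into an aperiodic
component (offset, exponent, optional knee) plus Gaussian peaks, following
the published iterative algorithm: initial robust aperiodic fit (refit on
the lowest 0.025th-percentile residuals), iterative peak guessing on the
flattened spectrum (argmax residual, half-height FWHM width estimate,
subtract, repeat), joint Gaussian refinement, and a final simple aperiodic
fit on the peak-removed spectrum.

Two numerical choices matter for reproducibility:

* The joint Gaussian refinement uses **unbounded Levenberg–Marquardt**
  (`minpack.lm`) with validity filtering instead of box constraints:
  after optimization, components with non-positive height, centers outside
  the frequency range, or widths outside twice the configured limits are
  dropped, and each multi-start candidate is scored by the sum of squared
  errors of its *surviving* components. This removes optimizer-specific
  behavior at the constraint boundary, so an independent implementation
  wrapping the same MINPACK code reproduces the fits to numerical
  precision (the test suite compares against a frozen, independently
  produced reference on 20 shared spectra).
* Multi-start (all guesses, and the tallest guess alone) prevents a broad
  true peak from being split into several narrow Gaussians at a slightly
  lower residual — a local-minimum failure mode of single-start fits.

Model quality is summarized by R² on the log spectrum; `qc_filter()`
excludes repetitions whose mean R² falls below a threshold (0.9 default).

## IAF and band definitions

`detect_iaf()` takes the aperiodic-adjusted spectrum and returns the
frequency of maximal adjusted power strictly inside 7–14 Hz; an argmax on
a border bin or non-positive adjusted power yields a missing IAF (the
subject is excluded rather than assigned a default). Bands are
IAF-relative: theta `IAF−6 .. IAF−4` Hz, alpha `IAF−4 .. IAF+2` Hz,
contiguous at `IAF−4`. Analysis windows: theta 100–500 ms, alpha
250–900 ms, baseline −500..−250 ms.

## Mediation analysis

The causal system is the linear two-equation model with treatment
`repetition` (X), mediator `prestim` (M) and outcome `ers_erd_rep` (Y),
each equation a linear mixed model with a random subject intercept
(`lme4`, REML; a fixed-effects fallback with a warning when the random
intercept variance degenerates):

```
M0: Y ~ X + (1|subject)          — total effect (premise check)
M:  M ~ X + (1|subject)          — path a
Y:  Y ~ X + M + (1|subject)      — paths b and c'
```

In this no-interaction linear system, ACME = a·b, ADE = c′, and
total = ACME + ADE exactly (the package asserts the additivity to 1e−10).
Uncertainty comes from either a **cluster bootstrap** (subjects resampled
with replacement and relabeled, preserving the within-subject repeated
measures) or **quasi-Bayesian Monte-Carlo** draws from the asymptotic
sampling distribution of the coefficients; both give percentile intervals.
The null-calibration study in the test suite (200 replicates under b = 0)
uses the Monte-Carlo intervals for runtime reasons; the bootstrap is the
default for single analyses. *Inconsistent mediation* — ACME and ADE of
opposite signs, i.e. the mediator suppresses the direct effect — is
flagged explicitly, and the proportion mediated is reported as undefined
when the total effect is near zero.

## Behavior

A sequence ends after 3 fully-correct recalls in total (not necessarily
consecutive) or 8 repetitions. `completion_time_distribution()` computes
the exact Markov-chain stopping-time distribution and serves as the oracle
for the Monte-Carlo generator. Per-item learning follows a logistic curve
per group; learning states (`unknown` → `newly_learned` → `known` →
`very_well_known`) follow a cumulative-correct rule. Fixation control uses
an inclusive Chebyshev criterion (gaze inside a centered 1.26° square for
at least 90% of the presentation).

## End-to-end pipeline

`run_pipeline()` chains all stages on a config
(`demo_config()` / `config_from_yaml()`): generation → amplitude rejection
→ TFR → spectral parameterization and QC → IAF/bands → band-power tables
under both schemes → behavioral scoring → mediation per band × group. With
the demo config, pre-stimulus alpha drifts upward across repetitions while
the evoked response drifts mildly upward, producing the characteristic
suppression pattern for the alpha outcome: negative ACME with positive
ADE. Artifacts are written as TSV with a hash manifest; re-runs with an
unchanged config are byte-identical.

## Limitations

* The generator is a stylized model (stationary 1/f noise, pure
  sinusoidal alpha, a single theta burst); it is not a biophysical
  simulation, and effect sizes are package choices, not empirical claims.
* Mediation assumes the linear no-interaction system with sequential
  ignorability; the estimator recovers the generating paths of that
  system and nothing stronger.
* Desk-scale defaults trade statistical power for runtime.
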
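---
title: "Models and methods behind caensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caensembles)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical conventions it fixes, and what its
synthetic-data validation does and does not demonstrate.

## Isosbestic ΔF/F correction

Two-channel fiber photometry interleaves a calcium-sensitive 470-nm
excitation with a 405-nm isosbestic excitation. At the isosbestic point the
indicator's fluorescence is independent of calcium binding, so the 405
channel carries only what both channels share: photobleaching and
motion/coupling artifacts. We model the channels as

$$F_{470}(t) = B_{470}\,b(t)\,[1 + a(t) + s(t)] + \epsilon(t), \qquad
  F_{405}(t) = B_{405}\,b(t)\,[1 + a(t)] + \epsilon'(t),$$

with bleach $b(t)$, shared multiplicative artifact $a(t)$, and calcium
transients $s(t)$ present only at 470 nm. Under this model the artifact
component of the 470 channel is an *affine* function of the 405 channel, so
a least-squares affine fit $\hat F = \alpha F_{405} + \beta$ followed by

$$\Delta F/F = \frac{F_{470} - \hat F}{\hat F}$$

removes bleach and artifact exactly in the noise-free limit and leaves
$\Delta F/F = s(t)$ up to the local artifact modulation. The fit is affine
(slope *and* intercept) rather than slope-only: the intercept absorbs
channel-specific offsets (autofluorescence, detector dark level) and the
affine fit contains the slope-only fit as a special case. A constant
control channel degenerates to an intercept-only fit with a warning;
ΔF/F is marked undefined where the fitted control is non-positive and the
whole fit is rejected when more than 1% of samples are undefined.

**Trimmed re-estimation.** Transient samples live only in the regressand,
so they exert leverage on a plain least-squares fit and bias the slope
upward by roughly the transient duty cycle (order $10^{-4}$ relative for
sparse events — enough to leave a visible baseline offset in ΔF/F). The
default fit therefore iterates: fit, compute residuals, drop samples whose
residual deviates from the median residual by more than `trim_mads`
(default 5) scaled MADs, refit, until the kept set stabilizes (at most
`max_iter = 20` passes, never trimming below half the trace). This mirrors
the baseline re-estimation used by the transient detector below, and in the
noise-free limit it converges to the exact generative coefficients, which
is what makes the package's exactness checks sharp (corrected ΔF/F ≤ 1e−9
on shared-artifact recordings; a planted 0.05 transient peak recovered to
1e−9). `trim_mads = Inf` gives the plain all-samples least-squares fit.

## MAD transient detection

A significant transient is an epoch in which ΔF/F exceeds
`onset_mads = 2.91` MADs above the baseline median and remains at least
`sustain_mads = 2` MADs above it for a sustained period. Conventions we
fix:

* **Raw MAD.** The MAD is the plain median absolute deviation, *without*
  the 1.4826 normal-consistency factor, because the thresholds are quoted
  directly in MAD units. Under Gaussian noise 2.91 raw MADs ≈ 1.96 σ, i.e.
  the onset threshold is a two-sided 95% criterion; the 2-MAD sustain level
  is ≈ 1.35 σ.
* **Sustained period.** The minimum epoch duration is not standardized
  anywhere we could anchor it, so it is an explicit parameter,
  `min_duration_s = 0.5` s by default — long enough (25 samples at 50 Hz)
  that white noise essentially never qualifies, short relative to a
  GCaMP6s transient.
* **Baseline.** By default the whole trace, with one re-estimation pass
  that excludes first-pass candidate epochs so large transients do not
  inflate their own threshold. A `pre_event` mode restricts the baseline to
  samples before the first event. A zero baseline MAD raises an error; we
  never floor the variance silently.
* **Epoch rule.** An epoch is a maximal run of samples at or above the
  sustain level that contains at least one sample at or above the onset
  level and lasts at least the minimum duration. This makes detection
  monotone: raising a pulse's amplitude can only preserve or extend
  detections.

Under these defaults the false-positive rate on pure white noise is
effectively zero: a one-time brute-force simulation of the thresholding
rule (100 seeds × 50,000 Gaussian samples) produced no epochs at all, and
the test suite freezes that bound (median count ≤ 0) as a regression check.
Note the bound is about *white* noise; correlated noise (e.g. hemodynamic
or slow-drift residue) can only be assessed on real data.

## Peri-event quantification

Photometry responses are aligned to event onsets on the native sampling
grid over [−10, +10] s. The baseline AUC integrates samples strictly before
the onset sample, the stimulus AUC integrates from the onset sample to
+10 s, both by the trapezoidal rule on the native grid (bit-reproducible,
additive over any interior split point); the peak is the maximum ΔF/F in
the stimulus window. Events without full window support are dropped and
counted. For nose-poke-style alignments each event onset gets its own
±10 s window; callers who want only a session's first and last pokes can
pass exactly those onsets — the event list is the interface, so both
readings of "per-poke" vs "first/last poke" alignment are expressible.

## Single-neuron z-scoring and responsiveness

Miniscope traces (15 Hz after downsampling) are aligned to events on
[−10, +20] s. Each neuron × trial segment is z-scored against *that
trial's* baseline window [−2, 0) s: $z = (x - \bar x_{base})/s_{base}$ with
the sample SD ($n-1$). Choices worth stating:

* **Per-trial, not pooled, baselines.** Pooling baselines across trials is
  also defensible; per-trial is the drift-robust reading and makes each
  trial's z self-normalizing (baseline mean 0, SD 1 exactly — asserted to
  1e−8 in the tests).
* **Baseline excludes the onset sample.** The window is half-open,
  $[-2, 0)$: the $t = 0$ sample belongs to the response.
* **Order of averaging.** The response summary takes the time-mean over
  [0, 20] s within each trial first, then averages the first four *valid*
  trials in event order. For complete windows this equals the pooled mean;
  the fixed order makes the statistic well-defined when bins are missing.
* **Zero-variance baselines invalidate the trial** for that neuron rather
  than being patched with a variance floor: a floor distorts z by an
  arbitrary factor, an exclusion is visible and testable.
* **Strict threshold.** Responsive means mean z *strictly greater than*
  1.5; a neuron at exactly 1.5 is not responsive.

These conventions make classification invariant to neuron ordering, to
trials after the fourth valid one, and to per-neuron positive affine
rescaling of raw fluorescence.

## Ensemble overlap statistics

Given label sets for two stimuli over the same registered neurons, the
observed overlap (fraction responsive to both) is compared with a
marginal-preserving shuffle: both label sets are independently re-drawn as
uniform random subsets of the observed sizes, 10,000 times. Shuffling both
sets independently is equivalent in distribution to shuffling one against
the other held fixed, and it makes the null overlap count exactly
hypergeometric — which gives a closed-form oracle, implemented as
`hypergeometric_tail()` via log-binomial summation (exact to ~1e−12 and
cross-checked against `stats::phyper` and full subset enumeration in the
tests). The one-tailed p uses the add-one correction
$(1 + \#\{ \text{null} \ge \text{obs} \})/(n_{perm}+1)$, standard practice
so a finite shuffle never reports p = 0. An optional stratified mode
shuffles within strata (e.g. animals) with per-stratum margins; the global
shuffle is the default. On the published 84/65/34/197 margins the global
exact tail is ≈ 0.24, which differs from the originally reported
permutation p for those counts — consistent with the original analysis
having used a stratification or neuron subset not recoverable from the
printed margins, and one reason the package treats the hypergeometric
equivalence, not any particular printed p, as the correctness criterion.

Magnitude correlation is plain Pearson r with the two-sided t-transform p
(`stats::cor.test`). Its recovery check plants r = −0.5 across n = 129
pairs and asks that the mean of seeded estimates fall in the single-sample
Fisher-z 95% band $\tanh(\mathrm{atanh}(\rho) \pm 1.96/\sqrt{n-3})$; the
band is deliberately the single-sample one because the estimator's known
$O(1/n)$ small-sample bias exceeds the width of a mean-of-500 band, which
no correct unadjusted estimator could satisfy. Proportion changes use the
two-proportion chi-square without continuity correction (a `correct` flag
enables Yates), with degenerate all-zero/all-one margins reported as
chi-square 0, p = 1. Printed percentages are reproduced with half-up
integer rounding.

## Cross-session registration

Full registration toolboxes model footprint shape and a same-cell
probability; here sessions are matched by centroids alone: mutual nearest
neighbors within `max_dist_px`, ties broken by distance then lexicographic
id. This is deterministic, one-to-one, symmetric under input swap, and
monotone in the distance cap. It is adequate when jitter is small relative
to spacing — at 1 px jitter and ≥ 15 px spacing it recovers 100% of planted
matches at a 5 px cap — and it is *not* a reimplementation of
footprint-based methods: published alignment yields (e.g. 380 of 948 cells)
depend on those toolboxes and real imaging noise, and are not a target. An
optional translation step (median displacement of provisional pairs,
off by default) handles small rigid field shifts; it requires the shift to
be below about half the cell spacing, or the provisional pairs are wrong.

## Tracing input indices

Input counts come from every third 60-µm section; a region whose
every-third count falls below 5 is recounted from every section and scaled
by `sampling_fraction` to stay commensurate. The scale factor is 1/3 by
construction of the every-third protocol — the factor restores the
expected one-third sampling, and the simulation tests confirm the scaled
counts are unbiased for one third of the true totals. Indices are each
region's effective count over the brain's total effective count, normalized
*within* brain before averaging across brains (totals vary several-fold
between brains). No double-counting correction is applied; cells split
across section boundaries inflate counts slightly and region-dependently,
a known bias we inherit rather than model.

## What the generators emulate — and what they do not

* `sim_photometry()`: shared multiplicative artifact (two slow sinusoids at
  0.005–0.05 Hz plus a scaled random walk), exponential bleach, additive
  Gaussian sensor noise scaled to baseline, and transients with
  instantaneous rise and exponential decay (`decay_tau = 1.5` s, a GCaMP6s
  approximation), truncated where the kernel falls below 1e−10 of its peak.
  Default 50 Hz, 0.05 ΔF/F transients, 0.05 artifact amplitude, 0.002
  ΔF/F-equivalent noise.
* `sim_ensemble_session()`: planted A-only/B-only/both fractions (defaults
  0.17/0.22/0.09, the observed selective/dual split; counts are floored,
  remainder to "neither", so planted counts are exact for every seed);
  responses in baseline-noise z units whose *post-window mean* equals
  `response_amp_z` (so the downstream mean-z summary estimates the planted
  amplitude directly), with 0.5 z trial-to-trial jitter and i.i.d. Gaussian
  frame noise. The response kernel decays with `kernel_tau = 6` s: with the
  amplitude defined as a 20-s window mean, a seconds-scale decay would
  force implausibly large peaks, while a sustained bout-locked response
  (seconds-long drug-seeking and interaction bouts) is the regime the
  classification window was designed for.
* `sim_centroid_pair()`: uniform centroids with rejection-sampled minimum
  spacing (default 15 px in a 300 px field), isotropic between-session
  jitter, dropout, permuted ids.
* `sim_region_counts()`: per-section Poisson counts, random counting phase,
  log-normal per-brain totals, and the low-count rescue applied exactly as
  in the counting protocol.

Not emulated: correlated (non-white) noise, hemodynamic contamination,
neuropil and crosstalk between neighboring ROIs, segmentation errors,
footprint shape, behavioral timing structure beyond event lists, and any
spiking-to-fluorescence biophysics. Passing the recovery suites therefore
demonstrates correctness of the *computations* under the stated model, not
robustness to every failure mode of real recordings.

## Problem sizes and determinism

Every stochastic routine takes an explicit `seed` and restores the
caller's RNG state (`withr::with_seed`), so identical calls are
bit-identical. The validation suites use: 20 seeded sessions of 200
neurons for classifier recovery; 20 margin configurations × 10,000
permutations for the overlap oracle; 100 seeds × 50,000 samples for the
false-positive bound; 500 seeds at n = 129 for correlation recovery; 200
seeds for counting unbiasedness — sizes chosen so each check's Monte-Carlo
error is small against the tolerance it asserts while the whole suite runs
in well under a minute on a laptop core.

## Known limitations

* The isosbestic model assumes the artifact is common-mode and
  multiplicative; wavelength-dependent artifacts (e.g. true hemodynamic
  absorption differences) are out of scope.
* Centroid-only registration degrades with dense packing or warping; it is
  a testing scaffold and a baseline, not a CellReg replacement.
* The overlap null treats neurons as exchangeable across the whole
  population unless strata are supplied; animal-level clustering otherwise
  inflates apparent significance.
* Input indices inherit the counting protocol's double-counting bias.
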
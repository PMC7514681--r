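---
title: "Multiscale entropy analysis of prefrontal fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy analysis of prefrontal fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsmse)
```

## The analysis

`nirsmse` implements a complexity analysis of prefrontal functional
near-infrared spectroscopy (fNIRS) recordings collected under different
communication media (audio speaker, video chat, a teleoperated humanoid,
and in-person conversation).  Each participant contributes one session per
medium: a ~60 s eyes-closed rest segment and a ~180 s listening-task
segment of 4-channel total-hemoglobin series sampled at 10 Hz, plus an
8-point fatigue self-report.  The pipeline is:

1. **Preprocessing** per channel: first-order Butterworth bandpass
   (0.01–0.6 Hz), linear detrending, then removal of the skin-blood-flow
   (SBF) subspace — the leading principal components of the channel
   covariance of the *rest* segment are projected out of the *task*
   segment.
2. **Multiscale entropy (MSE)**: sample entropy SampEn(m = 2, r = 0.15 σ)
   of the preprocessed task series coarse-grained at scale factors 1–20;
   the scalar per session is the arithmetic mean over defined scales
   ("averaged MSE").
3. **Group statistics**: Friedman test across media on the participants ×
   media averaged-MSE matrix, post hoc paired Wilcoxon signed-rank tests
   (Bonferroni-corrected over the 6 pairs), and per-medium Spearman
   correlation between averaged MSE and fatigue (Bonferroni-corrected over
   the 4 media).  Effect sizes follow the rank-statistics conventions
   r = √(χ²/N) (Friedman, N = total observations) and r = |Z|/√N
   (Wilcoxon, N = contributing pairs).
4. **Fatigue classification**: within each medium the mean of the averaged
   MSE values is the cluster's decision boundary.  A session above the
   boundary with fatigue ≤ 4 is a true positive — the positive class is
   *not fatigued*, because higher PFC complexity is hypothesized to
   accompany less perceived fatigue.  Confusion counts give accuracy,
   precision, recall and F1; the evaluation is in-sample by construction
   and reported as such.

## Sample entropy and its estimation

SampEn(m, r) is −ln(A/B), where B counts pairs of distinct length-m
templates within Chebyshev distance r and A counts those whose length-(m+1)
extensions still match.  Both counts run over the same n − m template
positions and exclude self-matches, so A/B is a conditional probability and
the estimate is nonnegative.  When A or B is zero the estimate is
*undefined*; undefined scales are recorded and excluded from the averaged
MSE rather than imputed, because imputation would bias the per-participant
scalar toward an arbitrary constant.

Numerical choices that are pinned for reproducibility:

* σ is the **population** SD (denominator n) of the scale-1 preprocessed
  series; r = 0.15 σ is then held fixed across all scales (the original
  coarse-graining convention).  Per-scale re-normalization would change
  what the profile measures.
* Entropies are natural-log (nats).
* Coarse-graining at scale τ averages non-overlapping windows and drops the
  trailing remainder, so a 1800-sample task series retains 90 points at
  τ = 20.  Estimates there are high-variance; the package warns when fewer
  than 100 points remain.

For iid Gaussian noise SampEn(2, r) has the closed form −ln(erf(r/2σ))
(≈ 2.47 at r = 0.15 σ), which the test suite uses as an independent
oracle, alongside an exhaustive O(n²) template-counting oracle.

## Preprocessing decisions

* "First-order Butterworth bandpass" is implemented by the standard analog
  prototype → band transform → bilinear transform route and applied
  forward–backward (zero phase) by default, because entropy is sensitive to
  waveform distortion; a causal single pass is available.  Odd-reflection
  padding (capped at the series length) suppresses edge transients of the
  very long 0.01 Hz high-pass memory.
* Stage order is filter → detrend → SBF removal.
* The SBF model is spatial: component vectors live in channel space, are
  fitted per session on that session's filtered and detrended rest segment,
  and the rest-period channel means are reused to center the task data
  before projection.  With 4 channels and the default 3 components the
  residual is spatially rank-1 — all channel pairs end up perfectly
  correlated — which is why correlation-based "SBF removed" checks are
  only meaningful for fewer components, and why the analysis proceeds on a
  single channel (left 3 cm, `L3`).
* Temporal-component alternatives were rejected: rest and task have
  different lengths, making a temporal projection ill-defined.

## The synthetic cohort: what it emulates

No raw recordings are distributed with the study this pipeline
re-implements, so `generate_cohort()` provides a seedable stand-in with
exactly the structure the preprocessing chain presupposes; every stage has
a component it demonstrably removes.

Each channel's series is a sum of, in units of the task-segment neural SD:

| component | default | removed by |
|---|---|---|
| neural: 1/f^β noise inside a hemodynamic band (spectral knee 0.05 Hz, order-2 rolloff) | β per medium: telenoid 0.55, face-to-face 0.66, speaker 0.92, video chat 1.19 | — (the signal of interest) |
| cardiac / respiratory / Mayer quasi-sinusoids (~1.1 / 0.3 / 0.1 Hz, 5 % frequency jitter), loading inside the SBF spatial subspace | SD 0.4 / 0.25 / 0.3 | bandpass (cardiac); SBF projection (slow components) |
| rank-3 SBF: slow latent series (β = 2, 0.08 Hz knee) mixed through a per-session random unit-norm spatial matrix | SD 2.5 per component | rest-period eigen-decomposition |
| linear instrumental drift | SD 0.3 | detrending |

The rest segment shares the session's SBF mixing and artifacts but carries
baseline pink neural noise at reduced amplitude (SD 0.5), reflecting the
lower variability of eyes-closed baselines.

**Direction of the complexity axis.** For broadband noise, coarse-scale
MSE famously *increases* toward 1/f — and the package's tests verify this
on raw colored noise.  Inside a band-limited hemodynamic world the relation
inverts: once the 0.01–0.6 Hz bandpass fixes the analysis band and r is
tied to the scale-1 SD, a *whiter* in-band spectrum (lower β) is the more
entropic signal at every scale.  The generator therefore assigns the
*lower* β to the media with the higher averaged MSE.  Condition defaults
were calibrated once against the pipeline so the between-media averaged-MSE
differences match the magnitudes a prefrontal total-hemoglobin study
reports (telenoid − video chat ≈ 0.12, face-to-face − video chat ≈ 0.10,
speaker − video chat ≈ 0.05); absolute levels come out ≈ 0.1 higher than
that study's printed means, a consequence of keeping the estimator noise
of the 180 s sessions acceptable.

**Participant effect.** Individuals differ in vascular response speed: the
hemodynamic knee is scaled per participant by a log-normal factor
(`participant_log_fc_sd`, default 0.35) shared across their sessions.
This trait is monotone in entropy, nearly linear over its range (unlike a
β offset, which would saturate), and is the *planted complexity* that the
fatigue link couples to.

**Fatigue link.** `fatigue_link` targets the Spearman correlation between
the *measured* averaged MSE and fatigue.  Discretizing the latent fatigue
to the 8-point scale and the MSE estimation noise of a single 180 s series
attenuate any latent association (attenuation ≈ 0.8 at default settings),
so the generator inflates the latent Gaussian-copula coupling by a fixed
calibrated de-attenuation factor of 1.24 before drawing scores
(fatigue ≈ round(4.5 + 2·latent), clamped to 1–8, matching the location
and spread such studies report).  The calibration constants were fixed
once from the default world and are not re-fitted.

**What a green test does not establish.** The generator's neural component
is stationary Gaussian noise with a planted spectrum; it contains no
hemodynamic response function, no task-locked activation, no motion
spikes, no optode physics, and its participant differences are a single
smoothness trait.  Passing recovery tests therefore show that the
*pipeline* is faithful and statistically powered for this class of signal
— not that the scientific conclusions of any particular study are correct.

## Degenerate inputs and tie-breaks

* A constant series has σ = 0: every scale is undefined and the averaged
  MSE is `NA` with an explicit flag.
* A session whose averaged MSE equals the decision boundary exactly counts
  as *below* (the positive side is strictly above).
* Zero differences are dropped from the Wilcoxon test; fewer than 5
  remaining pairs is an error, all-zero differences a degenerate p = 1
  result.  Exact signed-rank p-values are used for n < 20 without ties,
  the tie-corrected normal approximation otherwise; the reported statistic
  is always the standardized Z, since published "W" values in this
  literature are standardized.
* Friedman rows with missing values are dropped listwise; a fully tied
  matrix yields χ² = 0 rather than 0/0.
* Bonferroni correction multiplies by the number of comparisons (6 pairs
  for post hoc Wilcoxon, 4 media for the Spearman screen).  The alternative
  of multiplying by the sample size is not a recognized correction and was
  rejected.

## Known limitations

* The in-sample decision boundary makes the classifier's accuracy an
  optimistic estimate; the report labels it as such rather than adding a
  cross-validation the original procedure does not contain.
* With 60 s of rest and slow, band-limited signals, the rest-period
  covariance has few effective degrees of freedom, so the estimated SBF
  subspace is noisy and some superficial signal leaks into the task
  residual.  This is a property of the method itself, reproduced — not
  hidden — by the synthetic world.
* Averaged MSE from a single 180 s session carries estimation noise of
  roughly 0.08–0.10 nats at the default settings, which bounds how strong
  a measured MSE–fatigue correlation can be; the generator's de-attenuated
  coupling makes the planted and measured associations consistent.
* No refined or composite MSE variants, no multivariate MSE, and no fuzzy
  entropy; scales are fixed at 1–20 as in the procedure being
  re-implemented.
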
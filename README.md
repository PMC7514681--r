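# nirsmse

Multiscale-entropy analysis of prefrontal fNIRS recordings across
communication media, as a tested, reusable R pipeline.

## The problem

How strongly does the physical embodiment of a communication medium — an
audio speaker, a video chat, a teleoperated humanoid, an in-person
storyteller — modulate the dynamics of a listener's prefrontal cortex, and
does that modulation track the listener's perceived fatigue?  The analysis
operationalizes "dynamics" as the **multiscale entropy (MSE)** of 4-channel
total-hemoglobin fNIRS series (10 Hz; channels L1, L3, R1, R3; the 3 cm
channels carry cortical signal), recorded per participant × medium as a
~60 s rest segment plus a ~180 s listening-task segment with an 8-point
fatigue self-report.

The core statistic is sample entropy on coarse-grained series,

SampEn(m, r) = −ln(A/B),

where B counts template pairs of length m within Chebyshev distance
r = 0.15 σ (self-matches excluded) and A counts those still matching at
length m + 1; the series is coarse-grained by non-overlapping τ-windows for
τ = 1…20 and the per-session scalar is the mean over defined scales
("averaged MSE").  Group inference is nonparametric (Friedman across
media, paired Wilcoxon post hocs with r = |Z|/√N, Spearman vs fatigue,
Bonferroni), and a threshold classifier uses each medium's mean averaged
MSE as decision boundary with fatigue binarized at 4.0 (above-boundary ∧
fatigue ≤ 4 = TP: the positive class is "not fatigued").

Because the underlying study deposited no raw data, the package ships a
seedable synthetic-cohort generator (`generate_cohort()`) with the
statistical structure the preprocessing chain presupposes — power-law
neural signal in a hemodynamic band, systemic quasi-sinusoids, a low-rank
shared skin-blood-flow component, instrumental drift, and a planted
MSE–fatigue link — so every stage is testable offline.  See the methods
vignette (`vignettes/nirsmse-methods.Rmd`) for the generative model and
all calibration decisions.

## Worked example

```r
library(nirsmse)
cfg <- run_config(cohort = cohort_spec(n_participants = 16, seed = 42),
                  output_dir = "demo_run")
res <- run_pipeline(cfg)
res$stats[, c("test", "comparison", "statistic", "p_corrected", "effect_size")]
res$reports[["telenoid"]]
```

which prints (abridged):

```
                 test                               comparison statistic p_corrected effect_size
             friedman speaker|video_chat|telenoid|face_to_face   21.9750    0.000066      0.5860
 wilcoxon_signed_rank                      speaker vs telenoid   -3.4128    0.000549      0.8532
 wilcoxon_signed_rank                 telenoid vs face_to_face   -0.1551    1.000000      0.0388
 spearman_mse_fatigue                                 telenoid   -0.8018    0.000750     -0.8018
 ...
Fatigue classifier, medium telenoid (in-sample boundary 0.9795, fatigue cut 4.0)
  TP 6  TN 9  FP 1  FN 0   (n = 16, 0 excluded, chance 50.0%)
  accuracy 93.75%  precision 0.86  recall 1.00  F1 0.92
```

Reading: the media differ in PFC complexity (Friedman χ² = 21.98,
p_corr < 0.001, r = 0.59); the embodied medium and the in-person setting
sit above speaker/video chat (significant pairwise contrasts) but do not
differ from each other; averaged MSE anti-correlates with fatigue in the
telenoid condition only (ρ = −0.80), and thresholding MSE at the cluster
mean predicts fatigue well above the 50 % chance level there.  The run
also writes `sessions.csv`, `mse_profiles.csv`, `stats.csv`,
`classifier_table.csv`, `classifier_reports.json` and a reproducibility
`manifest.json` into `output_dir`; identical config + seed reproduces the
bundle byte for byte.

A command-line front end with `simulate | preprocess | mse | stats |
classify | run` subcommands is installed at
`system.file("cli", "nirsmse.R", package = "nirsmse")` (JSON config,
`--seed`, `--out`; exit codes 0/1/2 = ok/user error/internal error).

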
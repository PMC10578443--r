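---
title: "Methods: detecting OCD distress episodes from wrist biosensor signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting OCD distress episodes from wrist biosensor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e4episodes)
```

## The problem

Adolescents with obsessive-compulsive disorder (OCD) experience episodes of
distress driven by obsessions and compulsions. A wrist-worn biosensor can
record the autonomic correlates of such episodes continuously — blood volume
pulse (BVP, 64 Hz), electrodermal activity (EDA, 4 Hz), skin temperature
(TEMP, 4 Hz) and derived heart rate (HR, 1 Hz) — while the wearer marks
episodes with a button press. `e4episodes` implements the complete analysis
pipeline for this setting: session ingestion, sleep/non-wear filtering,
event windowing, feature extraction, classification under several
generalization scenarios, feature attribution, and sample-size planning —
plus a synthetic cohort generator so every stage is testable with known
ground truth.

## Windowing model

A button press is a *point* event; episode duration is unknown. Each tag
`t` therefore defines:

* an **event window** `[t - 300 s, t)` — the five minutes preceding the
  press;
* a **buffer** `[t, t + 300 s)` — excluded from both classes so that
  post-event physiology cannot contaminate nonevents;
* **nonevent windows** — 5-min windows sampled uniformly at random from
  remaining wear time, at least three per recording session.

Decisions the windowing scheme leaves open were resolved as follows:

* A tag falling inside a previous tag's event window or buffer is dropped
  (label purity beats data volume at this cohort size); its buffer still
  joins the exclusion zone for nonevent sampling, since data after *every*
  press is suspect.
* Windows containing any gap (sensor dropout, non-wear) are rejected
  rather than imputed; the per-channel slice must contain exactly
  `rate x 300` samples.
* Nonevent starts are drawn on the 0.25-s EDA grid so all four channels
  stay sample-aligned.
* Nonevent volume above the per-session minimum follows a cohort-wide
  negatives-per-positive target (default 1.67, matching the realized
  event/nonevent proportions of the motivating cohort). For
  null-calibration studies `nonevents_match_events = TRUE` draws exactly
  one nonevent per event in the same session, which fixes every
  participant's class prior at 1/2 — without matching, per-participant
  differences in tag rates let a classifier beat the pooled majority
  baseline from cluster priors alone, even when physiology carries no
  signal.

Sleep and non-wear are removed before windowing. The wristband reports
near-zero skin conductance and ambient temperature off-wrist, so non-wear
is flagged where EDA < 0.03 µS *and* TEMP < 30 °C for at least 5 min
(thresholds configurable; the rule is a conventional heuristic, not a
claim about the original study's method). Sleep defaults to a daily 23:00
to 07:00 clock mask; precedence is sleep > non-wear > wear, and the three
states always partition the session span.

## The 66 features

Each complete window yields 66 features: 24 from BVP, 9 from HR, 5 from
TEMP and 28 from EDA (`feature_catalog()` lists every definition). The
exact feature list used by the motivating study is not public; this
catalog is a reconstruction that honours the published group counts and
contains the feature families reported as most important (BVP slope,
BVP frequency content, BVP variation). It is data-driven, so a different
catalog can be swapped in without touching callers.

Numerical conventions are fixed for reproducibility:

* Spectra are Welch periodograms with 64-s Hann segments at 50 % overlap;
  band powers integrate the one-sided PSD.
* EDA splits into tonic (order-2 Butterworth low-pass, 0.05 Hz cutoff,
  zero-phase forward-backward filtering) and phasic (residual); the two
  components reconstruct the input exactly.
* Skin conductance responses (SCRs) are trough-to-peak excursions of the
  phasic component with amplitude >= 0.05 µS — the conservative end of
  conventional SCR criteria, chosen so instrument noise of a few
  thousandths of a µS is not counted. Rise time is onset-to-peak; half-recovery is peak to
  first crossing of half-amplitude and is excluded from its mean when the
  trace does not recover inside the window.
* Degenerate (constant) signals have skewness, kurtosis, spectral
  entropy, dominant frequency and zero-crossing rate defined as 0.

Features are standardized to zero mean and unit variance with statistics
estimated **on training rows only** and applied to validation/test rows;
fitting the scaler on all data would leak.

## Models

Four classifier families sit behind one interface, all trained after
random duplication-oversampling of the positive class to parity (the
simplest scheme consistent with "oversampled to match"; synthetic
interpolation is a known alternative):

* **LR** — ridge-penalized logistic regression (`glmnet`, small λ grid).
* **RF** — probability random forest (`ranger`).
* **NN** — single-hidden-layer feedforward network (`nnet`), width grid
  {16, 64}. `nnet` offers no validation-based early stopping, so weight
  decay (0.01) provides the equivalent regularization for a model this
  small.
* **MERF** — mixed-effect random forest, written in this package: a
  regression forest for the fixed-effect function `f(x)` plus a scalar
  random intercept `b_i` per participant,
  `y_ij = f(x_ij) + b_i + e_ij`, `b_i ~ N(0, σ_b²)`,
  `e_ij ~ N(0, σ²)`, estimated by EM-style alternation. For a random
  intercept the E-step is closed-form,
  `b_i = σ_b² Σ r_ij / (σ² + n_i σ_b²)` with `r_ij` the fixed-effect
  residuals; the M-step refits the forest on `y - b` and updates both
  variance components; iteration stops when the generalized
  log-likelihood criterion changes by less than `tol` (default 1e-3) or
  after `max_iter` rounds. Classification is regression on the 0/1
  response with scores clipped into [0, 1]. Rows from clusters unseen at
  training time receive the forest prediction alone, so on a new
  participant the MERF degrades gracefully to a plain random forest;
  with `sigma_b_init = 0` the intercepts stay pinned at zero and the
  model *is* a plain regression forest.

## Evaluation scenarios

`make_split_plan()` builds nested cross-validation plans for four
clinically distinct questions:

* **random** — stratified 10-fold outer CV, k-fold inner CV; an
  optimistic upper bound since windows from the same person and period
  appear on both sides.
* **participant** — leave-one-subject-out outer folds; the inner layer
  rotates one held-out training participant as validation. Fold metrics
  are aggregated weighted by each test participant's share of windows
  (the natural reading of weighting "by population percentage").
* **temporal** — per participant, the first 75 % of observation days
  train, the next 12.5 % validate, the final 12.5 % test; the 75 %
  boundary rounds down and the 87.5 % boundary rounds up so both sets
  are non-empty from 8 observation days. The hold-out is fixed; 10
  repetitions vary only oversampling draws and model seeds.
* **personalized** — the temporal split within each single participant
  (participants with < 8 observation days are skipped).

The inner layer selects the (model, hyperparameter) pair with the best
mean inner-validation accuracy; the winner is refit on the outer
training set and scored on the test set with accuracy, F1, precision,
recall and rank-based ROC-AUC (ties counted 1/2), next to the
majority-guess baseline. Fold-averaged metrics are reported (pooled
prediction metrics would be the alternative aggregation; fold averaging
matches the error-bar presentation this design supports).

`compare_personal_vs_temporal()` subtracts personalized from temporal
metrics per participant over paired repetitions with two-sided,
uncorrected paired t-tests — exploratory at n = 8, as any such table
must be. `downsample_other_participants()` equalizes training volume
across participants for the down-sampled generalized comparison.

## Feature attribution

Per-observation signed attributions use tree-path decomposition: each
observation is walked down every tree and the change in node mean
response at each split is credited to the split feature (positive values
push toward the event class). Node means are recomputed by routing the
training rows through each tree, so for forests grown on the full sample
the attributions plus the root value reconstruct the tree response
exactly; under bootstrap resampling they track it up to resampling
differences. No TreeSHAP implementation exists in this package's
dependency set, and tree-path attribution provides the same signed,
per-observation semantics; a permutation backend covers non-tree models.

## Learning curves

`power_analysis()` holds a participant's temporal test set fixed,
down-samples the training pool to {10, 25, 50, 75, 90, 100} % by
label-stratified sampling (10 repetitions per fraction, 100 % once), and
fits the inverse power law `performance(n) = a − b·n^(−c)` per metric.
Because the model is linear in `(a, b)` given `c`, the fit profiles `c`
over a dense grid by constrained linear least squares before a nonlinear
polish; the asymptote is bounded to [0, 1] for these bounded metrics,
which keeps the notoriously ill-posed small-`c` regime identifiable.
`extrapolate_n()` inverts the law and flags targets above the asymptote
as unattainable.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` reproduces the *structure* of the motivating cohort:
8 participants, 4–48 recording days, 4–11 wear hours/day placed inside
waking hours, per-participant tag rates (Poisson per wear-hour, spanning
the observed 0.02–2.5 tags/h), non-wear blocks, and per-participant
baseline shifts in tonic EDA and HR — the "random intercept" a
mixed-effect model should exploit. Signals are stylized: BVP is an
amplitude-modulated quasi-periodic pulse driven by a bounded random-walk
HR (not a morphologically realistic PPG); EDA is a drifting tonic level
plus Poisson-arriving SCR bursts (1.5/min at rest, exponential
amplitudes of mean 0.3 µS, 1-s rise / 4-s decay kernel); TEMP drifts
slowly around 33.5 °C. Tagged events perturb physiology in
`[t − onset_lead, t − onset_lead + duration)` via an SCR rate/amplitude
gain, a BVP envelope slope shift, and an HR offset. All effect
magnitudes are free parameters — the real cohort's effect sizes are
unknown — so passing tests demonstrate *recovery of known effects at
chosen signal-to-noise*, never real-world performance. Motion artifacts,
accelerometry, inter-beat intervals and realistic pulse morphology are
deliberately out of scope.

Two test-design consequences are worth spelling out. Under a null effect
with matched sampling, nested CV is calibrated (accuracy at baseline,
AUC near 0.5). And cross-participant generalization degrades exactly
when the event signature is participant-relative: a uniform HR elevation
over the pre-tag window is invisible to a model that has never seen that
participant's baseline, while a random-split model (and a MERF) can
anchor on it — the package's tests use such cohorts to reproduce the
qualitative ordering random >= participant.

## Problem sizes

The test-suite and acceptance-script cohorts are deliberately small —
2–5 participants, 1–3 days, 0.5–2 h/day, a few dozen to ~100 windows —
sizes at which every stage (including 64 Hz synthesis and nested CV over
two model families) completes in seconds while keeping the statistical
checks meaningful; tag-count arithmetic at the full published scale uses
the generator's layout-only mode, which emits sessions and tags without
synthesizing waveforms.

## Known limitations

* The feature catalog is a faithful reconstruction, not the original
  supplementary list.
* The MERF uses a Gaussian working likelihood on 0/1 responses
  (classification-via-regression); a bespoke binary mixed-model
  likelihood could be substituted.
* Sleep masking is a fixed clock window unless per-day annotations are
  supplied; adolescents' real sleep varies.
* Learning-curve extrapolations inherit the usual fragility of
  inverse-power-law fits near small curvature, even with the bounded
  asymptote.

## Appendix: the feature catalog

```{r catalog}
head(feature_catalog(), 8)
```

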
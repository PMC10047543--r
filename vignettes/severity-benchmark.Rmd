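---
title: "Benchmarking digital severity measures from wrist-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking digital severity measures from wrist-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristpd)
library(dplyr)
```

## The problem

Parkinson's disease symptoms — medication wearing-off (ON/OFF), dyskinesia,
and tremor — fluctuate over hours, far faster than clinic visits can sample.
Pairing a wrist-worn accelerometer with frequent patient diaries makes it
possible to ask whether free-living sensor data can track self-reported
severity. `wristpd` implements the full computational workflow for that
question: a synthetic two-cohort data generator, the data-preparation rules a
severity benchmark needs (harmonization, activity filtering, eligibility,
within-subject splitting), two window-feature families, per-subject and
global random-forest severity models against a subject-mean Null baseline,
sqrt(n)-weighted MSE scoring with paired bootstrap inference, heterogeneous
ensembling, and post-hoc subject-level and clinician-validation statistics.

Everything runs at desk scale with no external data: the simulator stands in
for the access-controlled studies whose structure it emulates.

## The synthetic cohorts

`generate_cohort()` draws, per subject, latent mean severities
$\theta_s$ per symptom, per-symptom diary noise SDs, a tremor frequency in
4–6 Hz, a mean diary reporting lag, and MDS-UPDRS covariates constructed to
correlate with $\theta_s$. Diary slots arrive every 30 minutes; medication
effectiveness alternates in 4-hour cycles (2 h ON / 2 h OFF) with a random
phase. Each diary label is $\mathrm{round}(\theta_s + N(0, \sigma_{label}))$
clipped to the cohort-native scale. The CIS-style cohort reports all three
symptoms on 0–4 scales; the REAL-style cohort reports tremor on a native 1–5
scale and medication state as a four-category response, and may emit a second
(phone) accelerometer stream per report.

The accelerometer signal for one 20-minute segment is, per axis,

* a gravity projection with slow orientation drift,
* band-limited (0.5–8 Hz) Gaussian baseline motion with SD
  `baseline_motion_sd` scaled by a per-segment log-normal activity
  multiplier (`activity_variability`),
* a tremor sinusoid at the subject's tremor frequency with random-walk
  phase and amplitude `tremor_coupling * tremor * onoff_attenuation^[ON]`,
* a 1–3 Hz dyskinesia band-noise component with SD
  `dyskinesia_coupling * dyskinesia`, expressed mainly in the ON state
  (`dyskinesia_off_expression` while OFF), and
* white sensor noise,

with a fraction `missingness_rate` of samples deleted at random and
timestamps reported relative to segment start.

### What the generator emulates, and what it does not

The couplings give the data the statistical structure the analysis needs:
tremor raises 3–7 Hz band power, the OFF state amplifies tremor, dyskinesia
adds low-frequency power in the ON state, and UPDRS covariates track latent
severity. Two mechanisms are deliberate sources of difficulty, because the
real problem has them:

* **State confounding.** Tremor expresses more strongly OFF and dyskinesia
  ON, while the diary reports severity regardless of state — so the
  label-to-signal coupling is a mixture, not a clean function.
* **Activity confounding.** Ordinary movement intensity varies strongly
  between free-living segments (the log-normal activity multiplier) and its
  spectrum overlaps the dyskinesia band, which is why dyskinesia is the
  hardest of the three targets here, matching clinical experience that
  dyskinetic movement is easily confused with voluntary movement.

The generator does *not* model gait or specific activities, circadian
structure, gyroscopes, or physiologic tremor waveforms; passing tests on
this data demonstrates that the pipeline recovers plantable signal under
realistic confounding, not that any model would work on real patients.

### Default parameter choices

| Parameter | Default | Why |
|---|---|---|
| `sampling_rate` | 50 Hz | typical consumer smartwatch rate |
| `segment_duration` | 1200 s | 20-minute diary-paired segments |
| `tremor_coupling` | 0.02 g/unit | tremor acceleration order of magnitude |
| `dyskinesia_coupling` | 0.009 g/unit | keeps dyskinesia detectable but activity-confounded |
| `onoff_attenuation` | 0.3 | strong ON suppression of tremor, the SC1 signal |
| `dyskinesia_off_expression` | 0.25 | dyskinesia is levodopa-induced (ON-state) |
| `baseline_motion_sd` | 0.02 g | resting wrist motion scale |
| `activity_variability` | 0.25 | log-normal SD of per-segment activity |
| `sensor_noise_sd` | 0.005 g | MEMS accelerometer noise floor |
| `missingness_rate` | 0.02 | occasional dropped samples |

Magnitudes are order-of-magnitude choices (device rates and real tremor
acceleration distributions are not published for these studies) and all are
config-exposed. The couplings, attenuation and activity variability were
calibrated once so that the benchmark's qualitative regime holds — both
model archetypes recover tremor and ON/OFF significantly while dyskinesia
shows the weakest margin — and then frozen.

## Preparation rules

* **Harmonization** (`harmonize_labels()`): REAL tremor 1–5 → 0–4 by
  subtracting one; the four REAL medication categories map to
  `(on_off, dyskinesia)` codes OFF→(1, 0), ON-without→(0, 0),
  ON-non-troublesome→(0, 1), ON-troublesome→(0, 3), so higher always means
  worse (0 = ON, 1 = OFF) and dyskinesia level 2 is unused by construction.
  The mapping is bijective on the categories and idempotent.
* **Activity filter** (`filter_segments()`): a segment must show at least
  2 minutes of activity, where activity means a 1-second epoch containing
  data (the boundary is inclusive); an epoch-motion criterion is available
  behind a flag.
* **Eligibility** (`filter_subjects()`): per symptom, at least 40
  non-missing observations and either ≥2 label categories with ≥10
  observations or ≥3 categories with ≥5.
* **Split** (`split_train_test()`): 75/25 within subject, stratified on the
  joint three-symptom label tuple (missing = own stratum) so one split
  serves all symptoms; the per-subject test count is exactly
  `round(0.25 n)` by largest-remainder allocation; singleton strata go to
  train. Rounding to nearest was chosen for odd `n` and is documented
  behaviour, not a tuning knob.

## Features and models

Segments are cut into non-overlapping 30-second windows; windows holding
fewer than half their expected samples are dropped, and each window inherits
its observation's labels. Two families are computed on a uniform grid
(linear interpolation; FFTs need uniform sampling):

* **generic** (34 features on the vector-magnitude signal): moments,
  deciles, peak and zero-crossing counts, the DC FFT coefficient (real and
  absolute — identically the sample sum), absolute and relative band powers
  (0.5–3, 3–7, 7–12 Hz), spectral entropy and dominant frequency. The
  relative band powers separate narrowband tremor content from overall
  movement intensity.
* **actigraphy** (16 features on the triaxial signal): VM mean/SD/max,
  dominant frequency and its power, spectral entropy, 3–7 Hz band power, a
  counts-per-minute surrogate (`mean(|VM - 1 g|) * 60`; the commercial
  counts algorithm is proprietary, so a transparent integral of dynamic
  acceleration stands in), the three inter-axis correlations, per-axis
  means, mean axis SD, and RMS jerk.

Three model archetypes: the **Null** predicts each subject's training-label
mean; the **per-subject** archetype fits one random forest per
subject–symptom on generic window features with random-search
hyperparameter tuning over 5-fold CV grouped by observation, aggregating
window predictions to an observation by the **median**; the **global**
archetype fits one random forest per cohort on actigraphy features plus
covariates (age, gender, UPDRS I/II totals, Part IV items, Part III on/off
sums and first principal-component score), aggregating by the **mean**.
Multi-device observations average their per-device predictions; outputs are
clipped to the label range (clipping can only reduce squared error);
observations with no surviving windows fall back to the Null prediction
because the scoring contract forbids missing values.

## Scoring

Per subject $k$ with $n_k$ test observations,
$\mathrm{WMSE} = \sum_k \sqrt{n_k}\,\mathrm{MSE}_k \big/ \sum_k \sqrt{n_k}$,
down-weighting data-rich subjects. Significance against the Null uses a
paired bootstrap: each iteration resamples every subject's test
observations with replacement, keeping $n_k$, and applies the *same* index
multiset to every model; `p = #(Null better) / B`, with ties counted one
half (a strict reading would give p = 0 for a Null-identical submission,
which is pathological; a `ties = "strict"` switch restores it). Two models
are "distinguishable" by a one-sided Wilcoxon signed-rank test on the
paired bootstrap scores, dropping zero differences, with p = 1 by
convention when every difference is zero.

## Ensembles

Base predictions are generated under a nested 6-fold plan: folds 1–5 give
out-of-fold predictions and tune the ensembles, fold 6 is an untouched
evaluation fold used only to pick one unsupervised (mean vs median) and one
supervised winner. Supervised candidates: stacking with five meta-learner
families (unregularized linear, lasso, ridge, shallow random forest,
regularized boosted trees) under raw, z-scored and per-subject variants;
greedy forward selection with replacement (stopping when no addition
improves WMSE); and an exhaustive regularized-subset search that enumerates
every non-empty subset of up to 12 bases and fits an L2 linear combination
on an 80 % learn split scored on the held-out 20 %. The exhaustive search is
the package's transparent replacement for sequential ensemble-search
procedures: at five bases (31 subsets) the brute force *is* the search, and
its reported optimum form — a full-set L2-regularized linear blend — is
representable exactly. Tree meta-learners are deliberately shallow: the
meta-problem has few inputs and noisy out-of-fold targets, and an
unconstrained forest memorizes fold idiosyncrasies that do not transfer to
bases refit on the full training data.

The five in-repo base configurations (two per-subject variants, two global
variants, Null-plus-noise) stand in for independently developed models.

## Post-hoc analyses

Per subject, `Lift = MSE_Null − MSE_model` (positive = the model helps that
subject), with a 100-resample paired bootstrap; a subject's lift is called
significant when the 2.5th percentile of its bootstrap distribution is
above zero (the display convention made into an explicit rule).
Associations between lift and subject covariates (label variance, test
count, reporting lag, age, UPDRS parts) use Kendall's tau-b (lift and UPDRS
covariates tie often, so the tie-corrected variant), converted to Pearson's
r by Greiner's relation $r = \sin(\pi\tau/2)$ and pooled across models by
fixed-effect meta-analysis on Fisher's z with weights $n-3$. Clinician
validation correlates model predictions with ratings within subject
(one-sided p, alternative r > 0) and combines subjects with Fisher's log-p
method ($X^2 = -2\sum\ln p_i$ on $2m$ df); exact-zero p-values from perfect
correlations are clamped to the smallest positive double before combining.

## Pipeline and determinism

`run_config()` + `run_all()` orchestrate
simulate → prepare → featurize → train → score → ensemble → posthoc.
Every stage writes its artifacts and a manifest (input/output MD5 hashes
plus its seed, derived deterministically from the one global seed); a stage
whose manifest matches current hashes is a no-op, so deleting an artifact
re-executes only the affected stages. All random forests run single-threaded
with explicit seeds, so one configuration produces byte-identical artifacts,
verified by hashing the concatenated report files of two independent runs.

```{r example, eval = FALSE}
cfg <- run_config(
  cohorts = list(cohort_spec("CIS", n_subjects = 8,
                             reports_per_subject = c(44, 56),
                             sampling_rate = 16, segment_duration = 90,
                             tremor_coupling = 0.05,
                             baseline_motion_sd = 0.02, seed = 1)),
  out_dir = "runs/demo", scoring_B = 1000, min_activity = 60, seed = 1)
report <- run_all(cfg)
report$leaderboards$tremor
```

## Problem sizes used in the package's own studies

The shipped tests and the reproduction script run the pipeline at desk
scale: 16 Hz sampling and 60–120 s segments (2–4 windows per report), with
8–10 subjects × 60–80 reports for the simulation studies, B = 250–1000
bootstrap iterations, and 40 replicates for the type-I-error study. These
sizes were chosen so a full run completes on a single CPU in minutes while
every statistic still has enough resolution for its check; the full-scale
defaults (50 Hz, 20-minute segments) remain the generator's defaults.

## Numerical choices and conventions

* Band powers use a one-sided periodogram with DC removed; an in-band
  sinusoid of amplitude A contributes A²/2.
* Spectral entropy is normalized to [0, 1]; constant windows have entropy 0
  and zero peaks by convention.
* Correlations with a zero-variance axis are 0 (logged); tau is missing for
  constant covariates; |r| = 1 is rejected by the meta-analysis with
  guidance to shrink by epsilon.
* Half-open windows `[a, b)` everywhere; timestamps are 0-based seconds.
* Stratified assignments use largest-remainder quotas; ties in leaderboards
  break lexicographically by submission id.

## Known limitations

The generator's realism is deliberately minimal (no activity recognition
context, no gyroscope, no circadian structure), so absolute WMSE values are
not comparable to any real study — only the relative behaviour of models,
ensembles and statistics is meaningful. The deep-learning archetype used by
one winning team is out of scope; the model interface accepts any
prediction set, so such a model can be benchmarked but not trained here.
Global models lean on UPDRS covariates that the simulator couples to latent
severity by construction; on real data that coupling is weaker and
cohort-dependent.
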
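---
title: "Predicting postoperative speech deterioration from intraoperative CCEPs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postoperative speech deterioration from intraoperative CCEPs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ccepml)
```

## The problem

During awake resection of glial tumours near the cortical speech areas,
cortico-cortical evoked potentials (CCEPs) can be recorded between a
stimulating electrode strip over the frontal speech region and a recording
strip over the posterior temporal/supramarginal region. Each stimulation
test yields an averaged evoked response over a 300 ms post-stimulus window
on 8 or 16 ECoG channels, digitised at 25 kHz (7500 samples per channel).
The clinical question is whether the pre-resection CCEP waveform carries
enough information to predict which patients will wake up with worse speech
— a binary outcome derived from a 0–45 neuropsychological dysfunction score
taken before and about a week after surgery (1 = worsened, 0 = improved or
unchanged).

`ccepml` implements the full analysis path for this question: waveform
reduction, descriptive feature extraction, and a repeated-resampling
classification experiment whose central methodological point is the
comparison between record-level ("by test") and patient-grouped
("by patient") train/test splitting. Because repeated tests of one patient
are strongly similar, record-level splitting lets a classifier recognise
*patients* rather than *outcomes*; patient-grouped splitting is the honest
evaluation, and the package is built to demonstrate and quantify that gap.

Clinical recordings of this kind are not publicly available. The package
therefore ships a synthetic cohort generator with known ground truth that
emulates the data's structure; every experiment in the tests and in
`scripts/acceptance.R` runs end-to-end on generated EDF files.

## Waveform reduction

Each channel of an epoch is reduced in three deterministic steps
(`preprocess_params()` holds the knobs):

1. **Bin averaging** (`bin_average`): the 7500-sample trace is split into
   300 consecutive blocks of 25 samples and each block is averaged — one
   value per millisecond.
2. **Trailing moving average** (`moving_average`): `smoothed[t]` is the
   mean of the preceding `ma_window = 20` bins, so the first 20 ms produce
   the first smoothed value, which sits at millisecond index 20. The
   trailing (not centred) window follows the convention that the first
   smoothed value exists only once 20 ms of signal have accrued. A
   consequence worth remembering: the apparent latency of a symmetric
   deflection is delayed by about half a window (~9.5 ms). Latency
   *features* inherit this fixed offset; since every signal is smoothed the
   same way, the offset is common to all rows and harmless to
   classification, but comparisons against stimulus-locked physiology
   should subtract it.
3. **Artifact trimming** (`trim_artifact`): the start index always advances
   1 ms (the first smoothed millisecond is discarded unconditionally), then
   up to 10 further times while the candidate start value deviates from the
   mean of the remaining trace by more than `1.25 ×` half the remaining
   trace's peak-to-peak range. The published description of this step says
   only that leading artifacts were removed "through comparison with the
   amplitude of the rest of the signal multiplied by 1.25"; the half-range
   criterion here is this package's precise rendering of that idea, locked
   by unit tests. The total shift is therefore always between 1 and 11 ms.

Analysis then proceeds on the channel whose trimmed trace has the largest
peak-to-peak amplitude (`select_channel`; ties go to the lowest channel
index). Most channels in this montage carry only low-amplitude impulse
noise, so the highest-amplitude channel is the one with the evoked
response. Trimming is applied per channel *before* selection; the original
description does not fix this order, and the choice is documented here
because a large artifact surviving on a noise channel could otherwise
inflate its amplitude.

Epochs arrive with 8 or 16 channels. They are standardised to 16 rows by
padding with *absent-channel markers*, not zeros
(`standardize_channels`): a zero-filled channel would have amplitude 0 and
would bias the channel-wise minimum and mean that become features. Absent
channels are excluded from every channel-wise statistic and are never
selected.

## Features

Per test (`build_feature_table`):

* `max_amp`, `mean_amp`, `min_amp` — maximum, mean and minimum of the
  per-channel peak-to-peak amplitudes over present channels (μV);
* `signal_mean` — mean of the selected channel's valid range (μV, may be
  negative);
* up to two maxima and two minima of the selected trace with their
  latencies (`detect_extrema`): local extrema at least 5 μV above (below)
  the valid-range mean, pairwise at least 20 ms apart, kept greedily in
  order of decreasing prominence and reported in latency order. The
  reference level for the 5 μV height threshold is not stated in the
  source description; the valid-range mean is this package's choice, made
  because the trace baseline is not otherwise anchored;
* `adf_pvalue` — the augmented Dickey–Fuller stationarity p-value of the
  valid range. The feature is computed and carried but excluded from the
  classifier input by default (`include_adf = FALSE`), mirroring the study
  design in which it was examined and then left out of the final models.

Missing extrema (a trace may legitimately have fewer than two peaks or
troughs) are imputed per split (`impute_missing`):

* `zeros` — values and latencies become 0;
* `ratio_mean` — a missing first peak is the training mean of
  (peak1 / channel amplitude) times this row's channel amplitude; a missing
  second peak is the training mean of (peak2 / peak1) times this row's
  (possibly imputed) first peak; troughs analogously on absolute
  magnitudes, re-signed negative; missing latencies take the training-mean
  latency of that extremum. The published description of the ratio scheme
  is ambiguous in translation; the formula above is the closest literal
  reading and is fixed by unit tests as this package's definition. Missing
  *latencies* are not mentioned there at all; the training-mean rule is
  ours.

Features are min-max normalised to the training range
(`fit_normalizer` / `apply_normalizer`); a constant training feature maps
to 0, and test values may legitimately fall outside [0, 1].

**Leakage policy.** Imputation ratios, mean latencies and normalisation
ranges are *training-side statistics*, re-fit inside every resampling
repetition. The study describes normalising after computing features,
i.e. apparently before splitting; `experiment_config(fit_on_all = TRUE)`
reproduces that order for comparison, but the default is the leakage-free
order, and a dedicated test asserts that no statistic of held-out rows
influences training-derived quantities.

## The experiment

`run_experiment_grid` iterates split mode (`by_test`, `by_patient`) ×
imputation scheme (`zeros`, `ratio_mean`) × classifier (random forest,
logistic regression, SVM with linear/RBF/polynomial kernel) — 20 cells —
and repeats each cell `n_repetitions = 300` times (6000 runs) with seeded
80/20 stratified resampling. Each run: split → fit imputation and
normalisation on the training side → 5-fold cross-validated accuracy on
the training side → fit on the full training side → metric suite on the
held-out side (sensitivity, specificity, precision, recall, accuracy, F1,
rank-based AUC with ties counted one half). Cell metrics are means over
repetitions; undefined values (AUC on a single-class held-out side) are
excluded from the average.

Implementation choices where the study description is silent:

* **Hyperparameters** are the backing R libraries' documented defaults
  (`randomForest` with 500 trees; `e1071::svm` with cost 1, γ = 1/p,
  degree 3, coef0 0; `stats::glm` binomial), pinned in `model_spec()` and
  recorded per run in the JSON-lines run log. No tuning is performed.
* **AUC scores** are continuous (class-1 probability for forest and
  logistic regression, signed decision value for SVMs), not hard labels.
* **By-patient splitting** assigns whole patients to a side, per
  patient-level class, filling the test side until it reaches the target
  row fraction while always leaving at least one patient of each class in
  training. It is approximate by necessity: patients contribute unequal
  row counts.
* **CV folds inherit the grouping mode**: under by-patient splitting the
  folds also group patients, so the inner validation answers the same
  question as the outer one.
* **Seeds**: repetition *r* uses `base_seed + r` for the split and fold
  structure and `base_seed + 10^6 + r` for the model fit, so results are
  bitwise reproducible at any `jobs` (parallelism) setting.

## The synthetic cohort

`synthetic_cohort_spec()` defaults describe the emulated study: 26
patients, 2–16 tests each, a mix of 8- and 16-channel recordings, about a
fifth of tests recorded post-resection and about half of all tests failing
quality screening — proportions chosen to land near the study's data-flow
(268 recorded tests, 105 usable pre-resection). The outcome prevalence
target is 0.6 positive: the study does not print its class counts, but its
uniformly high sensitivity / low specificity pattern is what
positive-majority data produce, and 0.6 keeps both classes large enough
for stratified splitting at n = 26.

Each patient has latent first-peak amplitude (~N(40, 12²) μV, floored at
8) and latency (~N(80, 15²) ms), an optional second peak and one or two
troughs at fixed amplitude ratios; each *test* jitters these by
`within_patient_sd` (default 0.2) times the between-patient sd, which is
what makes repeated tests of a patient much more alike than two patients —
the property the leakage demonstration needs. One randomly chosen channel
carries the response; the others carry a 4–15 Hz background oscillation of
~2 μV; all channels share white noise (3 μV) and a 150 μV stimulus
artifact decaying with a 5 ms constant. Deterioration is drawn once per
patient from a logistic model on the standardised latent amplitude (and
optionally latency), so all of a patient's tests share one label, matching
the patient-level outcome of the study. Speech scores consistent with the
drawn label are synthesised into the manifest so that `make_target`
reconstructs it.

What the generator does *not* emulate: real N1/N2 biphasic morphology,
electrode-distance effects, non-stationary background ECoG, or
post-resection signal change. The pipeline consumes only
amplitude/latency/shape summaries, so Gaussian deflections suffice for
testing the machinery; passing tests show the *pipeline* behaves correctly
under known ground truth, not that real CCEPs are this clean. One concrete
divergence: the study reports all real series non-stationary by the ADF
test, whereas the generator's smoothed traces — deterministic deflections
reverting to baseline under light noise — mostly test stationary. No test
asserts the real-data behaviour on synthetic data.

## Numerical and degenerate-input choices

* EDF is written with one data record, ±1000 μV physical range and 16-bit
  quantisation (step ≈ 0.03 μV); round-trips are tested to 0.1 μV.
  Out-of-range values are clipped.
* The ADF test uses the constant-only regression with the deterministic
  lag rule `trunc((n − 1)^(1/3))`; its t-statistic matches the reference
  implementation to 10 decimals on frozen fixtures, and p-values are
  interpolated from the classical quantile table, hence bounded to
  [0.01, 0.99]. Constant traces are rejected as degenerate and surface as
  missing feature values.
* Ties in channel selection go to the lowest channel index; ties in
  extremum ranking to the earlier latency; AUC ties count one half.
* Precision and F1 are defined as 0 when there are no positive
  predictions; metrics whose truth side is single-class are `NA` and
  excluded from averages.
* Record-level splits that lose a class are redrawn (up to 100 attempts);
  fold assignments whose training part loses a class likewise.

## Problem sizes in the tests and acceptance script

The shipped experiments are scaled to desk size as the package's own
defaults for verification work: the main grid runs 30 repetitions per cell
(the full 300 is a config change, and the design cardinalities — 20 cells,
6000 runs — are asserted from the configuration itself); the leakage
demonstration uses 100 repetitions of one high-similarity cohort; latency
recovery uses 200 epochs.

The null calibration deserves a note. With zero effect, the expected AUC
of any trained classifier on patient-grouped held-out data is exactly 0.5.
But within *one* finite 26-patient cohort, the random labels are always
somewhat correlated with patient-level features, and patient-grouped
resampling preserves that accident across every repetition: single-cohort
mean AUCs scatter with sd ≈ 0.12 around 0.5 no matter how many
repetitions are averaged. The calibration experiment therefore spreads its
300 repetitions over 60 independently drawn cohorts (8-channel tests, to
keep waveform synthesis cheap; calibration is channel-count invariant) and
averages across draws — this tests the property that actually matters,
namely that the evaluation machinery is unbiased, rather than one cohort's
luck.

## Known limitations

* The artifact-trimming criterion and the peak-height reference level are
  this package's precise renderings of loosely specified steps; both are
  unit-locked but alternative monotone variants would also be defensible.
* The ratio-mean imputation formula follows an ambiguous description; the
  zeros scheme (which the study found superior) is unambiguous.
* By-patient splits hit the 20% target only approximately when patients
  contribute very unequal test counts.
* The generator's outcome model links deterioration to waveform latents
  linearly on the logit scale; real pathophysiology is under no such
  obligation. Absolute metric values on synthetic cohorts say nothing
  about achievable clinical performance — only the *relative* structure
  (leakage gap, calibration, recovery) transfers.
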
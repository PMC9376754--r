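# ccepml

Predicting postoperative speech deterioration from intraoperative
cortico-cortical evoked potentials (CCEPs).

## What this package is for

During awake surgery for glial tumours near the cortical speech areas,
single-pulse electrical stimulation of one speech region evokes a response
— a CCEP — recorded over another. Each stimulation test yields an averaged
300 ms evoked waveform on 8 or 16 ECoG channels at 25 kHz (7500 samples
per channel); patients contribute 2–16 tests, and speech function is
scored on a 0–45 dysfunction scale before and about a week after surgery.
The analysis question: do the pre-resection waveforms predict which
patients deteriorate (binary target, 1 = the post-surgery score worsened)?

`ccepml` implements the full pipeline for clinical neurophysiologists and
methodologists working on this question:

* **I/O** — EDF epoch files plus a CSV cohort manifest
  (`test_id,file_path,patient_id,phase,quality_ok,pre_score,post_score`);
  loading applies the quality flag and the restriction to pre-resection
  tests.
* **Waveform reduction** — per channel: means of every 25 samples (7500 →
  300 values, one per ms), a trailing 20 ms moving average, a stimulus
  artifact trim (the start index always advances 1 ms, plus up to 10 ms
  while the leading value deviates from the mean of the remaining trace by
  more than 1.25 × half its peak-to-peak range), then selection of the
  channel with the largest amplitude.
* **Features** — channel amplitude summaries (max/mean/min of per-channel
  peak-to-peak amplitude), the selected trace's mean, up to 2 maxima and 2
  minima with latencies (≥ 5 μV above/below the trace mean, ≥ 20 ms
  apart), an augmented Dickey–Fuller stationarity p-value (carried, not
  modelled by default), missing-extremum imputation (zeros or training
  ratio means) and min-max normalisation fit on training rows.
* **Evaluation** — the repeated-resampling experiment: {by-test,
  by-patient} splits × {zeros, ratio-mean} imputation × {random forest,
  logistic regression, SVM linear/RBF/polynomial} = 20 cells, each run 300
  times (6000 runs) with seeded 80/20 stratified resampling, 5-fold CV on
  the training side, and a metric suite (sensitivity, specificity,
  precision, recall, accuracy, F1, AUC) averaged per cell. By-patient
  splitting keeps all tests of a patient on one side; the contrast with
  by-test splitting quantifies identity leakage.
* **Synthetic cohorts** — a generator with known ground truth (evoked
  deflection morphology, stimulus artifact, within-patient similarity,
  logistic outcome model) writing the same EDF + manifest formats, used by
  every shipped experiment since the clinical recordings are not public.

## Worked example

```r
library(ccepml)

## a synthetic 26-patient cohort written as EDF files + manifest
spec <- synthetic_cohort_spec(seed = 42)
gen  <- generate_cohort(spec, "cohort")
nrow(gen$manifest)
#> [1] 236

## quality-passing pre-resection tests -> per-test features
cohort   <- load_cohort(gen$manifest_path)
features <- build_feature_table(cohort)
nrow(features); sum(features$target)
#> [1] 93
#> [1] 61

features[1, c("max_amp", "peak1_value", "peak1_latency", "trough1_value")]
#>    max_amp peak1_value peak1_latency trough1_value
#> 1 86.97807    48.15302            85     -38.82506

## one seeded resampling run: patient-grouped split, zero imputation
cfg <- experiment_config(n_repetitions = 3, base_seed = 7)
run <- run_single(features, cfg, cfg$models$random_forest, 1,
                  "by_patient", "zeros")
round(unlist(run), 3)
#> cv_accuracy specificity sensitivity   precision      recall    accuracy
#>       0.805       0.667       0.667       0.800       0.667       0.667
#>          f1         auc
#>       0.727       0.648
```

`max_amp` is the largest per-channel peak-to-peak amplitude in microvolts;
`peak1_value`/`peak1_latency` describe the first retained maximum of the
selected channel (the trailing moving average delays apparent latencies by
~9.5 ms); the run metrics are one repetition's held-out performance — the
experiment averages hundreds of such seeded runs per grid cell via
`run_experiment_grid()`. A command-line wrapper with subcommands
`init`/`synth`/`features`/`evaluate`/`report` is installed at
`system.file("cli", "ccep.R", package = "ccepml")`.

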
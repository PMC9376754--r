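# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A flat patient record for generate_epoch(): a single positive deflection.
simple_patient <- function(amp1 = 40, lat1 = 80, id = "P01") {
  list(patient_id = id, amp1 = amp1, lat1 = lat1,
       has_peak2 = FALSE, lat2 = 180,
       has_trough1 = FALSE, tlat1 = 125,
       has_trough2 = FALSE, tlat2 = 230)
}

# Raw-sample epoch (channels x 7500) with a Gaussian bump on one channel.
bump_epoch <- function(bump_channel = 5, amp = 40, lat = 80, noise_sd = 5,
                       n_channels = 8, seed = 1) {
  set.seed(seed)
  t_ms <- (0:7499) / 25
  m <- matrix(rnorm(n_channels * 7500, sd = noise_sd), nrow = n_channels)
  m[bump_channel, ] <- m[bump_channel, ] + amp * exp(-((t_ms - lat)^2) / (2 * 100))
  ecog_epoch(m, test_id = "T1", patient_id = "P1")
}

# Default-scale synthetic cohort and its feature table (the workhorse for
# split/evaluation tests). Generated once, reused across files.
study_features <- function() {
  cached("study_features", function() {
    dir <- file.path(tempdir(), "ccepml-study-cohort")
    spec <- synthetic_cohort_spec(seed = 20101L)
    gen <- generate_cohort(spec, dir)
    cohort <- load_cohort(gen$manifest_path)
    list(features = build_feature_table(cohort), truth = gen$truth,
         manifest = gen$manifest, dir = dir)
  })
}

# High within-patient similarity, weak outcome signal: the leakage cohort.
leakage_features <- function() {
  cached("leakage_features", function() {
    dir <- file.path(tempdir(), "ccepml-leakage-cohort")
    spec <- synthetic_cohort_spec(within_patient_sd = 0.1, effect_amp = 0.5,
                                  quality_fail_prob = 0.2, post_fraction = 0,
                                  seed = 20103L)
    gen <- generate_cohort(spec, dir)
    build_feature_table(load_cohort(gen$manifest_path))
  })
}

# Mean by-patient AUC of a classifier on zero-effect cohorts: `n_cohorts`
# freshly drawn 26-patient cohorts with `reps_per_cohort` seeded resampling
# repetitions each. A single finite cohort carries an irreducible
# patient-level spurious association between features and random labels
# that repetition cannot average away, so the calibration average must
# span independent cohort draws.
null_calibration_auc <- function(n_cohorts, reps_per_cohort, seed0) {
  aucs <- unlist(lapply(seq_len(n_cohorts), function(c) {
    dir <- file.path(tempdir(), sprintf("ccepml-null-%d", c))
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    spec <- synthetic_cohort_spec(effect_amp = 0, effect_lat = 0,
                                  channel_counts = 8L,
                                  seed = seed0 + c)
    gen <- generate_cohort(spec, dir)
    ft <- build_feature_table(load_cohort(gen$manifest_path))
    cfg <- experiment_config(n_repetitions = reps_per_cohort,
                             base_seed = seed0 + 1000L + c)
    vapply(seq_len(reps_per_cohort), function(r) {
      run_single(ft, cfg, cfg$models$logistic_regression, r,
                 "by_patient", "zeros")$auc
    }, numeric(1))
  }))
  mean(aucs, na.rm = TRUE)
}
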
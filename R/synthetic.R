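# Synthetic CCEP cohort generator with known ground truth.
#
# Emulates the structure of the intraoperative dataset: per-patient evoked
# morphology (Gaussian-shaped deflections with patient-specific amplitudes
# and latencies), strong within-patient similarity across repeated tests, a
# decaying stimulus artifact in the first milliseconds, low-amplitude
# background channels, 8- or 16-channel tests, pre/post-resection phases, a
# quality-screening flag, and a patient-level outcome linked to waveform
# features through a logistic model. Everything the downstream pipeline sees
# is written in the same EDF + manifest formats as real data.

#' Synthetic cohort specification
#'
#' Defaults emulate the study conditions: 26 patients with 2-16 tests each,
#' a mix of 8- and 16-channel recordings at 25 kHz over 300 ms, roughly a
#' fifth of tests recorded post-resection and about half of all tests
#' failing quality screening, and a positive-majority outcome.
#'
#' @param n_patients Number of patients (default 26).
#' @param tests_range Integer range of tests per patient (default 2-16).
#' @param channel_counts Channel counts sampled per test (default 8 and 16).
#' @param sampling_rate Samples/second (default 25000).
#' @param epoch_ms Epoch duration (default 300 ms).
#' @param peak1_lat_mean,peak1_lat_sd Patient-level first-peak latency
#'   distribution, ms.
#' @param peak1_amp_mean,peak1_amp_sd Patient-level first-peak amplitude
#'   distribution, microvolts.
#' @param deflection_width_ms Gaussian deflection width (sd), ms.
#' @param peak2_prob,peak2_lat_mean,peak2_lat_sd,peak2_ratio Optional second
#'   peak: occurrence probability, latency distribution, amplitude as a
#'   fraction of the first peak.
#' @param trough1_prob,trough1_lat_mean,trough1_lat_sd,trough1_ratio First
#'   (negative) deflection, amplitude fraction of the first peak.
#' @param trough2_prob,trough2_lat_mean,trough2_lat_sd,trough2_ratio
#'   Optional second trough.
#' @param artifact_amp,artifact_decay_ms Initial stimulus artifact:
#'   amplitude (microvolts) and exponential decay constant (ms).
#' @param noise_sd Additive white-noise standard deviation, microvolts.
#' @param background_amp Amplitude of the slow background oscillation on
#'   non-response channels, microvolts.
#' @param within_patient_sd Within-patient test-to-test jitter of amplitudes
#'   and latencies, as a fraction of the between-patient sd (default 0.2:
#'   repeated tests of one patient are much more alike than two patients).
#' @param effect_amp,effect_lat Logistic coefficients linking the
#'   standardised patient-level first-peak amplitude and latency to the
#'   probability of postoperative speech deterioration.
#' @param prevalence Target marginal probability of deterioration.
#' @param post_fraction Fraction of tests recorded post-resection.
#' @param quality_fail_prob Probability a test fails quality screening.
#' @param seed Optional RNG seed used by [generate_cohort()].
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 26L, tests_range = c(2L, 16L),
                                  channel_counts = c(8L, 16L),
                                  sampling_rate = 25000, epoch_ms = 300,
                                  peak1_lat_mean = 80, peak1_lat_sd = 15,
                                  peak1_amp_mean = 40, peak1_amp_sd = 12,
                                  deflection_width_ms = 10,
                                  peak2_prob = 0.6, peak2_lat_mean = 180,
                                  peak2_lat_sd = 20, peak2_ratio = 0.6,
                                  trough1_prob = 1.0, trough1_lat_mean = 125,
                                  trough1_lat_sd = 15, trough1_ratio = 0.8,
                                  trough2_prob = 0.5, trough2_lat_mean = 230,
                                  trough2_lat_sd = 15, trough2_ratio = 0.5,
                                  artifact_amp = 150, artifact_decay_ms = 5,
                                  noise_sd = 3, background_amp = 2,
                                  within_patient_sd = 0.2,
                                  effect_amp = 1.5, effect_lat = 0,
                                  prevalence = 0.6,
                                  post_fraction = 0.2,
                                  quality_fail_prob = 0.49,
                                  seed = NULL) {
  stopifnot(n_patients >= 1, length(tests_range) == 2,
            tests_range[1] >= 1, tests_range[2] >= tests_range[1],
            all(channel_counts %in% c(8L, 16L)),
            peak1_amp_mean > 0, deflection_width_ms > 0,
            within_patient_sd >= 0, within_patient_sd <= 1,
            prevalence > 0, prevalence < 1,
            post_fraction >= 0, post_fraction < 1,
            quality_fail_prob >= 0, quality_fail_prob < 1)
  spec <- as.list(environment())
  spec$tests_range <- as.integer(tests_range)
  spec$n_patients <- as.integer(n_patients)
  structure(spec, class = "synthetic_cohort_spec")
}

gauss_bump <- function(t_ms, lat, amp, width) {
  amp * exp(-((t_ms - lat)^2) / (2 * width^2))
}

draw_patient <- function(spec, i) {
  amp1 <- max(8, stats::rnorm(1, spec$peak1_amp_mean, spec$peak1_amp_sd))
  lat1 <- min(max(stats::rnorm(1, spec$peak1_lat_mean, spec$peak1_lat_sd), 35),
              spec$epoch_ms - 60)
  z_amp <- (amp1 - spec$peak1_amp_mean) / spec$peak1_amp_sd
  z_lat <- (lat1 - spec$peak1_lat_mean) / spec$peak1_lat_sd
  p <- stats::plogis(stats::qlogis(spec$prevalence) +
                     spec$effect_amp * z_amp + spec$effect_lat * z_lat)
  list(patient_id = sprintf("P%02d", i),
       amp1 = amp1, lat1 = lat1,
       has_peak2 = stats::runif(1) < spec$peak2_prob,
       lat2 = min(max(stats::rnorm(1, spec$peak2_lat_mean, spec$peak2_lat_sd),
                      lat1 + 2 * spec$deflection_width_ms),
                  spec$epoch_ms - 20),
       has_trough1 = stats::runif(1) < spec$trough1_prob,
       tlat1 = min(max(stats::rnorm(1, spec$trough1_lat_mean,
                                    spec$trough1_lat_sd), 35),
                   spec$epoch_ms - 40),
       has_trough2 = stats::runif(1) < spec$trough2_prob,
       tlat2 = min(max(stats::rnorm(1, spec$trough2_lat_mean,
                                    spec$trough2_lat_sd), 35),
                   spec$epoch_ms - 15),
       n_tests = sample(spec$tests_range[1]:spec$tests_range[2], 1),
       p_deteriorate = p,
       target = as.integer(stats::runif(1) < p))
}

#' Generate one synthetic stimulation-test epoch
#'
#' One randomly chosen channel carries the evoked response: the patient's
#' deflections, jittered test-to-test by `within_patient_sd` times the
#' between-patient spread. The remaining channels carry a slow low-amplitude
#' oscillation. All channels share the decaying stimulus artifact and
#' additive white noise. Uses the current RNG state.
#'
#' @param patient A patient record from the cohort generator (latent
#'   amplitudes/latencies and identifiers).
#' @param test_index Test number within the patient.
#' @param spec A [synthetic_cohort_spec()].
#' @param n_channels Channel count for this test (8 or 16).
#' @param phase `"pre"` or `"post"`.
#' @return An [ecog_epoch()]; the response channel index is attached as
#'   attribute `response_channel` and the jittered deflection truth as
#'   attribute `truth`.
#' @export
generate_epoch <- function(patient, test_index, spec,
                           n_channels = NULL, phase = "pre") {
  if (is.null(n_channels)) {
    cc <- spec$channel_counts
    n_channels <- if (length(cc) == 1L) cc else sample(cc, 1)
  }
  n_samples <- round(spec$sampling_rate * spec$epoch_ms / 1000)
  t_ms <- (seq_len(n_samples) - 1) / spec$sampling_rate * 1000
  j_amp <- spec$within_patient_sd * spec$peak1_amp_sd
  j_lat <- spec$within_patient_sd * spec$peak1_lat_sd

  amp1 <- max(5, patient$amp1 + stats::rnorm(1, 0, j_amp))
  lat1 <- max(30, patient$lat1 + stats::rnorm(1, 0, j_lat))
  w <- spec$deflection_width_ms
  resp <- gauss_bump(t_ms, lat1, amp1, w)
  if (patient$has_trough1) {
    resp <- resp - gauss_bump(t_ms, patient$tlat1 + stats::rnorm(1, 0, j_lat),
                              spec$trough1_ratio * amp1, w)
  }
  if (patient$has_peak2) {
    resp <- resp + gauss_bump(t_ms, patient$lat2 + stats::rnorm(1, 0, j_lat),
                              spec$peak2_ratio * amp1, w)
  }
  if (patient$has_trough2) {
    resp <- resp - gauss_bump(t_ms, patient$tlat2 + stats::rnorm(1, 0, j_lat),
                              spec$trough2_ratio * amp1, w)
  }

  samples <- matrix(0, nrow = n_channels, ncol = n_samples)
  resp_ch <- sample.int(n_channels, 1)
  for (ch in seq_len(n_channels)) {
    base <- if (ch == resp_ch) resp else {
      freq <- stats::runif(1, 4, 15)   # Hz, slow background oscillation
      spec$background_amp *
        sin(2 * pi * freq * t_ms / 1000 + stats::runif(1, 0, 2 * pi))
    }
    chan <- base + stats::rnorm(n_samples, 0, spec$noise_sd)
    if (spec$artifact_amp > 0) {
      chan <- chan + spec$artifact_amp * exp(-t_ms / spec$artifact_decay_ms)
    }
    samples[ch, ] <- chan
  }
  ep <- ecog_epoch(samples,
                   test_id = sprintf("%s_T%02d", patient$patient_id, test_index),
                   patient_id = patient$patient_id, phase = phase,
                   sampling_rate = spec$sampling_rate,
                   epoch_ms = spec$epoch_ms)
  attr(ep, "response_channel") <- resp_ch
  attr(ep, "truth") <- list(amp1 = amp1, lat1 = lat1)
  ep
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one EDF file per test plus the cohort manifest CSV and a ground
#' truth JSON (patient latent features, outcome probabilities, labels, and
#' the generating parameters). All tests of a patient share one outcome,
#' drawn once per patient from the logistic model. The first test of every
#' patient is always pre-resection.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (data.frame), `manifest_path`, `truth`
#'   (list: per-patient records and per-test waveform truth), `dir`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)

  patients <- lapply(seq_len(spec$n_patients), function(i) {
    draw_patient(spec, i)
  })
  rows <- list()
  test_truth <- list()
  for (pt in patients) {
    # speech scores consistent with the binary outcome
    pre_score <- sample(0:20, 1)
    post_score <- if (pt$target == 1L) {
      sample((pre_score + 1):min(45, pre_score + 15), 1)
    } else {
      sample(0:pre_score, 1)
    }
    for (k in seq_len(pt$n_tests)) {
      phase <- if (k == 1L || stats::runif(1) >= spec$post_fraction) "pre"
               else "post"
      ep <- generate_epoch(pt, k, spec, phase = phase)
      fname <- paste0(ep$test_id, ".edf")
      write_epoch_file(ep, file.path(out_dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        test_id = ep$test_id, file_path = fname,
        patient_id = pt$patient_id, phase = phase,
        quality_ok = stats::runif(1) >= spec$quality_fail_prob,
        pre_score = pre_score, post_score = post_score)
      test_truth[[ep$test_id]] <- c(attr(ep, "truth"),
                                    list(response_channel =
                                           attr(ep, "response_channel")))
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, manifest_path)

  truth <- list(spec = unclass(spec)[setdiff(names(spec), "seed")],
                seed = spec$seed,
                patients = patients, tests = test_truth)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(manifest = manifest, manifest_path = manifest_path, truth = truth,
       dir = out_dir)
}

#' Summarise how well the experiment recovers a known effect
#'
#' For a cohort generated with known logistic coefficients, reports the
#' effect size alongside the mean AUC and F1 of each split mode, averaged
#' over the grid cells of a [run_experiment_grid()] result.
#'
#' @param truth Ground truth list from [generate_cohort()].
#' @param metrics_table A `ccep_metrics_table`.
#' @return Data.frame with one row per split mode.
#' @export
recovery_report <- function(truth, metrics_table) {
  eff <- truth$spec$effect_amp
  out <- do.call(rbind, lapply(unique(metrics_table$split_mode), function(sm) {
    sub <- metrics_table[metrics_table$split_mode == sm, ]
    data.frame(effect_amp = eff, split_mode = sm,
               mean_auc = mean(sub$auc_mean, na.rm = TRUE),
               mean_f1 = mean(sub$f1_mean, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
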
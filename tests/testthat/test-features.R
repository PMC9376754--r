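# Naive reference for constrained extremum detection: scan all local maxima,
# keep greedily by decreasing value under the distance constraint.
oracle_extrema <- function(v, start, min_dist, min_height, max_keep, sign = 1) {
  w <- sign * v
  base <- mean(w)
  cand <- c()
  for (i in 2:(length(w) - 1)) {
    if (w[i] > w[i - 1] && w[i] >= w[i + 1] && w[i] - base >= min_height) {
      cand <- c(cand, i)
    }
  }
  kept <- c()
  for (i in cand[order(-w[cand], cand)]) {
    if (length(kept) == max_keep) break
    if (all(abs(i - kept) >= min_dist)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(latency = start + kept - 1L, value = sign * w[kept])
}

bump_signal <- function(amps, lats, n = 280, start = 21L, width = 6) {
  t <- start:(start + n - 1)
  v <- rep(0, n)
  for (j in seq_along(amps)) v <- v + amps[j] * exp(-((t - lats[j])^2) / (2 * width^2))
  smoothed_signal(v, start)
}

test_that("amplitude summaries reduce present channels only", {
  mk <- function(amp, ch) smoothed_signal(c(0, amp, rep(0, 20)), 21L, ch)
  chans <- list(mk(10, 1), mk(20, 2), mk(30, 3))
  expect_equal(amplitude_summaries(chans),
               list(max_amp = 30, mean_amp = 20, min_amp = 10))
  expect_equal(amplitude_summaries(list(mk(7, 1))),
               list(max_amp = 7, mean_amp = 7, min_amp = 7))
  with_absent <- list(mk(10, 1), NULL, mk(30, 3), NULL)
  expect_equal(amplitude_summaries(with_absent)$mean_amp, 20)
})

test_that("extremum detection honours height and distance constraints", {
  fp <- feature_params()
  one <- detect_extrema(bump_signal(10, 80), fp)
  expect_equal(nrow(one$maxima), 1)
  expect_equal(one$maxima$latency, 80)
  expect_equal(nrow(one$minima), 0)

  # two 10 uV bumps 10 ms apart: only the larger survives the 20 ms spacing
  two_close <- detect_extrema(bump_signal(c(10, 10.5), c(80, 90), width = 3), fp)
  expect_equal(nrow(two_close$maxima), 1)

  # a 4 uV bump never clears the 5 uV height threshold
  low <- detect_extrema(bump_signal(4, 80), fp)
  expect_equal(nrow(low$maxima), 0)

  # two well-separated peaks: latencies ordered, both kept
  two <- detect_extrema(bump_signal(c(12, 20), c(80, 160)), fp)
  expect_equal(two$maxima$latency, c(80, 160))
  # troughs are maxima of the negated trace
  tr <- detect_extrema(bump_signal(c(15, -12), c(80, 160)), fp)
  expect_equal(tr$minima$latency, 160)
  expect_lt(tr$minima$value, 0)
})

test_that("extremum detection matches the brute-force reference on random traces", {
  fp <- feature_params()
  set.seed(202)
  for (i in 1:200) {
    n <- sample(100:280, 1)
    v <- as.numeric(stats::filter(rnorm(n, sd = 8), rep(1 / 5, 5),
                                  circular = TRUE))
    sig <- smoothed_signal(v, 21L)
    got <- detect_extrema(sig, fp)
    expect_equal(got$maxima, oracle_extrema(v, 21L, 20, 5, 2, 1),
                 tolerance = 1e-9)
    expect_equal(got$minima, oracle_extrema(v, 21L, 20, 5, 2, -1),
                 tolerance = 1e-9)
  }
})

make_ft <- function() {
  # small hand-written feature table with controlled missingness
  data.frame(
    test_id = sprintf("t%d", 1:6), patient_id = sprintf("P%d", c(1, 1, 2, 2, 3, 3)),
    max_amp = c(10, 20, 40, 8, 16, 30), mean_amp = c(5, 10, 20, 4, 8, 15),
    min_amp = c(1, 2, 4, 1, 2, 3), signal_mean = c(0.5, -0.2, 1, 0, 0.3, -1),
    peak1_value = c(8, 16, 32, NA, 12.8, 24),
    peak1_latency = c(80, 90, 70, NA, 85, 75),
    peak2_value = c(4, NA, 16, NA, 6.4, NA),
    peak2_latency = c(180, NA, 170, NA, 185, NA),
    trough1_value = c(-6, -12, NA, -5, -9, -18),
    trough1_latency = c(120, 130, NA, 125, 122, 128),
    trough2_value = c(NA, -6, NA, NA, NA, -9),
    trough2_latency = c(NA, 230, NA, NA, NA, 228),
    adf_pvalue = rep(0.6, 6), target = c(0, 0, 1, 1, 0, 1))
}

test_that("zero imputation fills value and latency cells with zeros only", {
  ft <- make_ft()
  out <- impute_missing(ft, "zeros")
  expect_equal(out$peak2_value[2], 0)
  expect_equal(out$peak2_latency[2], 0)
  expect_false(anyNA(out[, feature_model_columns()]))
  # non-missing cells untouched
  present <- !is.na(ft$peak1_value)
  expect_equal(out$peak1_value[present], ft$peak1_value[present])
})

test_that("ratio-mean imputation follows the training-ratio arithmetic", {
  ft <- make_ft()
  train <- ft[c(1, 2, 3, 5), ]
  stats <- fit_impute_stats(train)
  # all training peak1/max_amp ratios are 0.8; peak2/peak1 ratios are 0.5
  expect_equal(stats$r_peak1, 0.8)
  expect_equal(stats$r_peak2, 0.5)
  out <- impute_missing(ft, "ratio_mean", stats)
  expect_equal(out$peak1_value[4], 0.8 * ft$max_amp[4])       # 6.4
  expect_equal(out$peak2_value[4], 0.5 * out$peak1_value[4])  # chains off imputed peak1
  expect_equal(out$peak2_value[2], 0.5 * 16)
  expect_equal(out$peak2_latency[2], mean(train$peak2_latency, na.rm = TRUE))
  # troughs: magnitude ratios, re-signed negative
  expect_equal(out$trough1_value[3], -stats$r_trough1 * ft$max_amp[3])
  expect_false(anyNA(out[, feature_model_columns()]))
  # tables with nothing missing pass through unchanged under both schemes
  full <- impute_missing(ft, "zeros")
  expect_identical(impute_missing(full, "zeros"), full)
  expect_identical(impute_missing(full, "ratio_mean", stats), full)
})

test_that("ratio imputation falls back to zeros when no training row has the extremum", {
  ft <- make_ft()
  train <- ft[4, , drop = FALSE]    # no peak2 anywhere in training
  stats <- fit_impute_stats(train)
  w <- capture_warnings(out <- impute_missing(ft, "ratio_mean", stats))
  expect_true(any(grepl("peak2", w)))
  expect_equal(out$peak2_value[4], 0)
})

test_that("min-max normalisation learns its range from training rows only", {
  tr <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5))
  st <- fit_normalizer(tr, cols = c("a", "b"))
  out <- apply_normalizer(tr, st)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))       # constant feature maps to 0
  te <- apply_normalizer(data.frame(a = 8, b = 7), st)
  expect_equal(te$a, 1.5)               # extrapolation outside [0, 1] allowed
  expect_error(fit_normalizer(tr[0, ], cols = "a"), "empty")
})

test_that("feature table construction is complete, deterministic and order-invariant", {
  sf <- study_features()
  ft <- sf$features
  expect_s3_class(ft, "ccep_features")
  expect_true(all(c("test_id", "patient_id", "target") %in% names(ft)))
  expect_false(anyNA(ft[, c("max_amp", "mean_amp", "min_amp", "signal_mean")]))
  expect_true(all(ft$min_amp <= ft$mean_amp & ft$mean_amp <= ft$max_amp))
  both <- !is.na(ft$peak1_latency) & !is.na(ft$peak2_latency)
  expect_true(all(ft$peak2_latency[both] > ft$peak1_latency[both]))
  lat_cols <- grep("latency", names(ft), value = TRUE)
  for (col in lat_cols) {
    v <- ft[[col]][!is.na(ft[[col]])]
    expect_true(all(v >= 21 & v <= 300))
  }
  # imputation leaves no gaps
  expect_false(anyNA(impute_missing(ft, "zeros")[, feature_model_columns()]))
})

test_that("training-derived statistics ignore held-out rows entirely", {
  ft <- impute_missing(study_features()$features, "zeros")
  split <- split_data(ft, "by_patient", 0.2, seed = 77)
  st_train <- fit_normalizer(split$train)
  st_all_minus_test <- fit_normalizer(
    ft[!ft$test_id %in% split$test$test_id, ])
  expect_identical(st_train$range, st_all_minus_test$range)
  im_train <- fit_impute_stats(study_features()$features[
    study_features()$features$test_id %in% split$train$test_id, ])
  expect_equal(im_train$n_train, nrow(split$train))
  # after normalising its own training table, each column spans [0, 1]
  normed <- apply_normalizer(split$train, st_train)
  for (col in feature_model_columns()) {
    v <- normed[[col]]
    if (length(unique(v)) > 1) {
      expect_equal(min(v), 0)
      expect_equal(max(v), 1)
    }
  }
})

test_that("one fully worked epoch yields the hand-computed feature row", {
  # one deflection pattern built at raw resolution with zero noise
  t_ms <- (0:7499) / 25
  resp <- 40 * exp(-((t_ms - 80)^2) / 200) - 30 * exp(-((t_ms - 160)^2) / 200)
  m <- rbind(resp, matrix(0, 7, 7500))
  m[2, ] <- 2 * sin(2 * pi * 8 * t_ms / 1000)
  ep <- ecog_epoch(unname(m), test_id = "w1", patient_id = "P1")
  tests <- structure(list(list(test_id = "w1", patient_id = "P1",
                               epoch = ep, target = 1L)),
                     class = "ccep_cohort")
  ft <- build_feature_table(tests)
  expect_equal(nrow(ft), 1)
  sel <- preprocess_epoch(ep)
  expect_equal(sel$channel_index, 1L)
  expect_equal(ft$max_amp, sel$amplitude)
  # trailing 20 ms window delays the apparent extrema by ~9.5 ms
  expect_lt(abs(ft$peak1_latency - (80 + 9.5)), 2)
  expect_lt(abs(ft$trough1_latency - (160 + 9.5)), 2)
  expect_equal(ft$peak1_value, max(sel$values))
  expect_equal(ft$trough1_value, min(sel$values))
  expect_true(is.na(ft$peak2_value) && is.na(ft$trough2_value))
  expect_equal(ft$signal_mean, mean(sel$values))
  expect_equal(ft$target, 1L)
})
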
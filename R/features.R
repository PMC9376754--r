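# Descriptive feature generation.
#
# Per test: channel-amplitude summaries over all present channels, then the
# highest-amplitude channel's trace mean, constrained local extrema (up to 2
# maxima / 2 minima with latencies), and the ADF stationarity p-value.
# Missing extrema are imputed with zeros or training-derived ratio means;
# features are min-max normalised with statistics learned from training rows.

FEATURE_EXTREMUM_COLS <- c("peak1_value", "peak1_latency",
                           "peak2_value", "peak2_latency",
                           "trough1_value", "trough1_latency",
                           "trough2_value", "trough2_latency")
FEATURE_BASE_COLS <- c("max_amp", "mean_amp", "min_amp", "signal_mean")
FEATURE_TABLE_COLS <- c("test_id", "patient_id", FEATURE_BASE_COLS,
                        FEATURE_EXTREMUM_COLS, "adf_pvalue", "target")

#' Feature-extraction parameters
#'
#' @param peak_min_distance Minimum distance between retained extrema of the
#'   same polarity, in ms (default 20).
#' @param peak_min_height Minimum extremum height above (maxima) or below
#'   (minima) the valid-range mean, in microvolts (default 5).
#' @param max_maxima,max_minima Extrema retained per polarity (default 2).
#' @param impute_scheme `"zeros"` or `"ratio_mean"`; see [impute_missing()].
#' @param include_adf Include the ADF p-value in the classifier input
#'   (default `FALSE`: the feature is computed and carried, not modelled).
#' @return A validated list of class `feature_params`.
#' @export
feature_params <- function(peak_min_distance = 20L, peak_min_height = 5,
                           max_maxima = 2L, max_minima = 2L,
                           impute_scheme = c("zeros", "ratio_mean"),
                           include_adf = FALSE) {
  impute_scheme <- match.arg(impute_scheme)
  stopifnot(peak_min_distance >= 1, peak_min_height > 0,
            max_maxima >= 0, max_minima >= 0)
  structure(list(peak_min_distance = as.integer(peak_min_distance),
                 peak_min_height = peak_min_height,
                 max_maxima = as.integer(max_maxima),
                 max_minima = as.integer(max_minima),
                 impute_scheme = impute_scheme,
                 include_adf = isTRUE(include_adf)),
            class = "feature_params")
}

#' Model input columns
#' @param include_adf Whether the ADF p-value enters the model matrix.
#' @return Character vector of feature column names.
#' @export
feature_model_columns <- function(include_adf = FALSE) {
  c(FEATURE_BASE_COLS, FEATURE_EXTREMUM_COLS,
    if (include_adf) "adf_pvalue")
}

#' Channel amplitude summaries
#'
#' Maximum, mean and minimum of the per-channel peak-to-peak amplitudes over
#' present channels.
#'
#' @param per_channel List of [smoothed_signal()]s (`NULL` = absent channel).
#' @return List with `max_amp`, `mean_amp`, `min_amp` (microvolts).
#' @export
amplitude_summaries <- function(per_channel) {
  present <- !vapply(per_channel, is.null, logical(1))
  if (!any(present)) stop("no present channels to summarise")
  amps <- vapply(per_channel[present], `[[`, numeric(1), "amplitude")
  list(max_amp = max(amps), mean_amp = mean(amps), min_amp = min(amps))
}

greedy_extrema <- function(values, start_index, min_distance, min_height,
                           max_keep, sign = 1) {
  v <- sign * values
  n <- length(v)
  empty <- data.frame(latency = integer(0), value = numeric(0))
  if (n < 3 || max_keep == 0) return(empty)
  baseline <- mean(v)
  i <- 2:(n - 1)
  is_peak <- v[i] > v[i - 1] & v[i] >= v[i + 1] &
    (v[i] - baseline) >= min_height
  cand <- i[is_peak]
  if (!length(cand)) return(empty)
  # greedy by decreasing value, earliest-first on ties; enforce spacing
  cand <- cand[order(-v[cand], cand)]
  kept <- integer(0)
  for (ix in cand) {
    if (length(kept) >= max_keep) break
    if (all(abs(ix - kept) >= min_distance)) kept <- c(kept, ix)
  }
  kept <- sort(kept)   # relabel in latency order
  data.frame(latency = start_index + kept - 1L,
             value = sign * v[kept])
}

#' Constrained local extrema of a smoothed trace
#'
#' Local maxima at least `peak_min_height` microvolts above the valid-range
#' mean, pairwise at least `peak_min_distance` ms apart; candidates are kept
#' greedily in order of decreasing value and then relabelled in latency
#' order. Minima are found identically on the negated trace. At most
#' `max_maxima` / `max_minima` extrema are returned per polarity; fewer (or
#' none) is a legitimate outcome, later handled by imputation.
#'
#' @param signal A [smoothed_signal()].
#' @param params A [feature_params()].
#' @return List of two data.frames, `maxima` and `minima`, with columns
#'   `latency` (ms from stimulus onset) and `value` (microvolts).
#' @export
detect_extrema <- function(signal, params = feature_params()) {
  stopifnot(inherits(signal, "smoothed_signal"))
  list(maxima = greedy_extrema(signal$values, signal$start_index,
                               params$peak_min_distance,
                               params$peak_min_height,
                               params$max_maxima, sign = 1),
       minima = greedy_extrema(signal$values, signal$start_index,
                               params$peak_min_distance,
                               params$peak_min_height,
                               params$max_minima, sign = -1))
}

extremum_row <- function(df, k) {
  if (nrow(df) >= k) c(value = df$value[k], latency = as.numeric(df$latency[k]))
  else c(value = NA_real_, latency = NA_real_)
}

#' Build the per-test feature table
#'
#' One row per labelled test: amplitude summaries over channels, the selected
#' channel's mean, extrema values and latencies (missing as `NA` before
#' imputation), the ADF p-value, patient ID and target. Deterministic given
#' inputs and parameters; row order follows the input order.
#'
#' @param tests A `ccep_cohort` (list of labelled tests from
#'   [load_cohort()]).
#' @param pparams A [preprocess_params()].
#' @param fparams A [feature_params()].
#' @return A data.frame of class `ccep_features`.
#' @export
build_feature_table <- function(tests, pparams = preprocess_params(),
                                fparams = feature_params()) {
  rows <- lapply(tests, function(tt) {
    chans <- preprocess_channels(tt$epoch, pparams)
    summ <- amplitude_summaries(chans)
    sel <- select_channel(chans)
    ext <- detect_extrema(sel, fparams)
    p1 <- extremum_row(ext$maxima, 1); p2 <- extremum_row(ext$maxima, 2)
    t1 <- extremum_row(ext$minima, 1); t2 <- extremum_row(ext$minima, 2)
    adf <- tryCatch(adf_pvalue(sel), error = function(e) NA_real_)
    data.frame(test_id = as.character(tt$test_id),
               patient_id = as.character(tt$patient_id),
               max_amp = summ$max_amp, mean_amp = summ$mean_amp,
               min_amp = summ$min_amp, signal_mean = mean(sel$values),
               peak1_value = p1[["value"]], peak1_latency = p1[["latency"]],
               peak2_value = p2[["value"]], peak2_latency = p2[["latency"]],
               trough1_value = t1[["value"]], trough1_latency = t1[["latency"]],
               trough2_value = t2[["value"]], trough2_latency = t2[["latency"]],
               adf_pvalue = adf, target = tt$target)
  })
  if (length(rows) == 0L) {
    out <- as.data.frame(lapply(FEATURE_TABLE_COLS, function(col) {
      if (col %in% c("test_id", "patient_id")) character(0)
      else if (col == "target") integer(0) else numeric(0)
    }))
    names(out) <- FEATURE_TABLE_COLS
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("ccep_features", "data.frame")
  out
}

#' Training statistics for ratio-mean imputation
#'
#' Computed on training rows only. For each extremum the mean latency over
#' rows where it is present, and the mean magnitude ratios: first peak to
#' channel amplitude, second peak to first peak; troughs analogously on
#' absolute magnitudes.
#'
#' @param train A `ccep_features` table (training rows).
#' @return List of class `ccep_impute_stats`.
#' @export
fit_impute_stats <- function(train) {
  ratio_mean <- function(num, den) {
    ok <- !is.na(num) & !is.na(den) & den != 0
    if (!any(ok)) NA_real_ else mean(num[ok] / den[ok])
  }
  lat_mean <- function(col) {
    v <- train[[col]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(list(
    r_peak1 = ratio_mean(train$peak1_value, train$max_amp),
    r_peak2 = ratio_mean(train$peak2_value, train$peak1_value),
    r_trough1 = ratio_mean(abs(train$trough1_value), train$max_amp),
    r_trough2 = ratio_mean(abs(train$trough2_value), abs(train$trough1_value)),
    lat = vapply(c("peak1_latency", "peak2_latency",
                   "trough1_latency", "trough2_latency"),
                 lat_mean, numeric(1)),
    n_train = nrow(train)), class = "ccep_impute_stats")
}

#' Impute missing extremum features
#'
#' `scheme = "zeros"`: missing extremum values and latencies become 0.
#' `scheme = "ratio_mean"`: a missing first peak is imputed as the training
#' mean of (first peak / channel amplitude) times this row's channel
#' amplitude; a missing second peak as the training mean of (second peak /
#' first peak) times this row's (possibly just-imputed) first peak. Troughs
#' are treated the same way on absolute magnitudes and re-signed negative.
#' Missing latencies take the training-mean latency of that extremum. If a
#' needed training ratio is unavailable (no training row has the extremum),
#' the affected cells fall back to zeros with a warning. Non-missing cells
#' are never altered.
#'
#' @param table A `ccep_features` table.
#' @param scheme `"zeros"` or `"ratio_mean"`.
#' @param stats A `ccep_impute_stats` from [fit_impute_stats()]; required
#'   for `"ratio_mean"`.
#' @return The table with no missing extremum cells.
#' @export
impute_missing <- function(table, scheme = c("zeros", "ratio_mean"),
                           stats = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "zeros") {
    for (col in FEATURE_EXTREMUM_COLS) {
      table[[col]][is.na(table[[col]])] <- 0
    }
    return(table)
  }
  if (is.null(stats)) stop("ratio_mean imputation requires training stats")

  fill_value <- function(col, ratio, base) {
    miss <- is.na(table[[col]])
    if (!any(miss)) return(table)
    if (is.na(ratio)) {
      warning(sprintf("no training rows to estimate the %s ratio; imputing zeros",
                      col))
      table[[col]][miss] <- 0
    } else {
      table[[col]][miss] <- ratio * base[miss]
    }
    table
  }
  fill_latency <- function(col) {
    miss <- is.na(table[[col]])
    if (!any(miss)) return(table)
    m <- stats$lat[[col]]
    if (is.na(m)) {
      warning(sprintf("no training rows to estimate mean %s; imputing zeros", col))
      m <- 0
    }
    table[[col]][miss] <- m
    table
  }

  table <- fill_value("peak1_value", stats$r_peak1, table$max_amp)
  table <- fill_value("peak2_value", stats$r_peak2, table$peak1_value)
  table <- fill_value("trough1_value", -stats$r_trough1, table$max_amp)
  table <- fill_value("trough2_value", -stats$r_trough2, abs(table$trough1_value))
  for (col in grep("latency$", FEATURE_EXTREMUM_COLS, value = TRUE)) {
    table <- fill_latency(col)
  }
  table
}

#' Min-max normalisation fitted on training rows
#'
#' Learns per-feature minimum and maximum from the training table; applying
#' the normaliser maps each feature `x` to `(x - min)/(max - min)`. A
#' constant training feature maps to 0 everywhere. Values outside the
#' training range (possible on test rows) fall outside \[0, 1\]; that is the
#' intended extrapolation behaviour.
#'
#' @param train Training `ccep_features` table (already imputed).
#' @param cols Columns to normalise (default: the model input columns).
#' @return List of class `ccep_normalizer`.
#' @export
fit_normalizer <- function(train, cols = feature_model_columns()) {
  if (nrow(train) == 0L) stop("cannot fit a normaliser on an empty table")
  rng <- lapply(cols, function(col) {
    v <- train[[col]]
    if (is.null(v)) stop(sprintf("feature column '%s' is missing", col))
    c(min = min(v), max = max(v))
  })
  names(rng) <- cols
  structure(list(range = rng, cols = cols), class = "ccep_normalizer")
}

#' @rdname fit_normalizer
#' @param table Table to transform.
#' @param stats A `ccep_normalizer`.
#' @export
apply_normalizer <- function(table, stats) {
  stopifnot(inherits(stats, "ccep_normalizer"))
  for (col in stats$cols) {
    r <- stats$range[[col]]
    span <- r[["max"]] - r[["min"]]
    table[[col]] <- if (span == 0) rep(0, nrow(table))
                    else (table[[col]] - r[["min"]]) / span
  }
  table
}

#' Write / read a feature table as CSV
#'
#' Stable column order; missing extrema are written as empty cells.
#' @param table A `ccep_features` table.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table[, FEATURE_TABLE_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(test_id = "character",
                                        patient_id = "character"),
                         na.strings = "")
  if (!identical(names(out), FEATURE_TABLE_COLS)) {
    missing_cols <- setdiff(FEATURE_TABLE_COLS, names(out))
    if (length(missing_cols)) {
      stop(sprintf("feature table is missing columns: %s",
                   paste(missing_cols, collapse = ", ")))
    }
    out <- out[, FEATURE_TABLE_COLS]
  }
  class(out) <- c("ccep_features", "data.frame")
  out
}
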
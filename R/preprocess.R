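# Waveform reduction: 7500-sample epochs to millisecond-resolution smoothed
# traces.
#
# One bin equals one millisecond (300 bins over a 300 ms epoch), so windows
# and distances given in ms below are bin counts. Indexing is 1-based: bin t
# covers (t-1, t] ms after stimulus onset.

#' Preprocessing parameters
#'
#' @param n_bins Number of bins the raw epoch is reduced to (default 300, one
#'   per millisecond).
#' @param bin_size Raw samples per bin (default 25 at 25 kHz).
#' @param ma_window Trailing moving-average window in bins (default 20): the
#'   first 20 ms of the binned signal produce the first smoothed value.
#' @param artifact_factor Stimulus-artifact criterion multiplier (default
#'   1.25); see [trim_artifact()].
#' @param max_extra_shift Maximum artifact-driven start shift in bins beyond
#'   the mandatory one (default 10).
#' @param mandatory_shift Unconditional start shift in bins (default 1): the
#'   first smoothed millisecond is always discarded, artifact or not.
#' @return A validated list of class `preprocess_params`.
#' @export
preprocess_params <- function(n_bins = 300L, bin_size = 25L, ma_window = 20L,
                              artifact_factor = 1.25, max_extra_shift = 10L,
                              mandatory_shift = 1L) {
  stopifnot(n_bins >= 1, bin_size >= 1, ma_window >= 1,
            artifact_factor > 1, max_extra_shift >= 0, mandatory_shift >= 0)
  structure(list(n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
                 ma_window = as.integer(ma_window),
                 artifact_factor = artifact_factor,
                 max_extra_shift = as.integer(max_extra_shift),
                 mandatory_shift = as.integer(mandatory_shift)),
            class = "preprocess_params")
}

#' A binned, smoothed, artifact-trimmed single-channel trace
#'
#' `values[i]` is the smoothed signal at millisecond `start_index + i - 1`.
#' `amplitude` is max minus min over the valid (post-trim) range.
#'
#' @param values Numeric vector of smoothed microvolt values.
#' @param start_index Millisecond index of `values[1]`.
#' @param channel_index Source channel (1-based), or `NA`.
#' @return An object of class `smoothed_signal`.
#' @export
smoothed_signal <- function(values, start_index, channel_index = NA_integer_) {
  stopifnot(is.numeric(values), length(values) >= 1)
  structure(list(values = as.numeric(values),
                 start_index = as.integer(start_index),
                 channel_index = as.integer(channel_index),
                 amplitude = max(values) - min(values)),
            class = "smoothed_signal")
}

#' @export
print.smoothed_signal <- function(x, ...) {
  cat(sprintf("<smoothed_signal> channel %s, start %d ms, %d values, amplitude %.2f uV\n",
              x$channel_index, x$start_index, length(x$values), x$amplitude))
  invisible(x)
}

#' Reduce a raw channel to per-millisecond bin means
#'
#' Splits the raw vector into `n_bins` consecutive blocks of `bin_size`
#' samples and takes the arithmetic mean of each, yielding one value per
#' millisecond.
#'
#' @param raw Numeric vector of length `n_bins * bin_size`.
#' @param params A [preprocess_params()].
#' @return Numeric vector of length `n_bins`.
#' @export
bin_average <- function(raw, params = preprocess_params()) {
  expected <- params$n_bins * params$bin_size
  if (length(raw) != expected) {
    stop(sprintf("raw signal has %d samples; expected %d (%d bins x %d)",
                 length(raw), expected, params$n_bins, params$bin_size))
  }
  colMeans(matrix(raw, nrow = params$bin_size, ncol = params$n_bins))
}

#' Trailing moving-average smoothing
#'
#' `smoothed[t] = mean(binned[(t - w + 1) .. t])` for `t = w .. n` with
#' window `w = ma_window`: each output uses the preceding `w` bins, so the
#' first `w` ms of the binned signal produce the first smoothed value, which
#' sits at millisecond index `w`.
#'
#' @param binned Numeric vector (the bin means).
#' @param params A [preprocess_params()].
#' @return A [smoothed_signal()] with `start_index = ma_window` and
#'   `length(binned) - ma_window + 1` values.
#' @export
moving_average <- function(binned, params = preprocess_params()) {
  w <- params$ma_window
  n <- length(binned)
  if (n < w) {
    stop(sprintf("signal of %d bins is shorter than the %d-bin smoothing window",
                 n, w))
  }
  cs <- cumsum(c(0, binned))
  vals <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  smoothed_signal(vals, start_index = w)
}

#' Shift the trace start past the stimulus artifact
#'
#' The start index always advances by `mandatory_shift` (default 1 ms) to
#' discard the first smoothed millisecond. Then, for up to `max_extra_shift`
#' iterations, the candidate start value is compared with the rest of the
#' trace: if its deviation from the mean of the remaining values exceeds
#' `artifact_factor` times half their range (half peak-to-peak amplitude),
#' the start advances by one more millisecond. The criterion makes precise
#' the idea of discarding a leading value that stands out against the
#' amplitude of the rest of the signal scaled by 1.25.
#'
#' @param smoothed A [smoothed_signal()] (or numeric vector, taken to start
#'   at millisecond 1).
#' @param params A [preprocess_params()].
#' @return A [smoothed_signal()] with the advanced `start_index`, trimmed
#'   `values`, and `amplitude` computed over the valid range.
#' @export
trim_artifact <- function(smoothed, params = preprocess_params()) {
  if (!inherits(smoothed, "smoothed_signal")) {
    smoothed <- smoothed_signal(smoothed, start_index = 1L)
  }
  v <- smoothed$values
  # need a candidate start plus a non-empty remainder
  if (length(v) < params$mandatory_shift + 2L) {
    stop(sprintf("trace of %d values is too short to trim (need > %d)",
                 length(v), params$mandatory_shift + 1L))
  }
  i <- 1L + params$mandatory_shift
  extra <- 0L
  while (extra < params$max_extra_shift && i < length(v)) {
    rest <- v[(i + 1L):length(v)]
    half_range <- (max(rest) - min(rest)) / 2
    if (abs(v[i] - mean(rest)) > params$artifact_factor * half_range) {
      i <- i + 1L
      extra <- extra + 1L
    } else {
      break
    }
  }
  out <- smoothed_signal(v[i:length(v)],
                         start_index = smoothed$start_index + (i - 1L),
                         channel_index = smoothed$channel_index)
  out
}

#' Pick the channel with the highest oscillation amplitude
#'
#' Most channels carry only low-amplitude impulse noise; analysis proceeds on
#' the channel whose smoothed trace has the largest peak-to-peak amplitude.
#' Absent (padding) channels are `NULL` entries and are never selected. Ties
#' go to the lowest channel index.
#'
#' @param per_channel List of [smoothed_signal()] objects, `NULL` for absent
#'   channels.
#' @return The selected [smoothed_signal()].
#' @export
select_channel <- function(per_channel) {
  present <- !vapply(per_channel, is.null, logical(1))
  if (!any(present)) stop("no present channels to select from")
  amps <- rep(-Inf, length(per_channel))
  amps[present] <- vapply(per_channel[present], `[[`, numeric(1), "amplitude")
  per_channel[[which.max(amps)]]   # which.max takes the first maximum
}

#' Preprocess every present channel of an epoch
#'
#' Applies [bin_average()], [moving_average()] and [trim_artifact()] to each
#' present channel independently.
#'
#' @param epoch An [ecog_epoch()].
#' @param params A [preprocess_params()].
#' @return A list, one entry per channel row: a [smoothed_signal()] for
#'   present channels, `NULL` for absent ones.
#' @export
preprocess_channels <- function(epoch, params = preprocess_params()) {
  stopifnot(inherits(epoch, "ecog_epoch"))
  lapply(seq_len(nrow(epoch$samples)), function(ch) {
    if (!epoch$present[ch]) return(NULL)
    binned <- bin_average(epoch$samples[ch, ], params)
    sm <- moving_average(binned, params)
    sm$channel_index <- ch
    trim_artifact(sm, params)
  })
}

#' Full waveform reduction for one epoch
#'
#' Bin-averages, smooths and trims every present channel, then returns the
#' highest-amplitude channel's trace.
#'
#' @inheritParams preprocess_channels
#' @return The selected [smoothed_signal()].
#' @export
preprocess_epoch <- function(epoch, params = preprocess_params()) {
  select_channel(preprocess_channels(epoch, params))
}

#' Dump per-channel smoothed traces to CSV for plotting
#'
#' One row per (channel, millisecond) with the smoothed value; start indices
#' and amplitudes are repeated per channel. Intended for visual inspection of
#' the preprocessing, channel by channel.
#'
#' @inheritParams preprocess_channels
#' @param path Output CSV path.
#' @export
dump_smoothed_traces <- function(epoch, path, params = preprocess_params()) {
  chans <- preprocess_channels(epoch, params)
  rows <- do.call(rbind, lapply(chans, function(s) {
    if (is.null(s)) return(NULL)
    data.frame(channel = s$channel_index,
               ms = s$start_index + seq_along(s$values) - 1L,
               value = s$values, start_index = s$start_index,
               amplitude = s$amplitude)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
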
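# Minimal European Data Format (EDF) reader/writer.
#
# Covers the subset of EDF used for single-epoch evoked-potential exports:
# one data record holding the whole epoch, identical sampling rate and
# physical range across channels, 16-bit signed little-endian samples.
# No EDF+ annotations.

EDF_HEADER_BYTES <- 256L
EDF_SIGNAL_HEADER_BYTES <- 256L

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) {
    stop(sprintf("EDF header field '%s' exceeds %d characters", x, width))
  }
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  edf_pad(s, width)
}

#' Write a multichannel epoch to an EDF file
#'
#' Writes one data record spanning the whole epoch. Samples are quantized to
#' 16 bits over `phys_range`; with the default +/-1000 uV range the
#' quantization step is about 0.03 uV. Values outside `phys_range` are
#' clipped.
#'
#' @param path Output file path.
#' @param samples Numeric matrix, channels x samples, in physical units.
#' @param sampling_rate Samples per second per channel.
#' @param labels Channel labels (<= 16 ASCII characters each).
#' @param phys_dim Physical dimension string written for every channel.
#' @param phys_range Length-2 numeric, physical minimum and maximum.
#' @param patient_id,recording_id Free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, samples, sampling_rate,
                      labels = sprintf("ECOG%02d", seq_len(nrow(samples))),
                      phys_dim = "uV",
                      phys_range = c(-1000, 1000),
                      patient_id = "X", recording_id = "X") {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) stop("EDF samples must all be finite")
  ns <- nrow(samples)
  n_samp <- ncol(samples)
  if (length(labels) != ns) stop("one label per channel required")
  duration <- n_samp / sampling_rate

  dig_min <- -32768L
  dig_max <- 32767L
  pmin <- phys_range[1]
  pmax <- phys_range[2]
  if (!(pmax > pmin)) stop("phys_range must be increasing")

  con <- file(path, "wb")
  on.exit(close(con))

  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(patient_id, 80))
  wr(edf_pad(recording_id, 80))
  wr(edf_pad("01.01.22", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(EDF_HEADER_BYTES + ns * EDF_SIGNAL_HEADER_BYTES, 8))
  wr(edf_pad("", 44))
  wr(edf_num(1L, 8))
  wr(edf_num(duration, 8))
  wr(edf_num(ns, 4))

  for (lab in labels) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))          # transducer
  for (i in seq_len(ns)) wr(edf_pad(phys_dim, 8))
  for (i in seq_len(ns)) wr(edf_num(pmin, 8))
  for (i in seq_len(ns)) wr(edf_num(pmax, 8))
  for (i in seq_len(ns)) wr(edf_num(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_num(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))          # prefiltering
  for (i in seq_len(ns)) wr(edf_num(n_samp, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  scale <- (dig_max - dig_min) / (pmax - pmin)
  clipped <- pmin(pmax(samples, pmin), pmax)
  dig <- round((clipped - pmin) * scale + dig_min)
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # record layout: all samples of channel 1, then channel 2, ...
  writeBin(as.integer(t(dig)[, , drop = TRUE]), con, size = 2L,
           endian = "little")
  invisible(path)
}

edf_read_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF file written with a single data record
#'
#' @param path EDF file path.
#' @return A list with elements `samples` (channels x samples matrix in
#'   physical units), `labels`, `sampling_rate`, `duration` (seconds),
#'   `phys_dim`, `patient_id`, and `recording_id`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read EDF file '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_read_field(con, 8)
  if (version != "0") stop(sprintf("'%s' is not an EDF file", path))
  patient_id <- edf_read_field(con, 80)
  recording_id <- edf_read_field(con, 80)
  invisible(edf_read_field(con, 8))   # start date
  invisible(edf_read_field(con, 8))   # start time
  header_bytes <- as.integer(edf_read_field(con, 8))
  invisible(edf_read_field(con, 44))
  n_records <- as.integer(edf_read_field(con, 8))
  duration <- as.numeric(edf_read_field(con, 8))
  ns <- as.integer(edf_read_field(con, 4))
  if (is.na(ns) || ns < 1) stop(sprintf("malformed EDF header in '%s'", path))
  if (is.na(n_records) || n_records != 1L) {
    stop(sprintf("'%s': only single-record EDF files are supported", path))
  }

  rd <- function(width) vapply(seq_len(ns), function(i) {
    edf_read_field(con, width)
  }, character(1))
  labels <- rd(16)
  invisible(rd(80))
  phys_dim <- rd(8)
  pmin <- as.numeric(rd(8))
  pmax <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8))
  dmax <- as.numeric(rd(8))
  invisible(rd(80))
  n_samp <- as.integer(rd(8))
  invisible(rd(32))
  if (length(unique(n_samp)) != 1L) {
    stop(sprintf("'%s': channels have unequal sample counts", path))
  }
  expect_bytes <- EDF_HEADER_BYTES + ns * EDF_SIGNAL_HEADER_BYTES
  if (!is.na(header_bytes) && header_bytes != expect_bytes) {
    stop(sprintf("malformed EDF header in '%s'", path))
  }

  n <- n_samp[1]
  raw_dig <- readBin(con, what = "integer", n = ns * n, size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_dig) != ns * n) {
    stop(sprintf("'%s': truncated EDF data record", path))
  }
  dig <- matrix(raw_dig, nrow = ns, ncol = n, byrow = TRUE)
  scale <- (pmax - pmin) / (dmax - dmin)
  samples <- (dig - dmin) * scale + pmin
  rownames(samples) <- labels

  list(samples = samples, labels = labels,
       sampling_rate = n / duration, duration = duration,
       phys_dim = phys_dim[1], patient_id = patient_id,
       recording_id = recording_id)
}
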
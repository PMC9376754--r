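# Epoch and cohort-manifest input/output.
#
# An epoch is one CCEP stimulation test: the averaged evoked response over a
# fixed post-stimulus window, recorded on 8 or 16 ECoG channels. Cohort
# metadata (patient, surgical phase, quality screening, speech scores) rides
# in a CSV manifest, one row per test; EDF files carry only the waveforms.

MANIFEST_COLUMNS <- c("test_id", "file_path", "patient_id", "phase",
                      "quality_ok", "pre_score", "post_score")
SCORE_RANGE <- c(0L, 45L)
VALID_CHANNEL_COUNTS <- c(8L, 16L)
CANONICAL_CHANNELS <- 16L

#' Construct an ECoG epoch object
#'
#' @param samples Numeric matrix, channels x samples, in microvolts.
#' @param test_id,patient_id Identifiers.
#' @param phase `"pre"` or `"post"` (relative to tumour resection).
#' @param sampling_rate Samples per second (default 25000).
#' @param epoch_ms Epoch duration in milliseconds (default 300).
#' @param present Logical vector marking channels that carry real data;
#'   padding channels introduced by [standardize_channels()] are `FALSE`.
#' @return An object of class `ecog_epoch`.
#' @export
ecog_epoch <- function(samples, test_id = NA_character_,
                       patient_id = NA_character_, phase = "pre",
                       sampling_rate = 25000, epoch_ms = 300,
                       present = rep(TRUE, nrow(samples))) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) stop("epoch samples must all be finite")
  phase <- match.arg(phase, c("pre", "post"))
  expected <- round(sampling_rate * epoch_ms / 1000)
  if (ncol(samples) != expected) {
    stop(sprintf("epoch has %d samples per channel; expected %d (%g samples/s over %g ms)",
                 ncol(samples), expected, sampling_rate, epoch_ms))
  }
  if (length(present) != nrow(samples)) {
    stop("'present' must have one entry per channel")
  }
  structure(list(test_id = test_id, patient_id = patient_id, phase = phase,
                 samples = samples, sampling_rate = sampling_rate,
                 epoch_ms = epoch_ms, present = as.logical(present)),
            class = "ecog_epoch")
}

#' @export
print.ecog_epoch <- function(x, ...) {
  cat(sprintf("<ecog_epoch> test %s, patient %s, phase %s: %d/%d channels present, %d samples @ %g Hz\n",
              x$test_id, x$patient_id, x$phase, sum(x$present),
              nrow(x$samples), ncol(x$samples), x$sampling_rate))
  invisible(x)
}

#' Read one stimulation test from an EDF file
#'
#' The EDF file supplies only the waveforms; identifiers and phase are taken
#' from the cohort manifest and passed through the arguments.
#'
#' @param path EDF file path.
#' @inheritParams ecog_epoch
#' @return An [ecog_epoch()].
#' @export
read_epoch_file <- function(path, test_id = NA_character_,
                            patient_id = NA_character_, phase = "pre",
                            sampling_rate = 25000, epoch_ms = 300) {
  edf <- read_edf(path)
  n_ch <- nrow(edf$samples)
  if (!n_ch %in% VALID_CHANNEL_COUNTS) {
    stop(sprintf("'%s': %d channels; epochs must have %s channels", path,
                 n_ch, paste(VALID_CHANNEL_COUNTS, collapse = " or ")))
  }
  ecog_epoch(edf$samples, test_id = test_id, patient_id = patient_id,
             phase = phase, sampling_rate = sampling_rate,
             epoch_ms = epoch_ms)
}

#' Write an epoch's waveforms to an EDF file
#'
#' Only present channels are written, so a standardized epoch round-trips to
#' its original channel count.
#'
#' @param epoch An [ecog_epoch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_file <- function(epoch, path) {
  stopifnot(inherits(epoch, "ecog_epoch"))
  keep <- which(epoch$present)
  write_edf(path, epoch$samples[keep, , drop = FALSE],
            sampling_rate = epoch$sampling_rate,
            labels = sprintf("ECOG%02d", seq_along(keep)),
            patient_id = as.character(epoch$patient_id),
            recording_id = as.character(epoch$test_id))
}

#' Bring an epoch to the canonical channel count
#'
#' 8-channel epochs are padded to 16 rows; padding rows are marked absent
#' (`present = FALSE`) and are excluded from every channel-wise statistic and
#' from highest-amplitude channel selection — they are markers, not zeros.
#'
#' @param epoch An [ecog_epoch()].
#' @param canonical Target channel count (default 16).
#' @return An [ecog_epoch()] with `canonical` rows.
#' @export
standardize_channels <- function(epoch, canonical = CANONICAL_CHANNELS) {
  stopifnot(inherits(epoch, "ecog_epoch"))
  n_ch <- nrow(epoch$samples)
  if (!n_ch %in% VALID_CHANNEL_COUNTS) {
    stop(sprintf("cannot standardize an epoch with %d channels", n_ch))
  }
  if (n_ch == canonical) return(epoch)
  if (n_ch > canonical) stop("epoch already exceeds the canonical channel count")
  pad <- matrix(0, nrow = canonical - n_ch, ncol = ncol(epoch$samples))
  epoch$samples <- rbind(epoch$samples, pad)
  rownames(epoch$samples) <- NULL
  epoch$present <- c(epoch$present, rep(FALSE, nrow(pad)))
  epoch
}

#' Binary speech-deterioration target from Luria-scale scores
#'
#' Scores summarise speech dysfunction on a 0-45 scale (0 is the norm);
#' the target is 1 when speech worsened after surgery and 0 when it improved
#' or remained unchanged. Vectorised.
#'
#' @param pre_score,post_score Integer scores in \[0, 45\].
#' @return Integer vector of 0/1.
#' @export
make_target <- function(pre_score, post_score) {
  check_score <- function(x, what) {
    if (any(is.na(x)) || any(x < SCORE_RANGE[1]) || any(x > SCORE_RANGE[2])) {
      stop(sprintf("%s must lie in [%d, %d]", what, SCORE_RANGE[1],
                   SCORE_RANGE[2]))
    }
  }
  check_score(pre_score, "pre_score")
  check_score(post_score, "post_score")
  as.integer(post_score > pre_score)
}

#' Read and validate a cohort manifest CSV
#'
#' @param path Manifest CSV path with header exactly
#'   `test_id,file_path,patient_id,phase,quality_ok,pre_score,post_score`.
#' @return A data.frame, one row per test.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' does not exist", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest A manifest data.frame to validate in place.
#' @export
validate_manifest <- function(manifest) {
  if (!identical(names(manifest), MANIFEST_COLUMNS)) {
    stop(sprintf("manifest columns must be exactly: %s",
                 paste(MANIFEST_COLUMNS, collapse = ",")))
  }
  if (anyDuplicated(manifest$test_id)) {
    dup <- unique(manifest$test_id[duplicated(manifest$test_id)])
    stop(sprintf("duplicate test_id in manifest: %s",
                 paste(dup, collapse = ", ")))
  }
  if (!all(manifest$phase %in% c("pre", "post"))) {
    stop("manifest phase must be 'pre' or 'post'")
  }
  manifest$quality_ok <- as.logical(manifest$quality_ok)
  if (any(is.na(manifest$quality_ok))) stop("quality_ok must be TRUE/FALSE")
  for (col in c("pre_score", "post_score")) {
    v <- manifest[[col]]
    if (any(is.na(v)) || any(v < SCORE_RANGE[1]) || any(v > SCORE_RANGE[2])) {
      stop(sprintf("%s out of [%d, %d] in manifest", col, SCORE_RANGE[1],
                   SCORE_RANGE[2]))
    }
  }
  by_pat <- split(manifest[c("pre_score", "post_score")], manifest$patient_id)
  bad <- names(by_pat)[vapply(by_pat, function(d) {
    length(unique(d$pre_score)) > 1L || length(unique(d$post_score)) > 1L
  }, logical(1))]
  if (length(bad)) {
    stop(sprintf("patients with inconsistent scores across tests: %s",
                 paste(bad, collapse = ", ")))
  }
  manifest
}

#' Write a cohort manifest CSV
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the analysable cohort: quality-passing pre-resection tests
#'
#' Reads the manifest, keeps rows passing the quality flag and matching the
#' requested surgical phase, reads each EDF epoch, standardizes channel
#' counts, and attaches the binary deterioration target via [make_target()].
#' The study design restricts analysis to pre-resection tests; `phase` is
#' configurable because post-resection recordings exist but are not analysed.
#'
#' @param manifest_path Manifest CSV path, or an already-validated manifest
#'   data.frame.
#' @param data_dir Directory that `file_path` entries are relative to
#'   (defaults to the manifest's directory).
#' @param phase Phase to keep (default `"pre"`).
#' @param quality_only Keep only `quality_ok` rows (default `TRUE`).
#' @param canonical Canonical channel count after standardization.
#' @return A list of labelled tests, each a list with `test_id`,
#'   `patient_id`, `epoch` and `target`; class `ccep_cohort`.
#' @export
load_cohort <- function(manifest_path, data_dir = NULL, phase = "pre",
                        quality_only = TRUE,
                        canonical = CANONICAL_CHANNELS) {
  if (is.data.frame(manifest_path)) {
    manifest <- validate_manifest(manifest_path)
    if (is.null(data_dir)) data_dir <- "."
  } else {
    manifest <- read_manifest(manifest_path)
    if (is.null(data_dir)) data_dir <- dirname(manifest_path)
  }
  keep <- manifest$phase == phase
  if (quality_only) keep <- keep & manifest$quality_ok
  rows <- manifest[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning(sprintf("no tests match phase='%s'%s", phase,
                    if (quality_only) " with quality_ok=TRUE" else ""))
  }
  paths <- file.path(data_dir, rows$file_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("missing epoch files:\n%s",
                 paste(missing, collapse = "\n")))
  }
  targets <- if (nrow(rows)) make_target(rows$pre_score, rows$post_score)
             else integer(0)
  tests <- lapply(seq_len(nrow(rows)), function(i) {
    ep <- read_epoch_file(paths[i], test_id = rows$test_id[i],
                          patient_id = rows$patient_id[i],
                          phase = rows$phase[i])
    ep <- standardize_channels(ep, canonical)
    list(test_id = rows$test_id[i], patient_id = rows$patient_id[i],
         epoch = ep, target = targets[i])
  })
  structure(tests, class = "ccep_cohort")
}

#' @export
print.ccep_cohort <- function(x, ...) {
  cat(sprintf("<ccep_cohort> %d labelled tests from %d patients (%d positive)\n",
              length(x),
              length(unique(vapply(x, `[[`, character(1), "patient_id"))),
              sum(vapply(x, `[[`, integer(1), "target"))))
  invisible(x)
}
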
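#' Construct an ECG strip object
#'
#' An `ecg_strip` holds one short single-lead ECG recording: a numeric
#' vector of voltage samples in microvolts together with its sampling
#' metadata.  The default profile matches a handheld single-channel
#' recorder: 125 Hz for 28 s, i.e. 3500 samples per strip.
#'
#' @param samples Numeric vector of voltage samples (µV). All values must
#'   be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param patient_id Identifier of the patient the strip belongs to.
#' @param strip_index Ordinal recording index (day-to-day order).
#' @param duration_s Recording duration in seconds; inferred as
#'   `length(samples) / fs` when omitted. Must agree with the sample
#'   count to within one sample.
#'
#' @return An object of class `ecg_strip`: a list with elements
#'   `samples`, `fs`, `duration_s`, `patient_id`, `strip_index`.
#' @examples
#' s <- ecg_strip(sin(seq(0, 2 * pi, length.out = 250)), fs = 125)
#' s
#' @export
ecg_strip <- function(samples, fs = 125, patient_id = NA_character_,
                      strip_index = NA_integer_, duration_s = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("ecg_strip: no samples")
  if (!all(is.finite(samples))) stop("ecg_strip: non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("ecg_strip: fs must be a single positive number")
  }
  if (is.null(duration_s)) duration_s <- length(samples) / fs
  if (abs(length(samples) - round(fs * duration_s)) > 1) {
    stop("ecg_strip: length(samples) inconsistent with fs * duration_s")
  }
  structure(
    list(samples = samples, fs = fs, duration_s = duration_s,
         patient_id = patient_id, strip_index = as.integer(strip_index)),
    class = "ecg_strip"
  )
}

#' @export
print.ecg_strip <- function(x, ...) {
  cat(sprintf(
    "ECG strip: %d samples @ %g Hz (%.1f s), patient %s, strip %s\n",
    length(x$samples), x$fs, x$duration_s,
    as.character(x$patient_id), as.character(x$strip_index)))
  cat(sprintf("  voltage range [%.1f, %.1f] uV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Read one ECG strip from a single-column CSV file
#'
#' The on-disk format is one voltage sample (µV) per row, decimal point,
#' with an optional single header line.  This is the plain-text
#' intermediate a device-specific converter would emit.
#'
#' @param path Path to the strip file.
#' @param fs Sampling rate in Hz of the recording.
#' @param patient_id,strip_index Provenance metadata stored on the strip.
#' @param scale Optional multiplicative factor applied to the parsed
#'   values (e.g. to convert mV input to the internal µV convention).
#' @return A validated [ecg_strip()].
#' @seealso [write_strip()]
#' @export
read_strip <- function(path, fs = 125, patient_id = NA_character_,
                       strip_index = NA_integer_, scale = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("read_strip: empty file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  start <- 1L
  if (is.na(vals[1L]) && length(lines) > 1L) start <- 2L  # header line
  bad <- which(is.na(vals[start:length(vals)])) + start - 1L
  if (length(bad) > 0L) {
    stop(sprintf("read_strip: non-numeric value '%s' at row %d of %s",
                 lines[bad[1L]], bad[1L], path))
  }
  ecg_strip(vals[start:length(vals)] * scale, fs = fs,
            patient_id = patient_id, strip_index = strip_index)
}

#' Write an ECG strip to a single-column CSV file
#'
#' Values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the doubles bit-for-bit.
#'
#' @param strip An [ecg_strip()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_strip <- function(strip, path) {
  stopifnot(inherits(strip, "ecg_strip"))
  writeLines(sprintf("%.17g", strip$samples), path)
  invisible(path)
}

#' Check an ECG strip for gross quality problems
#'
#' Reports (rather than errors on) conditions that make complexity
#' analysis meaningless: too few samples, non-finite values, or a
#' constant (flat-line) signal.
#'
#' @param strip An [ecg_strip()].
#' @param min_samples Minimum acceptable number of samples
#'   (default 3500, the 28 s x 125 Hz profile).
#' @return Character vector of issue codes, possibly empty; a subset of
#'   `c("too_short", "non_finite", "constant_signal")`.
#' @export
validate_strip <- function(strip, min_samples = 3500) {
  stopifnot(inherits(strip, "ecg_strip"))
  issues <- character(0)
  if (length(strip$samples) < min_samples) issues <- c(issues, "too_short")
  if (!all(is.finite(strip$samples))) issues <- c(issues, "non_finite")
  if (length(unique(strip$samples)) == 1L) issues <- c(issues, "constant_signal")
  issues
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per strip and columns
#' `patient_id`, `label` (`"control"` or `"case"`) and `path` (strip file,
#' relative paths resolved against the manifest's directory).  Each
#' patient must carry a single, consistent label.
#'
#' @param path Manifest CSV path.
#' @param check_files If `TRUE` (default), error when a referenced strip
#'   file does not exist.
#' @return A `data.frame` of class `cohort_manifest` with columns
#'   `patient_id`, `label`, `path`; strip order within a patient is the
#'   manifest (recording) order.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "label", "path")
  if (!all(req %in% names(m))) {
    stop("read_manifest: manifest must have columns ",
         paste(req, collapse = ", "))
  }
  m$patient_id <- as.character(m$patient_id)
  m$label <- as.character(m$label)
  if (!all(m$label %in% c("control", "case"))) {
    stop("read_manifest: labels must be 'control' or 'case'")
  }
  lab_per_pat <- tapply(m$label, m$patient_id, function(x) length(unique(x)))
  if (any(lab_per_pat > 1L)) {
    stop("read_manifest: inconsistent labels for patient(s): ",
         paste(names(lab_per_pat)[lab_per_pat > 1L], collapse = ", "))
  }
  if (nrow(m) == 0L) stop("read_manifest: empty manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (check_files) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing) > 0L) {
      stop("read_manifest: missing strip file(s): ",
           paste(head(missing, 5L), collapse = ", "))
    }
  }
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Retain only patients contributing enough strips
#'
#' Mirrors the eligibility rule that a minimum number of recordings per
#' participant (30 in the source protocol) is needed before day-to-day
#' complexity variability is a stable quantity.  Excluded patients are
#' recorded in the `"exclusions"` attribute of the result.
#'
#' @param manifest A manifest `data.frame` (see [read_manifest()]).
#' @param min_strips Minimum number of strips per patient (>= 1).
#' @return The filtered manifest (same class), with attribute
#'   `exclusions`: a `data.frame` of `patient_id`, `n_strips`, `reason`.
#'   A warning is raised when no patient survives.
#' @export
filter_patients <- function(manifest, min_strips = 30) {
  stopifnot(is.data.frame(manifest), min_strips >= 1)
  counts <- table(manifest$patient_id)
  drop <- names(counts)[counts < min_strips]
  excl <- data.frame(
    patient_id = drop,
    n_strips = as.integer(counts[drop]),
    reason = if (length(drop)) sprintf("fewer than %d strips", min_strips)
             else character(0),
    stringsAsFactors = FALSE
  )
  out <- manifest[!(manifest$patient_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("filter_patients: no patients retained")
  }
  for (p in excl$patient_id) {
    message(sprintf("filter_patients: excluding %s (%d strips < %d)",
                    p, counts[[p]], min_strips))
  }
  attr(out, "exclusions") <- excl
  out
}
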
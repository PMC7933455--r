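#' Beat-detection (QRS detector) parameters
#'
#' Parameters of the derivative-threshold R-wave detector used by
#' [bd_binarize()]. Defaults follow the reference protocol: a
#' Savitzky-Golay smoothing window of 5 samples, a 6-s sliding search
#' window, and a relative derivative threshold of 0.7 within each
#' window. The refractory period controls how far the search window
#' advances after a detection, preventing one QRS complex from being
#' marked twice; 250 ms corresponds to an (unphysiological) upper rate
#' bound of 240 beats per minute and is far below any sinus-rhythm
#' RR interval.
#'
#' @param sg_window Savitzky-Golay window length in samples (odd,
#'   greater than `sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param search_window_s Sliding search window length, seconds.
#' @param rel_threshold Fraction of the within-window maximum derivative
#'   a sample must exceed to qualify as an R peak (0 < x < 1).
#' @param refractory_s Post-detection dead time, seconds.
#' @return An object of class `bd_params`.
#' @export
bd_params <- function(sg_window = 5, sg_polyorder = 2, search_window_s = 6,
                      rel_threshold = 0.7, refractory_s = 0.25) {
  stopifnot(rel_threshold > 0, rel_threshold < 1,
            sg_window %% 2 == 1, sg_window > sg_polyorder,
            search_window_s > 0, refractory_s > 0)
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 search_window_s = search_window_s,
                 rel_threshold = rel_threshold,
                 refractory_s = refractory_s),
            class = "bd_params")
}

new_binary_sequence <- function(bits, method, source = NULL) {
  structure(list(bits = as.integer(bits), method = method,
                 n = length(bits), source = source),
            class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  cat(sprintf("Binary sequence (%s): n = %d, ones = %d\n",
              x$method, x$n, sum(x$bits)))
  invisible(x)
}

#' Threshold-crossing binarization of an ECG strip
#'
#' Symbolizes the whole waveform against its median voltage: sample i
#' maps to 1 when `x[i] >= median(x)` and to 0 otherwise. The median is
#' used as threshold for its insensitivity to outliers; the resulting
#' string has the same length as the strip. Because the median is a
#' rank statistic, the output is invariant under any strictly
#' increasing transform of the voltages.
#'
#' @param strip An [ecg_strip()] with at least 2 samples.
#' @return A `binary_sequence` with `method = "TC"`. A constant strip
#'   yields an all-ones sequence with a warning (every sample equals,
#'   hence is >= , the threshold).
#' @export
tc_binarize <- function(strip) {
  stopifnot(inherits(strip, "ecg_strip"))
  x <- strip$samples
  if (length(x) < 2L) stop("tc_binarize: need at least 2 samples")
  td <- median(x)
  bits <- as.integer(x >= td)
  if (all(bits == 1L)) {
    warning("tc_binarize: constant signal, all samples >= threshold")
  }
  new_binary_sequence(bits, "TC",
                      source = list(patient_id = strip$patient_id,
                                    strip_index = strip$strip_index))
}

# central row of the Savitzky-Golay projection matrix = FIR smoothing
# coefficients for the window midpoint
sg_kernel <- function(window, polyorder) {
  sm <- signal::sgolay(p = polyorder, n = window, m = 0)
  as.numeric(sm[(window + 1L) %/% 2L, ])
}

#' Smoothed first derivative of an ECG strip
#'
#' Computes dV/dt by central differences (one-sided at the two ends) and
#' smooths it by convolution with a Savitzky-Golay filter. Ends are
#' mirror-padded before the convolution so the output has the same
#' length as the input with no phase shift. Units: µV per sample.
#'
#' @param strip An [ecg_strip()] at least `sg_window` samples long.
#' @param params A [bd_params()] object.
#' @return Numeric vector of smoothed derivative values, same length as
#'   `strip$samples`.
#' @export
smooth_derivative <- function(strip, params = bd_params()) {
  stopifnot(inherits(strip, "ecg_strip"), inherits(params, "bd_params"))
  x <- strip$samples
  n <- length(x)
  if (n < params$sg_window) {
    stop("smooth_derivative: strip shorter than the smoothing window")
  }
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w <- params$sg_window
  h <- (w - 1L) %/% 2L
  # mirror-pad, then convolve with the SG midpoint kernel
  dpad <- c(d[(h + 1L):2L], d, d[(n - 1L):(n - h)])
  k <- sg_kernel(w, params$sg_polyorder)
  sm <- stats::filter(dpad, rev(k), method = "convolution", sides = 2L)
  as.numeric(sm[(h + 1L):(h + n)])
}

#' Beat-detection binarization of an ECG strip
#'
#' Marks one sample per detected R wave with a 1 and all other samples
#' with 0. A sliding search window (default 6 s) moves along the
#' smoothed derivative; within the current window the maximum derivative
#' is found and the first sample that (i) exceeds `rel_threshold` times
#' that maximum and (ii) is a strict local maximum of the derivative is
#' taken as the R-peak time. After a detection the window restarts one
#' refractory period later; a window with no qualifying sample (or a
#' non-positive maximum derivative, e.g. a flat line) advances by half
#' its length. The final partial window is still scanned. The detector
#' is intended for sinus rhythm below 100 beats per minute.
#'
#' Because only the derivative is inspected, the output is invariant
#' under a uniform voltage offset.
#'
#' @param strip An [ecg_strip()].
#' @param params A [bd_params()] object.
#' @return A `binary_sequence` with `method = "BD"`; the number of ones
#'   equals the number of detected beats (attribute `beat_indices`
#'   stores their sample indices).
#' @export
bd_binarize <- function(strip, params = bd_params()) {
  stopifnot(inherits(strip, "ecg_strip"))
  d <- smooth_derivative(strip, params)
  n <- length(d)
  w <- max(2L, as.integer(round(params$search_window_s * strip$fs)))
  refr <- max(1L, as.integer(round(params$refractory_s * strip$fs)))
  bits <- integer(n)
  peaks <- integer(0)
  start <- 1L
  while (start <= n - 1L) {
    end <- min(start + w - 1L, n)
    win <- d[start:end]
    dmax <- max(win)
    p <- NA_integer_
    if (dmax > 0) {
      cand <- start + which(win > params$rel_threshold * dmax) - 1L
      cand <- cand[cand > 1L & cand < n]
      for (i in cand) {
        if (d[i] > d[i - 1L] && d[i] > d[i + 1L]) { p <- i; break }
      }
    }
    if (is.na(p)) {
      start <- start + max(1L, w %/% 2L)
    } else {
      bits[p] <- 1L
      peaks <- c(peaks, p)
      start <- p + refr
    }
  }
  out <- new_binary_sequence(bits, "BD",
                             source = list(patient_id = strip$patient_id,
                                           strip_index = strip$strip_index))
  attr(out, "beat_indices") <- peaks
  out
}
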
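#' Day-to-day variability of complexity scores
#'
#' The variability score of a patient's per-strip complexity values is
#' the sum of squared deviations from their mean,
#' varCS = sum((CS_i - mean(CS))^2). Note this is a raw second moment,
#' not divided by the number of strips, so it grows with strip count;
#' set `normalize = TRUE` to divide by (n - 1) when comparing patients
#' with very different strip counts.
#'
#' @param cs_values Numeric vector of per-strip CS values (>= 2 values).
#' @param normalize Divide by (n - 1)? Default `FALSE` (raw sum of
#'   squares).
#' @return Non-negative scalar; zero exactly when all values are equal.
#' @export
var_cs <- function(cs_values, normalize = FALSE) {
  cs_values <- as.numeric(cs_values)
  if (length(cs_values) < 2L) stop("var_cs: need at least 2 values")
  ss <- sum((cs_values - mean(cs_values))^2)
  if (normalize) ss / (length(cs_values) - 1L) else ss
}

#' Composite h-score
#'
#' Combines the two per-patient variability scores into a single
#' discriminant: h = sqrt(varCS_TC^2 + (k * varCS_BD)^2), the Euclidean
#' distance from the origin of the point (varCS_TC, k * varCS_BD). The
#' constant k rescales the beat-detection variability (numerically much
#' smaller) so the two axes carry comparable weight; it is the ratio of
#' the separating ellipse's axis intercepts (see [fit_ellipse()]), with
#' calibrated default 120.6.
#'
#' @param var_tc Threshold-crossing variability score (>= 0).
#' @param var_bd Beat-detection variability score (>= 0).
#' @param k Positive scaling constant.
#' @return Non-negative scalar h-score.
#' @examples
#' h_score(3.0e-3, 3.0e-5, k = 120.6)
#' @export
h_score <- function(var_tc, var_bd, k = 120.6) {
  if (any(var_tc < 0) || any(var_bd < 0)) stop("h_score: negative variability")
  if (any(k <= 0)) stop("h_score: k must be positive")
  sqrt(var_tc^2 + (k * var_bd)^2)
}

#' Score one patient from their ECG strips
#'
#' Computes per-strip CS_TC and CS_BD, their means, the day-to-day
#' variability scores varCS_TC and varCS_BD, and the composite h-score.
#' Strips failing [validate_strip()] are skipped with a message. Fewer
#' than 30 usable strips triggers a warning: below that count the
#' variability scores were found to lose discriminating power.
#'
#' @param strips List of [ecg_strip()] objects in recording order.
#' @param params [bd_params()] for the beat detector.
#' @param k Scaling constant for [h_score()].
#' @param normalize_var Passed to [var_cs()].
#' @param min_samples Per-strip sample minimum for validation; defaults
#'   to half the nominal strip length so mildly short recordings are
#'   kept.
#' @return An object of class `patient_scores`: list with `patient_id`,
#'   `cs_tc`, `cs_bd` (aligned per-strip vectors), `mean_cs_tc`,
#'   `mean_cs_bd`, `var_cs_tc`, `var_cs_bd`, `h`, `n_strips`,
#'   `skipped` (data.frame of skipped strips and reasons).
#' @export
score_patient <- function(strips, params = bd_params(), k = 120.6,
                          normalize_var = FALSE, min_samples = 1750) {
  stopifnot(is.list(strips), length(strips) >= 2L)
  keep <- logical(length(strips))
  reasons <- character(length(strips))
  for (i in seq_along(strips)) {
    iss <- validate_strip(strips[[i]], min_samples = min_samples)
    keep[i] <- length(iss) == 0L
    reasons[i] <- paste(iss, collapse = ";")
    if (!keep[i]) {
      message(sprintf("score_patient: skipping strip %d (%s)", i, reasons[i]))
    }
  }
  usable <- strips[keep]
  if (length(usable) < 2L) stop("score_patient: fewer than 2 usable strips")
  if (length(usable) < 30L) {
    warning(sprintf(
      "score_patient: only %d usable strips; variability scores are unstable below 30",
      length(usable)))
  }
  cs_tc <- vapply(usable, function(s) strip_cs(s, "TC")$cs, numeric(1))
  cs_bd <- vapply(usable, function(s) strip_cs(s, "BD", params)$cs, numeric(1))
  v_tc <- var_cs(cs_tc, normalize = normalize_var)
  v_bd <- var_cs(cs_bd, normalize = normalize_var)
  structure(list(
    patient_id = usable[[1L]]$patient_id,
    cs_tc = cs_tc, cs_bd = cs_bd,
    mean_cs_tc = mean(cs_tc), mean_cs_bd = mean(cs_bd),
    var_cs_tc = v_tc, var_cs_bd = v_bd,
    h = h_score(v_tc, v_bd, k = k),
    n_strips = length(usable),
    skipped = data.frame(index = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  ), class = "patient_scores")
}

#' @export
print.patient_scores <- function(x, ...) {
  cat(sprintf("Patient %s: %d strips\n", as.character(x$patient_id), x$n_strips))
  cat(sprintf("  mean CS_TC = %.4f, mean CS_BD = %.4f\n",
              x$mean_cs_tc, x$mean_cs_bd))
  cat(sprintf("  varCS_TC = %.3e, varCS_BD = %.3e, h = %.3e\n",
              x$var_cs_tc, x$var_cs_bd, x$h))
  invisible(x)
}

#' Score every patient of a cohort
#'
#' Applies [score_patient()] to each patient of an in-memory cohort (as
#' produced by [generate_cohort()]) or of a manifest read with
#' [read_manifest()], and assembles the per-patient summary table used
#' by calibration and evaluation.
#'
#' @param cohort Either a `synth_cohort` (list with `manifest` and
#'   `strips`) or a `cohort_manifest` data.frame with file paths.
#' @param params,k,normalize_var Passed to [score_patient()].
#' @param fs Sampling rate used when strips are read from files.
#' @param min_samples Passed to [score_patient()].
#' @return A `data.frame` with one row per patient: `patient_id`,
#'   `label`, `n_strips`, `mean_cs_tc`, `mean_cs_bd`, `var_cs_tc`,
#'   `var_cs_bd`, `h`, plus attribute `per_strip`: named list of
#'   `patient_scores` objects.
#' @export
score_cohort <- function(cohort, params = bd_params(), k = 120.6,
                         normalize_var = FALSE, fs = 125,
                         min_samples = 1750) {
  if (inherits(cohort, "synth_cohort")) {
    ids <- unique(cohort$manifest$patient_id)
    labels <- cohort$manifest$label[match(ids, cohort$manifest$patient_id)]
    strip_sets <- cohort$strips[ids]
  } else if (is.data.frame(cohort)) {
    ids <- unique(cohort$patient_id)
    labels <- cohort$label[match(ids, cohort$patient_id)]
    strip_sets <- lapply(ids, function(pid) {
      rows <- which(cohort$patient_id == pid)
      lapply(seq_along(rows), function(j) {
        read_strip(cohort$path[rows[j]], fs = fs, patient_id = pid,
                   strip_index = j)
      })
    })
    names(strip_sets) <- ids
  } else {
    stop("score_cohort: unsupported cohort object")
  }
  per <- vector("list", length(ids))
  names(per) <- ids
  for (i in seq_along(ids)) {
    per[[i]] <- score_patient(strip_sets[[i]], params = params, k = k,
                              normalize_var = normalize_var,
                              min_samples = min_samples)
  }
  out <- data.frame(
    patient_id = ids,
    label = labels,
    n_strips = vapply(per, function(p) p$n_strips, integer(1)),
    mean_cs_tc = vapply(per, function(p) p$mean_cs_tc, numeric(1)),
    mean_cs_bd = vapply(per, function(p) p$mean_cs_bd, numeric(1)),
    var_cs_tc = vapply(per, function(p) p$var_cs_tc, numeric(1)),
    var_cs_bd = vapply(per, function(p) p$var_cs_bd, numeric(1)),
    h = vapply(per, function(p) p$h, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "per_strip") <- per
  out
}
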
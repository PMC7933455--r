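#' Scaling constant from ellipse axis intercepts
#'
#' The separating quarter-ellipse in the (varCS_TC, varCS_BD) plane has
#' axis intercepts a (on the TC axis) and b (on the BD axis); the
#' constant k = a/b rescales the BD axis so the ellipse becomes a circle
#' of radius a and the two variability measures are equally weighted.
#'
#' @param a TC-axis intercept (> 0).
#' @param b BD-axis intercept (> 0).
#' @return k = a / b.
#' @examples
#' k_from_intercepts(4.546e-3, 3.77e-5)  # about 120.6
#' @export
k_from_intercepts <- function(a, b) {
  if (any(a <= 0)) stop("k_from_intercepts: a must be positive")
  if (any(b <= 0)) stop("k_from_intercepts: b must be positive")
  a / b
}

#' Fit the separating ellipse on per-patient variability scores
#'
#' Searches axis-aligned, origin-centered quarter-ellipses
#' (x/a)^2 + (y/b)^2 = 1 over a log-spaced grid of intercepts (a, b),
#' classifying points inside the ellipse as controls and outside as
#' cases, and returns the ellipse maximizing balanced accuracy (mean of
#' sensitivity and specificity). Ties are broken by the largest
#' worst-class radial margin, then by the smallest ellipse area. The
#' scaling constant k = a/b maps the fitted ellipse onto a circle of
#' radius a in the transformed plane (x, k*y), so the decision rule on
#' the composite score is simply h > a.
#'
#' @param var_tc,var_bd Per-patient variability scores (equal length,
#'   non-negative).
#' @param labels Character vector, `"control"` or `"case"`, aligned with
#'   the scores; at least two points per class.
#' @param grid_n Grid resolution per axis (default 200).
#' @return An object of class `calibration_model`: list with intercepts
#'   `a`, `b`, `k = a/b`, `radius = a`, `h_threshold = a`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`, and the grid
#'   ranges used.
#' @export
fit_ellipse <- function(var_tc, var_bd, labels, grid_n = 200) {
  x <- as.numeric(var_tc); y <- as.numeric(var_bd)
  stopifnot(length(x) == length(y), length(labels) == length(x))
  if (any(x < 0) || any(y < 0)) stop("fit_ellipse: negative coordinates")
  is_case <- labels == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("fit_ellipse: need at least 2 points per class")
  }
  if (max(x) == min(x) && max(y) == min(y)) {
    stop("fit_ellipse: degenerate geometry, all points identical")
  }
  log_grid <- function(v, n) {
    if (!any(v > 0)) stop("fit_ellipse: an axis has no positive values")
    hi <- max(v) * 1.05
    lo <- max(min(v[v > 0]) * 0.95, hi * 1e-4)
    exp(seq(log(lo), log(hi), length.out = n))
  }
  agrid <- log_grid(x, grid_n)
  bgrid <- log_grid(y, grid_n)
  best <- list(bal = -Inf, margin = -Inf, area = Inf, a = NA, b = NA,
               sens = NA, spec = NA)
  for (a in agrid) {
    xa2 <- (x / a)^2
    for (b in bgrid) {
      r <- sqrt(xa2 + (y / b)^2)
      pred_case <- r > 1
      sens <- mean(pred_case[is_case])
      spec <- mean(!pred_case[!is_case])
      bal <- (sens + spec) / 2
      if (bal < best$bal) next
      margin <- min(min(r[is_case]) - 1, 1 - max(r[!is_case]))
      area <- a * b
      if (bal > best$bal ||
          (margin > best$margin + 1e-12) ||
          (abs(margin - best$margin) <= 1e-12 && area < best$area)) {
        best <- list(bal = bal, margin = margin, area = area,
                     a = a, b = b, sens = sens, spec = spec)
      }
    }
  }
  structure(list(a = best$a, b = best$b, k = best$a / best$b,
                 radius = best$a, h_threshold = best$a,
                 balanced_accuracy = best$bal,
                 sensitivity = best$sens, specificity = best$spec,
                 grid_n = grid_n,
                 a_range = range(agrid), b_range = range(bgrid)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Separating-ellipse calibration\n")
  cat(sprintf("  intercepts: a = %.4e (varCS_TC), b = %.4e (varCS_BD)\n",
              x$a, x$b))
  cat(sprintf("  k = a/b = %.1f, circle radius = %.4e, h* = %.4e\n",
              x$k, x$radius, x$h_threshold))
  cat(sprintf("  training balanced accuracy = %.3f (sens %.2f, spec %.2f)\n",
              x$balanced_accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify h-scores against a decision threshold
#'
#' A patient is called a case when their h-score strictly exceeds the
#' threshold; a score exactly on the boundary is assigned to the
#' control class (fixed convention for determinism).
#'
#' @param h Numeric h-score(s), non-negative.
#' @param h_threshold Positive decision threshold (default 4.5e-3, the
#'   calibrated operating value).
#' @return Character vector `"case"`/`"control"`.
#' @export
classify <- function(h, h_threshold = 4.5e-3) {
  if (any(h < 0)) stop("classify: negative h-score")
  if (h_threshold <= 0) stop("classify: threshold must be positive")
  ifelse(h > h_threshold, "case", "control")
}
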
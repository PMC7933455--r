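#' Mann-Whitney U test between two cohorts
#'
#' Computes the Mann-Whitney U statistic from rank sums (tie-safe) and a
#' two-sided p-value: by exact permutation enumeration of U over all
#' group assignments when the combined sample size is at most
#' `exact_max` (default 12), otherwise by the tie-corrected normal
#' approximation with continuity correction (via [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric score vectors (each non-empty).
#' @param exact_max Largest combined n for which the exact enumeration
#'   is used.
#' @return List with `U` (the statistic for `group_a`, i.e. the number
#'   of (a, b) pairs with a > b, ties counting one half), `p`
#'   (two-sided), and `method`.
#' @export
rank_test <- function(group_a, group_b, exact_max = 12) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("rank_test: empty group")
  na <- length(a); nb <- length(b)
  u_stat <- function(xa, xb) {
    r <- rank(c(xa, xb))
    sum(r[seq_along(xa)]) - length(xa) * (length(xa) + 1) / 2
  }
  U <- u_stat(a, b)
  n <- na + nb
  if (n <= exact_max) {
    pooled <- c(a, b)
    idx <- utils::combn(n, na)
    us <- apply(idx, 2L, function(ii) u_stat(pooled[ii], pooled[-ii]))
    mu <- na * nb / 2
    # two-sided: permutations at least as far from the null mean
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact permutation")
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(U = U, p = wt$p.value, method = "normal approximation")
  }
}

#' Empirical ROC curve with AUC, confidence interval and operating point
#'
#' Builds the empirical ROC over all distinct score thresholds (a
#' subject is called a case when their score strictly exceeds the
#' threshold), computes the area under the curve by the trapezoid rule
#' (equivalently the tie-adjusted pairwise concordance probability: tied
#' case/control pairs count one half), a 95% confidence interval by the
#' Hanley-McNeil formula, and the operating point maximizing the Youden
#' index J = sensitivity + specificity - 1, the discrete analogue of the
#' point where a 45-degree line is tangent to the curve. Operating-point
#' ties are broken toward higher specificity.
#'
#' @param scores Numeric vector; higher values are more case-like.
#' @param labels Character vector `"control"`/`"case"` aligned with
#'   `scores`; both classes must be present.
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `pafc_roc`: list with `points`
#'   (data.frame `threshold`, `fpr`, `tpr`), `auc`, `ci` (length-2),
#'   `op` (list `threshold`, `sensitivity`, `specificity`, `youden`),
#'   `n_cases`, `n_controls`.
#' @export
roc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) stop("roc: need both classes")
  s1 <- scores[is_case]; s0 <- scores[!is_case]
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(s1 > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s0 > t), numeric(1))
  # left endpoint: threshold below all scores classifies everyone a case
  pts <- data.frame(threshold = c(-Inf, thr), fpr = c(1, fpr),
                    tpr = c(1, tpr))
  ord <- order(pts$fpr, pts$tpr)
  xs <- pts$fpr[ord]; ys <- pts$tpr[ord]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  na <- length(s1); nn <- length(s0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (na - 1) * (q1 - auc^2) +
                (nn - 1) * (q2 - auc^2)) / (na * nn))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  j <- pts$tpr - pts$fpr
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  op_i <- cand[which.min(pts$fpr[cand])]  # ties -> higher specificity
  op <- list(threshold = pts$threshold[op_i],
             sensitivity = pts$tpr[op_i],
             specificity = 1 - pts$fpr[op_i],
             youden = j[op_i])
  structure(list(points = pts, auc = auc, ci = ci, se = se, op = op,
                 n_cases = na, n_controls = nn),
            class = "pafc_roc")
}

#' @export
print.pafc_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d cases vs %d controls\n",
              x$n_cases, x$n_controls))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci[1], x$ci[2]))
  cat(sprintf("  operating point: threshold %.4g, sensitivity %.2f, specificity %.2f\n",
              x$op$threshold, x$op$sensitivity, x$op$specificity))
  invisible(x)
}

# DeLong placement values: for each case, the fraction of controls it
# beats (ties half); and symmetrically for controls
delong_placements <- function(s1, s0) {
  v10 <- vapply(s1, function(x) mean((x > s0) + 0.5 * (x == s0)), numeric(1))
  v01 <- vapply(s0, function(y) mean((s1 > y) + 0.5 * (s1 == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Tests whether two scores measured on the same subjects have equal
#' AUC, using DeLong's asymptotic normal test on the difference of the
#' placement-value means. When the two scores induce identical
#' placements (e.g. one is a monotone transform of the other) the
#' difference has zero variance and the p-value is 1.
#'
#' @param scores_1,scores_2 Two score vectors on the same subjects.
#' @param labels `"control"`/`"case"` labels aligned with the scores.
#' @return List with `auc_1`, `auc_2`, `z`, `p` (two-sided).
#' @export
compare_auc <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels)) {
    stop("compare_auc: length mismatch")
  }
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) stop("compare_auc: need both classes")
  p1 <- delong_placements(scores_1[is_case], scores_1[!is_case])
  p2 <- delong_placements(scores_2[is_case], scores_2[!is_case])
  na <- sum(is_case); nn <- sum(!is_case)
  d10 <- p1$v10 - p2$v10
  d01 <- p1$v01 - p2$v01
  v <- var(d10) / na + var(d01) / nn
  dauc <- p1$auc - p2$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(dauc) <= .Machine$double.eps) 1 else 0
    z <- if (abs(dauc) <= .Machine$double.eps) 0 else Inf
  } else {
    z <- dauc / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_1 = p1$auc, auc_2 = p2$auc, z = z, p = p)
}

#' Discrimination as a function of the number of strips used
#'
#' For each m in `m_range`, averages the first m per-strip CS values of
#' every patient (recording order) and rank-tests the cohort difference
#' of those means, tracing how the between-cohort p-value degrades as
#' fewer recordings are used.
#'
#' @param cs_lists Named list: one numeric vector of per-strip CS values
#'   per patient, in recording order.
#' @param labels `"control"`/`"case"` per patient, aligned with
#'   `cs_lists`.
#' @param m_range Integer vector of strip counts to evaluate.
#' @return `data.frame` with columns `m` and `p`.
#' @export
strips_needed_curve <- function(cs_lists, labels, m_range) {
  stopifnot(length(cs_lists) == length(labels))
  m_range <- sort(unique(as.integer(m_range)))
  nlen <- vapply(cs_lists, length, integer(1))
  short <- which(nlen < max(m_range))
  if (length(short) > 0L) {
    nm <- names(cs_lists)[short[1L]]
    if (is.null(nm)) nm <- as.character(short[1L])
    stop(sprintf("strips_needed_curve: patient %s has %d < %d strips",
                 nm, nlen[short[1L]], max(m_range)))
  }
  p <- vapply(m_range, function(m) {
    means <- vapply(cs_lists, function(v) mean(v[seq_len(m)]), numeric(1))
    rank_test(means[labels == "case"], means[labels == "control"])$p
  }, numeric(1))
  data.frame(m = m_range, p = p)
}

#' Within-patient independence of the two variability signals
#'
#' Spearman rank correlation between a patient's per-strip squared
#' deviations (CS_TC_i - mean)^2 and (CS_BD_i - mean)^2 — the per-strip
#' contributions to varCS_TC and varCS_BD. Independence of the two
#' justifies combining them as orthogonal axes of the h-score. Set
#' `raw = TRUE` to correlate the raw per-strip (CS_TC, CS_BD) pairs
#' instead.
#'
#' @param patient A `patient_scores` object (>= 5 strips).
#' @param raw Correlate raw CS series instead of squared deviations.
#' @return List with `rho`, `p`, `n`; `rho` is `NA` (with `p = NA`) when
#'   either series is constant.
#' @export
independence_check <- function(patient, raw = FALSE) {
  stopifnot(inherits(patient, "patient_scores"))
  if (length(patient$cs_tc) < 5L) stop("independence_check: need >= 5 strips")
  if (raw) {
    xa <- patient$cs_tc; xb <- patient$cs_bd
  } else {
    xa <- (patient$cs_tc - patient$mean_cs_tc)^2
    xb <- (patient$cs_bd - patient$mean_cs_bd)^2
  }
  if (length(unique(xa)) == 1L || length(unique(xb)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(xa),
                note = "constant series, correlation undefined"))
  }
  ct <- suppressWarnings(cor.test(xa, xb, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(xa))
}

#' Sensitivity/specificity under decision-threshold perturbation
#'
#' Recomputes the operating characteristics when the h-score threshold
#' is shifted by the given fractional deltas, quantifying how robust the
#' classification is to small miscalibrations of the decision boundary.
#'
#' @param h_scores Per-patient h-scores.
#' @param labels `"control"`/`"case"` per patient.
#' @param base_threshold Unperturbed threshold (default 4.5e-3).
#' @param deltas Fractional shifts, e.g. `c(-0.10, -0.05, 0, 0.05, 0.10)`.
#' @return An object of class `perturbation_report`: `data.frame` with
#'   columns `delta`, `threshold`, `sensitivity`, `specificity`.
#' @export
perturb_threshold <- function(h_scores, labels, base_threshold = 4.5e-3,
                              deltas = c(-0.10, -0.05, 0, 0.05, 0.10)) {
  stopifnot(length(h_scores) == length(labels))
  is_case <- labels == "case"
  rows <- lapply(deltas, function(d) {
    thr <- base_threshold * (1 + d)
    pred <- classify(h_scores, thr)
    data.frame(delta = d, threshold = thr,
               sensitivity = mean(pred[is_case] == "case"),
               specificity = mean(pred[!is_case] == "control"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("perturbation_report", "data.frame")
  out
}

#' Robustness of CS_TC to additive noise
#'
#' Adds i.i.d. Gaussian noise of each given standard deviation to every
#' strip, recomputes the threshold-crossing complexity score, and
#' reports the mean absolute percent change relative to the clean score
#' together with the corresponding signal-to-noise ratio. Signal power
#' is the variance of the strip about its mean, so
#' SNR_dB = 10 log10(signal power / sd^2).
#'
#' @param strips List of [ecg_strip()] objects.
#' @param noise_sds Noise standard deviations to test, µV (> 0).
#' @param reps Noise realizations per (strip, sd) pair.
#' @param seed Integer seed for the noise generator.
#' @return `data.frame` with columns `sd`, `snr_db` (using the mean
#'   signal power over strips) and `mean_pct_change`.
#' @export
noise_robustness <- function(strips, noise_sds, reps = 20, seed = 1) {
  stopifnot(all(noise_sds > 0), reps >= 1)
  set.seed(seed)
  clean_cs <- vapply(strips, function(s) strip_cs(s, "TC")$cs, numeric(1))
  powers <- vapply(strips, function(s) mean((s$samples - mean(s$samples))^2),
                   numeric(1))
  rows <- lapply(noise_sds, function(sd) {
    pct <- numeric(0)
    for (i in seq_along(strips)) {
      s <- strips[[i]]
      for (r in seq_len(reps)) {
        noisy <- ecg_strip(s$samples + rnorm(length(s$samples), 0, sd),
                           fs = s$fs, patient_id = s$patient_id,
                           strip_index = s$strip_index)
        cs <- strip_cs(noisy, "TC")$cs
        pct <- c(pct, 100 * abs(cs - clean_cs[i]) / clean_cs[i])
      }
    }
    data.frame(sd = sd, snr_db = 10 * log10(mean(powers) / sd^2),
               mean_pct_change = mean(pct))
  })
  do.call(rbind, rows)
}
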
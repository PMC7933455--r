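#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline with its calibrated
#' default: scaling constant k = 120.6, decision threshold 4.5e-3, a
#' 30-strip minimum per patient, and the standard beat-detector
#' parameters (5-sample Savitzky-Golay window, 6-s search window, 0.7
#' relative derivative threshold).
#'
#' @param manifest Path to a cohort manifest CSV (or `NULL` when the
#'   cohort object is passed to [run_pipeline()] directly).
#' @param out_dir Directory for pipeline outputs.
#' @param k Scaling constant; ignored when `k_source = "calibrate"`.
#' @param k_source `"fixed"` (use `k`) or `"calibrate"` (fit the
#'   separating ellipse on this cohort and derive k and the threshold
#'   from it).
#' @param h_threshold Decision threshold on the h-score (used when
#'   `k_source = "fixed"`).
#' @param min_strips Minimum strips per patient.
#' @param normalize_var Divide varCS by (n - 1)? See [var_cs()].
#' @param bd [bd_params()] for the beat detector.
#' @param fs Sampling rate of on-disk strips, Hz.
#' @param seed Seed for any stochastic evaluation step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = NULL, k = 120.6,
                       k_source = c("fixed", "calibrate"),
                       h_threshold = 4.5e-3, min_strips = 30,
                       normalize_var = FALSE, bd = bd_params(),
                       fs = 125, seed = 1L) {
  k_source <- match.arg(k_source)
  stopifnot(k > 0, h_threshold > 0, min_strips >= 1)
  structure(list(manifest = manifest, out_dir = out_dir, k = k,
                 k_source = k_source, h_threshold = h_threshold,
                 min_strips = min_strips, normalize_var = normalize_var,
                 bd = bd, fs = fs, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full screening pipeline
#'
#' Validates and filters the cohort, computes per-strip complexity
#' scores and per-patient variability and h-scores, optionally fits the
#' separating-ellipse calibration, classifies every patient, and
#' produces the cohort-level evaluation (rank tests, ROC curves with
#' AUC confidence intervals, operating point, threshold perturbation).
#' When `config$out_dir` is set, writes `scores.csv`, `model.yaml` and
#' `report.json` there.
#'
#' @param config A [run_config()].
#' @param cohort Optional in-memory cohort (`synth_cohort` or manifest
#'   data.frame); when omitted, `config$manifest` is read from disk.
#' @return An object of class `pafc_report`: list with `scores`
#'   (per-patient data.frame incl. predicted class), `model`
#'   (`calibration_model` or the fixed constants), `evaluation` (rank
#'   tests, ROC per score column, perturbation report), `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(config$manifest)) stop("run_pipeline: no manifest or cohort")
    cohort <- read_manifest(config$manifest)
  }
  if (is.data.frame(cohort)) {
    cohort <- filter_patients(cohort, min_strips = config$min_strips)
    if (nrow(cohort) == 0L) stop("run_pipeline: no patients after filtering")
  }
  scores <- score_cohort(cohort, params = config$bd, k = config$k,
                         normalize_var = config$normalize_var,
                         fs = config$fs)
  if (config$k_source == "calibrate") {
    model <- fit_ellipse(scores$var_cs_tc, scores$var_cs_bd, scores$label)
    k <- model$k
    thr <- model$h_threshold
    scores$h <- h_score(scores$var_cs_tc, scores$var_cs_bd, k = k)
  } else {
    k <- config$k
    thr <- config$h_threshold
    model <- list(k = k, h_threshold = thr, source = "fixed")
  }
  scores$predicted <- classify(scores$h, thr)

  both <- length(unique(scores$label)) == 2L
  evaluation <- list()
  if (both) {
    cs_case <- scores$label == "case"
    evaluation$rank_tests <- lapply(
      c(mean_cs_tc = "mean_cs_tc", mean_cs_bd = "mean_cs_bd",
        var_cs_tc = "var_cs_tc", var_cs_bd = "var_cs_bd", h = "h"),
      function(col) rank_test(scores[[col]][cs_case], scores[[col]][!cs_case]))
    evaluation$roc <- lapply(
      c(mean_cs_tc = "mean_cs_tc", var_cs_tc = "var_cs_tc",
        var_cs_bd = "var_cs_bd", h = "h"),
      function(col) roc(scores[[col]], scores$label))
    evaluation$auc_h_vs_var_tc <-
      compare_auc(scores$h, scores$var_cs_tc, scores$label)
    evaluation$auc_h_vs_var_bd <-
      compare_auc(scores$h, scores$var_cs_bd, scores$label)
    evaluation$perturbation <-
      perturb_threshold(scores$h, scores$label, base_threshold = thr)
    evaluation$sensitivity <-
      mean(scores$predicted[cs_case] == "case")
    evaluation$specificity <-
      mean(scores$predicted[!cs_case] == "control")
  }
  report <- structure(list(scores = scores, model = model,
                           evaluation = evaluation, config = config,
                           schema_version = "1.0"),
                      class = "pafc_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pafc_report <- function(x, ...) {
  cat(sprintf("PAF complexity screening report (%d patients)\n",
              nrow(x$scores)))
  cat(sprintf("  k = %.1f, h* = %.4g\n", x$model$k, x$model$h_threshold))
  if (length(x$evaluation) > 0L) {
    cat(sprintf("  h-score AUC = %.3f; sensitivity %.2f, specificity %.2f at h*\n",
                x$evaluation$roc$h$auc, x$evaluation$sensitivity,
                x$evaluation$specificity))
  }
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits `scores.csv` (per-patient table), `model.yaml` (calibration
#' constants) and `report.json` (evaluation summary, schema-versioned).
#'
#' @param report A `pafc_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pafc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  model <- report$model
  yaml::write_yaml(
    lapply(model[!vapply(model, is.function, logical(1))], unclass),
    file.path(dir, "model.yaml"))
  ev <- report$evaluation
  js <- list(schema_version = report$schema_version,
             n_patients = nrow(report$scores),
             k = model$k, h_threshold = model$h_threshold)
  if (length(ev) > 0L) {
    js$rank_tests <- lapply(ev$rank_tests, function(r) r[c("U", "p")])
    js$auc <- lapply(ev$roc, function(r)
      list(auc = r$auc, ci = r$ci,
           op = r$op[c("threshold", "sensitivity", "specificity")]))
    js$auc_h_vs_var_tc_p <- ev$auc_h_vs_var_tc$p
    js$auc_h_vs_var_bd_p <- ev$auc_h_vs_var_bd$p
    js$sensitivity <- ev$sensitivity
    js$specificity <- ev$specificity
    js$perturbation <- as.data.frame(unclass(ev$perturbation))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
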
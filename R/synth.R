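#' Gaussian-bump beat template
#'
#' Parameterizes one cardiac cycle as the sum of five Gaussian bumps
#' (P, Q, R, S, T), each with a center offset relative to the R peak
#' (seconds), a width (Gaussian SD, seconds) and an amplitude (µV).
#' Defaults are typical adult single-lead values: a dominant ~1.1 mV R
#' wave, narrow opposing Q and S deflections, and broader low-amplitude
#' P and T waves.
#'
#' @param centers,widths,amps Named numeric vectors over
#'   `c("P","Q","R","S","T")`.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(
    centers = c(P = -0.22, Q = -0.035, R = 0, S = 0.035, T = 0.27),
    widths = c(P = 0.035, Q = 0.010, R = 0.015, S = 0.010, T = 0.065),
    amps = c(P = 110, Q = -120, R = 1100, S = -250, T = 280)) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(centers), waves), setequal(names(widths), waves),
            setequal(names(amps), waves), all(widths > 0))
  if (abs(amps[["R"]]) <= max(abs(amps[setdiff(waves, "R")]))) {
    stop("beat_template: R amplitude must dominate")
  }
  if (is.unsorted(centers[waves])) {
    stop("beat_template: wave centers must be ordered P < Q < R < S < T")
  }
  structure(list(centers = centers[waves], widths = widths[waves],
                 amps = amps[waves]),
            class = "beat_template")
}

#' Per-patient parameters for the synthetic cohort generator
#'
#' Describes one simulated participant. The generator reproduces the
#' structure of the source protocol — 28-s strips at 125 Hz recorded
#' twice daily, resting heart rates between 59 and 91 per minute, and
#' recording signal-to-noise ratios of 15-20 dB — and injects the
#' cohort difference through *day-to-day* (between-strip) variation:
#' each strip draws its own mean heart rate and its own morphology
#' scale, with larger spreads for cases.
#'
#' @param patient_id Identifier.
#' @param label `"control"` or `"case"`.
#' @param base_hr Patient's long-run mean heart rate, min^-1, in
#'   \[59, 91\].
#' @param hr_day_sd SD of the per-strip mean heart rate, min^-1.
#' @param rr_jitter_sd Typical beat-to-beat RR-interval SD within a
#'   strip, s.
#' @param rr_jitter_day_sd Day-to-day SD of the per-strip RR-jitter
#'   level, s: each strip draws its own beat-to-beat jitter SD from
#'   Normal(rr_jitter_sd, rr_jitter_day_sd), so patients whose
#'   short-term heart-rate variability fluctuates between recordings
#'   acquire larger day-to-day spread of the beat-detection complexity
#'   score.
#' @param morph_day_sd SD of the per-strip morphology scale (fractional;
#'   amplitudes and widths of all waves are multiplied by one
#'   Normal(1, morph_day_sd) draw per strip).
#' @param snr_db Target additive-noise SNR in dB (`Inf` = noise-free).
#' @param n_strips Number of strips to simulate.
#' @param template A [beat_template()].
#' @return An object of class `synth_patient_params`.
#' @export
synth_patient_params <- function(patient_id, label = c("control", "case"),
                                 base_hr = 74, hr_day_sd = 1.5,
                                 rr_jitter_sd = 0.010,
                                 rr_jitter_day_sd = 0.002,
                                 morph_day_sd = 0.02,
                                 snr_db = 17.5, n_strips = 35,
                                 template = beat_template()) {
  label <- match.arg(label)
  stopifnot(base_hr >= 59, base_hr <= 91, hr_day_sd >= 0,
            rr_jitter_sd >= 0, rr_jitter_day_sd >= 0,
            morph_day_sd >= 0, n_strips >= 1)
  structure(list(patient_id = as.character(patient_id), label = label,
                 base_hr = base_hr, hr_day_sd = hr_day_sd,
                 rr_jitter_sd = rr_jitter_sd,
                 rr_jitter_day_sd = rr_jitter_day_sd,
                 morph_day_sd = morph_day_sd,
                 snr_db = snr_db, n_strips = as.integer(n_strips),
                 template = template),
            class = "synth_patient_params")
}

# deterministic substream seed below 2^31, derived from a root seed and
# patient/strip indices so a strip can be regenerated in isolation
derive_seed <- function(root, patient_idx, strip_idx = 0L) {
  s <- (abs(as.numeric(root)) %% 100000) * 20011 +
    patient_idx * 7919 + strip_idx * 104729
  as.integer(s %% 2147483647)
}

truncated_normal <- function(n, mean, sd, lo = -Inf, hi = Inf, cap = 100L) {
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("truncated_normal: degenerate mean outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in seq_len(cap)) {
      v <- rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
      v <- NA_real_
    }
    if (is.na(v)) stop("truncated_normal: rejection cap exceeded")
    out[i] <- v
  }
  out
}

#' Generate one synthetic ECG strip
#'
#' Simulates a 28-s single-lead strip at 125 Hz: the strip's mean heart
#' rate is drawn from Normal(base_hr, hr_day_sd) truncated to
#' \[50, 99\] min^-1; RR intervals from Normal(60/HR, rr_jitter_sd)
#' truncated to at least 0.33 s; one morphology scale from
#' Normal(1, morph_day_sd) (truncated positive) multiplies the template
#' amplitudes and widths; and white Gaussian noise is added with its SD
#' chosen so the realized signal power meets the requested SNR.
#'
#' @param params A [synth_patient_params()].
#' @param strip_index Ordinal index of the strip.
#' @param seed Integer seed for this strip's substream.
#' @param fs Sampling rate, Hz.
#' @param duration_s Strip duration, seconds.
#' @return List with `strip` (an [ecg_strip()]) and `r_indices`
#'   (ground-truth R-peak sample indices, 1-based).
#' @export
generate_strip <- function(params, strip_index = 1L, seed = 1L,
                           fs = 125, duration_s = 28) {
  stopifnot(inherits(params, "synth_patient_params"))
  set.seed(as.integer(abs(seed) %% 2147483647))
  n <- round(fs * duration_s)
  tt <- (seq_len(n) - 1) / fs
  hr <- truncated_normal(1, params$base_hr, params$hr_day_sd, 50, 99)
  jitter <- truncated_normal(1, params$rr_jitter_sd,
                             params$rr_jitter_day_sd, lo = 0)
  scale <- truncated_normal(1, 1, params$morph_day_sd, lo = 0.05)
  tpl <- params$template
  amps <- tpl$amps * scale
  widths <- tpl$widths * scale
  # beat times: first R peak shortly after the start, then jittered RRs
  r_times <- 0.4
  repeat {
    rr <- truncated_normal(1, 60 / hr, jitter, lo = 0.33)
    nxt <- r_times[length(r_times)] + rr
    if (nxt > duration_s + 0.4) break
    r_times <- c(r_times, nxt)
  }
  x <- numeric(n)
  for (tr in r_times) {
    for (wv in seq_along(amps)) {
      ctr <- tr + tpl$centers[wv]
      lo <- max(1L, floor((ctr - 5 * widths[wv]) * fs))
      hi <- min(n, ceiling((ctr + 5 * widths[wv]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        amps[wv] * exp(-((tt[idx] - ctr)^2) / (2 * widths[wv]^2))
    }
  }
  if (is.finite(params$snr_db)) {
    p_sig <- mean((x - mean(x))^2)
    noise_sd <- sqrt(p_sig / 10^(params$snr_db / 10))
    x <- x + rnorm(n, 0, noise_sd)
  }
  r_idx <- round(r_times * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  list(strip = ecg_strip(x, fs = fs, patient_id = params$patient_id,
                         strip_index = strip_index,
                         duration_s = duration_s),
       r_indices = r_idx)
}

#' Cohort preset distributions
#'
#' Hyper-distributions from which per-patient generator parameters are
#' drawn. The `"paper-like"` preset mirrors the study conditions the
#' package targets: resting heart rates centered near 74 min^-1 within
#' \[59, 91\], recording SNR uniform on 15-20 dB, and a roughly twofold
#' case/control ratio in the day-to-day spreads of heart rate and
#' morphology — the mechanism by which cases acquire larger varCS
#' scores. The `"null"` preset gives both cohorts the control
#' distributions (no true difference).
#'
#' @param name `"paper-like"` or `"null"`.
#' @return An object of class `cohort_preset`: per-label lists of
#'   hyper-parameters.
#' @export
cohort_preset <- function(name = c("paper-like", "null")) {
  name <- match.arg(name)
  control <- list(base_hr_mean = 74, base_hr_sd = 8,
                  hr_day_sd_mean = 1.5, hr_day_sd_sd = 0.5,
                  rr_jitter_sd_mean = 0.010, rr_jitter_sd_sd = 0.003,
                  rr_jitter_day_sd_mean = 0.002, rr_jitter_day_sd_sd = 0.001,
                  morph_day_sd_mean = 0.02, morph_day_sd_sd = 0.007,
                  snr_db_range = c(15, 20))
  case <- control
  if (name == "paper-like") {
    case$base_hr_mean <- 73
    case$hr_day_sd_mean <- 3.5; case$hr_day_sd_sd <- 1.0
    case$rr_jitter_day_sd_mean <- 0.006; case$rr_jitter_day_sd_sd <- 0.002
    case$morph_day_sd_mean <- 0.05; case$morph_day_sd_sd <- 0.015
  }
  structure(list(name = name, control = control, case = case),
            class = "cohort_preset")
}

draw_patient_params <- function(pid, label, hyper, n_strips) {
  synth_patient_params(
    patient_id = pid, label = label,
    base_hr = truncated_normal(1, hyper$base_hr_mean, hyper$base_hr_sd,
                               59, 91),
    hr_day_sd = truncated_normal(1, hyper$hr_day_sd_mean,
                                 hyper$hr_day_sd_sd, lo = 0.2),
    rr_jitter_sd = truncated_normal(1, hyper$rr_jitter_sd_mean,
                                    hyper$rr_jitter_sd_sd, lo = 0.003),
    rr_jitter_day_sd = truncated_normal(1, hyper$rr_jitter_day_sd_mean,
                                        hyper$rr_jitter_day_sd_sd,
                                        lo = 0.0002),
    morph_day_sd = truncated_normal(1, hyper$morph_day_sd_mean,
                                    hyper$morph_day_sd_sd, lo = 0.004),
    snr_db = runif(1, hyper$snr_db_range[1], hyper$snr_db_range[2]),
    n_strips = n_strips
  )
}

#' Generate a full synthetic cohort
#'
#' Samples per-patient generator parameters from the preset's
#' hyper-distributions (cases draw larger day-to-day spreads under the
#' `"paper-like"` preset), then generates every strip from a
#' deterministic per-strip substream of the root seed, so identical
#' seeds give identical cohorts and any strip can be regenerated alone.
#'
#' @param n_controls,n_cases Cohort sizes (default 24 and 28).
#' @param strips_per_patient Strips per participant (default 35).
#' @param preset A [cohort_preset()] or preset name.
#' @param seed Root integer seed.
#' @return An object of class `synth_cohort`: list with `manifest`
#'   (data.frame `patient_id`, `label`, `strip_index`), `strips` (named
#'   list: per patient, list of [ecg_strip()]), `truth` (per-patient
#'   parameters and ground-truth R indices).
#' @export
generate_cohort <- function(n_controls = 24, n_cases = 28,
                            strips_per_patient = 35,
                            preset = cohort_preset("paper-like"),
                            seed = 1L) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"),
            n_controls >= 1, n_cases >= 1, strips_per_patient >= 1)
  labels <- c(rep("control", n_controls), rep("case", n_cases))
  ids <- sprintf("%s%02d", ifelse(labels == "control", "C", "P"),
                 c(seq_len(n_controls), seq_len(n_cases)))
  strips <- vector("list", length(ids)); names(strips) <- ids
  truth <- vector("list", length(ids)); names(truth) <- ids
  manifest <- data.frame(patient_id = character(0), label = character(0),
                         strip_index = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    set.seed(derive_seed(seed, i))
    pp <- draw_patient_params(ids[i], labels[i],
                              preset[[labels[i]]], strips_per_patient)
    slist <- vector("list", strips_per_patient)
    ridx <- vector("list", strips_per_patient)
    for (j in seq_len(strips_per_patient)) {
      g <- generate_strip(pp, strip_index = j,
                          seed = derive_seed(seed, i, j))
      slist[[j]] <- g$strip
      ridx[[j]] <- g$r_indices
    }
    strips[[i]] <- slist
    truth[[i]] <- list(params = pp, r_indices = ridx)
    manifest <- rbind(manifest, data.frame(
      patient_id = ids[i], label = labels[i],
      strip_index = seq_len(strips_per_patient), stringsAsFactors = FALSE))
  }
  structure(list(manifest = manifest, strips = strips, truth = truth,
                 preset = preset$name, seed = seed),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  tab <- table(x$manifest$label[!duplicated(x$manifest$patient_id)])
  cat(sprintf("Synthetic ECG cohort ('%s' preset, seed %d): %d controls, %d cases, %d strips/patient\n",
              x$preset, x$seed, tab[["control"]], tab[["case"]],
              max(x$manifest$strip_index)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one single-column CSV per strip plus a cohort manifest CSV
#' (columns `patient_id`, `label`, `path`) referencing them, the on-disk
#' layout consumed by [read_manifest()] and [score_cohort()].
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pid in names(cohort$strips)) {
    lab <- cohort$manifest$label[match(pid, cohort$manifest$patient_id)]
    for (j in seq_along(cohort$strips[[pid]])) {
      fn <- sprintf("%s_strip%03d.csv", pid, j)
      write_strip(cohort$strips[[pid]][[j]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, label = lab, path = fn, stringsAsFactors = FALSE)
    }
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  invisible(mpath)
}
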
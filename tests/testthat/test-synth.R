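test_that("strip generation is deterministic under a fixed seed", {
  p <- synth_patient_params("d1", "control", snr_db = 17)
  g1 <- generate_strip(p, 1, seed = 101)
  g2 <- generate_strip(p, 1, seed = 101)
  expect_identical(g1$strip$samples, g2$strip$samples)
  expect_identical(g1$r_indices, g2$r_indices)
  g3 <- generate_strip(p, 1, seed = 102)
  expect_false(identical(g1$strip$samples, g3$strip$samples))
})

test_that("noise-free generation at 75 bpm yields the expected beat count", {
  g <- clean_strip(hr = 75, seed = 103)
  expect_gte(length(g$r_indices), 34)
  expect_lte(length(g$r_indices), 36)
  expect_equal(length(g$strip$samples), 3500L)
  expect_equal(g$strip$fs, 125)
})

test_that("realized SNR matches the requested level within half a dB", {
  for (snr in c(15, 17.5, 20)) {
    p <- synth_patient_params("s", "control", snr_db = snr,
                              hr_day_sd = 0, morph_day_sd = 0,
                              rr_jitter_day_sd = 0)
    clean <- generate_strip(
      synth_patient_params("s", "control", snr_db = Inf, hr_day_sd = 0,
                           morph_day_sd = 0, rr_jitter_day_sd = 0),
      1, seed = 104)$strip$samples
    noisy <- generate_strip(p, 1, seed = 104)$strip$samples
    noise <- noisy - clean
    p_sig <- mean((clean - mean(clean))^2)
    snr_emp <- 10 * log10(p_sig / mean(noise^2))
    expect_lt(abs(snr_emp - snr), 0.5)
  }
})

test_that("cohort generation is deterministic and labelled as requested", {
  c1 <- generate_cohort(3, 4, 6, seed = 105)
  c2 <- generate_cohort(3, 4, 6, seed = 105)
  expect_identical(c1$strips, c2$strips)
  expect_identical(c1$manifest, c2$manifest)
  ids <- unique(c1$manifest$patient_id)
  expect_equal(length(ids), 7L)
  labs <- c1$manifest$label[!duplicated(c1$manifest$patient_id)]
  expect_equal(sum(labs == "control"), 3L)
  expect_equal(sum(labs == "case"), 4L)
  expect_true(all(vapply(c1$truth, function(t)
    t$params$base_hr >= 59 && t$params$base_hr <= 91, logical(1))))
})

test_that("beat detector recovers ground truth on noise-free cohort strips", {
  total <- 0L; hit <- 0L
  for (hr in c(62, 75, 88)) {
    g <- clean_strip(hr = hr, seed = 106 + hr)
    det <- attr(bd_binarize(g$strip), "beat_indices")
    for (r in g$r_indices) {
      total <- total + 1L
      if (any(abs(det - r) <= 3)) hit <- hit + 1L
    }
  }
  expect_gte(hit / total, 0.95)
})

test_that("day-to-day morphology spread drives threshold-crossing variability", {
  var_at <- function(morph, reps = 10) {
    vapply(seq_len(reps), function(r) {
      p <- synth_patient_params("m", "control", base_hr = 72,
                                hr_day_sd = 0, rr_jitter_sd = 0.01,
                                rr_jitter_day_sd = 0,
                                morph_day_sd = morph, snr_db = 18,
                                n_strips = 10)
      cs <- vapply(1:10, function(j)
        strip_cs(generate_strip(p, j, seed = 1000 * r + 37 * j)$strip,
                 "TC")$cs, numeric(1))
      var_cs(cs)
    }, numeric(1))
  }
  grid <- c(0.005, 0.03, 0.09)
  means <- vapply(grid, function(m) mean(var_at(m)), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a cohort written to disk round-trips through the manifest reader", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(2, 2, 3, seed = 107)
  mpath <- write_cohort(co, dir)
  m <- read_manifest(mpath)
  expect_equal(nrow(m), 12L)
  s <- read_strip(m$path[1], fs = 125)
  expect_identical(s$samples, co$strips[[m$patient_id[1]]][[1]]$samples)
})
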
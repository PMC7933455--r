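test_that("strip files round-trip bit-for-bit and headers are tolerated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.0", "2.0", "3.0"), f)
  s <- read_strip(f, fs = 3)
  expect_equal(s$samples, c(1, 2, 3))
  expect_equal(s$duration_s, 1)

  set.seed(5)
  orig <- ecg_strip(rnorm(500) * exp(rnorm(500)), fs = 125,
                    patient_id = "p1", strip_index = 3L)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_strip(orig, f2)
  back <- read_strip(f2, fs = 125, patient_id = "p1", strip_index = 3L)
  expect_identical(back$samples, orig$samples)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("voltage_uV", "1.5", "-2.5"), f3)
  expect_equal(read_strip(f3, fs = 2)$samples, c(1.5, -2.5))
})

test_that("malformed strip files produce informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.0", "abc", "3.0"), f)
  expect_error(read_strip(f, fs = 3), "row 2")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f2)
  expect_error(read_strip(f2, fs = 3), "empty")
})

test_that("strip validation reports the expected issue codes", {
  set.seed(2)
  good <- ecg_strip(rnorm(3500), fs = 125)
  expect_identical(validate_strip(good, min_samples = 3500), character(0))
  short <- ecg_strip(rnorm(100), fs = 125)
  expect_identical(validate_strip(short, min_samples = 3500), "too_short")
  flat <- ecg_strip(rep(5, 3500), fs = 125)
  expect_identical(validate_strip(flat, min_samples = 3500),
                   "constant_signal")
})

make_manifest <- function(dir, strip_counts) {
  rows <- list()
  for (pid in names(strip_counts)) {
    for (j in seq_len(strip_counts[[pid]])) {
      fn <- sprintf("%s_%03d.csv", pid, j)
      writeLines(sprintf("%.6f", sin(seq_len(50) + j)), file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid,
        label = if (grepl("^C", pid)) "control" else "case",
        path = fn, stringsAsFactors = FALSE)
    }
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  mp
}

test_that("patient filtering drops under-recorded patients and is idempotent", {
  dir <- withr::local_tempdir()
  mp <- make_manifest(dir, c(C01 = 35, C02 = 29, P01 = 40))
  m <- read_manifest(mp)
  kept <- suppressMessages(filter_patients(m, min_strips = 30))
  expect_setequal(unique(kept$patient_id), c("C01", "P01"))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$patient_id, "C02")
  expect_equal(excl$n_strips, 29L)
  # idempotent
  again <- suppressMessages(filter_patients(kept, min_strips = 30))
  expect_equal(as.data.frame(again)[names(m)], as.data.frame(kept)[names(m)])
  # min_strips = 1 keeps everything
  expect_equal(nrow(filter_patients(m, min_strips = 1)), nrow(m))
})

test_that("a 57-patient cohort with 5 under-recorded patients filters to 52", {
  counts <- rep(35L, 57)
  names(counts) <- sprintf("%s%02d", c(rep("C", 27), rep("P", 30)), 1:57)
  set.seed(77)
  counts[sample(57, 5)] <- sample(10:29, 5)
  dir <- withr::local_tempdir()
  # build manifest without writing 1900 files: skip file checks
  m <- do.call(rbind, lapply(names(counts), function(pid) {
    data.frame(patient_id = pid,
               label = if (grepl("^C", pid)) "control" else "case",
               path = sprintf("%s_%03d.csv", pid, seq_len(counts[[pid]])),
               stringsAsFactors = FALSE)
  }))
  kept <- suppressMessages(filter_patients(m, min_strips = 30))
  expect_equal(length(unique(kept$patient_id)), 52L)
})

test_that("manifest reading enforces schema, labels and file existence", {
  dir <- withr::local_tempdir()
  mp <- make_manifest(dir, c(C01 = 2))
  m <- read_manifest(mp)
  expect_s3_class(m, "cohort_manifest")
  bad <- read.csv(mp)
  bad$label <- "healthy"
  write.csv(bad, mp, row.names = FALSE)
  expect_error(read_manifest(mp), "control")
  bad$label <- "control"
  bad$path <- "nope.csv"
  write.csv(bad, mp, row.names = FALSE)
  expect_error(read_manifest(mp), "missing")
})
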
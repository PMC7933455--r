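test_that("rank test matches exact enumeration and handles degenerate inputs", {
  r <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of 20 assignments as extreme
  same <- rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  set.seed(81)
  big <- rank_test(rnorm(100, 1), rnorm(100, 0))
  expect_lt(big$p, 0.001)
  expect_error(rank_test(numeric(0), 1:3), "empty")
})

test_that("rank test U agrees with wilcox.test and p-branches agree at n = 12", {
  set.seed(82)
  for (r in 1:15) {
    a <- rnorm(6); b <- rnorm(6, sample(c(0, 1), 1))
    mine <- rank_test(a, b)
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$U, unname(wt$statistic))
    expect_lt(abs(mine$p - wt$p.value), 0.02)
  }
})

test_that("trapezoid AUC equals the pairwise-concordance oracle, including ties", {
  set.seed(83)
  for (r in 1:50) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    if (r %% 2 == 0) scores <- round(scores, 1)  # force ties
    labels <- c(rep("case", n1), rep("control", n0))
    expect_equal(roc(scores, labels)$auc,
                 auc_concordance_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separable, crossing and all-tied scores", {
  r1 <- roc(c(10, 11, 1, 2), c("case", "case", "control", "control"))
  expect_equal(r1$auc, 1)
  expect_equal(r1$op$sensitivity, 1)
  expect_equal(r1$op$specificity, 1)
  expect_equal(r1$ci, c(1, 1))
  r2 <- roc(c(2, 4, 1, 3), c("case", "case", "control", "control"))
  expect_equal(r2$auc, 0.75)
  r3 <- roc(rep(1, 6), rep(c("case", "control"), 3))
  expect_equal(r3$auc, 0.5)
  expect_true(r1$ci[1] <= r1$auc && r1$auc <= r1$ci[2])
  expect_error(roc(1:3, rep("case", 3)), "both classes")
})

test_that("ROC is invariant under strictly increasing score transforms", {
  set.seed(84)
  scores <- rnorm(30)
  labels <- sample(c("case", "control"), 30, replace = TRUE,
                   prob = c(0.4, 0.6))
  base <- roc(scores, labels)
  tr <- roc(exp(scores), labels)
  expect_equal(tr$auc, base$auc)
  expect_equal(tr$op$sensitivity, base$op$sensitivity)
  expect_equal(tr$op$specificity, base$op$specificity)
})

test_that("the operating point maximizes Youden J over all empirical thresholds", {
  set.seed(85)
  for (r in 1:20) {
    scores <- round(rnorm(25), 1)
    labels <- sample(c("case", "control"), 25, replace = TRUE)
    if (length(unique(labels)) < 2) next
    rr <- roc(scores, labels)
    s1 <- scores[labels == "case"]; s0 <- scores[labels == "control"]
    js <- vapply(c(-Inf, sort(unique(scores))), function(t)
      mean(s1 > t) + mean(s0 <= t) - 1, numeric(1))
    expect_equal(rr$op$youden, max(js), tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil interval matches the closed form and brackets the AUC", {
  set.seed(86)
  scores <- c(rnorm(20, 1), rnorm(25))
  labels <- c(rep("case", 20), rep("control", 25))
  rr <- roc(scores, labels)
  a <- rr$auc; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 19 * (q1 - a^2) + 24 * (q2 - a^2)) / (20 * 25))
  expect_equal(rr$se, se)
  expect_true(rr$ci[1] <= a && a <= rr$ci[2])
})

test_that("AUC and DeLong comparison agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(87)
  scores1 <- c(rnorm(20, 1.2), rnorm(20))
  scores2 <- scores1 + rnorm(40, 0, 2)
  labels <- c(rep("case", 20), rep("control", 20))
  r1 <- suppressMessages(pROC::roc(labels, scores1, levels = c("control", "case"),
                                   direction = "<"))
  r2 <- suppressMessages(pROC::roc(labels, scores2, levels = c("control", "case"),
                                   direction = "<"))
  expect_equal(roc(scores1, labels)$auc, as.numeric(pROC::auc(r1)))
  mine <- compare_auc(scores1, scores2, labels)
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong comparison handles identical, transformed and separable scores", {
  set.seed(88)
  scores <- rnorm(30)
  labels <- sample(rep(c("case", "control"), 15))
  expect_equal(compare_auc(scores, scores, labels)$p, 1)
  expect_equal(compare_auc(scores, 2 * scores + 1, labels)$p, 1)
  expect_equal(compare_auc(scores, exp(scores), labels)$p, 1)
  # informative vs pure noise on separable data
  set.seed(89)
  good <- c(rnorm(25, 2), rnorm(25))
  noise <- rnorm(50)
  lab <- c(rep("case", 25), rep("control", 25))
  expect_lt(compare_auc(good, noise, lab)$p, 0.05)
  expect_error(compare_auc(1:3, 1:4, rep("case", 3)), "mismatch")
})

test_that("strips-needed curve is consistent with full-sample rank test", {
  set.seed(90)
  cs <- c(lapply(1:7, function(i) rnorm(40, 0.50, 0.02)),
          lapply(1:8, function(i) rnorm(40, 0.46, 0.02)))
  names(cs) <- c(sprintf("P%02d", 1:7), sprintf("C%02d", 1:8))
  labels <- c(rep("case", 7), rep("control", 8))
  curve <- strips_needed_curve(cs, labels, m_range = c(10, 20, 40))
  full_means <- vapply(cs, mean, numeric(1))
  full_p <- rank_test(full_means[labels == "case"],
                      full_means[labels == "control"])$p
  expect_equal(curve$p[curve$m == 40], full_p)
  # strong signal: discrimination at every m
  expect_true(all(curve$p < 0.05))
  expect_error(strips_needed_curve(cs, labels, m_range = 50), "has 40 < 50")
})

test_that("strips-needed curve shows no signal under the null", {
  set.seed(91)
  cs <- lapply(1:16, function(i) rnorm(30, 0.48, 0.02))
  labels <- rep(c("case", "control"), each = 8)
  curve <- strips_needed_curve(cs, labels, m_range = seq(10, 30, 5))
  expect_gt(mean(curve$p > 0.05), 0.5)
})

test_that("within-patient independence check computes Spearman rho on squared deviations", {
  fake_patient <- function(tc, bd) {
    structure(list(cs_tc = tc, cs_bd = bd, mean_cs_tc = mean(tc),
                   mean_cs_bd = mean(bd)), class = "patient_scores")
  }
  set.seed(92)
  tc <- rnorm(20, 0.5, 0.02)
  # identical deviation series -> rho = 1
  p1 <- fake_patient(tc, tc - 0.45)
  expect_equal(independence_check(p1)$rho, 1)
  # anti-ranked deviation series -> rho = -1
  dev <- seq(0.01, 0.2, length.out = 12)
  p2 <- fake_patient(0.5 + dev, 0.05 + rev(dev) - 0.05)
  expect_equal(independence_check(p2, raw = TRUE)$rho, -1)
  # constant series reported as undefined
  p3 <- fake_patient(rep(0.5, 10), rnorm(10, 0.05, 0.01))
  expect_true(is.na(independence_check(p3)$rho))
})

test_that("independent variability series rarely show significant correlation", {
  set.seed(93)
  hits <- replicate(100, {
    tc <- rnorm(35, 0.5, 0.02); bd <- rnorm(35, 0.044, 0.002)
    p <- structure(list(cs_tc = tc, cs_bd = bd, mean_cs_tc = mean(tc),
                        mean_cs_bd = mean(bd)), class = "patient_scores")
    ic <- independence_check(p)
    abs(ic$rho) < 0.4 && ic$p > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("threshold perturbation reproduces direct counting and is monotone", {
  set.seed(94)
  h <- abs(rnorm(40, 5e-3, 2e-3))
  labels <- sample(rep(c("case", "control"), 20))
  rep_ <- perturb_threshold(h, labels, base_threshold = 4.5e-3,
                            deltas = c(-0.10, -0.05, 0, 0.05, 0.10))
  base <- rep_[rep_$delta == 0, ]
  expect_equal(base$sensitivity, mean(h[labels == "case"] > 4.5e-3))
  expect_equal(base$specificity, mean(h[labels == "control"] <= 4.5e-3))
  expect_true(all(diff(rep_$sensitivity) <= 0))  # rising threshold
  expect_true(all(diff(rep_$specificity) >= 0))
  # direct counting oracle at one delta
  thr <- 4.5e-3 * 0.95
  expect_equal(rep_$sensitivity[rep_$delta == -0.05],
               sum(h[labels == "case"] > thr) / sum(labels == "case"))
})

test_that("noise robustness reports the definitional SNR and vanishing change at tiny noise", {
  g <- clean_strip(hr = 72, seed = 95, snr_db = 25)
  strips <- list(g$strip)
  p_sig <- mean((g$strip$samples - mean(g$strip$samples))^2)
  sd_target <- sqrt(p_sig / 10^1.59)
  tab <- noise_robustness(strips, c(1e-6, sd_target), reps = 3, seed = 7)
  expect_equal(tab$snr_db[2], 15.9, tolerance = 1e-9)
  expect_lt(tab$mean_pct_change[1], 0.5)
})
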
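test_that("category precedence follows the documented fixed order", {
  n <- 10
  m <- cbind(
    runif(n, 31, 34),                       # not expressed
    c(rep(24, 9), 26.5),                    # high: <27 in all, SD below 1
    c(rep(28.5, 9), 26),                    # low
    25 + c(-2, 2, -2, 2, -2, 2, -2, 2, -2, 2),  # unstable, SD > 1, Cq < 27
    rep(24, n))                             # high but bad melt curves
  colnames(m) <- sprintf("hsa-miR-%03d-tst", 1:5)
  rownames(m) <- sprintf("S%02d", 1:n)
  cq <- make_cq(m); cq$calibrated <- TRUE
  bad <- matrix(FALSE, n, ncol(cq$values), dimnames = dimnames(cq$values))
  bad[1:9, "hsa-miR-005-tst"] <- TRUE       # bad in 90% of samples
  cat1 <- categorize_mirnome(cq, melt_bad = bad)
  expect_equal(cat1$category,
               c("not_expressed", "high_expression", "low_expression",
                 "unstable", "bad_meltcurve"))
  # every miRNA gets exactly one category
  expect_equal(nrow(cat1), 5L)
  expect_false(anyNA(cat1$category))
})

test_that("category counts always partition the target panel", {
  cfg <- generator_config(seed = 19, n_healthy = 12, n_circadian_donors = 2,
                          frac_absent = 0.4, n_high = 10, n_unstable = 5,
                          n_circadian = 2)
  g <- generate_cohort(cfg, tiny_panel(50))
  ct <- categorize_mirnome(calibrate_cel39(g$cq))
  expect_equal(nrow(ct), 50L)
  expect_equal(sum(table(ct$category)), 50L)
  expect_true(all(ct$sd_cq[ct$category == "unstable"] > 1))
})

test_that("re-calibration shifts never change the unstable set", {
  cfg <- generator_config(seed = 29, n_healthy = 15, n_circadian_donors = 0,
                          frac_absent = 0.3, n_high = 8, n_unstable = 4,
                          n_circadian = 0)
  g <- generate_cohort(cfg, tiny_panel(40))
  cal <- calibrate_cel39(g$cq)
  ct1 <- categorize_mirnome(cal)
  shifted <- cal
  shifted$values <- cal$values + 0.7        # batch-wide constant
  ct2 <- categorize_mirnome(shifted)
  expect_identical(ct2$assay[ct2$category == "unstable"],
                   ct1$assay[ct1$category == "unstable"])
})

test_that("unstable flagging has high sensitivity and low false-positive rate", {
  res <- vapply(1:10, function(s) {
    cfg <- generator_config(seed = 700 + s, n_healthy = 27,
                            n_circadian_donors = 0, frac_absent = 0,
                            n_high = 20, n_unstable = 10, n_circadian = 0)
    g <- generate_cohort(cfg, tiny_panel(60))
    ct <- categorize_mirnome(calibrate_cel39(g$cq))
    truth <- g$truth$mirna
    planted <- truth$assay[truth$category == "unstable"]
    flagged <- ct$assay[ct$category == "unstable"]
    c(sens = mean(planted %in% flagged),
      fpr = mean(setdiff(truth$assay, planted) %in% flagged))
  }, numeric(2))
  expect_gte(mean(res["sens", ]), 0.95)
  expect_lte(mean(res["fpr", ]), 0.01)
})

test_that("a clean midday-only shift is a candidate; monotone drift is not", {
  cfg <- generator_config(seed = 3, n_healthy = 4, n_circadian_donors = 3,
                          frac_absent = 0, n_high = 30, n_unstable = 0,
                          n_circadian = 0, noise_sd = 0)
  g <- generate_cohort(cfg, tiny_panel(50))
  cal <- calibrate_cel39(g$cq)
  mid <- g$samples$sample_id[g$samples$timepoint %in% "midday"]
  ev <- g$samples$sample_id[g$samples$timepoint %in% "evening"]
  a_mid <- "hsa-miR-001-tst"; a_drift <- "hsa-miR-002-tst"
  cal$values[mid, a_mid] <- cal$values[mid, a_mid] - 1.5
  cal$values[mid, a_drift] <- cal$values[mid, a_drift] - 1.5
  cal$values[ev, a_drift] <- cal$values[ev, a_drift] - 3.0
  res <- circadian_analysis(cal, g$samples, delta = 0.58)
  expect_true(a_mid %in% res$assay)
  expect_false(a_drift %in% res$assay)
  fc <- res$fold_change[res$assay == a_mid]
  expect_equal(fc, 2^1.5, tolerance = 0.05)
  # donors missing a timepoint are dropped with a message
  broken <- g$samples[g$samples$sample_id != mid[1], ]
  cq_b <- subset_samples(cal, broken$sample_id)
  expect_message(circadian_analysis(cq_b, broken, delta = 0.58), "dropping")
})

test_that("fluctuating assays are not reported as circadian candidates", {
  cfg <- generator_config(seed = 13, n_healthy = 10, n_circadian_donors = 4,
                          frac_absent = 0, n_high = 6, n_unstable = 0,
                          n_circadian = 0, noise_sd = 0)
  g <- generate_cohort(cfg, tiny_panel(12))
  cal <- calibrate_cel39(g$cq)
  mid <- g$samples$sample_id[g$samples$timepoint %in% "midday"]
  a <- "hsa-miR-003-tst"
  cal$values[mid, a] <- cal$values[mid, a] - 1.5
  set.seed(1)
  cal$values[, a] <- cal$values[, a] + rnorm(nrow(cal$values), 0, 1.6)
  res <- circadian_analysis(cal, g$samples, delta = 0.58)
  expect_false(a %in% res$assay)
})

test_that("the reference profile reproduces degenerate cohorts exactly", {
  m <- matrix(c(24, 27), 1, 2,
              dimnames = list("A", c("hsa-miR-001-tst", "hsa-miR-002-tst")))
  cq <- make_cq(m); cq$calibrated <- TRUE
  prof <- reference_profile(cq)
  expect_equal(prof$mean_cq, c(24, 27))

  m2 <- rbind(A = c(24, 27), B = c(24, 27))
  colnames(m2) <- colnames(m)
  cq2 <- make_cq(m2); cq2$calibrated <- TRUE
  prof2 <- reference_profile(cq2)
  expect_equal(prof2$mean_cq, c(24, 27))
  expect_equal(prof2$sd_cq, c(0, 0))
})
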
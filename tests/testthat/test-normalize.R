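test_that("cel-39 calibration adds the stated correction factors", {
  m <- matrix(c(25, 26), 2, 1, dimnames = list(c("A", "B"),
                                               "hsa-miR-001-tst"))
  cq <- make_cq(m, cel39 = c(18, 20))
  cal <- calibrate_cel39(cq)
  expect_equal(unname(attr(cal, "corrections")), c(2, 0))
  expect_equal(cal$values["A", "hsa-miR-001-tst"], 27)
  expect_equal(cal$values["B", "hsa-miR-001-tst"], 26)
  expect_true(all(cal$values[, "cel-miR-39-3p"] == 20))

  single <- make_cq(m[1, , drop = FALSE], cel39 = 18)
  cal1 <- calibrate_cel39(single)
  expect_identical(cal1$values, single$values)

  und <- make_cq(m, cel39 = c(18, NA))
  expect_error(calibrate_cel39(und), "cel-39 not detected.*B")
})

test_that("calibration is idempotent and preserves within-sample contrasts", {
  set.seed(5)
  m <- matrix(runif(10 * 20, 20, 29), 10, 20)
  cq <- make_cq(m, cel39 = runif(10, 17, 19))
  cal1 <- calibrate_cel39(cq)
  cal2 <- calibrate_cel39(cal1)
  expect_equal(cal2$values, cal1$values, tolerance = 1e-9)
  # all cel-39 means equal the batch maximum after calibration
  expect_equal(unname(cal1$values[, "cel-miR-39-3p"]),
               rep(max(cq$values[, "cel-miR-39-3p"]), 10), tolerance = 1e-9)
  # within-sample differences between any two assays are unchanged
  d_raw <- cq$values[, 2] - cq$values[, 7]
  d_cal <- cal1$values[, 2] - cal1$values[, 7]
  expect_equal(d_cal, d_raw, tolerance = 1e-9)
})

test_that("censoring keeps the 30.0 boundary, masks above it and bad melts", {
  m <- matrix(c(30, 30.5, 22, 25), 2, 2,
              dimnames = list(c("A", "B"),
                              c("hsa-miR-001-tst", "hsa-miR-002-tst")))
  cq <- make_cq(m)
  cq$calibrated <- TRUE
  bad <- matrix(FALSE, 2, ncol(cq$values),
                dimnames = dimnames(cq$values))
  bad["A", "hsa-miR-002-tst"] <- TRUE       # Cq 22, good value, bad curve
  cen <- censor_cq(cq, melt_bad = bad)
  expect_equal(cen$values["A", "hsa-miR-001-tst"], 30)
  expect_true(is.na(cen$values["B", "hsa-miR-001-tst"]))
  expect_true(is.na(cen$values["A", "hsa-miR-002-tst"]))
  expect_equal(cen$values["B", "hsa-miR-002-tst"], 25)
})

test_that("global-mean normalization matches hand arithmetic and geometry", {
  m <- matrix(c(20, 22), 1, 2,
              dimnames = list("A", c("hsa-miR-001-tst", "hsa-miR-002-tst")))
  cq <- make_cq(m); cq$calibrated <- TRUE
  expr <- global_mean_normalize(censor_cq(cq))
  expect_equal(unname(expr$values["A", ]), c(2, 0.5))

  meq <- matrix(24, 3, 4)
  cq2 <- make_cq(meq); cq2$calibrated <- TRUE
  expect_true(all(global_mean_normalize(censor_cq(cq2))$values == 1))

  set.seed(8)
  mr <- matrix(runif(6 * 12, 20, 29), 6, 12)
  mr[sample(length(mr), 8)] <- NA
  cq3 <- make_cq(mr); cq3$calibrated <- TRUE
  e3 <- global_mean_normalize(censor_cq(cq3))
  gm <- apply(e3$values, 1, function(x) exp(mean(log(x), na.rm = TRUE)))
  expect_equal(unname(gm), rep(1, 6), tolerance = 1e-9)
  # masked entries stay masked
  expect_identical(is.na(e3$values), is.na(cq3$values[, colnames(e3$values)]))
})

test_that("stability measures honor their defining degeneracies", {
  set.seed(3)
  n <- 12
  base <- rnorm(n, 25, 1)
  m <- cbind(base, base + 2, rnorm(n, 24, 0.8), rep(26, n))
  colnames(m) <- sprintf("hsa-miR-%03d-tst", 1:4)
  rownames(m) <- sprintf("S%02d", 1:n)
  cq <- make_cq(m)
  rk <- stability_rank(cq)
  # two candidates with constant difference: both have zero pairwise SD
  # against each other; the constant candidate has BestKeeper SD 0
  expect_equal(rk$bestkeeper_sd[rk$assay == "hsa-miR-004-tst"], 0)
  expect_equal(rk$rank_bestkeeper[rk$assay == "hsa-miR-004-tst"], 1)
  pair_sd <- sd((m[, 1] - m[, 2]))
  expect_equal(pair_sd, 0, tolerance = 1e-12)

  two_const <- make_cq(cbind(m[, 1], m[, 1] + 2, m[, 1] - 1))
  rk2 <- stability_rank(two_const)
  expect_equal(rk2$genorm_m, rep(0, 3), tolerance = 1e-12)
})

test_that("geNorm and delta-Ct are invariant under per-sample shifts", {
  set.seed(4)
  m <- matrix(rnorm(8 * 6, 25, 0.8), 8, 6)
  cq <- make_cq(m)
  rk1 <- stability_rank(cq)
  shifted <- cq
  shifted$values <- cq$values + runif(8, 0, 3)   # per-sample constants
  rk2 <- stability_rank(shifted)
  ord <- match(rk1$assay, rk2$assay)
  expect_equal(rk2$genorm_m[ord], rk1$genorm_m, tolerance = 1e-9)
  expect_equal(rk2$delta_ct_sd[ord], rk1$delta_ct_sd, tolerance = 1e-9)
  expect_equal(rk2$normfinder_stability[ord], rk1$normfinder_stability,
               tolerance = 1e-9)
})

test_that("planted low-noise references take the top consensus ranks", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 20
    refs <- sapply(1:5, function(i) 24 + i + rnorm(n, 0, 0.05))
    noisy <- sapply(1:15, function(i) 25 + rnorm(n, 0, 0.6))
    m <- cbind(refs, noisy)
    colnames(m) <- sprintf("hsa-miR-%03d-tst", 1:20)
    cq <- make_cq(m)
    rk <- stability_rank(cq)
    all(rk$assay[rk$consensus_rank <= 5] %in% colnames(m)[1:5])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stable-reference normalization follows the reference mean", {
  n <- 4
  refs <- matrix(20, n, 5)
  target <- matrix(17, n, 1)
  m <- cbind(refs, target)
  colnames(m) <- sprintf("hsa-miR-%03d-tst", 1:6)
  cq <- make_cq(m); cq$calibrated <- TRUE
  rk <- stability_rank(cq, candidates = colnames(m)[1:5])
  expr <- stable_reference_normalize(censor_cq(cq), rk)
  expect_true(all(expr$values[, "hsa-miR-006-tst"] == 8))   # 2^(20-17)
  # references normalized by themselves: per-sample geometric mean is 1
  gm <- apply(expr$values[, attr(expr, "references")], 1,
              function(x) exp(mean(log(x))))
  expect_equal(unname(gm), rep(1, n), tolerance = 1e-9)
})

test_that("fold changes follow 2^(-ddCq) with the reciprocal identity", {
  set.seed(12)
  m <- rbind(matrix(24, 6, 3), matrix(24, 6, 3))
  m[1:6, 2] <- 24 - 6.09                     # group A overexpresses assay 2
  rownames(m) <- sprintf("S%02d", 1:12)
  colnames(m) <- sprintf("hsa-miR-%03d-tst", 1:3)
  cq <- make_cq(m); cq$calibrated <- TRUE
  expr <- global_mean_normalize(censor_cq(cq))
  a <- rownames(m)[1:6]; b <- rownames(m)[7:12]
  fc <- fold_change(expr, a, b)
  fc_ba <- fold_change(expr, b, a)
  expect_equal(fc$fold_change * fc_ba$fold_change, rep(1, 3),
               tolerance = 1e-9)
  # identical groups have FC 1
  fc_id <- fold_change(expr, a, a)
  expect_equal(fc_id$fold_change, rep(1, 3), tolerance = 1e-12)
})
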
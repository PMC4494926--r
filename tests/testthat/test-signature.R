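# Small two-group expression fixture: k informative assays separate the
# groups by `shift` in log2 units, the rest are noise.
sep_dataset <- function(n_per = 12, p = 10, k = 1, shift = 4, sd = 0.3,
                        seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p, 0, sd), 2 * n_per, p)
  x[seq_len(n_per), seq_len(k)] <- x[seq_len(n_per), seq_len(k)] + shift
  colnames(x) <- sprintf("hsa-miR-%03d-tst", seq_len(p))
  rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
  y <- factor(rep(c("healthy", "stage III"), each = n_per),
              levels = c("healthy", "stage III"))
  list(x = x, y = y)
}

patient_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_cohort(fixture_config("patients"), custom_panel())
      cen <- censor_cq(calibrate_cel39(g$cq))
      expr <- suppressMessages(
        stable_reference_normalize(cen, stability_rank(cen)))
      cache <<- list(g = g, expr = expr)
    }
    cache
  }
})

test_that("build_dataset restricts, labels and sizes the comparison groups", {
  fx <- patient_fixture()
  specs <- comparison_specs()
  dh <- build_dataset(fx$expr, fx$g$samples, specs$h)
  expect_equal(nrow(dh$x), 30 + 20)          # healthy vs stages III+IV
  expect_equal(levels(dh$y), c("healthy", "late stage"))
  da <- build_dataset(fx$expr, fx$g$samples, specs$a)
  expect_equal(sort(unique(as.character(da$y))), c("healthy", "melanoma"))
  expect_false(anyNA(dh$x))
  empty <- specs$h; empty$stages_b <- character(0)
  expect_error(build_dataset(fx$expr, fx$g$samples, empty), "fewer than 3")
})

test_that("SVM-RFE puts a perfectly separating feature first", {
  firsts <- vapply(1:10, function(s) {
    ds <- sep_dataset(seed = s)
    rank_svmrfe(ds$x, ds$y)[1]
  }, "")
  expect_true(all(firsts == "hsa-miR-001-tst"))
})

test_that("SVM-RFE is label-flip invariant and eliminates constants first", {
  ds <- sep_dataset(seed = 4)
  r1 <- rank_svmrfe(ds$x, ds$y)
  r2 <- rank_svmrfe(ds$x, factor(ds$y, levels = rev(levels(ds$y))))
  expect_identical(r1, r2)

  xc <- ds$x; xc[, "hsa-miR-007-tst"] <- 3   # all-constant feature
  r3 <- rank_svmrfe(xc, ds$y)
  expect_equal(r3[length(r3)], "hsa-miR-007-tst")
})

test_that("nested signatures reach perfect LOO accuracy on separable data", {
  ds <- sep_dataset(seed = 2, k = 2)
  rk <- rank_svmrfe(ds$x, ds$y)
  ev <- evaluate_signatures(ds$x, ds$y, rk, sizes = 2:6)
  expect_true(all(ev$accuracy == 1))
  expect_equal(ev$best_size, 2L)             # smallest size wins ties
  # nestedness of the reported signatures
  for (k in 2:5)
    expect_true(all(rk[seq_len(k)] %in% rk[seq_len(k + 1)]))
  expect_identical(ev$best_signature, rk[1:2])
})

test_that("LOO accuracy does not depend on sample order", {
  ds <- sep_dataset(seed = 6, k = 1, shift = 1.2, sd = 0.8)
  rk <- rank_svmrfe(ds$x, ds$y)
  ev1 <- evaluate_signatures(ds$x, ds$y, rk, sizes = c(2, 4))
  set.seed(9); perm <- sample(nrow(ds$x))
  ev2 <- evaluate_signatures(ds$x[perm, ], ds$y[perm], rk, sizes = c(2, 4))
  expect_equal(ev2$accuracy, ev1$accuracy)
})

test_that("label-permuted data stays inside its permutation null band", {
  set.seed(33)
  ds <- sep_dataset(seed = 33, k = 0, shift = 0)   # y independent of x
  rk <- rank_svmrfe(ds$x, ds$y)
  obs <- max(evaluate_signatures(ds$x, ds$y, rk, sizes = 2:5)$accuracy)
  nb <- signature_null_band(ds$x, ds$y, sizes = 2:5, n_perm = 20, seed = 5)
  expect_gte(obs, nb$band[1] - 1e-9)
  expect_lte(obs, nb$band[2] + 1e-9)
})

test_that("half-split ROC is perfect with CI [1,1] on separated data", {
  ds <- sep_dataset(seed = 7, k = 2)
  roc <- roc_half_split(ds$x, ds$y, c("hsa-miR-001-tst", "hsa-miR-002-tst"),
                        seed = 1, n_boot = 200)
  expect_equal(roc$auc, 1)
  expect_equal(unname(roc$ci), c(1, 1))
  expect_equal(roc$n_train + roc$n_test, nrow(ds$x))
})

test_that("exclusion flags mark whole-blood-high and unstable members", {
  wb <- generate_whole_blood_reference(custom_panel(), seed = 2)
  fl <- flag_candidates(c("hsa-miR-451a", "hsa-miR-205-5p"),
                        whole_blood_cq = wb,
                        unstable_list = "hsa-miR-205-5p")
  expect_true(fl$whole_blood_high[fl$assay == "hsa-miR-451a"])
  expect_false(fl$whole_blood_high[fl$assay == "hsa-miR-205-5p"])
  expect_true(fl$unstable[fl$assay == "hsa-miR-205-5p"])
  expect_warning(flag_candidates("hsa-miR-205-5p"), "whole-blood")
})

test_that("regulation direction is the strict group-mean comparison", {
  fx <- patient_fixture()
  specs <- comparison_specs()
  dir_f <- regulation_direction(fx$expr, fx$g$samples, specs$f,
                                c("hsa-miR-211-5p", "hsa-miR-200c-3p"))
  expect_equal(dir_f$direction[dir_f$assay == "hsa-miR-211-5p"], "up")
  expect_equal(dir_f$direction[dir_f$assay == "hsa-miR-200c-3p"], "down")
  # invariant under global rescaling of expression
  sc <- fx$expr; sc$values <- sc$values * 37
  dir_sc <- regulation_direction(sc, fx$g$samples, specs$f,
                                 c("hsa-miR-211-5p", "hsa-miR-200c-3p"))
  expect_identical(dir_sc$direction, dir_f$direction)
  # equal means: down by convention, flagged borderline
  eq <- fx$expr; eq$values[] <- 1
  dir_eq <- regulation_direction(eq, fx$g$samples, specs$f, "hsa-miR-211-5p")
  expect_equal(dir_eq$direction, "down")
  expect_true(dir_eq$borderline)
})

test_that("the full pipeline recovers planted late-stage markers", {
  fx <- patient_fixture()
  res <- run_signature(fx$expr, fx$g$samples, comparison_specs()$e,
                       seed = 1,
                       whole_blood_cq = generate_whole_blood_reference(
                         custom_panel(), seed = 3))
  planted <- unique(default_stage_effects()$assay)
  expect_true(all(utils::head(res$ranking, 4) %in% planted))
  expect_gte(max(res$accuracy), 0.95)
  expect_gte(res$auc, 0.95)
})
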
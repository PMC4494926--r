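test_that("zero-noise planting is exact and category assignment is forced", {
  cfg <- generator_config(seed = 1, n_healthy = 8, n_circadian_donors = 0,
                          frac_absent = 0, n_high = 1, n_unstable = 0,
                          n_circadian = 0, noise_sd = 0,
                          fixed_baselines = c("hsa-miR-001-tst" = 25))
  g <- generate_cohort(cfg, tiny_panel(4))
  expect_true(all(g$cq$values[, "hsa-miR-001-tst"] == 25))
  expect_equal(
    g$truth$mirna$category[g$truth$mirna$assay == "hsa-miR-001-tst"], "high")
})

test_that("absent fraction is deterministic and absent columns never dip to 30", {
  cfg <- generator_config(seed = 7, n_healthy = 10, n_circadian_donors = 0,
                          frac_absent = 0.5, n_high = 4, n_unstable = 2,
                          n_circadian = 0)
  g <- generate_cohort(cfg, tiny_panel(40))
  v <- g$cq$values[, panel_targets(tiny_panel(40))]
  absent_cols <- colnames(v)[apply(v, 2, function(x) all(is.na(x) | x > 30))]
  expect_equal(length(absent_cols), round(0.5 * 40))
  expect_setequal(absent_cols,
                  g$truth$mirna$assay[g$truth$mirna$category == "absent"])
})

test_that("outputs are bit-identical across runs with a fixed seed", {
  cfg <- generator_config(seed = 123, n_healthy = 6, n_circadian_donors = 1,
                          frac_absent = 0.3, n_high = 3, n_unstable = 2,
                          n_circadian = 1)
  g1 <- generate_cohort(cfg, tiny_panel(20))
  g2 <- generate_cohort(cfg, tiny_panel(20))
  expect_identical(g1$cq$values, g2$cq$values)
  expect_identical(g1$truth, g2$truth)
  m1 <- generate_melt_curves(generator_config(seed = 5), 10, 10)
  m2 <- generate_melt_curves(generator_config(seed = 5), 10, 10)
  expect_identical(m1, m2)
})

test_that("planted unstable miRNAs realize an across-sample SD above 1.2", {
  cfg <- generator_config(seed = 21, n_healthy = 25, n_circadian_donors = 0,
                          frac_absent = 0, n_high = 5, n_unstable = 10,
                          n_circadian = 0)
  g <- generate_cohort(cfg, tiny_panel(30))
  unst <- g$truth$mirna$assay[g$truth$mirna$category == "unstable"]
  sds <- apply(g$cq$values[, unst], 2, sd)
  expect_true(all(sds > 1.2))
  stable <- g$truth$mirna$assay[g$truth$mirna$category %in% c("high", "low")]
  expect_true(all(apply(g$cq$values[, stable], 2, sd) < 1))
})

test_that("circadian miRNAs shift only at the midday timepoint", {
  cfg <- generator_config(seed = 2, n_healthy = 0, n_circadian_donors = 4,
                          frac_absent = 0, n_high = 2, n_unstable = 0,
                          n_circadian = 2, noise_sd = 0)
  g <- generate_cohort(cfg, tiny_panel(8))
  circ <- g$truth$mirna[g$truth$mirna$category == "circadian", ]
  for (i in seq_len(nrow(circ))) {
    v <- g$cq$values[, circ$assay[i]]
    mid <- g$samples$timepoint == "midday"
    expect_equal(unname(v[mid]),
                 rep(circ$baseline_cq[i] + cfg$circadian_delta_cq, sum(mid)))
    expect_equal(unname(v[!mid]), rep(circ$baseline_cq[i], sum(!mid)))
  }
})

test_that("planted stage effects are recoverable from group means", {
  eff <- data.frame(assay = "hsa-miR-001-tst", stage = "IV", delta_cq = -2)
  cfg <- generator_config(seed = 31, n_healthy = 200, n_circadian_donors = 0,
                          stage_n = c("IV" = 200), frac_absent = 0,
                          n_high = 2, n_unstable = 0, n_circadian = 0,
                          stage_effects = eff)
  g <- generate_cohort(cfg, tiny_panel(4))
  v <- g$cq$values[, "hsa-miR-001-tst"]
  healthy <- g$samples$stage == "healthy"
  est <- mean(v[!healthy]) - mean(v[healthy])
  se <- cfg$noise_sd * sqrt(1 / 200 + 1 / 200)
  expect_lt(abs(est - (-2)), 3 * se)
})

test_that("good melt curves peak where planted; flat curves stay under the floor", {
  cfg <- generator_config(seed = 1, melt_noise_sd = 0)
  g1 <- generate_melt_curves(cfg, n_good = 1, n_bad = 0)
  cv <- g1$curves[[1]]
  tm <- cv$temperature[which.max(cv$signal)]
  expect_gte(tm, 74); expect_lte(tm, 84)
  expect_gte(max(cv$signal), 0.8)

  set.seed(2)
  g2 <- generate_melt_curves(generator_config(seed = 2), n_good = 0,
                             n_bad = 30)
  flat <- g2$curves[attr(g2$labels, "archetype") == "flat"]
  expect_true(all(vapply(flat, function(c) max(c$signal), 1) < 0.2))
  pd <- g2$curves[attr(g2$labels, "archetype") == "primer_dimer"]
  tms <- vapply(pd, function(c) c$temperature[which.max(c$signal)], 1)
  expect_true(all(tms < 74))
})

test_that("matched generator enforces planted compartment structure", {
  cfg <- generator_config(seed = 9, n_individuals = 3,
                          n_tissue_exclusive = 1, n_serum_exclusive = 1,
                          n_serum_higher = 0, n_gradient = 1, noise_sd = 0)
  g <- generate_matched_tissue_serum(cfg, custom_panel())
  tr <- g$truth$mirna
  serum_rows <- g$samples$sample_id[g$samples$source == "serum"]
  tissue_rows <- setdiff(g$samples$sample_id, serum_rows)
  tex <- tr$assay[tr$category == "tissue_exclusive"]
  expect_true(all(is.na(g$cq$values[serum_rows, tex])))
  expect_true(all(!is.na(g$cq$values[tissue_rows, tex])))
  grad <- tr$assay[tr$category == "stage_gradient"]
  ns <- g$samples$sample_id[g$samples$source == "tissue_normal_skin"]
  pr <- g$samples$sample_id[g$samples$source == "tissue_primary"]
  mt <- g$samples$sample_id[g$samples$source == "tissue_metastasis"]
  expect_true(all(colMeans(g$cq$values[mt, grad, drop = FALSE]) <
                  colMeans(g$cq$values[pr, grad, drop = FALSE])))
  expect_true(all(colMeans(g$cq$values[pr, grad, drop = FALSE]) <
                  colMeans(g$cq$values[ns, grad, drop = FALSE])))
  expect_error(
    generate_matched_tissue_serum(
      generator_config(n_tissue_exclusive = 80, n_serum_higher = 20),
      custom_panel()),
    "exceed")
})

test_that("inconsistent configurations are rejected", {
  expect_error(generator_config(n_high = -1), "non-negative")
  expect_error(generator_config(frac_absent = 1.2), "frac_absent")
  expect_error(
    generate_cohort(generator_config(seed = 1, n_high = 50, n_unstable = 0,
                                     n_circadian = 0, frac_absent = 0),
                    tiny_panel(10)),
    "more planted categories")
})
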
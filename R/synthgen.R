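#' Generator configuration
#'
#' Defines the synthetic study conditions: cohort composition, planted
#' per-miRNA categories (absent / high / low / unstable / circadian),
#' stage-differential effects, planted per-sample QC fates, control-assay
#' behaviour and melt-curve shape parameters.  Category assignment depends
#' only on the seed and the configuration; measurement noise only perturbs
#' the values.
#'
#' Defaults emulate the healthy serum cohort: 19 single-draw donors plus 4
#' circadian donors sampled at three times of day, a whole-miRNome panel on
#' which 63% of miRNAs are absent from serum, 82 are highly expressed
#' (Cq < 27), 30 fluctuate between individuals (across-sample SD well above
#' the 1-cycle instability cutoff) and 7 shift at the midday timepoint only.
#'
#' @param seed Integer RNG seed.
#' @param n_healthy Healthy donors sampled once.
#' @param n_circadian_donors Donors sampled at morning/midday/evening.
#' @param stage_n Named integer vector of patient counts per stage
#'   (names among "0","I","II","III","IV").
#' @param frac_absent Fraction of target miRNAs absent from serum.
#' @param n_high,n_unstable,n_circadian Planted category counts.
#' @param noise_sd Additive Gaussian noise on Cq (cycles) for stable wells.
#' @param unstable_sd Planted across-sample fluctuation (cycles) of unstable
#'   miRNAs; the realized per-miRNA fluctuation SD is fixed at exactly this
#'   value so the planted category is unambiguous ground truth.
#' @param circadian_delta_cq Cq shift applied to circadian miRNAs at the
#'   midday timepoint only (negative = higher midday expression).
#' @param stage_effects Data frame `assay`, `stage`, `delta_cq` of planted
#'   stage-differential shifts; effect-carrying assays are forced into a
#'   detected (high-expression) category.
#' @param fixed_baselines Named numeric vector pinning the baseline Cq of
#'   specific assays (these are likewise forced into the high category).
#' @param baseline_high,baseline_low,baseline_unstable,baseline_circadian
#'   Uniform baseline-Cq ranges per category.
#' @param n_hemolytic,n_contaminated,n_poor_spike Planted QC failures among
#'   the generated serum samples.
#' @param spike_nominal_cq Nominal Cq of cel-39/cel-54/cel-238 (the three
#'   spike-in concentrations).
#' @param spike_jitter_sd Spike Cq jitter for clean samples.
#' @param spike_fail_shift,spike_fail_sd Cq shift and jitter of spikes in
#'   poor-recovery samples (incomplete extraction = later Cq).
#' @param hemolysis_shift Cq shift of miR-451a in hemolytic samples.
#' @param melt_grid Temperature grid (degrees C) of generated melt curves.
#' @param melt_noise_sd Signal noise SD of generated melt curves.
#' @param n_individuals,n_tissue_exclusive,n_serum_exclusive,n_serum_higher,
#'   n_gradient Matched tissue/serum plan: matched individuals (serum,
#'   normal skin, primary tumour, metastasis each) and planted category
#'   counts on the custom panel.
#' @param serum_higher_delta_cq Cq advantage of serum over tissue for
#'   serum-higher miRNAs (negative = more abundant in serum).
#' @param gradient_step_cq Cq step normal skin -> primary -> metastasis for
#'   stage-gradient miRNAs (negative = increasing expression).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 20260101L,
                             n_healthy = 19L,
                             n_circadian_donors = 4L,
                             stage_n = c("0" = 0L, "I" = 0L, "II" = 0L,
                                         "III" = 0L, "IV" = 0L),
                             frac_absent = 0.63,
                             n_high = 82L,
                             n_unstable = 30L,
                             n_circadian = 7L,
                             noise_sd = 0.3,
                             unstable_sd = 1.3,
                             circadian_delta_cq = -1.9,
                             stage_effects = NULL,
                             fixed_baselines = NULL,
                             baseline_high = c(20, 25.5),
                             baseline_low = c(27.6, 29.6),
                             baseline_unstable = c(24, 27.5),
                             baseline_circadian = c(26.5, 28.0),
                             n_hemolytic = 0L,
                             n_contaminated = 0L,
                             n_poor_spike = 0L,
                             spike_nominal_cq = c(18, 21, 24),
                             spike_jitter_sd = 0.25,
                             spike_fail_shift = 4,
                             spike_fail_sd = 1.5,
                             hemolysis_shift = -8,
                             melt_grid = seq(65, 95, by = 0.5),
                             melt_noise_sd = 0.02,
                             n_individuals = 6L,
                             n_tissue_exclusive = 15L,
                             n_serum_exclusive = 2L,
                             n_serum_higher = 12L,
                             n_gradient = 5L,
                             serum_higher_delta_cq = -2.5,
                             gradient_step_cq = -1.5) {
  cfg <- as.list(environment())
  if (!is.null(cfg$stage_effects))
    cfg$stage_effects <- as.data.frame(cfg$stage_effects,
                                       stringsAsFactors = FALSE)
  counts <- c(cfg$n_healthy, cfg$n_circadian_donors, cfg$stage_n,
              cfg$n_high, cfg$n_unstable, cfg$n_circadian, cfg$n_hemolytic,
              cfg$n_contaminated, cfg$n_poor_spike, cfg$n_individuals,
              cfg$n_tissue_exclusive, cfg$n_serum_exclusive,
              cfg$n_serum_higher, cfg$n_gradient)
  if (any(counts < 0)) stop("configuration error: counts must be non-negative")
  if (cfg$frac_absent < 0 || cfg$frac_absent > 1)
    stop("configuration error: frac_absent must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (cfg$unstable_sd <= 0) stop("configuration error: unstable_sd must be > 0")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> seed=%d; %d healthy + %dx3 circadian",
                     " + %d staged samples; noise_sd=%.2f\n"),
              x$seed, x$n_healthy, x$n_circadian_donors, sum(x$stage_n),
              x$noise_sd))
  invisible(x)
}

# Deterministic category assignment for target miRNAs.  Effect-carrying and
# pinned-baseline assays are forced into the high (always detected) slot.
assign_categories <- function(targets, config) {
  n <- length(targets)
  n_absent <- round(config$frac_absent * n)
  forced_high <- character(0)
  if (!is.null(config$stage_effects))
    forced_high <- union(forced_high, unique(config$stage_effects$assay))
  if (!is.null(config$fixed_baselines))
    forced_high <- union(forced_high, names(config$fixed_baselines))
  if (length(setdiff(forced_high, targets)))
    stop("configuration error: effect assays not on panel: ",
         paste(setdiff(forced_high, targets), collapse = ", "))
  if (n_absent + config$n_high + config$n_unstable + config$n_circadian > n ||
      length(forced_high) > config$n_high)
    stop("configuration error: more planted categories than panel assays")
  category <- stats::setNames(rep("low", n), targets)
  pool <- setdiff(targets, forced_high)
  pick <- function(k) {
    chosen <- if (k > 0) sample(pool, k) else character(0)
    pool <<- setdiff(pool, chosen)
    chosen
  }
  category[pick(n_absent)] <- "absent"
  category[pick(config$n_unstable)] <- "unstable"
  category[pick(config$n_circadian)] <- "circadian"
  category[forced_high] <- "high"
  category[pick(config$n_high - length(forced_high))] <- "high"
  category
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# Baseline Cq per target miRNA given its planted category.
draw_baselines <- function(category, config) {
  baseline <- stats::setNames(numeric(length(category)), names(category))
  for (cat in c("high", "low", "unstable", "circadian")) {
    idx <- names(category)[category == cat]
    key <- switch(cat, high = "baseline_high", low = "baseline_low",
                  unstable = "baseline_unstable",
                  circadian = "baseline_circadian")
    baseline[idx] <- runif_range(length(idx), config[[key]])
  }
  baseline[category == "absent"] <- NA_real_
  if (!is.null(config$fixed_baselines))
    baseline[names(config$fixed_baselines)] <-
      unname(config$fixed_baselines)
  baseline
}

#' Generate a synthetic serum cohort with planted ground truth
#'
#' Draws a Cq matrix for healthy donors, circadian donors (three timepoints)
#' and staged patients on the given panel.  Absent miRNAs never yield a
#' Cq of 30 or below (half the wells are not detected at all); unstable
#' miRNAs carry an across-sample biological fluctuation of fixed SD;
#' circadian miRNAs shift only at midday; stage-differential miRNAs shift
#' only in the configured stages.  Control assays are drawn around their
#' nominal values, with planted QC failures expressed through the relevant
#' controls (hemolysis through miR-451a, contamination through the SNORDs,
#' poor spike recovery through shifted spike-ins).
#'
#' @param config A [generator_config()].
#' @param panel A `panel_definition`.
#' @return List with elements `cq` (`cq_matrix`), `samples`
#'   (`sample_table`) and `truth` (planted categories, effects and QC fates).
#' @export
generate_cohort <- function(config, panel) {
  set.seed(config$seed)
  targets <- panel_targets(panel)
  category <- assign_categories(targets, config)
  baseline <- draw_baselines(category, config)

  ids <- character(0); src <- character(0); stg <- character(0)
  tp <- character(0); ind <- character(0)
  if (config$n_healthy > 0) {
    ids <- c(ids, sprintf("HY%02d", seq_len(config$n_healthy)))
    src <- c(src, rep("serum", config$n_healthy))
    stg <- c(stg, rep("healthy", config$n_healthy))
    tp <- c(tp, rep(NA, config$n_healthy))
    ind <- c(ind, sprintf("HY%02d", seq_len(config$n_healthy)))
  }
  if (config$n_circadian_donors > 0) {
    for (d in seq_len(config$n_circadian_donors)) {
      for (t in c("morning", "midday", "evening")) {
        ids <- c(ids, sprintf("HYcd%d.%s", d, t))
        src <- c(src, "serum"); stg <- c(stg, "healthy"); tp <- c(tp, t)
        ind <- c(ind, sprintf("HYcd%d", d))
      }
    }
  }
  for (s in names(config$stage_n)) {
    k <- config$stage_n[[s]]
    if (k > 0) {
      ids <- c(ids, sprintf("MP.%s.%02d", s, seq_len(k)))
      src <- c(src, rep("serum", k)); stg <- c(stg, rep(s, k))
      tp <- c(tp, rep(NA, k)); ind <- c(ind, rep(NA, k))
    }
  }
  n <- length(ids)
  if (n == 0) stop("configuration error: empty cohort")
  samples <- sample_table(ids, src, stg, sample(c("male", "female"), n, TRUE),
                          tp, ind)

  n_fail <- config$n_hemolytic + config$n_contaminated + config$n_poor_spike
  if (n_fail > n)
    stop("configuration error: more planted QC failures than samples")
  fate <- stats::setNames(rep("clean", n), ids)
  failing <- sample(ids, n_fail)
  fate[failing[seq_len(config$n_hemolytic)]] <- "hemolytic"
  fate[failing[config$n_hemolytic + seq_len(config$n_contaminated)]] <-
    "contaminated"
  fate[failing[config$n_hemolytic + config$n_contaminated +
                 seq_len(config$n_poor_spike)]] <- "poor_spike_recovery"

  m <- matrix(NA_real_, n, length(panel$assay_id),
              dimnames = list(ids, panel$assay_id))
  noise <- function(k) stats::rnorm(k, 0, config$noise_sd)

  for (a in targets) {
    cat_a <- category[[a]]
    if (cat_a == "absent") {
      nd <- stats::runif(n) < 0.5
      v <- stats::runif(n, 31, 34.2)
      v[nd] <- NA_real_
      m[, a] <- v
    } else if (cat_a == "unstable") {
      fluct <- stats::rnorm(n)
      fluct <- (fluct - mean(fluct)) / stats::sd(fluct) * config$unstable_sd
      m[, a] <- baseline[[a]] + fluct + noise(n)
    } else {
      v <- baseline[[a]] + noise(n)
      if (cat_a == "circadian") {
        mid <- !is.na(samples$timepoint) & samples$timepoint == "midday"
        v[mid] <- v[mid] + config$circadian_delta_cq
      }
      m[, a] <- v
    }
  }
  if (!is.null(config$stage_effects)) {
    for (r in seq_len(nrow(config$stage_effects))) {
      e <- config$stage_effects[r, ]
      rows <- !is.na(samples$stage) & samples$stage == e$stage
      m[rows, e$assay] <- m[rows, e$assay] + e$delta_cq
    }
  }

  # Control assays, driven by the planted QC fate.
  for (i in seq_along(SPIKE_IDS)) {
    sp <- SPIKE_IDS[i]
    v <- config$spike_nominal_cq[i] + stats::rnorm(n, 0, config$spike_jitter_sd)
    poor <- fate == "poor_spike_recovery"
    v[poor] <- config$spike_nominal_cq[i] + config$spike_fail_shift +
      stats::rnorm(sum(poor), 0, config$spike_fail_sd)
    m[, sp] <- v
  }
  m[, "miRTC"] <- 20 + stats::rnorm(n, 0, config$spike_jitter_sd)
  m[, "PPC"] <- 19 + stats::rnorm(n, 0, config$spike_jitter_sd)
  for (sn in SNORD_IDS) {
    v <- rep(NA_real_, n)                     # normally absent in serum
    cont <- fate == "contaminated"
    v[cont] <- stats::runif(sum(cont), 25, 29)
    m[, sn] <- v
  }
  m[, HEMOLYSIS_REFERENCE] <- 25 + noise(n)
  v451 <- 22 + noise(n)
  hem <- fate == "hemolytic"
  v451[hem] <- v451[hem] + config$hemolysis_shift
  m[, HEMOLYSIS_TARGET] <- v451

  effects <- data.frame(assay = character(0), group = character(0),
                        delta_cq = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(config$stage_effects))
    effects <- data.frame(assay = config$stage_effects$assay,
                          group = paste0("stage_", config$stage_effects$stage),
                          delta_cq = config$stage_effects$delta_cq,
                          stringsAsFactors = FALSE)
  if (config$n_circadian > 0)
    effects <- rbind(effects, data.frame(
      assay = names(category)[category == "circadian"], group = "midday",
      delta_cq = config$circadian_delta_cq, stringsAsFactors = FALSE))

  truth <- list(
    mirna = data.frame(assay = targets, category = unname(category[targets]),
                       baseline_cq = unname(baseline[targets]),
                       stringsAsFactors = FALSE),
    effects = effects,
    sample_fate = data.frame(sample_id = ids, fate = unname(fate),
                             stringsAsFactors = FALSE))
  list(cq = cq_matrix(m, panel), samples = samples, truth = truth)
}

#' Generate a synthetic whole-blood reference profile
#'
#' Whole blood is dominated by cellular miRNAs; a handful of assays
#' (miR-451a, miR-16-5p and other erythrocyte/platelet miRNAs) are extremely
#' abundant (Cq < 15) and therefore disqualify serum biomarker candidates
#' that may simply leak from blood cells.
#'
#' @param panel A `panel_definition`.
#' @param seed RNG seed.
#' @param n_samples Number of whole-blood pools.
#' @return A `cq_matrix` of whole-blood Cq values.
#' @export
generate_whole_blood_reference <- function(panel, seed = 1L, n_samples = 3L) {
  set.seed(seed)
  blood_high <- intersect(
    c("hsa-miR-451a", "hsa-miR-16-5p", "hsa-miR-22-3p", "hsa-miR-1260a",
      "hsa-miR-1280"),
    panel$assay_id)
  m <- matrix(stats::runif(n_samples * nrow(panel), 18, 28),
              n_samples, nrow(panel),
              dimnames = list(sprintf("WB%d", seq_len(n_samples)),
                              panel$assay_id))
  m[, blood_high] <- stats::runif(n_samples * length(blood_high), 10, 14)
  cq_matrix(m, panel)
}

#' Default stage-differential effects of the synthetic patient cohort
#'
#' Late-stage (III/IV) shifts on melanoma-associated miRNAs: several
#' down-regulated in serum of late-stage patients (positive delta Cq) and
#' several up-regulated (negative delta Cq), with miR-211-5p planted at
#' delta Cq -6.09 in stage IV (a 2^6.09 ~ 68-fold overexpression).
#'
#' @return Data frame `assay`, `stage`, `delta_cq`.
#' @export
default_stage_effects <- function() {
  late <- function(assay, delta)
    data.frame(assay = assay, stage = c("III", "IV"),
               delta_cq = delta, stringsAsFactors = FALSE)
  rbind(
    late("hsa-miR-200c-3p", 2.5),
    late("hsa-miR-204-5p", 2.5),
    late("hsa-miR-182-5p", 2.2),
    late("hsa-miR-301a-3p", 2.0),
    late("hsa-miR-193b-3p", -2.0),
    late("hsa-miR-205-5p", -1.8),
    late("hsa-miR-720", -1.5),
    data.frame(assay = "hsa-miR-211-5p", stage = "IV", delta_cq = -6.09,
               stringsAsFactors = FALSE))
}

#' Built-in fixture configurations
#'
#' The four standard study fixtures: `healthy_cohort` (19 + 4x3 donors,
#' whole-miRNome panel), `qc_stream` (131 serum samples with 31 planted QC
#' failures: 11 hemolytic, 10 contaminated, 10 with poor spike recovery),
#' `patients` (30 healthy + 4/11/17/11/9 patients of stages 0-IV on the
#' custom panel with planted late-stage effects) and `matched_plan`
#' (matched serum/normal-skin/primary/metastasis quadruples).
#'
#' @param name One of "healthy_cohort", "qc_stream", "patients",
#'   "matched_plan".
#' @param seed Optional seed override.
#' @return A `generator_config`.
#' @export
fixture_config <- function(name, seed = NULL) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "serumiR")
  if (path == "") stop("unknown fixture: ", name)
  cfg <- read_generator_config(path)
  if (name == "patients") cfg$stage_effects <- default_stage_effects()
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
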
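#' Generate matched serum/tissue profiles with planted compartment categories
#'
#' For each matched individual a serum, normal-skin, primary-tumour and
#' metastasis profile is drawn on the custom panel.  The configured numbers
#' of miRNAs are planted as tissue-exclusive (never detected in serum),
#' serum-exclusive (never detected in tissue), serum-higher (>3-fold higher
#' mean expression in serum than tissue) and stage-gradient (expression
#' strictly increasing normal skin -> primary -> metastasis).  Named
#' melanoma-relevant assays are assigned to their literature-motivated
#' categories first (miR-3201 and miR-122-5p serum-exclusive; miR-204-5p,
#' miR-211-5p, miR-374c-5p, miR-363-3p, miR-483-5p stage-gradient;
#' miR-30b-5p, miR-374a-5p tissue-exclusive); remaining slots are filled at
#' random from the panel.
#'
#' @param config A [generator_config()] (matched-plan fields).
#' @param panel A custom `panel_definition` (88 targets).
#' @return List with `cq`, `samples` and `truth` as in [generate_cohort()].
#' @export
generate_matched_tissue_serum <- function(config = generator_config(),
                                          panel = custom_panel()) {
  if (attr(panel, "panel_kind") == "whole_miRNome")
    stop("matched tissue/serum generation expects the custom panel")
  set.seed(config$seed)
  targets <- panel_targets(panel)
  total <- config$n_tissue_exclusive + config$n_serum_exclusive +
    config$n_serum_higher + config$n_gradient
  if (total > length(targets))
    stop("configuration error: planted counts exceed panel size")

  category <- stats::setNames(rep("flat", length(targets)), targets)
  take_named <- function(anchors, k) {
    anchors <- intersect(anchors, names(category)[category == "flat"])
    utils::head(anchors, k)
  }
  assign_cat <- function(anchors, k, label) {
    chosen <- take_named(anchors, k)
    if (length(chosen) < k) {
      pool <- setdiff(names(category)[category == "flat"], chosen)
      chosen <- c(chosen, sample(pool, k - length(chosen)))
    }
    category[chosen] <<- label
  }
  assign_cat(c("hsa-miR-3201", "hsa-miR-122-5p"),
             config$n_serum_exclusive, "serum_exclusive")
  assign_cat(c("hsa-miR-204-5p", "hsa-miR-211-5p", "hsa-miR-374c-5p",
               "hsa-miR-363-3p", "hsa-miR-483-5p"),
             config$n_gradient, "stage_gradient")
  assign_cat(c("hsa-miR-30b-5p", "hsa-miR-374a-5p"),
             config$n_tissue_exclusive, "tissue_exclusive")
  assign_cat(character(0), config$n_serum_higher, "serum_higher_3x")

  baseline <- stats::setNames(stats::runif(length(targets), 22, 27), targets)
  types <- c(serum = "serum", normal_skin = "tissue_normal_skin",
             primary = "tissue_primary", metastasis = "tissue_metastasis")
  ids <- as.vector(t(outer(sprintf("IND%d", seq_len(config$n_individuals)),
                           names(types), paste, sep = ".")))
  src <- rep(unname(types), config$n_individuals)
  ind <- rep(sprintf("IND%d", seq_len(config$n_individuals)), each = 4)
  samples <- sample_table(ids, src, NA, NA, NA, ind)
  n <- length(ids)
  is_serum <- src == "serum"

  m <- matrix(NA_real_, n, nrow(panel), dimnames = list(ids, panel$assay_id))
  noise <- function(k) stats::rnorm(k, 0, config$noise_sd)
  for (a in targets) {
    v <- baseline[[a]] + noise(n)
    switch(category[[a]],
      tissue_exclusive = { v[is_serum] <- NA_real_ },
      serum_exclusive = { v[!is_serum] <- NA_real_ },
      serum_higher_3x = {
        v[is_serum] <- v[is_serum] + config$serum_higher_delta_cq },
      stage_gradient = {
        v[src == "tissue_primary"] <-
          v[src == "tissue_primary"] + config$gradient_step_cq
        v[src == "tissue_metastasis"] <-
          v[src == "tissue_metastasis"] + 2 * config$gradient_step_cq
      },
      flat = NULL)
    m[, a] <- v
  }
  for (i in seq_along(SPIKE_IDS))
    m[, SPIKE_IDS[i]] <- config$spike_nominal_cq[i] +
      stats::rnorm(n, 0, config$spike_jitter_sd)
  m[, "miRTC"] <- 20 + stats::rnorm(n, 0, config$spike_jitter_sd)
  m[, "PPC"] <- 19 + stats::rnorm(n, 0, config$spike_jitter_sd)
  for (sn in SNORD_IDS) {            # abundant in tissue, absent in serum
    v <- stats::runif(n, 18, 22)
    v[is_serum] <- NA_real_
    m[, sn] <- v
  }
  m[, HEMOLYSIS_REFERENCE] <- 25 + noise(n)
  m[, HEMOLYSIS_TARGET] <- 22 + noise(n)

  truth <- list(
    mirna = data.frame(assay = targets, category = unname(category[targets]),
                       baseline_cq = unname(baseline[targets]),
                       stringsAsFactors = FALSE),
    effects = data.frame(assay = character(0), group = character(0),
                         delta_cq = numeric(0)),
    sample_fate = data.frame(sample_id = ids, fate = "clean",
                             stringsAsFactors = FALSE))
  list(cq = cq_matrix(m, panel), samples = samples, truth = truth)
}
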
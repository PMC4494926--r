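#' Categorize the healthy miRNome
#'
#' Assigns every target miRNA to exactly one of five disjoint categories,
#' evaluated in a fixed precedence order on calibrated, uncensored Cq:
#' \enumerate{
#'   \item `not_expressed` — not detected, or Cq > 30, in all samples;
#'   \item `bad_meltcurve` — bad melt label in more than 80% of samples;
#'   \item `unstable` — across-sample Cq SD above 1 cycle (computed over
#'     detected samples, requiring detection in at least 50% of samples so
#'     absent miRNAs cannot be "unstable");
#'   \item `high_expression` — Cq below 27 in more than 80% of samples;
#'   \item `low_expression` — everything else.
#' }
#' The precedence makes the five slices of the summary pie disjoint.
#'
#' @param cq A calibrated, uncensored `cq_matrix` of the healthy cohort.
#' @param melt_bad Optional logical matrix (samples x assays) of bad melt
#'   calls.
#' @param sd_cutoff Instability cutoff on the across-sample Cq SD.
#' @param high_cq,high_frac High expression: Cq below `high_cq` in more
#'   than `high_frac` of samples.
#' @param na_cq Not-expressed bound: Cq above this in all samples.
#' @return A `mirnome_catalog` data frame: `assay`, `category`, `mean_cq`,
#'   `sd_cq`, `detection_fraction`, `mean_expression` (global-mean
#'   normalized, detected samples).
#' @export
categorize_mirnome <- function(cq, melt_bad = NULL, sd_cutoff = 1,
                               high_cq = 27, high_frac = 0.8, na_cq = 30) {
  targets <- target_columns(cq)
  v <- cq$values[, targets, drop = FALSE]
  if (nrow(v) == 0) stop("empty cohort")
  n <- nrow(v)
  expr <- tryCatch(global_mean_normalize(censor_cq(cq, cutoff = na_cq)),
                   error = function(e) NULL)

  category <- character(length(targets))
  mean_cq <- sd_cq <- detfrac <- mean_expr <- numeric(length(targets))
  for (j in seq_along(targets)) {
    x <- v[, j]
    det <- !is.na(x)
    detfrac[j] <- mean(det)
    mean_cq[j] <- if (any(det)) mean(x[det]) else NA_real_
    sd_cq[j] <- if (sum(det) > 1) stats::sd(x[det]) else NA_real_
    bad_frac <- if (is.null(melt_bad)) 0
      else mean(melt_bad[rownames(v), targets[j]])
    category[j] <-
      if (all(!det | x > na_cq)) "not_expressed"
      else if (bad_frac > 0.8) "bad_meltcurve"
      else if (detfrac[j] >= 0.5 && !is.na(sd_cq[j]) && sd_cq[j] > sd_cutoff)
        "unstable"
      else if (mean(det & x < high_cq) > high_frac) "high_expression"
      else "low_expression"
    mean_expr[j] <- if (!is.null(expr) && targets[j] %in% colnames(expr$values))
      mean(expr$values[, targets[j]], na.rm = TRUE) else NA_real_
  }
  out <- data.frame(assay = targets, category = category, mean_cq = mean_cq,
                    sd_cq = sd_cq, detection_fraction = detfrac,
                    mean_expression = mean_expr,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mirnome_catalog", "data.frame")
  out
}

#' @export
print.mirnome_catalog <- function(x, ...) {
  tab <- table(factor(x$category,
                      levels = c("not_expressed", "bad_meltcurve",
                                 "low_expression", "high_expression",
                                 "unstable")))
  cat(sprintf("<mirnome_catalog> %d target miRNAs\n", nrow(x)))
  for (k in names(tab))
    cat(sprintf("  %-15s %4d (%.1f%%)\n", k, tab[[k]],
                100 * tab[[k]] / nrow(x)))
  invisible(x)
}

#' Circadian (midday) candidate analysis
#'
#' Looks for miRNAs with a measurably different expression at one timepoint
#' only.  Per-sample delta Cq values (global-mean normalized, which also
#' cancels calibration constants) are averaged per timepoint over the
#' circadian donors; a miRNA is a midday candidate iff its midday mean
#' deviates from both the morning and the evening mean by at least `delta`
#' cycles with the same sign, while morning and evening agree within
#' `delta / 2` (a single-timepoint deviation).  The fold change compares
#' midday expression with the mean of the two other timepoints.
#'
#' A fluctuating miRNA is not a circadian candidate: assays whose
#' across-sample Cq SD outside the midday timepoint exceeds the
#' instability cutoff are excluded, so inter-individual instability is not
#' mistaken for a time-of-day effect.
#'
#' @param cq A calibrated `cq_matrix` including the circadian samples.
#' @param samples The matching `sample_table`; donors missing a timepoint
#'   are dropped (logged).
#' @param delta Minimal midday deviation in cycles.  The default 1.25
#'   (about 2.4-fold) balances, at the default noise level with four
#'   donors, the power of the two midday gates against the
#'   morning/evening consistency gate.
#' @param max_sd Instability cutoff applied to the non-midday samples.
#' @return Data frame of midday candidates: `assay`, `delta_midday` (Cq),
#'   `fold_change`, `sd`.
#' @export
circadian_analysis <- function(cq, samples, delta = 1.25, max_sd = 1) {
  check_samples_match(cq, samples)
  circ <- samples[!is.na(samples$timepoint), , drop = FALSE]
  tps <- c("morning", "midday", "evening")
  keep <- vapply(split(circ$timepoint, circ$individual_id),
                 function(x) all(tps %in% x), logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped))
    message("dropping donor(s) missing a timepoint: ",
            paste(dropped, collapse = ", "))
  circ <- circ[circ$individual_id %in% names(keep)[keep], , drop = FALSE]
  if (length(unique(circ$individual_id)) < 2)
    stop("need at least 2 donors with complete timepoint triples")

  expr <- global_mean_normalize(censor_cq(cq, cutoff = 30),
                                common_only = TRUE)
  dcq <- -log2(expr$values[circ$sample_id, , drop = FALSE])  # normalized delta Cq
  tp_mean <- function(t) colMeans(dcq[circ$timepoint == t, , drop = FALSE],
                                  na.rm = TRUE)
  mo <- tp_mean("morning"); mi <- tp_mean("midday"); ev <- tp_mean("evening")
  d_mo <- mi - mo; d_ev <- mi - ev
  mid_ids <- circ$sample_id[circ$timepoint == "midday"]
  non_mid <- setdiff(rownames(cq$values), mid_ids)
  off_sd <- apply(cq$values[non_mid, colnames(dcq), drop = FALSE], 2,
                  stats::sd, na.rm = TRUE)
  cand <- !is.na(d_mo) & !is.na(d_ev) &
    abs(d_mo) >= delta & abs(d_ev) >= delta & sign(d_mo) == sign(d_ev) &
    abs(mo - ev) < delta / 2 &
    !is.na(off_sd) & off_sd <= max_sd

  assays <- colnames(dcq)[cand]
  rows <- lapply(assays, function(a) {
    e <- expr$values[circ$sample_id, a]
    mid <- circ$timepoint == "midday"
    fc_per_donor <- e[mid] / mean(e[!mid], na.rm = TRUE)
    data.frame(assay = a, delta_midday = mi[[a]] - (mo[[a]] + ev[[a]]) / 2,
               fold_change = mean(e[mid], na.rm = TRUE) /
                 mean(e[!mid], na.rm = TRUE),
               sd = stats::sd(fc_per_donor, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(assay = character(0), delta_midday = numeric(0),
                    fold_change = numeric(0), sd = numeric(0))
  rownames(out) <- NULL
  out
}

#' Averaged healthy reference miRNome
#'
#' Per-miRNA mean and SD of calibrated Cq and of normalized expression over
#' all (QC-passed) healthy samples; the table new cohorts are compared
#' against.
#'
#' @param cq A calibrated `cq_matrix` of healthy samples.
#' @return Data frame `assay`, `mean_cq`, `sd_cq`, `detection_fraction`,
#'   `mean_expression`, `sd_expression`.
#' @export
reference_profile <- function(cq) {
  targets <- target_columns(cq)
  v <- cq$values[, targets, drop = FALSE]
  expr <- tryCatch(global_mean_normalize(censor_cq(cq, cutoff = 30))$values,
                   error = function(e) NULL)
  data.frame(
    assay = targets,
    mean_cq = colMeans(v, na.rm = TRUE),
    sd_cq = apply(v, 2, stats::sd, na.rm = TRUE),
    detection_fraction = colMeans(!is.na(v)),
    mean_expression = if (is.null(expr)) NA_real_
      else colMeans(expr, na.rm = TRUE),
    sd_expression = if (is.null(expr)) NA_real_
      else apply(expr, 2, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}
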
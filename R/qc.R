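#' Default QC thresholds
#'
#' Hemolysis: a Cq(miR-23a-5p) - Cq(miR-451a) difference above 5 cycles
#' fails the sample (values in (5, 7] are additionally reported as
#' borderline for manual review).  Contamination: any blood-cell SNORD/RNU6
#' detected below Cq 32 counts as a hit.  Spike recovery: any spike-in more
#' than 2 cycles from the batch median, or undetected, fails.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(hemolysis_delta = 5, hemolysis_borderline = 7,
       contamination_cq = 32, spike_tolerance = 2)
}

#' Hemolysis indicator
#'
#' Cq(miR-23a-5p) - Cq(miR-451a) per sample, on raw (pre-calibration) Cq:
#' per-sample calibration shifts cancel in the within-sample difference.
#' miR-451a is strongly enriched in erythrocytes, so a large delta means
#' red-cell lysis is contaminating the serum miRNA pool.  The delta is
#' undefined (NA, sample flagged for manual review) when either assay of
#' the pair is not detected.
#'
#' @param cq A `cq_matrix` containing both pair assays.
#' @return Named numeric vector of per-sample deltas.
#' @export
hemolysis_indicator <- function(cq) {
  v <- cq$values
  if (!all(c(HEMOLYSIS_TARGET, HEMOLYSIS_REFERENCE) %in% colnames(v)))
    stop("hemolysis pair assays not on panel")
  v[, HEMOLYSIS_REFERENCE] - v[, HEMOLYSIS_TARGET]
}

#' Blood-cell contamination check
#'
#' The SNORDs and RNU6-2 are highly expressed in blood cells and normally
#' absent from serum; detecting any of them below the contamination bound
#' flags cellular contamination.
#'
#' @param cq A `cq_matrix`.
#' @param bound Cq bound below which a detected SNORD counts as a hit.
#' @return Named list (per sample) of character vectors of hit assays.
#' @export
contamination_check <- function(cq, bound = qc_thresholds()$contamination_cq) {
  snords <- intersect(SNORD_IDS, colnames(cq$values))
  if (!length(snords)) stop("no blood-cell control assays on panel")
  v <- cq$values[, snords, drop = FALSE]
  hits <- !is.na(v) & v < bound
  lapply(stats::setNames(seq_len(nrow(v)), rownames(v)),
         function(i) snords[hits[i, ]])
}

#' Spike-in recovery check
#'
#' Per spike-in, the absolute deviation of each sample's Cq from the batch
#' median; recovery fails when any spike deviates by more than the
#' tolerance or is not detected.
#'
#' @param cq A `cq_matrix`.
#' @return Matrix samples x spikes of |Cq - batch median| (NA where the
#'   spike was not detected).
#' @export
spike_recovery <- function(cq) {
  spikes <- intersect(SPIKE_IDS, colnames(cq$values))
  if (!length(spikes)) stop("no spike-in assays on panel")
  if (nrow(cq$values) == 1)
    warning("single-sample batch: spike deviations are 0 by definition")
  v <- cq$values[, spikes, drop = FALSE]
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  abs(sweep(v, 2, med))
}

#' Per-sample QC verdict
#'
#' Combines the hemolysis indicator, the blood-cell contamination check and
#' spike-in recovery into an include/exclude verdict: a sample fails if and
#' only if at least one criterion fails.  Failing is data, not an error.
#'
#' @param cq A `cq_matrix` (raw Cq).
#' @param thresholds See [qc_thresholds()].
#' @return A `qc_report`: data frame with per-sample `hemolysis_delta`,
#'   `hemolysis_borderline`, `contamination_hits` (comma-separated),
#'   `max_spike_deviation`, `verdict` ("pass"/"fail") and `fail_reasons`.
#' @export
qc_verdict <- function(cq, thresholds = qc_thresholds()) {
  delta <- hemolysis_indicator(cq)
  hits <- contamination_check(cq, thresholds$contamination_cq)
  dev <- spike_recovery(cq)
  ids <- rownames(cq$values)

  hem_fail <- !is.na(delta) & delta > thresholds$hemolysis_delta
  hem_review <- is.na(delta)
  cont_fail <- lengths(hits) > 0
  spike_fail <- apply(dev, 1, function(d)
    any(is.na(d)) || any(d > thresholds$spike_tolerance))

  reasons <- mapply(function(h, c, s) {
    paste(c(if (h) "hemolysis", if (c) "contamination",
            if (s) "spike_recovery"), collapse = ",")
  }, hem_fail, cont_fail, spike_fail)
  rep <- data.frame(
    sample_id = ids,
    hemolysis_delta = unname(delta),
    hemolysis_borderline = unname(!is.na(delta) &
      delta > thresholds$hemolysis_delta &
      delta <= thresholds$hemolysis_borderline),
    needs_manual_review = unname(hem_review),
    contamination_hits = unname(vapply(hits, paste, "", collapse = ",")),
    max_spike_deviation = unname(apply(dev, 1, max)),
    verdict = unname(ifelse(hem_fail | cont_fail | spike_fail,
                            "fail", "pass")),
    fail_reasons = unname(reasons),
    stringsAsFactors = FALSE)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples: %d pass, %d fail\n",
              nrow(x), sum(x$verdict == "pass"), sum(x$verdict == "fail")))
  if (any(x$verdict == "fail")) {
    tab <- table(unlist(strsplit(x$fail_reasons[x$verdict == "fail"], ",")))
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Drop QC-failed samples from a Cq matrix
#' @param cq A `cq_matrix`.
#' @param report A `qc_report` from [qc_verdict()].
#' @return The `cq_matrix` restricted to passing samples.
#' @export
apply_qc <- function(cq, report) {
  subset_samples(cq, report$sample_id[report$verdict == "pass"])
}
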
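#' cel-39 inter-sample calibration
#'
#' The cel-39 spike-in is added at a fixed amount to every sample before
#' extraction, so its Cq differences between samples reflect technical
#' recovery/amplification differences.  Calibration computes each sample's
#' cel-39 mean, takes the highest mean over all samples, and adds the
#' difference (the correction factor, >= 0) to every Cq value of the
#' sample.  After calibration all cel-39 means equal the batch maximum;
#' within-sample differences between assays are unchanged, and the
#' operation is idempotent.
#'
#' @param cq A `cq_matrix`; cel-39 must be detected in every sample.
#' @return Calibrated `cq_matrix` with per-sample corrections in the
#'   `corrections` attribute.
#' @export
calibrate_cel39 <- function(cq) {
  v <- cq$values
  if (!CEL39 %in% colnames(v)) stop("cel-39 assay not on panel")
  cel <- v[, colnames(v) == CEL39, drop = FALSE]
  cel_mean <- rowMeans(cel)
  if (any(is.na(cel_mean)))
    stop("cel-39 not detected in sample(s): ",
         paste(rownames(v)[is.na(cel_mean)], collapse = ", "))
  correction <- max(cel_mean) - cel_mean
  out <- cq_matrix(v + correction, cq$panel, calibrated = TRUE,
                   censored = cq$censored)
  attr(out, "corrections") <- correction
  out
}

#' Censor undetectable and unspecific wells
#'
#' Calibrated Cq values greater than the cutoff (strictly; the boundary
#' value is kept), as well as wells whose melt curve was classified bad,
#' are set to not detected.  Bad melt curves are censored regardless of
#' their Cq, since a low Cq with an unspecific product is still not a
#' measurement of the target.  The mask is sticky: downstream stages never
#' resurrect censored wells.
#'
#' @param cq A calibrated `cq_matrix`.
#' @param melt_bad Optional logical matrix (same dimnames) marking wells
#'   with bad (or, under the conservative default policy, questionable)
#'   melt curves.
#' @param cutoff Cq cutoff; the default 30 reflects the 12 extra
#'   pre-amplification PCR cycles.
#' @return Censored `cq_matrix`.
#' @export
censor_cq <- function(cq, melt_bad = NULL, cutoff = 30) {
  if (!cq$calibrated)
    warning("censoring is specified on calibrated Cq values")
  v <- cq$values
  v[!is.na(v) & v > cutoff] <- NA_real_
  if (!is.null(melt_bad)) {
    melt_bad <- melt_bad[rownames(v), colnames(v), drop = FALSE]
    v[melt_bad] <- NA_real_
  }
  cq_matrix(v, cq$panel, calibrated = cq$calibrated, censored = TRUE)
}

new_rel_expr <- function(values, method, ref_cq, panel) {
  structure(list(values = values, method = method, ref_cq = ref_cq,
                 panel = panel),
            class = "rel_expr")
}

#' @export
print.rel_expr <- function(x, ...) {
  cat(sprintf("<rel_expr> %d samples x %d assays, method=%s\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Global-mean normalization
#'
#' Per sample, delta Cq = Cq - mean of the sample's detected target Cq
#' values ("global plate mean"); relative expression = 2^(-delta Cq).
#' Control assays are excluded from the mean and from the output.  The
#' geometric mean of each sample's detected expressions is 1 by
#' construction.
#'
#' With `common_only = TRUE` the per-sample mean is taken over the assays
#' detected in every sample instead.  This keeps the reference composition
#' identical across samples, which matters when sample means are compared
#' directly (censoring near the cutoff otherwise shifts each sample's mean
#' by a different amount).
#'
#' @param cq A censored `cq_matrix`.
#' @param common_only Use only assays detected in all samples for the
#'   per-sample mean.
#' @return A `rel_expr` (samples x target assays); per-sample reference Cq
#'   means are kept in `$ref_cq`.
#' @export
global_mean_normalize <- function(cq, common_only = FALSE) {
  v <- cq$values[, target_columns(cq), drop = FALSE]
  ref_cols <- if (common_only) {
    common <- colSums(is.na(v)) == 0
    if (!any(common)) stop("no assays detected in all samples")
    v[, common, drop = FALSE]
  } else v
  ref <- rowMeans(ref_cols, na.rm = TRUE)
  if (any(is.nan(ref)))
    stop("sample(s) with zero detected assays: ",
         paste(rownames(v)[is.nan(ref)], collapse = ", "))
  expr <- 2^(-(v - ref))
  new_rel_expr(expr, "global_mean", ref, cq$panel)
}

#' Stable-reference normalization
#'
#' Per sample, delta Cq = Cq - mean Cq of the five most stable assays of
#' the consensus ranking; relative expression = 2^(-delta Cq).  If a top-5
#' assay is masked in any sample it is replaced by the next-ranked
#' candidate (logged via message).
#'
#' @param cq A censored `cq_matrix`.
#' @param ranking A `stability_ranking` from [stability_rank()].
#' @param n_refs Number of reference assays (default 5).
#' @return A `rel_expr` with the reference set in the `references`
#'   attribute.
#' @export
stable_reference_normalize <- function(cq, ranking, n_refs = 5L) {
  ord <- ranking$assay[order(ranking$consensus_rank)]
  if (length(ord) < n_refs)
    stop("ranking has fewer than ", n_refs, " candidates")
  v_all <- cq$values
  refs <- character(0)
  for (a in ord) {
    if (length(refs) == n_refs) break
    if (anyNA(v_all[, a])) {
      message("reference ", a, " masked in some sample; using next rank")
      next
    }
    refs <- c(refs, a)
  }
  if (length(refs) < n_refs)
    stop("fewer than ", n_refs, " fully detected reference candidates")
  ref <- rowMeans(v_all[, refs, drop = FALSE])
  v <- v_all[, target_columns(cq), drop = FALSE]
  expr <- 2^(-(v - ref))
  out <- new_rel_expr(expr, "stable5", ref, cq$panel)
  attr(out, "references") <- refs
  out
}

#' Fold change between two sample groups
#'
#' FC = mean expression in group A / mean expression in group B
#' (equivalently 2^(-delta delta Cq) on group means), with an SD taken over
#' the per-sample ratios expr_A(i) / mean(expr_B).  An assay must be
#' detected in at least half of each group; an assay undetected in a whole
#' group has no finite fold change (compartment-exclusive calls are the
#' business of the tissue/serum comparison).
#'
#' @param expr A `rel_expr`.
#' @param group_a,group_b Character vectors of sample ids.
#' @return Data frame `assay`, `fold_change`, `sd`, `n_a`, `n_b`;
#'   `fold_change` is NA where the detection requirement fails.
#' @export
fold_change <- function(expr, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  va <- expr$values[group_a, , drop = FALSE]
  vb <- expr$values[group_b, , drop = FALSE]
  det_a <- colMeans(!is.na(va))
  det_b <- colMeans(!is.na(vb))
  mean_a <- colMeans(va, na.rm = TRUE)
  mean_b <- colMeans(vb, na.rm = TRUE)
  fc <- mean_a / mean_b
  ok <- det_a >= 0.5 & det_b >= 0.5
  fc[!ok] <- NA_real_
  sdv <- vapply(seq_len(ncol(va)), function(j) {
    if (!ok[j]) return(NA_real_)
    stats::sd(va[, j] / mean_b[j], na.rm = TRUE)
  }, numeric(1))
  data.frame(assay = colnames(va), fold_change = unname(fc), sd = sdv,
             n_a = unname(colSums(!is.na(va))),
             n_b = unname(colSums(!is.na(vb))),
             row.names = NULL, stringsAsFactors = FALSE)
}
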
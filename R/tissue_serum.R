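#' Compare matched serum and tissue compartments
#'
#' Per miRNA, mean normalized expression per sample type (serum, normal
#' skin, primary tumour, metastasis) over the matched individuals, the
#' serum/tissue ratio (tissue pools all three tissue types) and the
#' compartment categories:
#' \itemize{
#'   \item `tissue_exclusive` — detected in at least one tissue sample and
#'     undetected in every serum sample (panel-level call);
#'   \item `serum_exclusive` — the symmetric case;
#'   \item `serum_higher_3x` — detected in both compartments with mean
#'     serum expression more than 3-fold above mean tissue expression.
#' }
#' Serum-vs-tissue comparisons are semi-quantitative: serum input amounts
#' may vary more than tissue input amounts, which is reported as a footnote
#' attribute, not a computation.
#'
#' @param expr A `rel_expr` of the matched samples.
#' @param samples The matching `sample_table`.
#' @param ratio_bound Serum/tissue ratio bound for the serum-higher call.
#' @return A `tissue_serum_comparison` data frame.
#' @export
compare_compartments <- function(expr, samples, ratio_bound = 3) {
  src <- samples$source[match(rownames(expr$values), samples$sample_id)]
  is_serum <- src == "serum"
  tissue_types <- c("tissue_normal_skin", "tissue_primary",
                    "tissue_metastasis")
  is_tissue <- src %in% tissue_types
  if (!any(is_serum) || !any(is_tissue))
    stop("need matched serum and tissue samples")
  paired <- intersect(samples$individual_id[is_serum[match(samples$sample_id,
                        rownames(expr$values))]],
                      samples$individual_id[samples$source %in% tissue_types])
  if (!length(paired)) stop("no matched serum/tissue individuals")

  v <- expr$values
  mean_by <- function(rows) colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
  m_serum <- mean_by(is_serum)
  m_tissue <- mean_by(is_tissue)
  det_serum <- colSums(!is.na(v[is_serum, , drop = FALSE])) > 0
  det_tissue <- colSums(!is.na(v[is_tissue, , drop = FALSE])) > 0

  ratio <- ifelse(det_serum & det_tissue, m_serum / m_tissue, NA_real_)
  out <- data.frame(
    assay = colnames(v),
    mean_serum = ifelse(det_serum, m_serum, NA_real_),
    mean_normal_skin = mean_by(src == "tissue_normal_skin"),
    mean_primary = mean_by(src == "tissue_primary"),
    mean_metastasis = mean_by(src == "tissue_metastasis"),
    serum_tissue_ratio = unname(ratio),
    tissue_exclusive = unname(det_tissue & !det_serum),
    serum_exclusive = unname(det_serum & !det_tissue),
    serum_higher_3x = unname(!is.na(ratio) & ratio > ratio_bound),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "footnote") <- paste(
    "Serum-vs-tissue comparisons are semi-quantitative: serum input",
    "amounts may vary and be less consistent than tissue input amounts.")
  class(out) <- c("tissue_serum_comparison", "data.frame")
  out
}

#' @export
print.tissue_serum_comparison <- function(x, ...) {
  cat(sprintf(paste0("<tissue_serum_comparison> %d assays: %d tissue-",
                     "exclusive, %d serum-exclusive, %d serum >%s-fold\n"),
              nrow(x), sum(x$tissue_exclusive), sum(x$serum_exclusive),
              sum(x$serum_higher_3x), "3"))
  cat(strwrap(attr(x, "footnote"), prefix = "  "), sep = "\n")
  invisible(x)
}

#' Stage-gradient flag
#'
#' A miRNA shows a disease-progression gradient when its mean tissue
#' expression strictly increases normal skin -> primary tumour ->
#' metastasis, with each step exceeding a minimum fold ratio.
#'
#' @param expr A `rel_expr` of the matched samples.
#' @param samples The matching `sample_table`.
#' @param min_step_ratio Minimum per-step fold increase.
#' @return Named logical vector per assay (all NA when a tissue type is
#'   missing, logged).
#' @export
stage_gradient <- function(expr, samples, min_step_ratio = 1.5) {
  src <- samples$source[match(rownames(expr$values), samples$sample_id)]
  types <- c("tissue_normal_skin", "tissue_primary", "tissue_metastasis")
  if (!all(types %in% src)) {
    message("missing tissue type: gradient flags undefined")
    return(stats::setNames(rep(NA, ncol(expr$values)),
                           colnames(expr$values)))
  }
  v <- expr$values
  m <- vapply(types, function(tp)
    colMeans(v[src == tp, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(v)))
  if (!is.matrix(m))
    m <- matrix(m, nrow = 1, dimnames = list(colnames(v), types))
  flag <- m[, 2] > min_step_ratio * m[, 1] &
    m[, 3] > min_step_ratio * m[, 2]
  flag[is.na(flag)] <- FALSE
  flag
}
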
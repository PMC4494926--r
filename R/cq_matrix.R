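#' Construct a Cq matrix
#'
#' The central object of the pipeline: a samples x assays matrix of
#' quantification-cycle values.  Not-detected wells are stored as `NA`;
#' detected values must be finite and in (0, 45].
#'
#' @param values Numeric matrix (samples x assays) with row and column names;
#'   `NA` marks not-detected wells.
#' @param panel The `panel_definition` the columns belong to.
#' @param calibrated Logical; has cel-39 calibration been applied?
#' @param censored Logical; has the Cq cutoff / melt censoring been applied?
#' @return A `cq_matrix` object.
#' @export
cq_matrix <- function(values, panel, calibrated = FALSE, censored = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample (row) and assay (column) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("sample and assay ids must be unique")
  if (!all(colnames(values) %in% panel$assay_id))
    stop("columns not in panel: ",
         paste(setdiff(colnames(values), panel$assay_id), collapse = ", "))
  det <- values[!is.na(values)]
  if (length(det) && (any(!is.finite(det)) || any(det <= 0) || any(det > 45)))
    stop("detected Cq values must be finite and in (0, 45]")
  structure(list(values = values, panel = panel,
                 calibrated = calibrated, censored = censored),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cq_matrix> %d samples x %d assays (%s, %s); %.1f%% detected\n",
              nrow(v), ncol(v),
              if (x$calibrated) "calibrated" else "raw",
              if (x$censored) "censored" else "uncensored",
              100 * mean(!is.na(v))))
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$values)

#' @export
as.matrix.cq_matrix <- function(x, ...) x$values

#' Detection mask of a Cq matrix
#' @param cq A `cq_matrix`.
#' @return Logical matrix, `TRUE` where the well was detected.
#' @export
is_detected <- function(cq) !is.na(cq$values)

#' Subset a Cq matrix by samples
#' @param cq A `cq_matrix`.
#' @param sample_ids Row names to keep.
#' @export
subset_samples <- function(cq, sample_ids) {
  missing <- setdiff(sample_ids, rownames(cq$values))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "))
  cq_matrix(cq$values[sample_ids, , drop = FALSE], cq$panel,
            calibrated = cq$calibrated, censored = cq$censored)
}

# Columns of the Cq matrix that are target miRNAs (not controls).
target_columns <- function(cq) {
  intersect(colnames(cq$values), panel_targets(cq$panel))
}

#' Construct a sample metadata table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param source One of serum, plasma, whole_blood, tissue_normal_skin,
#'   tissue_primary, tissue_metastasis, cell_line.
#' @param stage healthy, 0, I, II, III, IV or NA (non-patient material).
#' @param gender male, female or NA.
#' @param timepoint morning, midday, evening or NA.
#' @param individual_id Donor identifier linking matched samples; NA if
#'   unmatched.
#' @return A `sample_table` data frame.
#' @export
sample_table <- function(sample_id, source = "serum", stage = NA,
                         gender = NA, timepoint = NA, individual_id = NA) {
  sources <- c("serum", "plasma", "whole_blood", "tissue_normal_skin",
               "tissue_primary", "tissue_metastasis", "cell_line")
  stages <- c("healthy", "0", "I", "II", "III", "IV")
  tps <- c("morning", "midday", "evening")
  st <- data.frame(sample_id = as.character(sample_id),
                   source = as.character(source),
                   stage = as.character(stage),
                   gender = as.character(gender),
                   timepoint = as.character(timepoint),
                   individual_id = as.character(individual_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(st$sample_id)) stop("sample ids must be unique")
  if (!all(st$source %in% sources)) stop("invalid sample source")
  if (!all(is.na(st$stage) | st$stage %in% stages)) stop("invalid stage")
  if (!all(is.na(st$timepoint) | st$timepoint %in% tps))
    stop("invalid timepoint")
  class(st) <- c("sample_table", "data.frame")
  st
}

# Check that every cq row has exactly one sample_table entry.
check_samples_match <- function(cq, samples) {
  if (!setequal(rownames(cq$values), samples$sample_id))
    stop("cq_matrix rows and sample_table entries do not match")
  invisible(TRUE)
}
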
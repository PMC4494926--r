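#' @name plate_io
#' @title Reading and writing plate exports
#' @description Long (tidy) CSV/TSV is the canonical interchange format:
#'   one row per well with `sample_id, assay_id, cq, detected`.  Not-detected
#'   wells are written with the Cq 35 sentinel and `detected = FALSE`;
#'   blank or "N/A" Cq fields on read are mapped to not-detected.  All
#'   temperatures are degrees Celsius and all Cq values cycles; no unit
#'   conversion happens anywhere.
NULL

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

# Not-detected sentinel used in written files.
ND_SENTINEL <- 35

#' Read a long-format Cq table
#'
#' @param path CSV/TSV file with columns `sample_id`, `assay_id`, `cq`
#'   (and optionally `detected`).  `cq` values of "N/A", "NA" or blank are
#'   treated as not detected, as is `detected = FALSE`.
#' @param panel `panel_definition` the assays must belong to.
#' @return A `cq_matrix` (raw: uncalibrated, uncensored).
#' @export
read_cq_table <- function(path, panel) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "assay_id", "cq")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$assay_id), panel$assay_id)
  if (length(bad))
    stop("assays not in panel: ", paste(utils::head(bad, 5), collapse = ", "))
  cqs <- suppressWarnings(as.numeric(df$cq))
  nd <- df$cq %in% c("", "N/A", "NA") | is.na(cqs)
  malformed <- which(nd & !(df$cq %in% c("", "N/A", "NA")))
  if (length(malformed))
    stop("malformed Cq value at data line ", malformed[1])
  if ("detected" %in% names(df))
    nd <- nd | !as.logical(df$detected)
  cqs[nd] <- NA_real_
  samples <- unique(df$sample_id)
  assays <- unique(df$assay_id)
  m <- matrix(NA_real_, length(samples), length(assays),
              dimnames = list(samples, assays))
  m[cbind(match(df$sample_id, samples), match(df$assay_id, assays))] <- cqs
  cq_matrix(m, panel)
}

#' Write a Cq matrix as a long-format table
#'
#' @param cq A `cq_matrix`.
#' @param path Output CSV/TSV path.
#' @export
write_cq_table <- function(cq, path) {
  v <- cq$values
  df <- data.frame(
    sample_id = rep(rownames(v), times = ncol(v)),
    assay_id = rep(colnames(v), each = nrow(v)),
    cq = as.vector(v),
    detected = !is.na(as.vector(v)),
    stringsAsFactors = FALSE)
  df$cq[is.na(df$cq)] <- ND_SENTINEL
  df$cq <- formatC(df$cq, digits = 17, format = "g")
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a melt-curve export
#'
#' Generic CSV/TSV schema with columns `well_id`, `temperature`, `signal`
#' (the post-run dissociation signal, interpreted as -dF/dT) and optionally
#' `assay_id` and `cq`.  Temperatures must be strictly increasing within a
#' well.
#'
#' @param path File path.
#' @return List of `melt_curve` objects, in order of first appearance.
#' @export
read_melt_export <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE)
  need <- c("well_id", "temperature", "signal")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  wells <- unique(df$well_id)
  lapply(wells, function(w) {
    sub <- df[df$well_id == w, , drop = FALSE]
    if (any(diff(sub$temperature) <= 0))
      stop("non-monotone temperature grid in well ", w)
    melt_curve(well_id = w,
               assay_id = if ("assay_id" %in% names(sub)) sub$assay_id[1] else NA,
               temperature = sub$temperature,
               signal = sub$signal,
               cq = if ("cq" %in% names(sub))
                 suppressWarnings(as.numeric(sub$cq[1])) else NA_real_)
  })
}

#' Write melt curves to a long-format export
#' @param curves List of `melt_curve` objects.
#' @param path Output CSV/TSV path.
#' @export
write_melt_export <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(well_id = cv$well_id, assay_id = cv$assay_id,
               temperature = formatC(cv$temperature, digits = 17, format = "g"),
               signal = formatC(cv$signal, digits = 17, format = "g"),
               cq = cv$cq, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#' @param path CSV/TSV path.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, sep = delim_for(path), stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sample_table(df$sample_id, df$source, df$stage, df$gender,
               df$timepoint, df$individual_id)
}

#' @rdname read_sample_table
#' @param samples A `sample_table`.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a generator configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [generator_config()].
#' @param path YAML file.
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

#' Write a generator configuration to YAML
#' @param config A `generator_config`.
#' @param path Output path.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
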
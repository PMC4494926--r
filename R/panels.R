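#' Control assays shared by all panels
#'
#' The qPCR panels carry, besides the target miRNAs, a fixed set of control
#' assays: three exogenous C. elegans spike-ins added at three different
#' concentrations (cel-39 also anchors inter-sample calibration), a reverse
#' transcription control (miRTC), a PCR positive control (PPC), six small
#' RNAs abundant in blood cells but normally absent from serum (the SNORDs
#' and RNU6-2, used to flag cellular contamination), and the hemolysis pair
#' miR-451a (erythrocyte-enriched) / miR-23a-5p (serum-stable).
#'
#' @return Named character vector mapping assay id to assay class.
#' @export
control_assays <- function() {
  c("cel-miR-39-3p"   = "spike",
    "cel-miR-54-3p"   = "spike",
    "cel-miR-238-3p"  = "spike",
    "miRTC"           = "rt_control",
    "PPC"             = "pcr_control",
    "SNORD61"         = "snord",
    "SNORD68"         = "snord",
    "SNORD72"         = "snord",
    "SNORD95"         = "snord",
    "SNORD96A"        = "snord",
    "RNU6-2"          = "snord",
    "hsa-miR-451a"    = "hemolysis_pair",
    "hsa-miR-23a-5p"  = "hemolysis_pair")
}

# Assay ids used by the QC and calibration stages.
CEL39 <- "cel-miR-39-3p"
SPIKE_IDS <- c("cel-miR-39-3p", "cel-miR-54-3p", "cel-miR-238-3p")
SNORD_IDS <- c("SNORD61", "SNORD68", "SNORD72", "SNORD95", "SNORD96A", "RNU6-2")
HEMOLYSIS_TARGET <- "hsa-miR-451a"   # red-cell enriched
HEMOLYSIS_REFERENCE <- "hsa-miR-23a-5p"

# miRNAs of specific interest on the custom melanoma panel (miRBase v16
# naming).  The remainder of each panel is filled with systematically named
# assays; names are opaque strings to every pipeline stage.
named_custom_targets <- function() {
  c("hsa-miR-211-5p", "hsa-miR-200c-3p", "hsa-miR-204-5p", "hsa-miR-182-5p",
    "hsa-miR-301a-3p", "hsa-miR-193b-3p", "hsa-miR-720", "hsa-miR-205-5p",
    "hsa-miR-3201", "hsa-miR-122-5p", "hsa-miR-30b-5p", "hsa-miR-374a-5p",
    "hsa-miR-374c-5p", "hsa-miR-363-3p", "hsa-miR-483-5p", "hsa-miR-127-3p",
    "hsa-miR-337-3p", "hsa-miR-29a-3p", "hsa-miR-29b-3p", "hsa-miR-29c-5p",
    "hsa-miR-324-3p", "hsa-miR-16-5p", "hsa-miR-22-3p", "hsa-miR-1260a",
    "hsa-miR-1280", "hsa-miR-432-3p", "hsa-miR-373-5p", "hsa-miR-150-5p",
    "hsa-miR-15b-5p", "hsa-miR-199a-5p", "hsa-miR-33a-5p", "hsa-miR-424-5p",
    "hsa-miR-21-5p")
}

#' Construct a panel definition
#'
#' @param target_ids Character vector of target miRNA assay ids.
#' @param panel_kind `"whole_miRNome"` (1066 targets), `"custom"` (88 targets)
#'   or `"ad_hoc"` (any size, used for reduced test panels).
#' @return A `panel_definition` object: data frame of `assay_id`,
#'   `assay_class` plus a `panel_kind` attribute.
#' @export
panel_definition <- function(target_ids, panel_kind = "ad_hoc") {
  ctrl <- control_assays()
  target_ids <- as.character(target_ids)
  if (anyDuplicated(c(target_ids, names(ctrl))))
    stop("assay ids must be unique within a panel")
  if (panel_kind == "whole_miRNome" && length(target_ids) != 1066L)
    stop("whole-miRNome panel must have exactly 1066 target assays")
  if (panel_kind == "custom" && length(target_ids) != 88L)
    stop("custom panel must have exactly 88 target assays")
  panel <- data.frame(
    assay_id = c(target_ids, names(ctrl)),
    assay_class = c(rep("target_mirna", length(target_ids)), unname(ctrl)),
    stringsAsFactors = FALSE)
  attr(panel, "panel_kind") <- panel_kind
  class(panel) <- c("panel_definition", "data.frame")
  panel
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("<panel_definition> kind=%s, %d target assays, %d controls\n",
              attr(x, "panel_kind"),
              sum(x$assay_class == "target_mirna"),
              sum(x$assay_class != "target_mirna")))
  invisible(x)
}

#' Target assay ids of a panel
#' @param panel A `panel_definition`.
#' @export
panel_targets <- function(panel) {
  panel$assay_id[panel$assay_class == "target_mirna"]
}

#' The whole-miRNome panel (1066 target assays)
#'
#' miRBase v16-style naming; the named melanoma-relevant assays are included
#' and the panel is padded with systematically numbered assay ids.
#' @return A `panel_definition`.
#' @export
whole_mirnome_panel <- function() {
  named <- named_custom_targets()
  fill <- sprintf("hsa-miR-%04d-sim", seq_len(1066L - length(named)))
  panel_definition(c(named, fill), panel_kind = "whole_miRNome")
}

#' The custom melanoma panel (88 target assays)
#'
#' A subset of the whole-miRNome panel: the named melanoma-relevant assays
#' plus the first filler assays, mirroring the selection of candidate
#' biomarkers onto a smaller array.
#' @return A `panel_definition`.
#' @export
custom_panel <- function() {
  named <- named_custom_targets()
  fill <- sprintf("hsa-miR-%04d-sim", seq_len(88L - length(named)))
  panel_definition(c(named, fill), panel_kind = "custom")
}
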
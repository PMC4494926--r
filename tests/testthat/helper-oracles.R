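# Shared fixtures and independent oracles.

# Small ad-hoc panel: n target assays plus the standard controls.
tiny_panel <- function(n = 6L) {
  panel_definition(sprintf("hsa-miR-%03d-tst", seq_len(n)))
}

# Build a cq_matrix from a plain matrix of target values, padding the
# control columns (cel-39 at `cel39`, others detected at fixed values).
make_cq <- function(values, cel39 = 18, panel = NULL, snord_cq = NA_real_) {
  if (is.null(panel)) panel <- tiny_panel(ncol(values))
  if (is.null(colnames(values)))
    colnames(values) <- panel_targets(panel)[seq_len(ncol(values))]
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  n <- nrow(values)
  ctrl <- matrix(NA_real_, n, length(control_assays()),
                 dimnames = list(rownames(values), names(control_assays())))
  ctrl[, "cel-miR-39-3p"] <- cel39
  ctrl[, "cel-miR-54-3p"] <- 21
  ctrl[, "cel-miR-238-3p"] <- 24
  ctrl[, "miRTC"] <- 20
  ctrl[, "PPC"] <- 19
  ctrl[, "hsa-miR-451a"] <- 22
  ctrl[, "hsa-miR-23a-5p"] <- 25
  for (sn in c("SNORD61", "SNORD68", "SNORD72", "SNORD95", "SNORD96A",
               "RNU6-2"))
    ctrl[, sn] <- snord_cq
  cq_matrix(cbind(values, ctrl), panel)
}

# Trapezoidal ROC integral (threshold sweep), independent of the rank
# statistic implementation.
auc_trapezoid <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Brute-force pairwise-comparison AUC (ties count one half).
auc_pairwise <- function(scores, labels, positive = TRUE) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A melt curve with given Gaussian peaks on the standard grid.
peaked_curve <- function(peaks, heights, sigma = 1.2, well = "W1",
                         cq = 24, grid = seq(65, 95, by = 0.5)) {
  sig <- rep(0, length(grid))
  for (i in seq_along(peaks))
    sig <- sig + heights[i] * exp(-0.5 * ((grid - peaks[i]) / sigma)^2)
  melt_curve(well, NA, grid, sig, cq = cq)
}
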
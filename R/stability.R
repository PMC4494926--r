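#' Reference-stability ranking (geNorm / NormFinder / BestKeeper /
#' comparative delta-Ct, consensus)
#'
#' Ranks candidate reference assays by expression stability with the four
#' classical measures and aggregates them into a consensus (geometric mean
#' of the four per-method ranks, the documented RefFinder-style
#' convention):
#' \itemize{
#'   \item geNorm M: for candidate j, the mean over all other candidates k
#'     of the across-sample SD of the pairwise difference Cq_j - Cq_k.
#'     Shift-invariant under per-sample constants (and hence under cel-39
#'     calibration).
#'   \item comparative delta-Ct: the same mean of pairwise SDs, kept as a
#'     distinct report column by the method's convention.
#'   \item BestKeeper: the plain across-sample SD of the candidate's Cq.
#'   \item NormFinder (single-group form): the model-based estimate of the
#'     candidate's own variance after removing the per-sample effect.  With
#'     g candidates and residuals r_ij from the two-way additive fit,
#'     E[ms_j] = sigma_j^2 (g-2)/g + S/g^2 where S is the summed variance,
#'     giving the unbiased estimate sigma_j^2 = g/(g-2) (ms_j - S_hat/g^2)
#'     with S_hat = g/(g-1) sum(ms).  Normalization precedes any group
#'     comparison here, so the multi-group disease-variance term is out of
#'     scope.
#' }
#' Lower is more stable for every measure.  Candidates with any masked
#' entry are dropped (logged); consensus ties break by assay name.
#'
#' @param cq A `cq_matrix`.
#' @param candidates Candidate assay ids; defaults to all target assays
#'   detected in every sample.
#' @return A `stability_ranking` data frame with per-method values, ranks,
#'   `consensus_score` and `consensus_rank`.
#' @export
stability_rank <- function(cq, candidates = NULL) {
  v_all <- cq$values
  if (is.null(candidates))
    candidates <- target_columns(cq)
  candidates <- intersect(candidates, colnames(v_all))
  masked <- candidates[vapply(candidates,
                              function(a) anyNA(v_all[, a]), logical(1))]
  if (length(masked)) {
    message("dropping ", length(masked),
            " candidate(s) with masked entries")
    candidates <- setdiff(candidates, masked)
  }
  if (length(candidates) < 3) stop("need at least 3 fully detected candidates")
  v <- v_all[, candidates, drop = FALSE]
  if (nrow(v) < 3) stop("need at least 3 samples")
  g <- ncol(v)

  pairwise_sd <- vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j), function(k)
      stats::sd(v[, j] - v[, k]), numeric(1)))
  }, numeric(1))
  bestkeeper <- apply(v, 2, stats::sd)

  # NormFinder, single group: residuals of the additive sample+assay fit
  r <- sweep(sweep(v, 1, rowMeans(v)), 2, colMeans(v)) + mean(v)
  ms <- apply(r, 2, function(x) sum(x^2)) / (nrow(v) - 1)
  S_hat <- g / (g - 1) * sum(ms)
  sigma2 <- g / (g - 2) * (ms - S_hat / g^2)
  normfinder <- sqrt(pmax(sigma2, 0))

  rk <- function(x) rank(x, ties.method = "average")
  ranks <- cbind(genorm = rk(pairwise_sd), normfinder = rk(normfinder),
                 bestkeeper = rk(bestkeeper), delta_ct = rk(pairwise_sd))
  consensus_score <- exp(rowMeans(log(ranks)))
  consensus_rank <- integer(g)
  consensus_rank[order(consensus_score, candidates)] <- seq_len(g)

  out <- data.frame(assay = candidates,
                    genorm_m = unname(pairwise_sd),
                    delta_ct_sd = unname(pairwise_sd),
                    bestkeeper_sd = unname(bestkeeper),
                    normfinder_stability = unname(normfinder),
                    rank_genorm = unname(ranks[, "genorm"]),
                    rank_normfinder = unname(ranks[, "normfinder"]),
                    rank_bestkeeper = unname(ranks[, "bestkeeper"]),
                    rank_delta_ct = unname(ranks[, "delta_ct"]),
                    consensus_score = unname(consensus_score),
                    consensus_rank = unname(consensus_rank),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$consensus_rank), ]
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("<stability_ranking> %d candidates; top 5:\n", nrow(x)))
  top <- utils::head(x, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. %s (M=%.3f, NF=%.3f, BK=%.3f)\n",
                top$consensus_rank[i], top$assay[i], top$genorm_m[i],
                top$normfinder_stability[i], top$bestkeeper_sd[i]))
  invisible(x)
}
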
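#' The nine stage comparisons
#'
#' (a) healthy vs melanoma (all stages), (b)-(f) healthy vs single stages
#' 0-IV, (g) healthy vs early (0+I+II), (h) healthy vs late (III+IV),
#' (i) early vs late.
#'
#' @return Named list of `comparison_spec` objects with `id`, `label_a`,
#'   `label_b`, `stages_a`, `stages_b`.
#' @export
comparison_specs <- function() {
  mk <- function(id, la, sa, lb, sb)
    structure(list(id = id, label_a = la, stages_a = sa,
                   label_b = lb, stages_b = sb),
              class = "comparison_spec")
  list(
    a = mk("a", "healthy", "healthy", "melanoma", c("0", "I", "II", "III", "IV")),
    b = mk("b", "healthy", "healthy", "stage 0", "0"),
    c = mk("c", "healthy", "healthy", "stage I", "I"),
    d = mk("d", "healthy", "healthy", "stage II", "II"),
    e = mk("e", "healthy", "healthy", "stage III", "III"),
    f = mk("f", "healthy", "healthy", "stage IV", "IV"),
    g = mk("g", "healthy", "healthy", "early stage", c("0", "I", "II")),
    h = mk("h", "healthy", "healthy", "late stage", c("III", "IV")),
    i = mk("i", "early stage", c("0", "I", "II"), "late stage", c("III", "IV")))
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("<comparison_spec %s> %s (%s) vs %s (%s)\n", x$id, x$label_a,
              paste(x$stages_a, collapse = "+"), x$label_b,
              paste(x$stages_b, collapse = "+")))
  invisible(x)
}

#' Build a classification dataset for one comparison
#'
#' Restricts the normalized expression matrix to the two groups, labels the
#' samples (stages pooled into a group share a common label), log2
#' transforms the expression, drops assays undetected in more than 20% of
#' the selected samples, and imputes remaining missing entries at the
#' censoring bound (the expression a well at the Cq cutoff would have in
#' that sample).
#'
#' @param expr A `rel_expr` of QC-passed samples.
#' @param samples The matching `sample_table`.
#' @param spec A `comparison_spec`.
#' @param max_undetected Maximal allowed undetected fraction per assay.
#' @param cutoff Cq censoring bound used for imputation.
#' @return List `x` (matrix, log2 expression), `y` (factor, level 1 =
#'   group A/reference, level 2 = group B).
#' @export
build_dataset <- function(expr, samples, spec, max_undetected = 0.2,
                          cutoff = 30) {
  stage <- samples$stage[match(rownames(expr$values), samples$sample_id)]
  in_a <- !is.na(stage) & stage %in% spec$stages_a
  in_b <- !is.na(stage) & stage %in% spec$stages_b
  if (sum(in_a) < 3 || sum(in_b) < 3)
    stop(sprintf("comparison (%s): a group has fewer than 3 samples", spec$id))
  sel <- in_a | in_b
  v <- expr$values[sel, , drop = FALSE]
  keep <- colMeans(is.na(v)) <= max_undetected
  v <- v[, keep, drop = FALSE]
  if (anyNA(v)) {
    bound <- 2^(-(cutoff - expr$ref_cq[rownames(v)]))
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      v[miss, j] <- bound[miss]
    }
  }
  x <- log2(v)
  y <- factor(ifelse(in_a[sel], spec$label_a, spec$label_b),
              levels = c(spec$label_a, spec$label_b))
  list(x = x, y = y)
}

svm_linear_weights <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)
}

#' SVM-RFE feature ranking
#'
#' Recursive feature elimination with a linear-kernel SVM on standardized
#' features: fit, remove the feature with the smallest absolute weight,
#' repeat until none remain; the ranking is the reverse elimination order.
#' Weight ties are broken by fixed feature order (the later column is
#' eliminated first).  All-constant features carry zero weight and are
#' eliminated first.  The procedure is deterministic given the data.
#'
#' @param x Feature matrix (samples x assays).
#' @param y Two-level factor.
#' @param cost Linear SVM cost.
#' @return Character vector of assay ids, most discriminative first.
#' @export
rank_svmrfe <- function(x, y, cost = 1) {
  if (ncol(x) < 2) stop("need at least 2 features")
  if (nlevels(droplevels(factor(y))) != 2) stop("y must have two classes")
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)   # constant columns become all-zero
  remaining <- colnames(xs)
  elimination <- character(0)
  while (length(remaining) > 1) {
    xr <- xs[, remaining, drop = FALSE]
    w <- abs(svm_linear_weights(xr, y))
    worst <- remaining[max(which(w == min(w)))]
    elimination <- c(elimination, worst)
    remaining <- setdiff(remaining, worst)
  }
  rev(c(elimination, remaining))
}

svm_fit_predict <- function(x_train, y_train, x_test, kernel = "radial",
                            cost = 1, decision = FALSE) {
  st <- standardize_fit(x_train)
  fit <- e1071::svm(standardize_apply(x_train, st), y_train, kernel = kernel,
                    cost = cost, scale = FALSE)
  pred <- stats::predict(fit, standardize_apply(x_test, st),
                         decision.values = decision)
  if (!decision) return(pred)
  dv <- as.numeric(attr(pred, "decision.values"))
  # e1071's decision value is positive for the first of fit$levels
  first <- fit$levels[1]
  list(class = pred, score_level2 = if (first == levels(y_train)[2]) dv else -dv)
}

#' Leave-one-out evaluation of nested signatures
#'
#' For each signature size k in `sizes`, the top-k ranked assays form the
#' signature (signatures are nested by construction) and a leave-one-out
#' cross-validation is run: each sample is predicted once by an SVM trained
#' on all others using only those k features.  Accuracy is the fraction of
#' correct assignments; the best signature is the one with the highest
#' accuracy, ties broken toward the smaller size.
#'
#' @param x,y Dataset from [build_dataset()].
#' @param ranking Ranking from [rank_svmrfe()] computed on this dataset.
#' @param sizes Signature sizes to evaluate.
#' @param kernel,cost SVM settings for the evaluation classifier.
#' @return List `accuracy` (named by size), `best_size`, `best_signature`.
#' @export
evaluate_signatures <- function(x, y, ranking, sizes = 2:10,
                                kernel = "radial", cost = 1) {
  sizes <- sizes[sizes <= length(ranking)]
  if (nrow(x) < 10)
    warning("fewer than 10 samples; leave-one-out still runs")
  acc <- stats::setNames(numeric(length(sizes)), sizes)
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    feats <- ranking[seq_len(k)]
    correct <- vapply(seq_len(nrow(x)), function(i) {
      pred <- svm_fit_predict(x[-i, feats, drop = FALSE], y[-i],
                              x[i, feats, drop = FALSE], kernel, cost)
      as.character(pred) == as.character(y[i])
    }, logical(1))
    acc[si] <- mean(correct)
  }
  best <- sizes[which.max(acc)]   # which.max takes the first (smallest) tie
  list(accuracy = acc, best_size = best,
       best_signature = ranking[seq_len(best)])
}

#' Half-split ROC with bootstrap confidence interval
#'
#' A stratified half of the samples trains an SVM on the signature; the
#' decision values on the other half give the ROC AUC by the rank
#' statistic.  The 95% CI comes from a stratified bootstrap (resampling
#' within classes) of the test half.
#'
#' @param x,y Dataset from [build_dataset()].
#' @param signature Assay ids of the signature.
#' @param seed RNG seed for the split and the bootstrap.
#' @param kernel,cost SVM settings.
#' @param n_boot Bootstrap resamples.
#' @return List `auc`, `ci` (length 2), `n_train`, `n_test`.
#' @export
roc_half_split <- function(x, y, signature, seed = 1L, kernel = "radial",
                           cost = 1, n_boot = 2000L) {
  set.seed(seed)
  idx <- split(seq_along(y), y)
  repeat {
    train <- sort(unlist(lapply(idx, function(i)
      sample(i, floor(length(i) / 2)))))
    test <- setdiff(seq_along(y), train)
    if (length(unique(y[train])) == 2 && length(unique(y[test])) == 2) break
    message("resampling half split without both classes")
  }
  pred <- svm_fit_predict(x[train, signature, drop = FALSE], y[train],
                          x[test, signature, drop = FALSE], kernel, cost,
                          decision = TRUE)
  score <- pred$score_level2
  y_test <- y[test]
  pos <- levels(y)[2]
  auc <- auc_rank(score, y_test, positive = pos)
  bpos <- which(y_test == pos); bneg <- which(y_test != pos)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(bpos, replace = TRUE), sample(bneg, replace = TRUE))
    auc_rank(score[i], y_test[i], positive = pos)
  }, numeric(1))
  list(auc = auc, ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       n_train = length(train), n_test = length(test))
}

#' Biomarker exclusion flags
#'
#' A signature miRNA should not be considered a biomarker candidate when it
#' is highly expressed in whole blood (mean whole-blood Cq below 15 - it
#' may simply derive from contaminating blood cells) or when it belongs to
#' the unstable list of the healthy miRNome.  Flags annotate; they never
#' remove a miRNA.
#'
#' @param signature Assay ids.
#' @param whole_blood_cq Optional `cq_matrix` of whole-blood reference
#'   samples.
#' @param unstable_list Character vector of unstable miRNAs (e.g. from the
#'   `mirnome_catalog`).
#' @param cq_bound Whole-blood Cq bound.
#' @return Data frame `assay`, `whole_blood_high`, `unstable`.
#' @export
flag_candidates <- function(signature, whole_blood_cq = NULL,
                            unstable_list = character(0), cq_bound = 15) {
  wb_high <- rep(NA, length(signature))
  if (is.null(whole_blood_cq)) {
    warning("no whole-blood reference: whole_blood_high flags undefined")
  } else {
    wbm <- colMeans(whole_blood_cq$values, na.rm = TRUE)
    wb_high <- !is.na(wbm[signature]) & wbm[signature] < cq_bound
  }
  data.frame(assay = signature, whole_blood_high = unname(wb_high),
             unstable = signature %in% unstable_list,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulation direction of signature miRNAs
#'
#' "up" iff the mean expression in the disease/late group (group B of the
#' comparison) strictly exceeds the reference group's; equal means count as
#' "down" by convention and are reported as borderline.
#'
#' @param expr A `rel_expr`.
#' @param samples The matching `sample_table`.
#' @param spec A `comparison_spec`.
#' @param signature Assay ids.
#' @return Data frame `assay`, `direction`, `borderline`.
#' @export
regulation_direction <- function(expr, samples, spec, signature) {
  stage <- samples$stage[match(rownames(expr$values), samples$sample_id)]
  va <- expr$values[!is.na(stage) & stage %in% spec$stages_a, signature,
                    drop = FALSE]
  vb <- expr$values[!is.na(stage) & stage %in% spec$stages_b, signature,
                    drop = FALSE]
  ma <- colMeans(va, na.rm = TRUE); mb <- colMeans(vb, na.rm = TRUE)
  data.frame(assay = signature,
             direction = ifelse(mb > ma, "up", "down"),
             borderline = mb == ma,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full signature pipeline for one comparison
#'
#' Builds the dataset, ranks by SVM-RFE, evaluates nested signatures of
#' sizes 2-10 by leave-one-out, selects the best, computes the half-split
#' ROC AUC with bootstrap CI, the regulation directions and the exclusion
#' flags.  Rankings are computed independently per comparison, never cached
#' across comparisons.
#'
#' @param expr A `rel_expr` of QC-passed custom-panel samples.
#' @param samples The matching `sample_table`.
#' @param spec A `comparison_spec` (see [comparison_specs()]).
#' @param seed RNG seed (half split / bootstrap).
#' @param whole_blood_cq Optional whole-blood reference `cq_matrix`.
#' @param unstable_list Unstable miRNAs from the healthy catalog.
#' @param sizes Signature sizes.
#' @return A `signature_result`.
#' @export
run_signature <- function(expr, samples, spec, seed = 1L,
                          whole_blood_cq = NULL,
                          unstable_list = character(0), sizes = 2:10) {
  ds <- build_dataset(expr, samples, spec)
  ranking <- rank_svmrfe(ds$x, ds$y)
  ev <- evaluate_signatures(ds$x, ds$y, ranking, sizes)
  roc <- roc_half_split(ds$x, ds$y, ev$best_signature, seed = seed)
  flags <- suppressWarnings(
    flag_candidates(ev$best_signature, whole_blood_cq, unstable_list))
  dir <- regulation_direction(expr, samples, spec, ev$best_signature)
  structure(list(spec = spec, ranking = ranking, accuracy = ev$accuracy,
                 best_size = ev$best_size,
                 best_signature = ev$best_signature,
                 auc = roc$auc, auc_ci = roc$ci, flags = flags,
                 direction = dir, n = nrow(ds$x), seed = seed),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result %s> %s vs %s (n=%d)\n", x$spec$id,
              x$spec$label_a, x$spec$label_b, x$n))
  cat(sprintf("  best signature (ACC %.3f, AUC %.3f, CI %.2f-%.2f):\n",
              max(x$accuracy), x$auc, x$auc_ci[1], x$auc_ci[2]))
  for (i in seq_along(x$best_signature)) {
    fl <- c(if (isTRUE(x$flags$whole_blood_high[i])) "whole_blood_high",
            if (x$flags$unstable[i]) "unstable")
    cat(sprintf("   %2d. %s [%s]%s\n", i, x$best_signature[i],
                x$direction$direction[i],
                if (length(fl)) paste0(" !", paste(fl, collapse = ",")) else ""))
  }
  invisible(x)
}

#' Permutation null band for the best signature accuracy
#'
#' Re-runs the full ranking + nested-signature leave-one-out selection on
#' label-permuted data to obtain the null distribution of the best
#' accuracy, guarding against selection-bias optimism.
#'
#' @param x,y Dataset from [build_dataset()].
#' @param sizes Signature sizes.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param level Band coverage (default 0.95).
#' @return List `band` (two quantiles) and `null` (permuted best
#'   accuracies).
#' @export
signature_null_band <- function(x, y, sizes = 2:10, n_perm = 30L, seed = 1L,
                                level = 0.95) {
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(p) {
    yp <- sample(y)
    rk <- rank_svmrfe(x, yp)
    max(evaluate_signatures(x, yp, rk, sizes)$accuracy)
  }, numeric(1))
  a <- (1 - level) / 2
  list(band = unname(stats::quantile(null, c(a, 1 - a))), null = null)
}
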
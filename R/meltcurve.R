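#' Extract classification features from a melt curve
#'
#' The feature vector covers the quantities a curve reviewer looks at: the
#' associated Cq, the melting temperature Tm (temperature of the global
#' -dF/dT maximum, ties broken toward the lower temperature), the peak
#' height, the start and end temperatures of the grid, the number of
#' secondary peaks (local maxima of the lightly smoothed signal reaching at
#' least 30% of the main peak), the peak width at half height, and the
#' curve shape itself resampled to a fixed-length, max-normalized profile.
#'
#' @param curve A `melt_curve`.
#' @param profile_length Length of the resampled shape profile.
#' @return A `melt_features` object (named list); `degenerate` is TRUE for
#'   an all-zero signal.
#' @export
extract_features <- function(curve, profile_length = 32L) {
  tt <- curve$temperature
  ss <- curve$signal
  peak_height <- max(ss)
  degenerate <- peak_height <= 0
  tm <- if (degenerate) tt[1] else tt[which.max(ss)]

  # light smoothing for peak counting only; Tm/height use the raw signal
  sm <- stats::filter(ss, rep(1 / 3, 3), sides = 2)
  sm[c(1, length(sm))] <- ss[c(1, length(ss))]
  sm <- as.numeric(sm)
  n_secondary <- 0L
  if (!degenerate) {
    loc <- which(diff(sign(diff(sm))) == -2) + 1L
    loc <- loc[sm[loc] >= 0.3 * max(sm)]
    n_secondary <- max(0L, length(loc) - 1L)
  }

  width <- 0
  if (!degenerate) {
    half <- peak_height / 2
    i <- which.max(ss)
    lo <- i; while (lo > 1 && ss[lo] > half) lo <- lo - 1
    hi <- i; while (hi < length(ss) && ss[hi] > half) hi <- hi + 1
    interp <- function(a, b) {
      if (ss[b] == ss[a]) return(tt[a])
      tt[a] + (half - ss[a]) * (tt[b] - tt[a]) / (ss[b] - ss[a])
    }
    t_lo <- if (ss[lo] > half) tt[lo] else interp(lo, lo + 1)
    t_hi <- if (ss[hi] > half) tt[hi] else interp(hi - 1, hi)
    width <- t_hi - t_lo
  }

  grid <- seq(tt[1], tt[length(tt)], length.out = profile_length)
  profile <- stats::approx(tt, ss, xout = grid)$y
  if (max(profile) > 0) profile <- profile / max(profile)

  structure(list(cq = curve$cq, tm = tm, peak_height = peak_height,
                 start_temp = tt[1], end_temp = tt[length(tt)],
                 n_secondary_peaks = n_secondary,
                 peak_width_at_half_height = width,
                 profile = profile, degenerate = degenerate),
            class = "melt_features")
}

#' Feature matrix for a list of melt curves
#'
#' Not-detected Cq values are imputed at 35 cycles (beyond any detected
#' well) so the classifier sees "no amplification" as an informative value.
#'
#' @param curves List of `melt_curve` objects (or of `melt_features`).
#' @return Numeric matrix, one row per curve.
#' @export
melt_feature_matrix <- function(curves) {
  feats <- lapply(curves, function(x)
    if (inherits(x, "melt_features")) x else extract_features(x))
  rows <- lapply(feats, function(f) {
    c(cq = if (is.na(f$cq)) 35 else f$cq, tm = f$tm,
      peak_height = f$peak_height, start_temp = f$start_temp,
      end_temp = f$end_temp, n_secondary_peaks = f$n_secondary_peaks,
      peak_width = f$peak_width_at_half_height,
      stats::setNames(f$profile, sprintf("p%02d", seq_along(f$profile))))
  })
  do.call(rbind, rows)
}

# Standardize columns with training-set statistics; constant columns map to 0.
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
}

#' Train the melt-curve quality classifier
#'
#' A probability-calibrated RBF-kernel SVM on standardized features
#' (Platt-style probability estimates as implemented in e1071).
#'
#' @param features Matrix from [melt_feature_matrix()] (or a list of
#'   curves/features).
#' @param labels Character vector "good"/"bad".
#' @param seed RNG seed (probability calibration uses internal
#'   cross-validation).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the 1/p
#'   default.
#' @return A `melt_classifier`.
#' @export
train_melt_classifier <- function(features, labels, seed = 1L,
                                  cost = 1, gamma = NULL) {
  if (is.list(features) && !is.matrix(features))
    features <- melt_feature_matrix(features)
  y <- factor(as.character(labels), levels = c("bad", "good"))
  if (nlevels(droplevels(y)) < 2)
    stop("training requires both good and bad curves")
  st <- standardize_fit(features)
  xs <- standardize_apply(features, st)
  set.seed(seed)
  args <- list(x = xs, y = y, kernel = "radial", cost = cost,
               probability = TRUE, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, standardize = st, seed = seed,
                 feature_names = colnames(features)),
            class = "melt_classifier")
}

#' @export
print.melt_classifier <- function(x, ...) {
  cat(sprintf("<melt_classifier> RBF SVM, %d support vectors, %d features\n",
              x$fit$tot.nSV, length(x$feature_names)))
  invisible(x)
}

#' Classify melt curves with the questionable rule
#'
#' Each curve gets the SVM's predicted class and the probability of that
#' prediction.  Over the classified batch, a threshold of
#' mean(probabilities) - SD(probabilities) is computed; curves whose
#' probability falls strictly below it are labeled "questionable" (to be
#' inspected manually; the downstream censoring default treats them as
#' bad).  The threshold is a symmetric function of the batch, so labels do
#' not depend on curve order.
#'
#' @param clf A `melt_classifier`.
#' @param features Feature matrix or list of curves.
#' @return A `curve_labels` data frame: `predicted_class`, `probability`,
#'   `label` in {good, bad, questionable}; the threshold is stored in the
#'   `threshold` attribute.
#' @export
classify_curves <- function(clf, features) {
  if (is.list(features) && !is.matrix(features))
    features <- melt_feature_matrix(features)
  if (nrow(features) == 0) {
    out <- data.frame(predicted_class = character(0),
                      probability = numeric(0), label = character(0))
    class(out) <- c("curve_labels", "data.frame")
    return(out)
  }
  xs <- standardize_apply(features, clf$standardize)
  pred <- stats::predict(clf$fit, xs, probability = TRUE)
  pr <- attr(pred, "probabilities")
  prob <- pr[cbind(seq_len(nrow(pr)), match(as.character(pred), colnames(pr)))]
  threshold <- mean(prob) - stats::sd(prob)
  if (is.na(threshold)) threshold <- -Inf   # single-curve batch: SD undefined
  label <- ifelse(prob < threshold, "questionable", as.character(pred))
  out <- data.frame(predicted_class = as.character(pred),
                    probability = unname(prob), label = label,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("curve_labels", "data.frame")
  out
}

#' Questionable-rule threshold on a bare probability vector
#'
#' mean(p) - sd(p) with the sample (n-1) standard deviation; curves with
#' probability strictly below the threshold become questionable.
#' @param probabilities Numeric vector in [0, 1].
#' @return List with `threshold` and logical `questionable`.
#' @export
questionable_rule <- function(probabilities) {
  thr <- mean(probabilities) - stats::sd(probabilities)
  if (is.na(thr)) thr <- -Inf
  list(threshold = thr, questionable = probabilities < thr)
}

#' Rank-statistic ROC AUC
#'
#' The probability that a random positive scores above a random negative
#' (Mann-Whitney statistic; ties count one half).  Equals the trapezoidal
#' integral of the ROC curve.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or two-level vector; `positive` names the positive
#'   class.
#' @param positive Positive class value.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated-holdout evaluation of the melt-curve classifier
#'
#' Per repeat: a stratified random third (by default) of the labeled set is
#' held out, the classifier is trained on the remainder, and the ROC AUC of
#' the good-class probabilities on the holdout is computed by the rank
#' statistic.  The mean over repeats measures classifier efficiency.
#'
#' @param features Feature matrix or list of curves.
#' @param labels "good"/"bad" labels.
#' @param holdout_fraction Fraction held out per repeat (in (0, 1)).
#' @param repeats Number of random splits.
#' @param seed RNG seed.
#' @return List with `mean_roc` and the per-repeat `roc` vector.
#' @export
evaluate_melt_classifier <- function(features, labels,
                                     holdout_fraction = 1 / 3,
                                     repeats = 100L, seed = 1L) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be in (0, 1)")
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.list(features) && !is.matrix(features))
    features <- melt_feature_matrix(features)
  y <- as.character(labels)
  set.seed(seed)
  rocs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    repeat {
      hold <- unlist(lapply(split(seq_along(y), y), function(idx)
        sample(idx, max(1, round(length(idx) * holdout_fraction)))))
      if (length(unique(y[hold])) == 2 &&
          length(unique(y[-hold])) == 2) break
      message("resampling split without both classes")
    }
    clf <- train_melt_classifier(features[-hold, , drop = FALSE], y[-hold],
                                 seed = seed + r)
    xs <- standardize_apply(features[hold, , drop = FALSE], clf$standardize)
    pred <- stats::predict(clf$fit, xs, probability = TRUE)
    p_good <- attr(pred, "probabilities")[, "good"]
    rocs[r] <- auc_rank(p_good, y[hold], positive = "good")
  }
  list(mean_roc = mean(rocs), roc = rocs)
}
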
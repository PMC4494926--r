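#' Heatmap-ready log2 expression matrix
#'
#' Log2-transforms normalized expression, drops assays absent in all
#' samples and leaves masked entries as NA.  Clustering and plot aesthetics
#' are left to the caller.
#'
#' @param expr A `rel_expr`.
#' @return Numeric matrix (samples x detected assays) of log2 expression.
#' @export
prepare_heatmap_matrix <- function(expr) {
  v <- expr$values
  keep <- colSums(!is.na(v)) > 0
  log2(v[, keep, drop = FALSE])
}

#' 2-D sample embedding (PCA or t-SNE)
#'
#' PCA: eigendecomposition of the covariance of the centered log2
#' expression; the first two components, with the sign convention that the
#' largest-magnitude loading of each component is positive (making the
#' result fully deterministic).  t-SNE: the exact (non-approximated)
#' algorithm on PCA-whitened input with the given perplexity; reproducible
#' given the seed.  Masked entries are imputed at the assay minimum before
#' embedding.
#'
#' @param expr A `rel_expr`.
#' @param method "pca" or "tsne".
#' @param perplexity t-SNE perplexity (default 10).
#' @param seed RNG seed for t-SNE initialisation.
#' @param whiten Whiten the input before t-SNE (PCA-whitening to full
#'   retained rank).
#' @return An `embedding`: data frame `sample_id`, `dim1`, `dim2` with
#'   method parameters in attributes.
#' @export
embed_samples <- function(expr, method = c("pca", "tsne"), perplexity = 10,
                          seed = 1L, whiten = TRUE) {
  method <- match.arg(method)
  v <- expr$values
  if (nrow(v) < 3) stop("need at least 3 samples")
  v <- v[, colSums(!is.na(v)) > 0, drop = FALSE]
  lm2 <- log2(v)
  for (j in seq_len(ncol(lm2))) {       # impute masked wells at assay minimum
    miss <- is.na(lm2[, j])
    if (any(miss)) lm2[miss, j] <- min(lm2[, j], na.rm = TRUE)
  }
  coords <- if (method == "pca") pca_2d(lm2)
    else tsne_2d(lm2, perplexity = perplexity, seed = seed, whiten = whiten)
  out <- data.frame(sample_id = rownames(v), dim1 = coords[, 1],
                    dim2 = coords[, 2], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "params") <- list(perplexity = perplexity, seed = seed,
                              whiten = whiten)
  class(out) <- c("embedding", "data.frame")
  out
}

pca_2d <- function(x) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  if (k < 2) scores <- cbind(scores, 0)
  scores
}

# PCA-whitening: unit variance along each kept principal axis.  The
# retained rank is capped (initial_dims convention): whitening every
# component up to n - 1 would make all points exactly equidistant whenever
# there are at least as many assays as samples.
whiten_input <- function(x, k = 30L, tol = 1e-10) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > tol * pc$sdev[1])
  keep <- keep[seq_len(min(length(keep), k))]
  sweep(pc$x[, keep, drop = FALSE], 2, pc$sdev[keep], "/")
}

# Exact t-SNE (Student-t embedding of the perplexity-calibrated affinities,
# gradient descent with momentum and early exaggeration).  Suitable for the
# small sample counts of qPCR cohorts.
tsne_2d <- function(x, perplexity = 10, seed = 1L, whiten = TRUE,
                    n_iter = 600L, eta = 100) {
  n <- nrow(x)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity must be below (n - 1) / 3")
  if (whiten) x <- whiten_input(x)
  d2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {               # per-point precision by bisection
    di <- d2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    exaggeration <- if (iter <= 100) 4 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    qd <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(qd) <- 0
    Q <- pmax(qd / sum(qd), 1e-12)
    W <- (exaggeration * P - Q) * qd
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("dim1", "dim2")
  rownames(Y) <- rownames(x)
  Y
}

#' Mean silhouette width between two sample groups in an embedding
#'
#' A positive silhouette means samples sit closer to their own group than
#' to the other; used to verify that planted group structure survives the
#' embedding.
#'
#' @param coords Matrix or `embedding` with two coordinate columns.
#' @param groups Two-level grouping vector.
#' @return Mean silhouette width.
#' @export
embedding_silhouette <- function(coords, groups) {
  if (inherits(coords, "embedding"))
    coords <- as.matrix(coords[, c("dim1", "dim2")])
  d <- as.matrix(stats::dist(coords))
  groups <- as.character(groups)
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own & seq_len(nrow(d)) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
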
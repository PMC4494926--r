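#' A single melt (dissociation) curve
#'
#' @param well_id Well identifier.
#' @param assay_id Assay in the well (may be NA).
#' @param temperature Strictly increasing temperature grid (degrees C).
#' @param signal -dF/dT values on the grid.
#' @param cq Associated quantification cycle (NA if not detected).
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(well_id, assay_id = NA, temperature, signal,
                       cq = NA_real_) {
  if (length(temperature) < 10) stop("melt curve needs >= 10 grid points")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (length(signal) != length(temperature))
    stop("signal and temperature lengths differ")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(list(well_id = well_id, assay_id = assay_id,
                 temperature = as.numeric(temperature),
                 signal = as.numeric(signal), cq = cq),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> well %s: %d points %.1f-%.1f C, peak %.3f @ %.1f C\n",
              x$well_id, length(x$signal), min(x$temperature),
              max(x$temperature), max(x$signal),
              x$temperature[which.max(x$signal)]))
  invisible(x)
}

gaussian_peak <- function(grid, tm, height, sigma) {
  height * exp(-0.5 * ((grid - tm) / sigma)^2)
}

#' Generate labeled synthetic melt curves
#'
#' Good curves carry a single Gaussian -dF/dT peak with melting temperature
#' in 74-84 degrees C and height well above the noise floor.  Bad curves are
#' drawn from three failure archetypes: a low-Tm primer-dimer peak (Tm
#' 65.5-72), a multi-peak profile (main peak plus a comparable secondary
#' peak), and a flat/no-peak profile with only small bumps.  Each curve
#' carries an associated Cq.
#'
#' @param config A [generator_config()] (uses `seed`, `melt_grid`,
#'   `melt_noise_sd`).
#' @param n_good,n_bad Numbers of curves per class.
#' @return List with `curves` (list of `melt_curve`) and `labels`
#'   (character, "good"/"bad", with archetypes in the `archetype` attribute),
#'   in randomized order.
#' @export
generate_melt_curves <- function(config = generator_config(),
                                 n_good = 500L, n_bad = 500L) {
  if (n_good < 0 || n_bad < 0) stop("configuration error: negative counts")
  set.seed(config$seed)
  grid <- config$melt_grid
  nz <- function() stats::rnorm(length(grid), 0, config$melt_noise_sd)
  one_good <- function(i) {
    melt_curve(sprintf("G%04d", i), NA, grid,
               gaussian_peak(grid, stats::runif(1, 74, 84),
                             stats::runif(1, 0.8, 1.2),
                             stats::runif(1, 0.8, 1.5)) + nz(),
               cq = stats::runif(1, 18, 29))
  }
  one_bad <- function(i, type) {
    sig <- switch(type,
      primer_dimer = gaussian_peak(grid, stats::runif(1, 65.5, 72),
                                   stats::runif(1, 0.5, 1.1),
                                   stats::runif(1, 0.8, 1.8)),
      multi_peak = {
        tm1 <- stats::runif(1, 74, 84)
        tm2 <- tm1 + sample(c(-1, 1), 1) * stats::runif(1, 4, 8)
        tm2 <- min(max(tm2, 66), 94)
        gaussian_peak(grid, tm1, stats::runif(1, 0.5, 0.9),
                      stats::runif(1, 0.8, 1.5)) +
          gaussian_peak(grid, tm2, stats::runif(1, 0.35, 0.8),
                        stats::runif(1, 0.8, 1.5))
      },
      flat = gaussian_peak(grid, stats::runif(1, 66, 94),
                           stats::runif(1, 0.02, 0.08),
                           stats::runif(1, 2, 6)))
    melt_curve(sprintf("B%04d", i), NA, grid, sig + nz(),
               cq = if (type == "flat") stats::runif(1, 30, 34.5)
                    else stats::runif(1, 24, 33))
  }
  types <- rep(c("primer_dimer", "multi_peak", "flat"), length.out = n_bad)
  curves <- c(lapply(seq_len(n_good), one_good),
              if (n_bad > 0) lapply(seq_len(n_bad),
                                    function(i) one_bad(i, types[i])))
  labels <- c(rep("good", n_good), rep("bad", n_bad))
  arche <- c(rep("single_peak", n_good), types)
  ord <- sample(length(curves))
  labels <- labels[ord]
  attr(labels, "archetype") <- arche[ord]
  list(curves = curves[ord], labels = labels)
}
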
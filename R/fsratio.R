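#' Integrated spectral power over a frequency band
#'
#' Computes \eqn{\hat r_{a,b} = \int_a^b \|\mathrm{vec}\,\hat f(\omega)\|_2^2
#' \, d\omega}, discretized as a Riemann sum over the Fourier frequencies
#' inside the band with weight \eqn{2\pi/T}. Band membership uses the
#' half-open convention \eqn{(a, b]} so that band partitions are disjoint and
#' exhaustive.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param band a \code{\link{frequency_band}}.
#' @return Nonnegative band power.
#' @export
band_power <- function(est, band) {
  stopifnot(inherits(est, "spectral_estimate"), inherits(band, "frequency_band"))
  idx <- band_members(est$omegas, band$a, band$b)
  if (length(idx) == 0L) {
    stop(sprintf(
      "band (%.4f, %.4f) contains no Fourier frequency at T = %d",
      band$a, band$b, est$n_time))
  }
  (2 * pi / est$n_time) * sum(est$power[idx])
}

#' FS-ratio: proportion of spectral power in a band
#'
#' The frequency-specific spectral ratio
#' \eqn{\hat R_{a,b} = \hat r_{a,b} / \hat r_{0,\pi}} is the proportion of
#' total spectral power (squared Frobenius norm of the spectral matrix,
#' integrated over \eqn{(0,\pi)}) that falls in the band \eqn{(a,b)}. It is a
#' scalar in \eqn{(0,1)} and is blind to the dimension of the process, which
#' makes it comparable across epochs whose number of components differs.
#'
#' @inheritParams band_power
#' @return FS-ratio in \eqn{(0, 1)}.
#' @examples
#' e <- epoch_series(matrix(rnorm(2048), 2048, 2))
#' fs_ratio(spectral_estimate(e), frequency_band(0.1, 0.2, unit = "normalized"))
#' @export
fs_ratio <- function(est, band) {
  stopifnot(inherits(est, "spectral_estimate"))
  total <- sum(est$power)
  if (total <= 0) stop("total spectral power is zero; FS-ratio undefined")
  idx <- band_members(est$omegas, band$a, band$b)
  if (length(idx) == 0L) {
    stop(sprintf(
      "band (%.4f, %.4f) contains no Fourier frequency at T = %d",
      band$a, band$b, est$n_time))
  }
  sum(est$power[idx]) / total
}

# Composite Simpson quadrature of a vectorized function on [a, b].
simpson <- function(f, a, b, n = 4096L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  hh <- (b - a) / n
  hh / 3 * (y[1L] + y[n + 1L] +
            4 * sum(y[seq(2L, n, by = 2L)]) +
            2 * sum(y[seq(3L, n - 1L, by = 2L)]))
}

#' Population FS-ratio of an analytically known spectral matrix field
#'
#' Quadrature version of the FS-ratio for a known spectral density
#' \eqn{\omega \mapsto f(\omega)}; used as the population oracle against
#' which estimates are compared. Also evaluates the equivalent complement
#' form \eqn{\{1 + r_{\bar\Pi(a,b)}/r_{a,b}\}^{-1}}, where
#' \eqn{\bar\Pi(a,b) = (0,\pi) \setminus (a,b)}, from independently
#' integrated pieces, and checks that the two agree.
#'
#' @param field function mapping an angular frequency to a (possibly 1x1)
#'   spectral matrix, or to a scalar spectral density.
#' @param band a \code{\link{frequency_band}}.
#' @param n_quad number of Simpson panels per integration segment.
#' @return The population FS-ratio, with the complement form attached as
#'   attribute \code{"complement_form"} and the band power as
#'   \code{"band_power"}.
#' @export
fs_ratio_parameter <- function(field, band, n_quad = 4096L) {
  stopifnot(inherits(band, "frequency_band"))
  pw <- function(om) {
    vapply(om, function(w) sum(abs(field(w))^2), numeric(1L))
  }
  r_ab <- simpson(pw, band$a, band$b, n_quad)
  r_lo <- simpson(pw, 0, band$a, n_quad)
  r_hi <- simpson(pw, band$b, pi, n_quad)
  r_tot <- simpson(pw, 0, pi, n_quad)
  ratio <- r_ab / r_tot
  comp <- 1 / (1 + (r_lo + r_hi) / r_ab)
  if (abs(ratio - comp) > 1e-8) {
    stop("quadrature inconsistency between direct and complement forms: ",
         format(abs(ratio - comp)))
  }
  structure(ratio, complement_form = comp, band_power = r_ab)
}

#' Scan statistic at a single frequency
#'
#' \eqn{\hat\lambda_a = 1 - \hat r_{0,a-\Delta} / \hat r_{0,a}}: the relative
#' increment of cumulative spectral power arriving in the window
#' \eqn{(a - \Delta, a)}. Large values flag frequencies just below which the
#' process carries substantial power. Equivalently expressible as a ratio of
#' FS-ratios, since the total-power denominator cancels; both forms are
#' computed and checked against each other.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param a evaluation frequency (angular), must exceed \code{delta}.
#' @param delta window width \eqn{\Delta} (angular), positive.
#' @return Scan statistic in \eqn{[0, 1)}.
#' @export
scan_statistic <- function(est, a, delta) {
  stopifnot(inherits(est, "spectral_estimate"), delta > 0)
  if (a <= delta) {
    stop("scan frequency a = ", format(a), " must exceed delta = ",
         format(delta))
  }
  idx1 <- band_members(est$omegas, 0, a - delta)
  if (length(idx1) == 0L) {
    stop("no Fourier frequency in (0, a - delta); increase a or T")
  }
  r1 <- sum(est$power[band_members(est$omegas, 0, a - delta)])
  r2 <- sum(est$power[band_members(est$omegas, 0, a)])
  direct <- 1 - r1 / r2
  total <- sum(est$power)
  alt <- 1 - (r1 / total) / (r2 / total)
  if (!isTRUE(abs(direct - alt) <= 1e-12)) {
    stop("scan statistic forms disagree beyond tolerance")  # unreachable
  }
  direct
}

#' Scan profile over a grid of frequencies
#'
#' Evaluates the scan statistic on an equally spaced grid of normalized
#' frequencies \eqn{a_j = j\Delta}, \eqn{j = 1, \dots, Q}, with grid spacing
#' equal to the scan increment \eqn{\Delta} (so consecutive cumulative-power
#' ratios and the windowed definition coincide). The statistic needs
#' \eqn{a_j - \Delta > 0} and is therefore reported at \eqn{a_2, \dots, a_Q}.
#' Defaults \eqn{\Delta = 0.01}, \eqn{Q = 49} span \eqn{(0, 0.5)}.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param delta scan increment on the normalized \eqn{(0, 0.5)} scale.
#' @param Q number of grid points \eqn{j\Delta}; requires \eqn{Q\Delta < 0.5}.
#' @return Object of class \code{"scan_profile"}: list with \code{delta},
#'   \code{grid} (normalized evaluation frequencies), \code{lambdas},
#'   \code{flat_lambdas} (the exact profile a flat spectrum would give at this
#'   \code{T}, used as the detection reference), \code{n_time}.
#' @export
scan_profile <- function(est, delta = 0.01, Q = 49L) {
  stopifnot(inherits(est, "spectral_estimate"), delta > 0, Q >= 2L)
  if (Q * delta >= 0.5) {
    stop("grid exceeds the normalized range (0, 0.5): Q * delta = ",
         format(Q * delta))
  }
  n <- est$n_time
  if (n < 1 / delta) {
    stop("delta = ", delta, " is finer than the Fourier resolution at T = ",
         n, "; need T >= 1/delta")
  }
  a_norm <- delta * seq(2L, Q)
  cum <- function(x_ang) {
    vapply(x_ang, function(x) sum(est$power[est$omegas <= x]), numeric(1L))
  }
  cnt <- function(x_ang) {
    vapply(x_ang, function(x) sum(est$omegas <= x), numeric(1L))
  }
  hi <- 2 * pi * a_norm
  lo <- 2 * pi * (a_norm - delta)
  lam <- 1 - cum(lo) / cum(hi)
  lam_flat <- 1 - cnt(lo) / cnt(hi)
  structure(
    list(delta = delta, grid = a_norm, lambdas = lam,
         flat_lambdas = lam_flat, n_time = n, Q = as.integer(Q)),
    class = "scan_profile"
  )
}

#' @export
print.scan_profile <- function(x, ...) {
  cat("Scan profile: delta =", x$delta, ",", length(x$grid),
      "normalized frequencies in [", format(min(x$grid)), ",",
      format(max(x$grid)), "], peak at",
      format(x$grid[which.max(x$lambdas)]), "\n")
  invisible(x)
}

#' Detect power-carrying bands from a scan profile
#'
#' Flags maximal runs of grid points where the scan statistic exceeds what a
#' power-flat process would produce by more than a robust threshold. The
#' excess \eqn{e_j = \hat\lambda(a_j) - \lambda^{\rm flat}(a_j)} is compared
#' against \code{median(e) + 2 * mad(e)}; runs shorter than 2 grid steps are
#' dropped; a run from \eqn{a_{j_1}} to \eqn{a_{j_2}} is reported as the band
#' \eqn{(a_{j_1} - \Delta,\; a_{j_2})}. The flat reference is needed because
#' the scan statistic of even a flat spectrum decreases like \eqn{\Delta/a};
#' comparing against it makes a flat process yield no detections.
#'
#' @param profile a \code{\link{scan_profile}}.
#' @param threshold_rule optional function mapping the excess vector to a
#'   scalar baseline; default \code{function(e) median(e) + 2 * mad(e)}.
#' @param min_width minimum run length in grid steps (default 2).
#' @return List of \code{\link{frequency_band}} objects (possibly empty).
#' @export
detect_bands <- function(profile, threshold_rule = NULL, min_width = 2L) {
  stopifnot(inherits(profile, "scan_profile"))
  if (is.null(threshold_rule)) {
    threshold_rule <- function(e) stats::median(e) + 2 * stats::mad(e)
  }
  e <- profile$lambdas - profile$flat_lambdas
  base <- threshold_rule(e)
  hot <- e > base & e > 0
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < min_width) next
    a <- profile$grid[starts[k]] - profile$delta
    b <- profile$grid[ends[k]]
    out[[length(out) + 1L]] <- frequency_band(max(a, 1e-6), b,
                                              unit = "normalized")
  }
  out
}

#' Multiscale scan over several increments
#'
#' Runs \code{\link{scan_profile}} + \code{\link{detect_bands}} for a sequence
#' of \eqn{\Delta} values and reports consensus bands: the frequency regions
#' detected for at least half (rounded up) of the increments. Bumps that are
#' stable across scales are more trustworthy than single-scale detections.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param deltas vector of at least two normalized increments.
#' @param Q optional number of grid points per increment; default spans
#'   \eqn{(0, 0.5)} for each \eqn{\Delta}.
#' @return List with \code{profiles}, \code{detections} (per \eqn{\Delta})
#'   and \code{consensus} (list of \code{\link{frequency_band}}).
#' @export
multiscale_scan <- function(est, deltas, Q = NULL) {
  stopifnot(inherits(est, "spectral_estimate"), length(deltas) >= 2L)
  profiles <- list()
  detections <- list()
  for (i in seq_along(deltas)) {
    d <- deltas[i]
    q <- if (is.null(Q)) floor(0.499 / d) else Q
    profiles[[i]] <- scan_profile(est, delta = d, Q = q)
    detections[[i]] <- detect_bands(profiles[[i]])
  }
  fine <- seq(5e-4, 0.4995, by = 1e-3)
  cover <- integer(length(fine))
  for (det in detections) {
    inside <- rep(FALSE, length(fine))
    for (bd in det) {
      nv <- band_endpoints(bd, "normalized")
      inside <- inside | (fine > nv[1L] & fine <= nv[2L])
    }
    cover <- cover + inside
  }
  need <- ceiling(length(deltas) / 2)
  hot <- cover >= need
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  consensus <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    consensus[[length(consensus) + 1L]] <-
      frequency_band(max(fine[starts[k]] - 5e-4, 1e-6),
                     min(fine[ends[k]] + 5e-4, 0.4999),
                     unit = "normalized")
  }
  list(profiles = profiles, detections = detections, consensus = consensus)
}
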
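#' Fourier frequency grid for a series of length T
#'
#' The Fourier frequencies are \eqn{\omega_j = 2\pi j / T} for integer
#' \eqn{j \in (-\lfloor T/2 \rfloor, \lfloor T/2 \rfloor]}, covering
#' \eqn{(-\pi, \pi]}. Band statistics are evaluated only on the positive
#' interior frequencies \eqn{\omega_j \in (0, \pi)}; the endpoints 0 and
#' \eqn{\pi} contribute to kernel smoothing but never to band integrals.
#'
#' @param n_time series length T (integer, >= 2).
#' @return Object of class \code{"fourier_grid"}: list with \code{j}
#'   (integer indices), \code{omegas} (angular frequencies, increasing),
#'   \code{spacing} (\eqn{2\pi/T}), \code{positive} (logical mask of
#'   \eqn{\omega \in (0,\pi)}), \code{n_time}.
#' @export
fourier_grid <- function(n_time) {
  n_time <- as.integer(n_time)
  stopifnot(n_time >= 2L)
  j <- seq.int(-floor(n_time / 2) + 1L, floor(n_time / 2))
  omegas <- 2 * pi * j / n_time
  structure(
    list(j = j, omegas = omegas, spacing = 2 * pi / n_time,
         positive = (j > 0L & omegas < pi - 1e-12), n_time = n_time),
    class = "fourier_grid"
  )
}

# Wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi + 1e-15] <- pi
  y
}

# Indices (into an increasing vector of angular frequencies) belonging to the
# band (a, b]. The half-open convention makes band partitions disjoint and
# exhaustive: a frequency equal to a boundary belongs to the lower band.
band_members <- function(omegas, a, b) {
  which(omegas > a & omegas <= b)
}
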
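#' Smoothing kernels for spectral estimation
#'
#' Registered kernels are supported on \eqn{[-\pi, \pi]} and integrate to 1.
#' The default \code{"epanechnikov"},
#' \eqn{K(\omega) = \frac{3}{4\pi}\{1 - (\omega/\pi)^2\}_+}, is bounded,
#' symmetric, nonnegative and Lipschitz continuous, as spectral consistency
#' theory requires. The \code{"boxcar"} kernel \eqn{1/(2\pi)} on
#' \eqn{[-\pi,\pi]} is registered for testing only: it is not Lipschitz at its
#' support edges but makes complete-smoothing limits exact.
#'
#' @param name kernel identifier, one of \code{"epanechnikov"}, \code{"boxcar"}.
#' @return A list with elements \code{name}, \code{fun} (vectorized kernel
#'   function), and \code{test_only}.
#' @export
spectral_kernel <- function(name = c("epanechnikov", "boxcar")) {
  name <- match.arg(name)
  fun <- switch(name,
    epanechnikov = function(u) {
      v <- 1 - (u / pi)^2
      ifelse(abs(u) <= pi, 0.75 / pi * v, 0)
    },
    boxcar = function(u) ifelse(abs(u) <= pi, 1 / (2 * pi), 0)
  )
  list(name = name, fun = fun, test_only = identical(name, "boxcar"))
}

#' Default smoothing bandwidth
#'
#' \eqn{h = 0.3\, T^{-0.3}}. The exponent \eqn{-0.3} lies strictly inside
#' the admissible range for the spectral asymptotics used here
#' (\eqn{h^{9/2} T \to 0} and \eqn{h^2 T \to \infty} require
#' \eqn{T^{-1/2} \ll h \ll T^{-2/9}}). Because the registered kernels are
#' supported on \eqn{[-\pi, \pi]}, the effective spectral window halfwidth is
#' \eqn{\pi h}; the constant 0.3 keeps that window narrow enough to resolve
#' autoregressive resonances at \eqn{T \sim 10^3} while averaging enough
#' Fourier ordinates (about \eqn{hT}) for stable estimates. See the package
#' vignette for the calibration rationale.
#'
#' @param n_time series length T.
#' @return Positive bandwidth in angular frequency units.
#' @export
default_bandwidth <- function(n_time) {
  0.3 * n_time^(-0.3)
}

# Resolve a kernel argument that may be a name or an object from
# spectral_kernel().
resolve_kernel <- function(kernel) {
  if (is.character(kernel)) {
    if (!kernel %in% c("epanechnikov", "boxcar")) {
      stop("unknown kernel: ", kernel)
    }
    spectral_kernel(kernel)
  } else if (is.list(kernel) && is.function(kernel$fun)) {
    kernel
  } else {
    stop("kernel must be a registered kernel name or a spectral_kernel() object")
  }
}
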
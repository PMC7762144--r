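#' Joint spectral estimate of two equal-dimension epochs
#'
#' Stacks the two epochs into the \eqn{(d_1 + d_2)}-variate series
#' \eqn{Z_t = (X_t', Y_t')'} and smooths its periodogram with a common kernel
#' and bandwidth. Block accessors expose the marginal spectra
#' \eqn{f_{Z,11}, f_{Z,22}} and the cross-spectra \eqn{f_{Z,12}, f_{Z,21}};
#' because the stacked DFT is the concatenation of the marginal DFTs, the
#' diagonal blocks equal the separately computed marginal estimates exactly.
#'
#' @param epoch_x,epoch_y \code{\link{epoch_series}} objects with equal
#'   \code{T} and equal dimension.
#' @inheritParams spectral_estimate
#' @return Object of class \code{"joint_spectral_estimate"}: list with
#'   \code{est} (the stacked \code{\link{spectral_estimate}}) and
#'   \code{d1}, \code{d2}.
#' @export
joint_spectral_estimate <- function(epoch_x, epoch_y,
                                    kernel = "epanechnikov", h = NULL) {
  stopifnot(inherits(epoch_x, "epoch_series"), inherits(epoch_y, "epoch_series"))
  if (epoch_x$n_time != epoch_y$n_time) {
    stop("epochs must have equal length T")
  }
  if (epoch_x$n_comp != epoch_y$n_comp) {
    stop("the equality test requires equal dimensions (d1 = d2); got ",
         epoch_x$n_comp, " and ", epoch_y$n_comp)
  }
  z <- epoch_series(cbind(center_epoch(epoch_x)$values,
                          center_epoch(epoch_y)$values))
  structure(
    list(est = spectral_estimate(z, kernel = kernel, h = h),
         d1 = epoch_x$n_comp, d2 = epoch_y$n_comp),
    class = "joint_spectral_estimate"
  )
}

#' Extract a block of a joint spectral estimate
#'
#' @param joint a \code{\link{joint_spectral_estimate}}.
#' @param p,q block row and column indices in \{1, 2\} (1 = first epoch's
#'   components, 2 = second epoch's).
#' @return Complex \code{d1 x d1 x n_freq} array \eqn{f_{Z,pq}(\omega)}.
#' @export
joint_block <- function(joint, p, q) {
  stopifnot(inherits(joint, "joint_spectral_estimate"),
            p %in% 1:2, q %in% 1:2)
  d1 <- joint$d1
  ri <- if (p == 1L) seq_len(d1) else d1 + seq_len(joint$d2)
  ci <- if (q == 1L) seq_len(d1) else d1 + seq_len(joint$d2)
  joint$est$f[ri, ci, , drop = FALSE]
}

#' L2 discrepancy between two spectral matrix estimates over a band
#'
#' \eqn{\hat D = \int_a^b \|\mathrm{vec}(\hat f_X(\omega) -
#' \hat f_Y(\omega))\|_2^2 \, d\omega}, discretized as a Riemann sum over the
#' Fourier frequencies in the band with weight \eqn{2\pi/T}. Requires the two
#' estimates to share dimension, length, kernel and bandwidth.
#'
#' @param est_x,est_y \code{\link{spectral_estimate}} objects.
#' @param band a \code{\link{frequency_band}}.
#' @return Nonnegative discrepancy; zero iff the estimates coincide on the
#'   band's frequency grid.
#' @export
dxy_statistic <- function(est_x, est_y, band) {
  stopifnot(inherits(est_x, "spectral_estimate"),
            inherits(est_y, "spectral_estimate"),
            inherits(band, "frequency_band"))
  if (est_x$n_comp != est_y$n_comp) stop("estimates have different dimensions")
  if (est_x$n_time != est_y$n_time) stop("estimates have different lengths")
  if (!identical(est_x$kernel, est_y$kernel) ||
      !isTRUE(all.equal(est_x$h, est_y$h))) {
    stop("estimates must share kernel and bandwidth")
  }
  idx <- band_members(est_x$omegas, band$a, band$b)
  if (length(idx) == 0L) {
    stop(sprintf("band (%.4f, %.4f) contains no Fourier frequency at T = %d",
                 band$a, band$b, est_x$n_time))
  }
  diff2 <- apply(abs(est_x$f[, , idx, drop = FALSE] -
                     est_y$f[, , idx, drop = FALSE])^2, 3L, sum)
  (2 * pi / est_x$n_time) * sum(diff2)
}

#' Kernel constants for the spectral equality test
#'
#' \eqn{A_K = \int_{-\pi}^{\pi} K^2(v)\, dv} and
#' \eqn{B_K = 4 \int_{a-\pi}^{b+\pi} \left\{\int_{-\pi}^{\pi} K(u) K(u+v)\, du
#' \right\}^2 dv}, evaluated by composite Simpson quadrature.
#'
#' @param kernel kernel name or \code{\link{spectral_kernel}} object.
#' @param band a \code{\link{frequency_band}} (its endpoints set the outer
#'   integration range of \eqn{B_K}).
#' @param n_quad Simpson panels per axis (default 1200; raise for refinement
#'   checks).
#' @return List with positive constants \code{A_K} and \code{B_K}.
#' @export
kernel_constants <- function(kernel, band, n_quad = 1200L) {
  kernel <- resolve_kernel(kernel)
  stopifnot(inherits(band, "frequency_band"))
  if (n_quad %% 2L == 1L) n_quad <- n_quad + 1L
  a_k <- simpson(function(v) kernel$fun(v)^2, -pi, pi, n_quad)
  # Inner convolution g(v) = int K(u) K(u+v) du: integrate over the exact
  # overlap of the two supports so the integrand is smooth on the panel
  # (avoids the support-edge kinks that slow composite quadrature).
  n_u <- max(400L, n_quad %/% 4L)
  if (n_u %% 2L == 1L) n_u <- n_u + 1L
  conv_g <- function(v) {
    lo <- max(-pi, -pi - v)
    hi <- min(pi, pi - v)
    if (hi <= lo) return(0)
    simpson(function(u) kernel$fun(u) * kernel$fun(u + v), lo, hi, n_u)
  }
  v <- seq(band$a - pi, band$b + pi, length.out = n_quad + 1L)
  g <- vapply(v, conv_g, numeric(1L))
  sv <- simpson_weights(n_quad) * ((band$b - band$a + 2 * pi) / n_quad)
  b_k <- 4 * sum(sv * g^2)
  list(A_K = a_k, B_K = b_k)
}

# Simpson composite weights (1,4,2,...,4,1)/3 for n panels (n even).
simpson_weights <- function(n) {
  w <- rep(c(4, 2), length.out = n - 1L)
  c(1, w, 1) / 3
}

#' Null mean and variance of the L2 spectral discrepancy
#'
#' Plug-in estimates of the first-order mean and variance of
#' \code{\link{dxy_statistic}} under the null of equal spectra, built from the
#' joint smoothed spectrum of the stacked series. With \eqn{f_{Z,pq}} the
#' blocks of the joint spectrum and \eqn{\delta} the Kronecker delta,
#' \deqn{\hat\mu = \frac{2\pi A_K}{Th} \int_a^b \sum_{p_1,p_2=1}^{2}
#'   (-1 + 2\delta_{p_1 p_2})\, |\mathrm{tr} f_{Z,p_1p_2}(\omega)|^2 d\omega,}
#' \deqn{\hat\sigma^2 = \frac{2\pi^2 B_K}{T^2 h} \int_a^b
#'   \sum_{p_1,p_2,p_3,p_4=1}^{2} (-1+2\delta_{p_1p_2})(-1+2\delta_{p_3p_4})
#'   \left|\mathrm{tr}\{ f_{Z,p_1p_2}(\omega) f_{Z,p_3p_4}(\omega)^* \}
#'   \right|^2 d\omega,}
#' with \eqn{A_K, B_K} from \code{\link{kernel_constants}} and integrals as
#' Riemann sums over the band's Fourier frequencies. Both sums are
#' nonnegative for any positive semidefinite joint spectrum.
#'
#' @param joint a \code{\link{joint_spectral_estimate}}.
#' @param band a \code{\link{frequency_band}}.
#' @param kernel kernel (must match the one used for \code{joint}).
#' @return List with \code{mu}, \code{sigma2}, \code{A_K}, \code{B_K}.
#' @export
null_mean_variance <- function(joint, band, kernel = "epanechnikov") {
  stopifnot(inherits(joint, "joint_spectral_estimate"))
  kernel <- resolve_kernel(kernel)
  if (!identical(kernel$name, joint$est$kernel)) {
    stop("kernel does not match the one used for the joint estimate")
  }
  kc <- kernel_constants(kernel, band)
  est <- joint$est
  idx <- band_members(est$omegas, band$a, band$b)
  if (length(idx) == 0L) {
    stop(sprintf("band (%.4f, %.4f) contains no Fourier frequency at T = %d",
                 band$a, band$b, est$n_time))
  }
  blocks <- list(list(joint_block(joint, 1, 1), joint_block(joint, 1, 2)),
                 list(joint_block(joint, 2, 1), joint_block(joint, 2, 2)))
  d1 <- joint$d1
  tr_of <- function(arr, k) sum(diag(matrix(arr[, , k], d1, d1)))
  mu_sum <- 0
  var_sum <- 0
  sgn <- function(p, q) if (p == q) 1 else -1
  for (k in idx) {
    f <- lapply(1:2, function(p) lapply(1:2, function(q) {
      matrix(blocks[[p]][[q]][, , k], d1, d1)
    }))
    for (p1 in 1:2) for (p2 in 1:2) {
      tr <- sum(diag(f[[p1]][[p2]]))
      mu_sum <- mu_sum + sgn(p1, p2) * abs(tr)^2
      for (p3 in 1:2) for (p4 in 1:2) {
        tpr <- sum(f[[p1]][[p2]] * Conj(f[[p3]][[p4]]))   # tr(A B*)
        var_sum <- var_sum + sgn(p1, p2) * sgn(p3, p4) * abs(tpr)^2
      }
    }
  }
  n <- est$n_time
  h <- est$h
  mu <- (2 * pi * kc$A_K / (n * h)) * (2 * pi / n) * mu_sum
  sigma2 <- (2 * pi^2 * kc$B_K / (n^2 * h)) * (2 * pi / n) * var_sum
  if (sigma2 <= 0) {
    stop("plug-in variance is nonpositive; the equality test is inconclusive")
  }
  list(mu = mu, sigma2 = sigma2, A_K = kc$A_K, B_K = kc$B_K)
}

#' Test equality of two spectral matrices over a frequency band
#'
#' Tests \eqn{H_0: f_X(\omega) = f_Y(\omega)} for all \eqn{\omega \in (a,b)}
#' for two epochs of equal dimension and length, using the L2 discrepancy
#' \code{\link{dxy_statistic}} standardized by its estimated null mean and
#' variance (\code{\link{null_mean_variance}}); the standardized statistic is
#' referred to the standard normal, with a one-sided upper-tail p-value
#' (large discrepancies indicate inequality).
#'
#' @param epoch_x,epoch_y \code{\link{epoch_series}} objects, equal \code{T}
#'   and dimension.
#' @param band a \code{\link{frequency_band}}.
#' @inheritParams spectral_estimate
#' @return Object of classes \code{"spectral_equality_test"} and
#'   \code{"htest"} with components \code{statistic} (z-score),
#'   \code{p.value}, \code{d_hat}, \code{mu}, \code{sigma2}, \code{A_K},
#'   \code{B_K}, \code{band}, \code{kernel}, \code{h}.
#' @examples
#' set.seed(1)
#' x <- epoch_series(matrix(rnorm(1024), 512, 2))
#' y <- epoch_series(matrix(rnorm(1024), 512, 2))
#' spectral_equality_test(x, y, frequency_band(0.1, 0.2, unit = "normalized"))
#' @export
spectral_equality_test <- function(epoch_x, epoch_y, band,
                                   kernel = "epanechnikov", h = NULL) {
  kernel <- resolve_kernel(kernel)
  joint <- joint_spectral_estimate(epoch_x, epoch_y, kernel = kernel, h = h)
  est <- joint$est
  d1 <- joint$d1
  idx <- band_members(est$omegas, band$a, band$b)
  if (length(idx) == 0L) {
    stop(sprintf("band (%.4f, %.4f) contains no Fourier frequency at T = %d",
                 band$a, band$b, est$n_time))
  }
  fx <- joint_block(joint, 1, 1)[, , idx, drop = FALSE]
  fy <- joint_block(joint, 2, 2)[, , idx, drop = FALSE]
  d_hat <- (2 * pi / est$n_time) * sum(abs(fx - fy)^2)
  nv <- null_mean_variance(joint, band, kernel = kernel)
  z <- (d_hat - nv$mu) / sqrt(nv$sigma2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(
    list(statistic = c(z = z), p.value = p,
         d_hat = d_hat, mu = nv$mu, sigma2 = nv$sigma2,
         A_K = nv$A_K, B_K = nv$B_K, band = band,
         kernel = kernel$name, h = est$h,
         method = "L2 spectral matrix equality test (normal approximation)",
         data.name = sprintf("two %d-variate epochs of length %d",
                             d1, est$n_time),
         alternative = "spectra differ somewhere on the band"),
    class = c("spectral_equality_test", "htest")
  )
}

#' Export an equality test result as JSON
#'
#' @param test a \code{\link{spectral_equality_test}} result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_eqtest_json <- function(test, path) {
  stopifnot(inherits(test, "spectral_equality_test"))
  rec <- list(
    d_hat = test$d_hat, mu = test$mu, sigma2 = test$sigma2,
    z_score = unname(test$statistic), p_value = test$p.value,
    A_K = test$A_K, B_K = test$B_K,
    band = list(a = test$band$a, b = test$band$b, label = test$band$label),
    kernel = test$kernel, bandwidth_h = test$h
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
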
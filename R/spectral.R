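#' Discrete Fourier transform of an epoch
#'
#' Computes \eqn{J(\omega_j) = (2\pi T)^{-1/2} \sum_{t=1}^{T} X_t e^{-it\omega_j}}
#' at every Fourier frequency \eqn{\omega_j = 2\pi j/T},
#' \eqn{j \in (-\lfloor T/2\rfloor, \lfloor T/2\rfloor]}. The epoch is centered
#' first if it is not already.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @return Complex matrix with one row per Fourier frequency (ordered as in
#'   \code{\link{fourier_grid}}) and one column per component; the grid is
#'   attached as attribute \code{"grid"}.
#' @export
epoch_dft <- function(epoch) {
  stopifnot(inherits(epoch, "epoch_series"))
  epoch <- center_epoch(epoch)
  x <- epoch$values
  n <- epoch$n_time
  grid <- fourier_grid(n)
  f <- stats::mvfft(x)
  rows <- (grid$j %% n) + 1L
  phase <- exp(-1i * grid$omegas)
  j_mat <- (f[rows, , drop = FALSE] * phase) / sqrt(2 * pi * n)
  attr(j_mat, "grid") <- grid
  j_mat
}

#' Periodogram matrices of an epoch
#'
#' The periodogram at frequency \eqn{\omega_j} is the rank-one outer product
#' \eqn{I(\omega_j) = J(\omega_j) J(\omega_j)^*} of the DFT vector; each matrix
#' is Hermitian positive semidefinite of rank at most one.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @return List of class \code{"periodogram"} with \code{grid}
#'   (\code{\link{fourier_grid}}) and \code{I}, a complex
#'   \code{d x d x n_freq} array.
#' @export
epoch_periodogram <- function(epoch) {
  j_mat <- epoch_dft(epoch)
  grid <- attr(j_mat, "grid")
  d <- ncol(j_mat)
  nf <- nrow(j_mat)
  I <- array(0i, dim = c(d, d, nf))
  for (r in seq_len(d)) {
    for (s in seq_len(d)) {
      I[r, s, ] <- j_mat[, r] * Conj(j_mat[, s])
    }
  }
  structure(list(grid = grid, I = I), class = "periodogram")
}

# Kernel smoothing weights on the cyclic Fourier grid (m = 0..T-1), plus their
# FFT, cached per (kernel, T, h) because the bootstrap re-estimates spectra
# thousands of times at fixed (T, h).
.spec_cache <- new.env(parent = emptyenv())

kernel_weights_fft <- function(kernel, n_time, h) {
  key <- paste(kernel$name, n_time, format(h, digits = 17), sep = "|")
  hit <- .spec_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- seq_len(n_time) - 1L
  w <- kernel$fun(wrap_angle(2 * pi * m / n_time) / h) / h
  out <- list(w = w, W = stats::fft(w), n_pos = sum(w > 0))
  .spec_cache[[key]] <- out
  out
}

#' Kernel-smoothed spectral matrix estimate
#'
#' Estimates the spectral matrix
#' \eqn{\hat f(\omega) = \frac{2\pi}{T} \sum_j K_h(\omega - \omega_j)\, I(\omega_j)},
#' where \eqn{K_h(u) = K(u/h)/h} and the frequency difference is taken modulo
#' \eqn{2\pi} into \eqn{(-\pi,\pi]} (periodic smoothing on the circle, so
#' frequencies near 0 and \eqn{\pi} are not starved of kernel mass). The sum
#' runs over all Fourier frequencies; the estimate is returned on the positive
#' interior Fourier frequencies \eqn{\omega \in (0, \pi)}, which is the grid
#' on which all band statistics are evaluated.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @param kernel kernel name or \code{\link{spectral_kernel}} object.
#' @param h bandwidth in angular frequency units; default
#'   \code{\link{default_bandwidth}(T)}.
#' @return Object of class \code{"spectral_estimate"}: list with
#'   \code{omegas} (positive interior Fourier frequencies), \code{f}
#'   (complex \code{d x d x n_freq} array, Hermitian at every frequency),
#'   \code{power} (per-frequency squared Frobenius norm
#'   \eqn{\|\mathrm{vec}\,\hat f(\omega)\|_2^2}), \code{kernel}, \code{h},
#'   \code{n_time}, \code{n_comp}.
#' @examples
#' e <- epoch_series(matrix(rnorm(512), 512, 1))
#' est <- spectral_estimate(e)
#' mean(Re(est$f[1, 1, ]))  # near 1/(2*pi) for unit white noise
#' @export
spectral_estimate <- function(epoch, kernel = "epanechnikov", h = NULL) {
  stopifnot(inherits(epoch, "epoch_series"))
  epoch <- center_epoch(epoch)
  kernel <- resolve_kernel(kernel)
  n <- epoch$n_time
  d <- epoch$n_comp
  if (is.null(h)) h <- default_bandwidth(n)
  stopifnot(is.numeric(h), length(h) == 1L, h > 0)
  kw <- kernel_weights_fft(kernel, n, h)
  if (kw$n_pos < 3L) {
    warning("bandwidth h = ", format(h),
            " gives fewer than 3 Fourier frequencies positive kernel weight ",
            "at every evaluation frequency; increase h")
  }
  # Periodogram entries on the cyclic grid m = 0..T-1 (phase factors cancel in
  # J J*), then exact circular convolution with the kernel weights via FFT.
  f_big <- stats::mvfft(epoch$values)
  scale <- 1 / (2 * pi * n)
  jmax <- ceiling(n / 2) - 1L
  keep <- seq_len(jmax) + 1L            # cyclic rows for omega in (0, pi)
  f_arr <- array(0i, dim = c(d, d, jmax))
  for (r in seq_len(d)) {
    for (s in r:d) {
      i_rs <- (f_big[, r] * Conj(f_big[, s])) * scale
      sm <- stats::fft(stats::fft(i_rs) * kw$W, inverse = TRUE) / n
      vals <- (2 * pi / n) * sm[keep]
      if (s == r) {
        f_arr[r, r, ] <- Re(vals) + 0i
      } else {
        f_arr[r, s, ] <- vals
        f_arr[s, r, ] <- Conj(vals)
      }
    }
  }
  power <- apply(abs(f_arr)^2, 3L, sum)
  structure(
    list(omegas = 2 * pi * seq_len(jmax) / n, f = f_arr, power = power,
         kernel = kernel$name, h = h, n_time = n, n_comp = d),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("Smoothed spectral matrix estimate: d =", x$n_comp, ", T =", x$n_time,
      "\n  kernel =", x$kernel, ", h =", format(x$h, digits = 4),
      ",", length(x$omegas), "frequencies in (0, pi)\n")
  invisible(x)
}

#' Evaluate the smoothed spectral matrix at arbitrary frequencies
#'
#' Direct-summation version of \code{\link{spectral_estimate}} for frequencies
#' that need not be Fourier frequencies. Identical (up to rounding) to the
#' FFT-convolution path at Fourier frequencies.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @param omega vector of angular frequencies.
#' @inheritParams spectral_estimate
#' @return Complex \code{d x d x length(omega)} array.
#' @export
spectral_density_at <- function(epoch, omega, kernel = "epanechnikov", h = NULL) {
  stopifnot(inherits(epoch, "epoch_series"))
  kernel <- resolve_kernel(kernel)
  n <- epoch$n_time
  if (is.null(h)) h <- default_bandwidth(n)
  pg <- epoch_periodogram(epoch)
  out <- array(0i, dim = c(epoch$n_comp, epoch$n_comp, length(omega)))
  for (k in seq_along(omega)) {
    w <- kernel$fun(wrap_angle(omega[k] - pg$grid$omegas) / h) / h
    acc <- matrix(0i, epoch$n_comp, epoch$n_comp)
    for (j in which(w > 0)) acc <- acc + w[j] * pg$I[, , j]
    out[, , k] <- (2 * pi / n) * acc
  }
  out
}

#' Squared coherence between two components
#'
#' \eqn{C_{pq}(\omega) = |\hat f_{pq}(\omega)|^2 /
#' \{\hat f_{pp}(\omega) \hat f_{qq}(\omega)\}}, the frequency-resolved squared
#' correlation between components \code{p} and \code{q}, in \eqn{[0, 1]}.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param p,q distinct component indices.
#' @return Numeric vector of coherences along \code{est$omegas}.
#' @export
squared_coherence <- function(est, p, q) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (p == q) stop("p and q must be distinct components")
  num <- abs(est$f[p, q, ])^2
  den <- Re(est$f[p, p, ]) * Re(est$f[q, q, ])
  zero <- which(den <= 0)
  if (length(zero) > 0L) {
    stop("zero diagonal spectrum at omega = ", format(est$omegas[zero[1L]]),
         "; coherence undefined")
  }
  co <- num / den
  over <- co > 1 & co <= 1 + 1e-8
  co[over] <- 1
  co[co < 0 & co >= -1e-8] <- 0
  co
}

#' Export a spectral estimate as tidy CSV
#'
#' Writes one row per (frequency, matrix entry): columns \code{omega},
#' \code{row}, \code{col}, \code{real}, \code{imag}.
#'
#' @param est a \code{\link{spectral_estimate}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_spectral_csv <- function(est, path) {
  stopifnot(inherits(est, "spectral_estimate"))
  d <- est$n_comp
  idx <- expand.grid(row = seq_len(d), col = seq_len(d),
                     k = seq_along(est$omegas))
  vals <- est$f[cbind(idx$row, idx$col, idx$k)]
  df <- data.frame(omega = est$omegas[idx$k], row = idx$row, col = idx$col,
                   real = Re(vals), imag = Im(vals))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
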
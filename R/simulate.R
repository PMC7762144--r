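#' Specify a stationary AR(2) process
#'
#' \eqn{v_t = \phi_1 v_{t-1} + \phi_2 v_{t-2} + \epsilon_t} with Gaussian
#' innovations. The coefficients must lie inside the stationarity triangle
#' (\eqn{\phi_2 + \phi_1 < 1}, \eqn{\phi_2 - \phi_1 < 1},
#' \eqn{|\phi_2| < 1}).
#'
#' @param phi1,phi2 AR coefficients.
#' @param innovation_sd innovation standard deviation (default 1).
#' @return Object of class \code{"ar2_spec"}.
#' @examples
#' ar2_spec(1.25, -0.75)
#' @export
ar2_spec <- function(phi1, phi2, innovation_sd = 1) {
  stopifnot(is.numeric(phi1), is.numeric(phi2), innovation_sd > 0)
  if (!(phi2 + phi1 < 1 && phi2 - phi1 < 1 && abs(phi2) < 1)) {
    stop("AR(2) coefficients (", phi1, ", ", phi2,
         ") are outside the stationarity triangle")
  }
  structure(list(phi1 = phi1, phi2 = phi2, innovation_sd = innovation_sd),
            class = "ar2_spec")
}

#' Simulate a stationary AR(2) series
#'
#' Runs the AR(2) recursion from zero initial conditions and discards a
#' burn-in. Uses the current RNG state.
#'
#' @param spec an \code{\link{ar2_spec}}.
#' @param n_time output length T.
#' @param burn_in discarded warm-up samples (default 200).
#' @return Numeric vector of length \code{n_time}.
#' @export
simulate_ar2 <- function(spec, n_time, burn_in = 200L) {
  stopifnot(inherits(spec, "ar2_spec"))
  eps <- stats::rnorm(n_time + burn_in, sd = spec$innovation_sd)
  x <- stats::filter(eps, c(spec$phi1, spec$phi2), method = "recursive")
  as.numeric(x)[burn_in + seq_len(n_time)]
}

#' Spectral density of an AR(2) process
#'
#' \eqn{f(\omega) = \frac{\sigma^2}{2\pi}
#' |1 - \phi_1 e^{-i\omega} - \phi_2 e^{-2i\omega}|^{-2}}.
#'
#' @param spec an \code{\link{ar2_spec}}.
#' @param omega angular frequency (vectorized).
#' @return Positive spectral density values.
#' @export
ar2_spectrum <- function(spec, omega) {
  stopifnot(inherits(spec, "ar2_spec"))
  denom <- abs(1 - spec$phi1 * exp(-1i * omega) -
                 spec$phi2 * exp(-2i * omega))^2
  spec$innovation_sd^2 / (2 * pi) / denom
}

#' Peak frequency of an AR(2) spectral density
#'
#' Minimizes the spectral denominator over \eqn{c = \cos\omega}:
#' \eqn{c^* = -\phi_1(1-\phi_2)/(4\phi_2)} when \eqn{\phi_2 \neq 0} and
#' \eqn{c^* \in (-1, 1)}; the peak is \eqn{\omega^* = \arccos c^*}, returned
#' on the normalized scale \eqn{\omega^*/(2\pi) \in (0, 0.5)}. Returns
#' \code{NA} when the spectrum has no interior peak (its maximum sits at 0 or
#' \eqn{\pi}).
#'
#' @param spec an \code{\link{ar2_spec}}.
#' @return Normalized peak frequency in \eqn{(0, 0.5)}, or \code{NA}.
#' @examples
#' ar2_peak_frequency(ar2_spec(1.25, -0.75))  # ~0.12
#' @export
ar2_peak_frequency <- function(spec) {
  stopifnot(inherits(spec, "ar2_spec"))
  if (spec$phi2 == 0) {
    return(NA_real_)  # AR(1): monotone spectrum, no interior peak
  }
  c_star <- -spec$phi1 * (1 - spec$phi2) / (4 * spec$phi2)
  if (!(c_star > -1 && c_star < 1)) return(NA_real_)
  # interior critical point is a minimum of the denominator iff -4*phi2 > 0
  if (spec$phi2 >= 0) return(NA_real_)
  acos(c_star) / (2 * pi)
}

#' AR(2) process variance (Yule-Walker closed form)
#'
#' @param spec an \code{\link{ar2_spec}}.
#' @return The stationary variance
#'   \eqn{\gamma_0 = \sigma^2 (1-\phi_2) / [(1+\phi_2)\{(1-\phi_2)^2 -
#'   \phi_1^2\}]}.
#' @export
ar2_variance <- function(spec) {
  stopifnot(inherits(spec, "ar2_spec"))
  p1 <- spec$phi1
  p2 <- spec$phi2
  spec$innovation_sd^2 * (1 - p2) / ((1 + p2) * ((1 - p2)^2 - p1^2))
}

# The three AR(2) components of the two-regime epoch design.
two_regime_specs <- function() {
  list(v0 = ar2_spec(-0.8, -0.7),
       v1 = ar2_spec(0.25, -0.75),
       v2 = ar2_spec(1.25, -0.75))
}

#' Simulate one epoch of the two-regime benchmark design
#'
#' A benchmark with \code{N} epochs whose latent dimension changes midway:
#' epochs \eqn{i < N/2} are trivariate, each component \eqn{k = 1, 2, 3}
#' equal to \eqn{v_{0,t+k-1} + v_{1,t+k-1}} built from shared realizations of
#' two independent AR(2) processes with coefficients \eqn{(-0.8, -0.7)}
#' (spectral peak near normalized 0.33) and \eqn{(0.25, -0.75)} (peak near
#' 0.23); epochs \eqn{i \ge N/2} are bivariate with components
#' \eqn{v_{2,t+k-1}}, \eqn{k = 1, 2}, from a single AR(2) with coefficients
#' \eqn{(1.25, -0.75)} (peak near 0.12). Components within an epoch are
#' lag-shifted copies, so the dimension change (3 to 2) is accompanied by a
#' clear change in where spectral power lives. Innovations have unit
#' standard deviation. Epoch indices are 1-based; with \code{N = 600},
#' epochs 1-299 are trivariate and 300-600 bivariate.
#'
#' @param i epoch index in \code{1:N}.
#' @param n_epochs total number of epochs N (even; default 600).
#' @param n_time samples per epoch (default 1000).
#' @return An \code{\link{epoch_series}} with \code{d = 3} (first regime) or
#'   \code{d = 2} (second regime).
#' @export
example_epoch <- function(i, n_epochs = 600L, n_time = 1000L) {
  stopifnot(n_epochs %% 2L == 0L)
  if (!(i >= 1L && i <= n_epochs)) {
    stop("epoch index must be in 1..", n_epochs)
  }
  specs <- two_regime_specs()
  if (i < n_epochs / 2) {
    v0 <- simulate_ar2(specs$v0, n_time + 2L)
    v1 <- simulate_ar2(specs$v1, n_time + 2L)
    cols <- vapply(1:3, function(k) {
      v0[(k - 1L) + seq_len(n_time)] + v1[(k - 1L) + seq_len(n_time)]
    }, numeric(n_time))
  } else {
    v2 <- simulate_ar2(specs$v2, n_time + 1L)
    cols <- vapply(1:2, function(k) {
      v2[(k - 1L) + seq_len(n_time)]
    }, numeric(n_time))
  }
  # keep raw values so the exact lag-shift structure between columns is
  # preserved; spectral estimation centers at estimation time
  epoch_series(cols, epoch_index = as.integer(i), center = FALSE)
}

#' Analytic spectral density of the two-regime design
#'
#' Population univariate spectral density of the processes driving
#' \code{\link{example_epoch}}: the first regime's components have density
#' \eqn{f_{v_0} + f_{v_1}} (independent sum), the second regime's
#' \eqn{f_{v_2}}.
#'
#' @param regime 1 or 2.
#' @param omega angular frequencies.
#' @return Spectral density values.
#' @export
example_regime_spectrum <- function(regime, omega) {
  specs <- two_regime_specs()
  if (regime == 1L) {
    ar2_spectrum(specs$v0, omega) + ar2_spectrum(specs$v1, omega)
  } else if (regime == 2L) {
    ar2_spectrum(specs$v2, omega)
  } else {
    stop("regime must be 1 or 2")
  }
}

#' Simulate a stable VAR(p) epoch
#'
#' @param coef_list list of \code{d x d} coefficient matrices
#'   \eqn{\Phi_1, \dots, \Phi_p}; the companion matrix must have spectral
#'   radius < 1.
#' @param innovation_cov innovation covariance matrix (default identity).
#' @param n_time output length.
#' @param burn_in discarded warm-up samples (default 500).
#' @return An \code{\link{epoch_series}}.
#' @export
simulate_var <- function(coef_list, innovation_cov = NULL, n_time,
                         burn_in = 500L) {
  stopifnot(is.list(coef_list), length(coef_list) >= 1L)
  d <- nrow(coef_list[[1L]])
  for (m in coef_list) stopifnot(is.matrix(m), nrow(m) == d, ncol(m) == d)
  p <- length(coef_list)
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[seq_len(d), (k - 1L) * d + seq_len(d)] <- coef_list[[k]]
  if (p > 1L) {
    comp[d + seq_len(d * (p - 1L)), seq_len(d * (p - 1L))] <-
      diag(d * (p - 1L))
  }
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1) {
    stop("VAR coefficients are unstable (companion spectral radius >= 1)")
  }
  if (is.null(innovation_cov)) innovation_cov <- diag(d)
  chol_s <- chol(innovation_cov)
  total <- n_time + burn_in
  eps <- matrix(stats::rnorm(total * d), total, d) %*% chol_s
  x <- matrix(0, total, d)
  for (t in seq_len(total)) {
    acc <- eps[t, ]
    for (k in seq_len(p)) {
      if (t - k >= 1L) acc <- acc + as.numeric(coef_list[[k]] %*% x[t - k, ])
    }
    x[t, ] <- acc
  }
  epoch_series(x[burn_in + seq_len(n_time), , drop = FALSE])
}

#' Build a spectral estimate object from a known spectral field
#'
#' Injects an analytically known spectral matrix field \eqn{\omega \mapsto
#' f(\omega)} into the \code{"spectral_estimate"} container on the positive
#' Fourier grid of a nominal length \code{n_time}, bypassing estimation.
#' Intended for oracle computations and tests of the band statistics.
#'
#' @param field function mapping an angular frequency to a \code{d x d}
#'   matrix (or a scalar for \code{d = 1}).
#' @param n_time nominal series length defining the Fourier grid.
#' @param n_comp dimension d of the field's matrices.
#' @return A \code{"spectral_estimate"} with \code{kernel = "injected"}.
#' @export
synthetic_spectral_estimate <- function(field, n_time, n_comp = 1L) {
  jmax <- ceiling(n_time / 2) - 1L
  omegas <- 2 * pi * seq_len(jmax) / n_time
  f_arr <- array(0i, dim = c(n_comp, n_comp, jmax))
  for (k in seq_len(jmax)) {
    m <- field(omegas[k])
    f_arr[, , k] <- matrix(as.complex(m), n_comp, n_comp)
  }
  structure(
    list(omegas = omegas, f = f_arr, power = apply(abs(f_arr)^2, 3L, sum),
         kernel = "injected", h = NA_real_, n_time = as.integer(n_time),
         n_comp = as.integer(n_comp)),
    class = "spectral_estimate"
  )
}

#' Write a full two-regime benchmark dataset to disk
#'
#' Generates all \code{N} epochs of \code{\link{example_epoch}}, writes one
#' CSV per epoch plus a YAML manifest listing the files in epoch order, for
#' end-to-end pipeline runs.
#'
#' @param dir output directory (created if missing).
#' @param n_epochs,n_time design size (defaults 600 epochs of 1000 samples).
#' @param seed RNG seed.
#' @param sampling_rate_hz sampling rate recorded in the manifest
#'   (default 1000).
#' @return Path to the manifest file, invisibly.
#' @export
write_example_dataset <- function(dir, n_epochs = 600L, n_time = 1000L,
                                  seed = 1L, sampling_rate_hz = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- character(n_epochs)
  for (i in seq_len(n_epochs)) {
    e <- example_epoch(i, n_epochs, n_time)
    files[i] <- sprintf("epoch_%04d.csv", i)
    utils::write.csv(as.data.frame(e$values),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(sampling_rate_hz = sampling_rate_hz,
                        epochs = as.list(files)), manifest)
  invisible(manifest)
}
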
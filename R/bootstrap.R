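#' Stationary bootstrap index vector
#'
#' Draws one resampling index vector of length \code{T} by concatenating
#' blocks with independent geometric lengths (mean
#' \code{expected_block_length}) and uniform random start points, wrapping
#' circularly at \code{T}. The same index vector is applied to all components
#' of a multivariate epoch jointly, preserving cross-series dependence.
#' Uses the current RNG state; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param n_time series length T.
#' @param expected_block_length mean block length (>= 1).
#' @return Integer vector of length \code{n_time} with values in
#'   \code{1:n_time}.
#' @export
stationary_bootstrap_indices <- function(n_time, expected_block_length) {
  stopifnot(n_time >= 1L, expected_block_length >= 1)
  p <- 1 / expected_block_length
  idx <- integer(0L)
  while (length(idx) < n_time) {
    start <- sample.int(n_time, 1L)
    len <- if (p <= 1e-12) n_time else stats::rgeom(1L, p) + 1L
    len <- min(len, n_time - length(idx))
    idx <- c(idx, ((start - 1L + seq_len(len) - 1L) %% n_time) + 1L)
  }
  idx
}

#' Automatic expected block length (flat-top autocorrelation rule)
#'
#' Selects the stationary-bootstrap expected block length for each component
#' by the flat-top lag-window plug-in rule of Politis-White with the
#' Patton-Politis-White correction, then averages over components. The rule
#' picks the largest significant autocorrelation lag by comparing the sample
#' autocorrelations against a \eqn{2\sqrt{\log_{10}T/T}} threshold over a
#' moving window, sets the lag-window span to twice that lag, and combines
#' the flat-top-weighted autocovariances into
#' \eqn{b = (2 \hat G^2 / D_{SB})^{1/3} T^{1/3}} with
#' \eqn{D_{SB} = 2 \hat g(0)^2}.
#'
#' @param epoch an \code{\link{epoch_series}} with \code{T >= 50}.
#' @return Positive expected block length (floored at 1). Constant columns
#'   are skipped with a warning.
#' @export
auto_block_length <- function(epoch) {
  stopifnot(inherits(epoch, "epoch_series"))
  n <- epoch$n_time
  if (n < 50L) stop("automatic block length needs T >= 50")
  vals <- numeric(0L)
  for (j in seq_len(epoch$n_comp)) {
    x <- epoch$values[, j]
    if (stats::sd(x) == 0) {
      warning("column ", j, " is constant; skipped in block-length selection")
      next
    }
    vals <- c(vals, block_length_one(x))
  }
  if (length(vals) == 0L) stop("no usable columns for block-length selection")
  max(1, mean(vals))
}

# Politis-White (2004) b.star for one series, with the Patton-Politis-White
# (2009) correction D_SB = 2 g(0)^2.
block_length_one <- function(x) {
  n <- length(x)
  k_n <- max(5, ceiling(sqrt(log10(n))))
  m_max <- ceiling(sqrt(n)) + k_n
  b_max <- ceiling(min(3 * sqrt(n), n / 3))
  rho <- stats::acf(x, lag.max = m_max, plot = FALSE)$acf[-1L]
  thresh <- 2 * sqrt(log10(n) / n)
  sig <- abs(rho) > thresh
  # m_hat: largest lag followed by k_n consecutive insignificant correlations
  m_hat <- 1L
  num_ins <- 0L
  for (lag in seq_len(m_max)) {
    if (sig[lag]) {
      m_hat <- lag
      num_ins <- 0L
    } else {
      num_ins <- num_ins + 1L
      if (num_ins >= k_n) break
    }
  }
  if (all(!sig)) m_hat <- 1L
  m <- min(2L * m_hat, m_max)
  kk <- seq(-m, m)
  lam <- flat_top(kk / m)
  gam <- vapply(abs(kk), function(k) {
    mean((x[seq_len(n - k)] - mean(x)) * (x[seq_len(n - k) + k] - mean(x)))
  }, numeric(1L))
  g_hat <- sum(lam * abs(kk) * gam)
  g0 <- sum(lam * gam)
  d_sb <- 2 * g0^2
  if (d_sb <= 0) return(1)
  b <- ((2 * g_hat^2 / d_sb)^(1 / 3)) * n^(1 / 3)
  min(max(b, 1), b_max)
}

flat_top <- function(t) {
  at <- abs(t)
  ifelse(at <= 0.5, 1, ifelse(at <= 1, 2 * (1 - at), 0))
}

# Deterministic per-replicate seed derived from (seed, r); order-independent.
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) + 9973 * as.double(r)) %% 2147483629)
}

# One bootstrap FS-ratio: resample rows, re-center, re-estimate the spectrum
# with the same kernel/bandwidth, recompute the ratio. Mirrors
# fs_ratio(spectral_estimate(...)) but avoids object construction overhead;
# equality with the public path is asserted in the test suite.
fsratio_boot_once <- function(values, idx, band_lo, band_hi, kernel, h) {
  x <- values[idx, , drop = FALSE]
  x <- sweep(x, 2L, colMeans(x))
  n <- nrow(x)
  d <- ncol(x)
  kw <- kernel_weights_fft(kernel, n, h)
  f_big <- stats::mvfft(x)
  scale <- 1 / (2 * pi * n)
  jmax <- ceiling(n / 2) - 1L
  keep <- seq_len(jmax) + 1L
  power <- numeric(jmax)
  for (r in seq_len(d)) {
    for (s in r:d) {
      i_rs <- (f_big[, r] * Conj(f_big[, s])) * scale
      sm <- (2 * pi / n) *
        (stats::fft(stats::fft(i_rs) * kw$W, inverse = TRUE) / n)[keep]
      power <- power + (if (s == r) 1 else 2) * abs(sm)^2
    }
  }
  omegas <- 2 * pi * seq_len(jmax) / n
  in_band <- omegas > band_lo & omegas <= band_hi
  sum(power[in_band]) / sum(power)
}

#' Stationary-bootstrap confidence interval for the FS-ratio
#'
#' Resamples the epoch with the stationary block bootstrap, recomputes the
#' full FS-ratio pipeline (re-center, re-estimate the spectral matrix with
#' the same kernel and bandwidth, recompute the ratio) on every replicate,
#' and returns the percentile confidence interval. Replicate \code{r} uses a
#' deterministic substream derived from \code{(seed, r)}, so results are
#' reproducible and independent of evaluation order.
#'
#' @param epoch an \code{\link{epoch_series}}.
#' @param band a \code{\link{frequency_band}}.
#' @param n_replicates number of bootstrap replicates (>= 100 recommended;
#'   default 500).
#' @param block_length expected block length, or \code{"auto"} for the
#'   \code{\link{auto_block_length}} rule.
#' @param seed integer seed driving all resampling.
#' @param ci_level confidence level in (0.5, 1), default 0.95.
#' @inheritParams spectral_estimate
#' @return Object of class \code{"fsratio_ci"}: list with \code{estimate}
#'   (FS-ratio on the original epoch), \code{lower}, \code{upper},
#'   \code{replicates}, \code{block_length}, \code{ci_level}.
#' @export
fsratio_bootstrap_ci <- function(epoch, band, n_replicates = 500L,
                                 block_length = "auto", seed = 1L,
                                 ci_level = 0.95,
                                 kernel = "epanechnikov", h = NULL) {
  stopifnot(inherits(epoch, "epoch_series"), inherits(band, "frequency_band"))
  stopifnot(ci_level > 0.5, ci_level < 1)
  if (n_replicates < 2 / (1 - ci_level)) {
    stop("n_replicates too small to estimate the ", ci_level,
         " percentile endpoints; need at least ", ceiling(2 / (1 - ci_level)))
  }
  kernel <- resolve_kernel(kernel)
  epoch <- center_epoch(epoch)
  if (is.null(h)) h <- default_bandwidth(epoch$n_time)
  if (identical(block_length, "auto")) block_length <- auto_block_length(epoch)
  stopifnot(is.numeric(block_length), block_length >= 1)
  est <- spectral_estimate(epoch, kernel = kernel, h = h)
  point <- fs_ratio(est, band)
  reps <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    idx <- stationary_bootstrap_indices(epoch$n_time, block_length)
    reps[r] <- fsratio_boot_once(epoch$values, idx, band$a, band$b, kernel, h)
  }
  alpha <- 1 - ci_level
  qs <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(estimate = point, lower = qs[1L], upper = qs[2L], replicates = reps,
         block_length = block_length, ci_level = ci_level,
         n_replicates = n_replicates, seed = seed),
    class = "fsratio_ci"
  )
}

#' @export
print.fsratio_ci <- function(x, ...) {
  cat(sprintf(
    "FS-ratio %.4f, %d%% bootstrap CI [%.4f, %.4f] (%d replicates, block length %.1f)\n",
    x$estimate, round(100 * x$ci_level), x$lower, x$upper,
    x$n_replicates, x$block_length))
  invisible(x)
}
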
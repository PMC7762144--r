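# Shared fixtures and independent oracles for the test suite.

rand_epoch <- function(n_time, d) {
  epoch_series(matrix(rnorm(n_time * d), n_time, d))
}

# Brute-force O(T^2) DFT of a centered matrix, straight from the definition
# J(omega_j) = (2 pi T)^{-1/2} sum_{t=1}^T X_t exp(-i t omega_j).
dft_oracle <- function(values) {
  n <- nrow(values)
  grid <- fourier_grid(n)
  out <- matrix(0i, length(grid$omegas), ncol(values))
  for (k in seq_along(grid$omegas)) {
    ph <- exp(-1i * seq_len(n) * grid$omegas[k])
    out[k, ] <- colSums(values * ph) / sqrt(2 * pi * n)
  }
  out
}

# Entry-by-entry band power: vectorize each matrix, sum squared moduli.
band_power_oracle <- function(est, band) {
  tot <- 0
  for (k in seq_along(est$omegas)) {
    w <- est$omegas[k]
    if (w > band$a && w <= band$b) {
      v <- as.vector(est$f[, , k])
      tot <- tot + sum(Re(v)^2 + Im(v)^2)
    }
  }
  (2 * pi / est$n_time) * tot
}

# Flat identity spectral field of dimension d on the grid of length n_time.
flat_field_estimate <- function(n_time, d = 1L) {
  synthetic_spectral_estimate(function(w) diag(d), n_time, d)
}

# Indices of strict local maxima of a vector.
local_maxima <- function(x) {
  which(diff(sign(diff(x))) == -2) + 1L
}

expect_hermitian_psd <- function(est, herm_tol = 1e-10, psd_tol = -1e-8) {
  worst_h <- 0
  worst_e <- Inf
  for (k in seq_along(est$omegas)) {
    m <- matrix(est$f[, , k], est$n_comp, est$n_comp)
    worst_h <- max(worst_h, max(abs(m - Conj(t(m)))))
    hm <- (m + Conj(t(m))) / 2
    worst_e <- min(worst_e, min(Re(eigen(hm, only.values = TRUE)$values)))
  }
  expect_lt(worst_h, herm_tol)
  expect_gt(worst_e, psd_tol)
}
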
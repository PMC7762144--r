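# Build a joint estimate around an injected analytic block field.
make_injected_joint <- function(field, n_time, d1, h) {
  se <- synthetic_spectral_estimate(field, n_time, 2L * d1)
  se$h <- h
  se$kernel <- "epanechnikov"
  structure(list(est = se, d1 = d1, d2 = d1),
            class = "joint_spectral_estimate")
}

# Hand-expanded delta-sign sums, written as explicit loops over matrix
# entries; independent of the package's vectorized implementation.
mu_sigma_oracle <- function(joint, band, kernel = "epanechnikov") {
  est <- joint$est
  kc <- kernel_constants(kernel, band)
  d1 <- joint$d1
  idx <- which(est$omegas > band$a & est$omegas <= band$b)
  mu_int <- 0
  var_int <- 0
  for (k in idx) {
    fz <- matrix(est$f[, , k], 2 * d1, 2 * d1)
    blk <- function(p, q) {
      fz[(p - 1) * d1 + seq_len(d1), (q - 1) * d1 + seq_len(d1), drop = FALSE]
    }
    for (p1 in 1:2) for (p2 in 1:2) {
      s12 <- if (p1 == p2) 1 else -1
      tr <- 0
      for (r in seq_len(d1)) tr <- tr + blk(p1, p2)[r, r]
      mu_int <- mu_int + s12 * (Re(tr)^2 + Im(tr)^2)
      for (p3 in 1:2) for (p4 in 1:2) {
        s34 <- if (p3 == p4) 1 else -1
        tp <- 0
        for (r in seq_len(d1)) for (s in seq_len(d1)) {
          tp <- tp + blk(p1, p2)[r, s] * Conj(blk(p3, p4)[r, s])
        }
        var_int <- var_int + s12 * s34 * (Re(tp)^2 + Im(tp)^2)
      }
    }
  }
  n <- est$n_time
  list(mu = (2 * pi * kc$A_K / (n * est$h)) * (2 * pi / n) * mu_int,
       sigma2 = (2 * pi^2 * kc$B_K / (n^2 * est$h)) * (2 * pi / n) * var_int)
}

test_that("L2 discrepancy vanishes for identical estimates", {
  set.seed(301)
  e <- rand_epoch(256, 2)
  est <- spectral_estimate(e)
  band <- frequency_band(0.1, 0.3, unit = "normalized")
  expect_identical(dxy_statistic(est, est, band), 0)
})

test_that("L2 discrepancy of a constant injected difference is exact", {
  n <- 512
  d <- 2
  cshift <- 0.3
  ex <- synthetic_spectral_estimate(function(w) diag(d), n, d)
  ey <- synthetic_spectral_estimate(function(w) (1 + cshift) * diag(d), n, d)
  a <- 2 * pi * 40 / n
  b <- 2 * pi * 160 / n
  got <- dxy_statistic(ex, ey, frequency_band(a, b))
  expect_equal(got, d * cshift^2 * (b - a), tolerance = 1e-12)
})

test_that("L2 discrepancy matches the entrywise oracle on random pairs", {
  set.seed(302)
  ex <- spectral_estimate(rand_epoch(128, 2))
  ey <- spectral_estimate(rand_epoch(128, 2))
  band <- frequency_band(0.1, 0.35, unit = "normalized")
  idx <- which(ex$omegas > band$a & ex$omegas <= band$b)
  acc <- 0
  for (k in idx) {
    dmat <- matrix(ex$f[, , k] - ey$f[, , k], 2, 2)
    for (r in 1:2) for (s in 1:2) {
      acc <- acc + Re(dmat[r, s])^2 + Im(dmat[r, s])^2
    }
  }
  expect_equal(dxy_statistic(ex, ey, band), (2 * pi / 128) * acc,
               tolerance = 1e-10)
  expect_error(dxy_statistic(ex, spectral_estimate(rand_epoch(128, 3)), band),
               "dimensions")
})

test_that("kernel constants: boxcar closed form and positivity", {
  band <- frequency_band(0.5, 1.5)
  kc_box <- kernel_constants("boxcar", band)
  expect_equal(kc_box$A_K, 1 / (2 * pi), tolerance = 1e-10)
  expect_gt(kc_box$B_K, 0)
  kc_ep <- kernel_constants("epanechnikov", band)
  expect_gt(kc_ep$A_K, 0)
  expect_gt(kc_ep$B_K, 0)
  # closed form for the Epanechnikov-type kernel: A_K = 3/(5*pi)
  expect_equal(kc_ep$A_K, 3 / (5 * pi), tolerance = 1e-8)
})

test_that("kernel constants agree with a 10x-finer quadrature", {
  band <- frequency_band(0.5, 1.5)
  kc1 <- kernel_constants("epanechnikov", band, n_quad = 1200L)
  kc2 <- kernel_constants("epanechnikov", band, n_quad = 12000L)
  expect_equal(kc1$A_K, kc2$A_K, tolerance = 1e-6)
  expect_equal(kc1$B_K, kc2$B_K, tolerance = 1e-6)
})

test_that("null moments reduce to closed forms for flat independent spectra", {
  n <- 512
  d1 <- 2
  h <- 0.1
  joint <- make_injected_joint(function(w) diag(2 * d1) / (2 * pi), n, d1, h)
  band <- frequency_band(2 * pi * 50 / n, 2 * pi * 150 / n)
  nv <- null_mean_variance(joint, band)
  len <- 2 * pi * 100 / n            # exact Riemann band length
  mu_closed <- (2 * pi * nv$A_K / (n * h)) * len * 2 * (d1 / (2 * pi))^2
  sig_closed <- (2 * pi^2 * nv$B_K / (n^2 * h)) * len * 4 * (d1 / (4 * pi^2))^2
  expect_equal(nv$mu, mu_closed, tolerance = 1e-10)
  expect_equal(nv$sigma2, sig_closed, tolerance = 1e-10)
})

test_that("null moments match the hand-expanded loop oracle", {
  # correlated PSD block field: f_Z = M M* with frequency-dependent mixing
  d1 <- 2
  mfun <- function(w) {
    m <- matrix(c(1, 0.5 * exp(1i * w), 0.2, 0.1,
                  0.3 * exp(-2i * w), 1, 0, 0.4,
                  0.2, 0.1 * exp(1i * w), 0.8, 0.2,
                  0, 0.3, 0.1, 1.2), 4, 4)
    m %*% Conj(t(m)) / (2 * pi)
  }
  joint <- make_injected_joint(mfun, 256, d1, h = 0.15)
  band <- frequency_band(0.12, 0.37, unit = "normalized")
  nv <- null_mean_variance(joint, band)
  orc <- mu_sigma_oracle(joint, band)
  expect_equal(nv$mu, orc$mu, tolerance = 1e-10)
  expect_equal(nv$sigma2, orc$sigma2, tolerance = 1e-10)
})

test_that("null moments are symmetric in the two processes", {
  set.seed(303)
  x <- rand_epoch(256, 2)
  y <- rand_epoch(256, 2)
  band <- frequency_band(0.1, 0.3, unit = "normalized")
  nv_xy <- null_mean_variance(joint_spectral_estimate(x, y), band)
  nv_yx <- null_mean_variance(joint_spectral_estimate(y, x), band)
  expect_equal(nv_xy$mu, nv_yx$mu, tolerance = 1e-10)
  expect_equal(nv_xy$sigma2, nv_yx$sigma2, tolerance = 1e-10)
})

test_that("null moments scale as f^2 and f^4 under spectrum doubling", {
  d1 <- 2
  base <- function(w) diag(2 * d1) / (2 * pi)
  joint1 <- make_injected_joint(base, 256, d1, h = 0.1)
  joint2 <- make_injected_joint(function(w) 2 * base(w), 256, d1, h = 0.1)
  band <- frequency_band(0.1, 0.3, unit = "normalized")
  nv1 <- null_mean_variance(joint1, band)
  nv2 <- null_mean_variance(joint2, band)
  expect_equal(nv2$mu, 4 * nv1$mu, tolerance = 1e-10)
  expect_equal(nv2$sigma2, 16 * nv1$sigma2, tolerance = 1e-10)
})

test_that("joint estimate blocks are mutually consistent with the marginals", {
  set.seed(304)
  x <- rand_epoch(256, 2)
  y <- rand_epoch(256, 2)
  h <- default_bandwidth(256)
  joint <- joint_spectral_estimate(x, y, h = h)
  f12 <- joint_block(joint, 1, 2)
  f21 <- joint_block(joint, 2, 1)
  worst <- 0
  for (k in seq_along(joint$est$omegas)) {
    worst <- max(worst, max(abs(matrix(f21[, , k], 2, 2) -
                                Conj(t(matrix(f12[, , k], 2, 2))))))
  }
  expect_lt(worst, 1e-10)
  expect_lt(max(abs(joint_block(joint, 1, 1) - spectral_estimate(x, h = h)$f)),
            1e-10)
  expect_lt(max(abs(joint_block(joint, 2, 2) - spectral_estimate(y, h = h)$f)),
            1e-10)
  expect_error(joint_spectral_estimate(x, rand_epoch(256, 3)), "equal dim")
})

test_that("the equality test is calibrated at its degenerate extremes", {
  set.seed(305)
  x <- rand_epoch(512, 2)
  band <- frequency_band(0.1, 0.3, unit = "normalized")
  # literally identical epochs collapse the plug-in variance (the signed
  # four-index sum cancels exactly), so the test must refuse to report
  expect_error(spectral_equality_test(x, x, band), "inconclusive")
  # two independent draws from one process: D-hat small relative to its
  # null mean more often than not; just check the machinery end to end
  y <- rand_epoch(512, 2)
  res <- spectral_equality_test(x, y, band)
  expect_gte(res$d_hat, 0)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  # a band with no interior Fourier frequency is rejected up front
  expect_error(spectral_equality_test(x, y, frequency_band(0.1, 0.105)),
               "no Fourier frequency")
})

test_that("equality test JSON export round-trips its fields", {
  set.seed(306)
  res <- spectral_equality_test(rand_epoch(256, 2), rand_epoch(256, 2),
                                frequency_band(0.1, 0.3, unit = "normalized"))
  path <- tempfile(fileext = ".json")
  write_eqtest_json(res, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$d_hat, res$d_hat, tolerance = 1e-12)
  expect_equal(rec$z_score, unname(res$statistic), tolerance = 1e-12)
  expect_equal(rec$kernel, "epanechnikov")
})
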
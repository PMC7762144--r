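test_that("band power integrates a flat identity field exactly", {
  n <- 256
  est <- flat_field_estimate(n, d = 3)
  # Fourier-aligned endpoints make the Riemann sum exact: r = d * (b - a)
  a <- 2 * pi * 16 / n
  b <- 2 * pi * 48 / n
  r <- band_power(est, frequency_band(a, b))
  expect_equal(r, 3 * (b - a), tolerance = 1e-12)
})

test_that("band power is additive across an interior Fourier-aligned cut", {
  set.seed(201)
  est <- spectral_estimate(rand_epoch(256, 2))
  a <- 2 * pi * 5 / 256
  b <- 2 * pi * 120 / 256
  cc <- 2 * pi * 60 / 256
  whole <- band_power(est, frequency_band(a, b))
  parts <- band_power(est, frequency_band(a, cc)) +
    band_power(est, frequency_band(cc, b))
  expect_equal(whole, parts, tolerance = 1e-10)
})

test_that("band power matches the entrywise brute-force oracle", {
  set.seed(202)
  est <- spectral_estimate(rand_epoch(128, 3))
  band <- frequency_band(0.08, 0.31, unit = "normalized")
  expect_equal(band_power(est, band), band_power_oracle(est, band),
               tolerance = 1e-10)
  expect_error(band_power(est, frequency_band(0.101, 0.102)),
               "no Fourier frequency")
})

test_that("FS-ratio of the full range is exactly one", {
  set.seed(203)
  est <- spectral_estimate(rand_epoch(128, 2))
  full <- frequency_band(min(est$omegas) / 2, pi - 1e-9)
  expect_identical(fs_ratio(est, full), 1)
})

test_that("white-noise FS-ratio matches the flat-spectrum closed form", {
  set.seed(204)
  band <- frequency_band(0.1, 0.2, unit = "normalized")
  errs <- replicate(20, {
    est <- spectral_estimate(epoch_series(matrix(rnorm(4096), ncol = 1)))
    abs(fs_ratio(est, band) - (band$b - band$a) / pi)
  })
  expect_gte(sum(errs < 0.05), 18)
})

test_that("FS-ratio is blind to duplication of components", {
  set.seed(205)
  x <- matrix(rnorm(512 * 2), 512, 2)
  est1 <- spectral_estimate(epoch_series(x))
  est2 <- spectral_estimate(epoch_series(cbind(x, x)))
  for (nv in list(c(0.05, 0.15), c(0.2, 0.35), c(0.4, 0.49))) {
    band <- frequency_band(nv[1], nv[2], unit = "normalized")
    expect_equal(fs_ratio(est1, band), fs_ratio(est2, band),
                 tolerance = 1e-10)
  }
})

test_that("FS-ratios over a disjoint band cover sum to one", {
  set.seed(206)
  est <- spectral_estimate(rand_epoch(400, 2))
  cuts <- c(1e-9, 0.4, 0.9, 1.8, 2.6, pi - 1e-9)
  total <- sum(vapply(seq_len(length(cuts) - 1), function(k) {
    fs_ratio(est, frequency_band(cuts[k], cuts[k + 1]))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("FS-ratio and scan statistic are scale invariant", {
  set.seed(207)
  e <- rand_epoch(512, 2)
  e5 <- epoch_series(5.5 * e$values)
  band <- frequency_band(0.1, 0.2, unit = "normalized")
  est <- spectral_estimate(e)
  est5 <- spectral_estimate(e5)
  expect_equal(fs_ratio(est, band), fs_ratio(est5, band), tolerance = 1e-10)
  expect_equal(scan_statistic(est, 0.9, 0.1), scan_statistic(est5, 0.9, 0.1),
               tolerance = 1e-10)
})

test_that("population FS-ratio oracle: flat field and complement identity", {
  band <- frequency_band(0.7, 1.5)
  flat <- fs_ratio_parameter(function(w) 1, band)
  expect_equal(as.numeric(flat), (1.5 - 0.7) / pi, tolerance = 1e-8)
  expect_equal(as.numeric(flat), attr(flat, "complement_form"),
               tolerance = 1e-8)
  ar <- ar2_spec(1.25, -0.75)
  r <- fs_ratio_parameter(function(w) ar2_spectrum(ar, w),
                          frequency_band(0.08, 0.16, unit = "normalized"))
  expect_equal(as.numeric(r), attr(r, "complement_form"), tolerance = 1e-8)
})

test_that("population FS-ratio oracle agrees with a 10x-finer quadrature", {
  band <- frequency_band(0.18, 0.38, unit = "normalized")
  mix <- function(w) example_regime_spectrum(1, w)
  coarse <- as.numeric(fs_ratio_parameter(mix, band, n_quad = 1024))
  fine <- as.numeric(fs_ratio_parameter(mix, band, n_quad = 10240))
  expect_equal(coarse, fine, tolerance = 1e-6)
})

test_that("scan statistic equals its ratio-of-FS-ratio form", {
  set.seed(208)
  est <- spectral_estimate(rand_epoch(512, 2))
  for (a in c(0.8, 1.6, 2.4)) {
    delta <- 0.15
    r1 <- sum(est$power[est$omegas <= a - delta])
    r2 <- sum(est$power[est$omegas <= a])
    tot <- sum(est$power)
    alt <- 1 - (r1 / tot) / (r2 / tot)
    expect_equal(scan_statistic(est, a, delta), alt, tolerance = 1e-12)
  }
  expect_error(scan_statistic(est, 0.1, 0.15), "exceed")
})

test_that("scan statistic of a flat field is exactly Delta/a on aligned grids", {
  n <- 1000
  est <- flat_field_estimate(n, d = 1)
  # a and delta as exact multiples of the Fourier spacing
  a <- 2 * pi * 125 / n
  delta <- 2 * pi * 25 / n
  expect_equal(scan_statistic(est, a, delta), delta / a, tolerance = 1e-12)
})

test_that("scan statistic vanishes where the spectrum carries no new power", {
  gap_lo <- 2 * pi * 0.20
  gap_hi <- 2 * pi * 0.25
  fld <- function(w) if (w > gap_lo && w <= gap_hi) 0 else 1
  est <- synthetic_spectral_estimate(fld, 2048, 1)
  expect_lt(scan_statistic(est, gap_hi, gap_hi - gap_lo), 1e-12)
})

test_that("estimated scan statistic of white noise tracks Delta/a", {
  set.seed(209)
  a <- 2 * pi * 0.25
  delta <- 2 * pi * 0.01
  errs <- replicate(20, {
    est <- spectral_estimate(epoch_series(matrix(rnorm(4096), ncol = 1)))
    abs(scan_statistic(est, a, delta) - delta / a)
  })
  expect_gte(sum(errs < 0.02), 18)
})

test_that("white-noise scan profiles decrease with frequency", {
  set.seed(210)
  lam <- 0
  for (k in 1:30) {
    est <- spectral_estimate(epoch_series(matrix(rnorm(1024), ncol = 1)))
    p <- scan_profile(est)
    lam <- lam + p$lambdas
  }
  expect_lt(cor(lam / 30, p$grid, method = "spearman"), -0.9)
})

test_that("scan profile validates its grid", {
  set.seed(211)
  est <- spectral_estimate(rand_epoch(512, 1))
  expect_error(scan_profile(est, delta = 0.02, Q = 30), "0.5")
  expect_error(scan_profile(spectral_estimate(rand_epoch(64, 1)),
                            delta = 0.01, Q = 20), "resolution")
  p <- scan_profile(est, delta = 0.01, Q = 49)
  expect_length(p$lambdas, 48)
  expect_true(all(p$lambdas >= 0 & p$lambdas < 1))
  expect_true(all(diff(p$grid) > 0))
})

test_that("band detection flags an injected resonance and nothing in a flat field", {
  est <- synthetic_spectral_estimate(function(w) example_regime_spectrum(2, w),
                                     2048, 1)
  bands <- detect_bands(scan_profile(est))
  expect_length(bands, 1)
  nv <- band_endpoints(bands[[1]], "normalized")
  expect_true(nv[1] < 0.12 && 0.12 <= nv[2])

  flat <- flat_field_estimate(2048, 1)
  expect_length(detect_bands(scan_profile(flat)), 0)
})

test_that("band detection separates two well-separated injected peaks", {
  fld <- function(w) {
    1 + 40 * exp(-((w - 2 * pi * 0.10) / 0.05)^2) +
      40 * exp(-((w - 2 * pi * 0.35) / 0.05)^2)
  }
  bands <- detect_bands(scan_profile(synthetic_spectral_estimate(fld, 2048, 1)))
  expect_length(bands, 2)
  iv <- lapply(bands, band_endpoints, unit = "normalized")
  expect_true(iv[[1]][1] < 0.10 && 0.10 <= iv[[1]][2])
  expect_true(iv[[2]][1] < 0.35 && 0.35 <= iv[[2]][2])
  expect_lt(iv[[1]][2], iv[[2]][1])   # disjoint
})

test_that("multiscale consensus keeps stable bumps and drops flat fields", {
  est <- synthetic_spectral_estimate(function(w) example_regime_spectrum(2, w),
                                     4096, 1)
  ms <- multiscale_scan(est, deltas = c(0.005, 0.01, 0.02))
  expect_gte(length(ms$consensus), 1)
  hit <- any(vapply(ms$consensus, function(b) {
    nv <- band_endpoints(b, "normalized")
    nv[1] < 0.12 && 0.12 <= nv[2]
  }, logical(1)))
  expect_true(hit)

  flat <- multiscale_scan(flat_field_estimate(4096, 1),
                          deltas = c(0.005, 0.01, 0.02))
  expect_length(flat$consensus, 0)

  # consensus is contained in the union of per-increment detections
  fine <- seq(5e-4, 0.4995, by = 1e-3)
  in_bands <- function(bs) {
    inside <- rep(FALSE, length(fine))
    for (b in bs) {
      nv <- band_endpoints(b, "normalized")
      inside <- inside | (fine > nv[1] & fine <= nv[2])
    }
    inside
  }
  union_det <- Reduce(`|`, lapply(ms$detections, in_bands))
  cons <- in_bands(ms$consensus)
  expect_true(all(union_det[cons]))
})

test_that("estimated FS-ratio is dimension blind across embeddings", {
  set.seed(212)
  ar <- ar2_spec(1.25, -0.75)
  band <- frequency_band(0.08, 0.16, unit = "normalized")
  e1 <- epoch_series(matrix(simulate_ar2(ar, 4096), ncol = 1))
  e3 <- epoch_series(vapply(1:3, function(k) simulate_ar2(ar, 4096),
                            numeric(4096)))
  r1 <- fs_ratio(spectral_estimate(e1), band)
  r3 <- fs_ratio(spectral_estimate(e3), band)
  expect_lt(abs(r1 - r3), 0.05)
})
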
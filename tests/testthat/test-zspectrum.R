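test_that("normalization divides by the reference and records it", {
  z <- normalize_zspectrum(c(-1, 1), c(0.3, 0.6), reference = 0.6)
  expect_equal(z$signal, c(0.5, 1.0))
  expect_identical(z$reference_offset, 333)

  raw <- rep(0.42, 5)
  z2 <- normalize_zspectrum(seq(-2, 2), raw, reference = 0.42)
  expect_equal(z2$signal, rep(1, 5))

  expect_error(normalize_zspectrum(0, 1, reference = 0), "positive")

  # round trip against the simulator: scaling to raw counts and back is exact
  pools <- six_pools()
  offsets <- cest_offsets_invivo()
  truth <- simulate_zspectrum(pools, offsets)
  s0 <- 1234.5
  z3 <- normalize_zspectrum(offsets, truth$signal * s0, s0)
  expect_equal(z3$signal, truth$signal, tolerance = 1e-12)
})

test_that("WASSR fitting finds the dip center at sub-grid resolution", {
  grid <- wassr_offsets()
  sym <- simulate_zspectrum(list(pool_spec(0, 0.5, 0.7, "water")), grid)
  expect_equal(as.numeric(fit_wassr(sym)), 0, tolerance = 1e-6)

  shifted <- simulate_zspectrum(list(pool_spec(0, 0.5, 0.7, "water")), grid,
                                b0_offset = 0.23)
  expect_equal(as.numeric(fit_wassr(shifted)), 0.23, tolerance = 1e-3)

  edge <- simulate_zspectrum(list(pool_spec(0, 0.5, 0.7, "water")), grid,
                             b0_offset = 1.0)
  expect_error(fit_wassr(edge), "edge")
})

test_that("WASSR center estimates are unbiased under noise", {
  grid <- wassr_offsets()
  centers <- vapply(1:300, function(s) {
    z <- simulate_zspectrum(list(pool_spec(0, 0.5, 0.7, "water")), grid,
                            noise_sd = 0.005, seed = 5000 + s,
                            b0_offset = 0.23)
    as.numeric(fit_wassr(z))
  }, numeric(1))
  expect_lt(abs(mean(centers) - 0.23), 0.005)
})

test_that("B0 correction restores displaced spectra and is self-inverse", {
  pools <- six_pools()
  offsets <- cest_offsets_invivo()[-1]  # drop the 333-ppm reference
  base <- simulate_zspectrum(pools, offsets)

  zc0 <- apply_b0_correction(base, 0)
  expect_identical(zc0$signal, base$signal)

  displaced <- simulate_zspectrum(pools, offsets, b0_offset = 0.2)
  corrected <- suppressWarnings(apply_b0_correction(displaced, 0.2))
  interior <- abs(offsets) <= 8
  err_single <- max(abs(corrected$signal - base$signal)[interior])
  expect_lt(err_single, 1e-3)
  expect_equal(corrected$b0_shift, 0.2)

  # shift then unshift deviates by at most twice one interpolation error
  fwd <- suppressWarnings(apply_b0_correction(base, 0.3))
  back <- suppressWarnings(apply_b0_correction(fwd, -0.3))
  fwd_err <- max(abs(
    suppressWarnings(apply_b0_correction(
      simulate_zspectrum(pools, offsets, b0_offset = 0.3), 0.3
    ))$signal - base$signal)[interior])
  expect_lt(max(abs(back$signal - base$signal)[interior]),
            2 * fwd_err + 1e-9)

  w <- testthat::capture_warnings(apply_b0_correction(base, 1.2))
  expect_match(w, "exceeds 1 ppm", all = FALSE)
})

test_that("two-pool background fit recovers water and MT parameters", {
  offsets <- cest_offsets_invivo()[-1]
  wm <- list(pool_spec(0, 0.85, 1.4, "water"), pool_spec(-2.5, 0.08, 25, "mt"))
  z <- simulate_zspectrum(wm, offsets)
  fit <- fit_two_pool(z)
  expect_equal(fit$water_amp, 0.85, tolerance = 1e-4)
  expect_equal(fit$water_fwhm, 1.4, tolerance = 1e-4)
  expect_equal(fit$mt_amp, 0.08, tolerance = 1e-4)
  expect_equal(fit$mt_fwhm, 25, tolerance = 1e-3)
  expect_equal(fit$mt_center, -2.5, tolerance = 1e-3)
  expect_lt(max(abs(fit$fitted_curve - z$signal)), 1e-6)
  expect_identical(fit$f_m, fit$mt_amp)

  # with no MT pool the fitted MT amplitude collapses
  zw <- simulate_zspectrum(list(pool_spec(0, 0.85, 1.4, "water")), offsets)
  expect_lt(fit_two_pool(zw)$f_m, 0.01)
})

test_that("the fitted background envelopes the CEST bands from above", {
  offsets <- cest_offsets_invivo()[-1]
  z <- simulate_zspectrum(six_pools(), offsets)
  fit <- fit_two_pool(z)
  bands <- (offsets >= 1 & offsets <= 4.5) | (offsets >= -4.5 & offsets <= -1)
  excluded <- bands & !fit$fit_mask
  frac <- mean(fit$fitted_curve[excluded] >= z$signal[excluded] - 1e-9)
  expect_gte(frac, 0.95)
})

test_that("AREX residuals follow the inverse-difference formula exactly", {
  mkz <- function(s) zspectrum(c(-3.5, -1.6), s)
  mkfit <- function(sfit, fm) {
    structure(list(water_amp = 0.8, water_fwhm = 1.4, water_center = 0,
                   mt_amp = fm, mt_fwhm = 25, mt_center = -2.5, f_m = fm,
                   fitted_curve = sfit, fit_mask = c(TRUE, TRUE),
                   residual_norm = 0), class = "two_pool_fit")
  }
  # S_meas = S_fit gives exactly zero
  a0 <- arex_resid(mkz(c(0.5, 0.7)), mkfit(c(0.5, 0.7), 0.1), 1.3)
  expect_identical(a0$arex, c(0, 0))

  a1 <- arex_resid(mkz(c(0.5, 0.5)), mkfit(c(1.0, 1.0), 0), 1)
  expect_equal(a1$arex, c(100, 100), tolerance = 1e-12)

  a2 <- arex_resid(mkz(c(0.4, 0.4)), mkfit(c(0.5, 0.5), 0.25), 2)
  expect_equal(a2$arex, c(20, 20), tolerance = 1e-12)

  # zero measured signal is flagged, not fatal
  a3 <- arex_resid(mkz(c(0, 0.5)), mkfit(c(0.9, 0.9), 0), 1)
  expect_true(is.na(a3$arex[1]))
  expect_true(a3$flag[1])

  expect_error(arex_resid(mkz(c(0.4, 0.4)), mkfit(c(0.5, 0.5), 0), -1), "t1")
})

test_that("AREX is invariant to rescaling the raw intensities", {
  offsets <- cest_offsets_invivo()
  pools <- six_pools()
  raw <- simulate_zspectrum(pools, offsets)$signal * 800
  run <- function(scale) {
    z <- normalize_zspectrum(offsets[-1], raw[-1] * scale, raw[1] * scale)
    fit <- fit_two_pool(z)
    arex_resid(z, fit, 1.8)$arex
  }
  expect_equal(run(1), run(7.3), tolerance = 1e-4)
})

test_that("a single injected pool surfaces as an AREX peak at its center", {
  offsets <- cest_offsets_invivo()[-1]
  pools <- list(pool_spec(0, 0.85, 1.4, "water"),
                pool_spec(-2.5, 0.08, 25, "mt"),
                pool_spec(-3.5, 0.03, 1.0, "rnoe35"))
  z <- simulate_zspectrum(pools, offsets)
  fit <- fit_two_pool(z)
  ar <- arex_resid(z, fit, 1.8)
  win <- ar$offsets >= -4.5 & ar$offsets <= -1
  peak_at <- ar$offsets[win][which.max(ar$arex[win])]
  expect_lte(abs(peak_at - (-3.5)), 0.1 + 1e-9)
})
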
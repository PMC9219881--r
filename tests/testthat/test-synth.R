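test_that("simulated z-spectra match a brute-force Lorentzian-sum oracle", {
  offsets <- cest_offsets_invivo()
  z <- simulate_zspectrum(six_pools(), offsets, noise_sd = 0)
  expect_equal(z$signal, lorentzian_sum_oracle(six_pools(), offsets),
               tolerance = 1e-12)

  # far-offset reference is effectively unsaturated
  zw <- simulate_zspectrum(list(pool_spec(0, 0.9, 1.4, "water")), 333)
  expect_gte(zw$signal, 0.99998)

  # at a pool center with no other pools the dip depth is the amplitude
  za <- simulate_zspectrum(list(pool_spec(3.5, 0.03, 1.0, "amide")), 3.5)
  expect_identical(za$signal, 1 - 0.03)
})

test_that("z-spectrum simulation is deterministic and normalized", {
  offsets <- cest_offsets_invivo()
  z1 <- simulate_zspectrum(six_pools(), offsets, noise_sd = 0.01, seed = 42)
  z2 <- simulate_zspectrum(six_pools(), offsets, noise_sd = 0.01, seed = 42)
  expect_identical(z1$signal, z2$signal)
  z3 <- simulate_zspectrum(six_pools(), offsets, noise_sd = 0.01, seed = 43)
  expect_false(identical(z1$signal, z3$signal))

  znl <- simulate_zspectrum(six_pools(), offsets)
  expect_true(all(znl$signal >= 0 & znl$signal <= 1))
})

test_that("disjoint pool sets superpose: saturation fractions add", {
  offsets <- seq(-6, 6, by = 0.25)
  a <- list(pool_spec(0, 0.5, 1.4, "water"), pool_spec(-2.5, 0.05, 20, "mt"))
  b <- list(pool_spec(-3.5, 0.04, 1.5, "rnoe35"), pool_spec(2, 0.02, 1.5, "amine"))
  zab <- simulate_zspectrum(c(a, b), offsets)
  za <- simulate_zspectrum(a, offsets)
  zb <- simulate_zspectrum(b, offsets)
  expect_equal(zab$signal, 1 - ((1 - za$signal) + (1 - zb$signal)),
               tolerance = 1e-14)
})

test_that("over-saturating pool sets are rejected", {
  expect_error(
    simulate_zspectrum(list(pool_spec(0, 0.7, 1.4, "water"),
                            pool_spec(0, 0.7, 2.0, "mt")),
                       seq(-2, 2, 0.5)),
    "invalid pool specification"
  )
  expect_error(pool_spec(0, 1.2, 1, "water"), "amplitude")
  expect_error(pool_spec(0, 0.5, 0, "water"), "fwhm")
})

test_that("recovery curves obey the closed-form relaxation models", {
  # half-recovery at t = T1 * ln 2
  cv <- simulate_recovery_curve("saturation", list(I0 = 1, T1 = 1), log(2))
  expect_equal(cv$intensities, 0.5, tolerance = 1e-12)

  # normalized inversion recovery starts at -1
  ci <- simulate_recovery_curve("inversion", list(x_a = 1, T1_a = 2), 1e-9)
  expect_equal(ci$intensities, -1, tolerance = 1e-6)

  # bi-exponential values match direct formula evaluation
  delays <- inversion_delays()
  cb <- simulate_recovery_curve("inversion",
                                list(x_a = 0.6, T1_a = 0.5, T1_b = 3.0),
                                delays)
  direct <- 1 - 2 * (0.6 * exp(-delays / 0.5) + 0.4 * exp(-delays / 3.0))
  expect_equal(cb$intensities, direct, tolerance = 1e-12)

  expect_error(
    simulate_recovery_curve("inversion", list(x_a = 1.4, T1_a = 1, T1_b = 2),
                            delays),
    "x_a"
  )
})

test_that("synthetic NMR peaks carry their specified areas", {
  axis <- seq(-1, 1, by = 5e-4)
  sp <- simulate_nmr_spectrum(list(nmr_peak_spec(0, 1.0, 0.01, "gaussian")),
                              axis)
  expect_equal(pracma::trapz(axis, sp$intensity), 1.0, tolerance = 1e-3)

  # integration is linear: band areas keep their 3:12 ratio
  sp2 <- simulate_nmr_spectrum(list(nmr_peak_spec(0.68, 3, 0.01, "gaussian"),
                                    nmr_peak_spec(0, 12, 0.01, "gaussian")),
                               axis)
  r <- integrate_band(sp2, c(0.65, 0.71)) / integrate_band(sp2, c(-0.03, 0.03))
  expect_equal(r, 0.25, tolerance = 1e-3)

  expect_warning(
    simulate_nmr_spectrum(list(nmr_peak_spec(5, 1, 0.01)), axis),
    "truncated"
  )
  expect_error(simulate_nmr_spectrum(list(nmr_peak_spec(0, 1, 0.01)),
                                     c(0, 1, 0.5)),
               "monotone")
})

test_that("noisy NMR integration is unbiased over repeated seeds", {
  axis <- seq(-0.5, 0.5, by = 1e-3)
  peak <- list(nmr_peak_spec(0, 2.0, 0.02, "gaussian"))
  n_rep <- 200
  ints <- vapply(seq_len(n_rep), function(s) {
    sp <- simulate_nmr_spectrum(peak, axis, noise_sd = 0.01, seed = 1000 + s)
    pracma::trapz(axis, sp$intensity)
  }, numeric(1))
  # Monte-Carlo noise on a trapezoid integral: se ~ noise_sd * sqrt(w * dx)
  se <- stats::sd(ints) / sqrt(n_rep)
  expect_lt(abs(mean(ints) - 2.0), 2.5 * se + 1e-4)
})

test_that("phantom simulation is homogeneous, deterministic and truthful", {
  spec <- default_phantom_spec(shape = c(16, 16), noise_sd = 0, b0_range = 0,
                               seed = 3)
  ph <- simulate_phantom(spec)
  normal_idx <- which(spec$region_masks == "normal", arr.ind = TRUE)
  v1 <- ph$stack$volumes[normal_idx[1, 1], normal_idx[1, 2], ]
  v2 <- ph$stack$volumes[normal_idx[5, 1], normal_idx[5, 2], ]
  expect_identical(v1, v2)

  ph2 <- simulate_phantom(spec)
  expect_identical(ph$stack$volumes, ph2$stack$volumes)
  expect_identical(ph$wassr$volumes, ph2$wassr$volumes)

  # ground-truth record carries the injected parameters
  expect_identical(ph$truth$spec$t1_by_region[["normal"]], 1.8)
  expect_s3_class(ph$truth$region_spectra$normal, "zspectrum")

  expect_error(
    phantom_spec(matrix("normal", 4, 4),
                 list(normal = default_brain_pools("normal")),
                 c(normal = 1.8), b0_field = matrix(0, 3, 3)),
    "shape"
  )
})
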
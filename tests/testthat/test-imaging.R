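test_that("the 3x3 median filter matches a brute-force oracle", {
  const <- matrix(4.2, 6, 6)
  expect_equal(median_filter_3x3(const), const)

  spiky <- matrix(1, 7, 7)
  spiky[4, 4] <- 100
  expect_equal(median_filter_3x3(spiky), matrix(1, 7, 7))

  set.seed(3)
  img <- matrix(stats::rnorm(64), 8, 8)
  out <- median_filter_3x3(img)
  # per-pixel 9-element median with replicated edges, computed by hand
  oracle <- matrix(NA_real_, 8, 8)
  for (i in 1:8) {
    for (j in 1:8) {
      vals <- numeric(0)
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), 8)
          jj <- min(max(j + dj, 1), 8)
          vals <- c(vals, img[ii, jj])
        }
      }
      oracle[i, j] <- stats::median(vals)
    }
  }
  expect_equal(out, oracle)

  # idempotence on piecewise-constant images
  pc <- matrix(1, 8, 8); pc[, 5:8] <- 2
  expect_equal(median_filter_3x3(median_filter_3x3(pc)),
               median_filter_3x3(pc))
})

test_that("ROI-averaged z-spectra normalize by the reference ROI mean", {
  nr <- 10; nc <- 10
  offsets <- c(333, -2, 0, 2)
  vols <- array(0, dim = c(nr, nc, 4))
  vols[, , 1] <- 1000
  vols[, , 2] <- 400
  vols[, , 3] <- 100
  vols[, , 4] <- 400
  stack <- offset_image_stack(vols, offsets, reference_index = 1)
  roi <- square_roi(c(5, 5), 5)
  expect_equal(nrow(roi), 25)
  z <- roi_mean_zspectrum(stack, roi)
  expect_equal(z$offsets, c(-2, 0, 2))
  expect_equal(z$signal, c(0.4, 0.1, 0.4))
  # homogeneous image: ROI mean equals any single voxel
  z1 <- roi_mean_zspectrum(stack, matrix(c(2, 2), 1, 2))
  expect_equal(z1$signal, z$signal)

  # two-value ROI: weighted mean (20 voxels at 0.4, 5 at 0.9)
  vols2 <- vols
  vols2[cbind(roi[1:5, 1], roi[1:5, 2], 2)] <- 900
  z2 <- roi_mean_zspectrum(offset_image_stack(vols2, offsets, 1), roi)
  expect_equal(z2$signal[1], (20 * 0.4 + 5 * 0.9) / 25)

  expect_error(roi_mean_zspectrum(stack, matrix(c(0, 5), 1, 2)),
               "out-of-bounds")
})

test_that("phantom ROI spectra agree with the generating region spectrum", {
  spec <- default_phantom_spec(shape = c(24, 24), noise_sd = 0.002,
                               b0_range = 0, seed = 9)
  ph <- simulate_phantom(spec)
  roi <- square_roi(c(12, 8), 5)
  z <- roi_mean_zspectrum(ph$stack, roi)
  truth <- ph$truth$region_spectra$normal
  keep <- match(z$offsets, truth$offsets)
  # ROI averaging beats single-voxel noise by sqrt(25)
  expect_lt(max(abs(z$signal - truth$signal[keep])), 5 * 0.002 / sqrt(25) + 1e-3)
})

test_that("voxelwise maps equal the scalar pipeline voxel by voxel", {
  spec <- default_phantom_spec(shape = c(12, 12), noise_sd = 0.002,
                               b0_range = 0.2, seed = 5)
  ph <- simulate_phantom(spec)
  tissue <- spec$region_masks != "background"
  maps <- voxelwise_arex_maps(ph$stack, ph$wassr, ph$t1_map,
                              filter_stage = "none")
  idx <- which(!maps$failure_mask, arr.ind = TRUE)
  set.seed(1)
  pick <- idx[sample(nrow(idx), 10), , drop = FALSE]
  ref_idx <- ph$stack$reference_index
  keep <- seq_along(ph$stack$offsets) != ref_idx
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    z <- normalize_zspectrum(ph$stack$offsets[keep],
                             ph$stack$volumes[i, j, keep],
                             ph$stack$volumes[i, j, ref_idx])
    wsig <- ph$wassr$volumes[i, j, ]
    wz <- zspectrum(ph$wassr$offsets, wsig / max(wsig))
    b0 <- as.numeric(fit_wassr(wz))
    zc <- suppressWarnings(apply_b0_correction(z, b0))
    tp <- fit_two_pool(zc)
    ar <- arex_resid(zc, tp, ph$t1_map[i, j])
    dec <- deconvolve_invivo(ar)
    expect_equal(maps$auc_rnoe35[i, j], dec$auc_by_label$rnoe35,
                 tolerance = 1e-10)
    expect_equal(maps$auc_rnoe16[i, j], dec$auc_by_label$rnoe16,
                 tolerance = 1e-10)
    expect_equal(maps$b0[i, j], b0, tolerance = 1e-10)
  }
})

test_that("maps are insensitive to a smooth B0 ramp", {
  spec0 <- default_phantom_spec(shape = c(16, 16), noise_sd = 0.001,
                                b0_range = 0, seed = 13,
                                tumor_rnoe16 = 0.015)  # uniform pools
  spec1 <- default_phantom_spec(shape = c(16, 16), noise_sd = 0.001,
                                b0_range = 0.6, seed = 13,
                                tumor_rnoe16 = 0.015)
  m0 <- voxelwise_arex_maps(simulate_phantom(spec0)$stack,
                            simulate_phantom(spec0)$wassr,
                            simulate_phantom(spec0)$t1_map,
                            filter_stage = "none")
  ph1 <- simulate_phantom(spec1)
  m1 <- voxelwise_arex_maps(ph1$stack, ph1$wassr, ph1$t1_map,
                            filter_stage = "none")
  spread0 <- stats::sd(m0$auc_rnoe16[!m0$failure_mask])
  spread1 <- stats::sd(m1$auc_rnoe16[!m1$failure_mask])
  expect_lt(spread1, 2 * spread0 + 1e-4)
})

test_that("degenerate stacks are flagged, never fatal", {
  vols <- array(0, dim = c(4, 4, length(cest_offsets_invivo())))
  stack <- offset_image_stack(vols, cest_offsets_invivo(), 1)
  wvols <- array(0, dim = c(4, 4, length(wassr_offsets())))
  wstack <- offset_image_stack(wvols, wassr_offsets())
  maps <- voxelwise_arex_maps(stack, wstack, matrix(1.8, 4, 4))
  expect_true(all(maps$failure_mask))
  expect_true(all(is.na(maps$auc_rnoe16)))

  expect_error(voxelwise_arex_maps(stack, wstack, matrix(1.8, 3, 3)),
               "geometries")
})
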
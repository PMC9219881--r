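#' Phantom specification
#'
#' Describes a synthetic two-region imaging phantom: a label map assigning
#' each voxel to background, normal or tumor tissue; per-region pool sets
#' and T1 values; a per-voxel B0 offset field; and an additive noise level.
#' The phantom stands in for a CEST acquisition with matching WASSR and
#' variable-TR scans.
#'
#' @param region_masks Character matrix with values `"background"`,
#'   `"normal"` or `"tumor"`; its dimensions define the image grid.
#' @param pools_by_region Named list (names `"normal"`, `"tumor"`) of
#'   [pool_spec()] lists.
#' @param t1_by_region Named numeric vector of T1 values in seconds; all
#'   positive.
#' @param b0_field Numeric matrix of per-voxel B0 offsets in ppm, same
#'   shape as `region_masks`; finite everywhere.
#' @param noise_sd Additive Gaussian noise standard deviation as a fraction
#'   of the unsaturated signal.
#' @param seed Integer seed for all random draws in [simulate_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(region_masks, pools_by_region, t1_by_region,
                         b0_field = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(region_masks))
  regions <- unique(as.vector(region_masks))
  if (!all(regions %in% c("background", "normal", "tumor"))) {
    stop("region_masks values must be 'background', 'normal' or 'tumor'")
  }
  tissue <- setdiff(regions, "background")
  if (!all(tissue %in% names(pools_by_region))) {
    stop("pools_by_region must name every tissue region present in the mask")
  }
  if (!all(tissue %in% names(t1_by_region))) {
    stop("t1_by_region must name every tissue region present in the mask")
  }
  if (any(t1_by_region <= 0)) stop("t1 values must be positive")
  if (is.null(b0_field)) {
    b0_field <- matrix(0, nrow(region_masks), ncol(region_masks))
  }
  if (!is.matrix(b0_field) || !all(dim(b0_field) == dim(region_masks))) {
    stop("b0_field shape does not match region_masks")
  }
  if (!all(is.finite(b0_field))) stop("b0_field must be finite")
  pools_by_region <- lapply(pools_by_region, validate_pool_list)
  structure(list(shape = dim(region_masks), region_masks = region_masks,
                 pools_by_region = pools_by_region,
                 t1_by_region = t1_by_region, b0_field = b0_field,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default two-region phantom
#'
#' Builds a circular "brain" of normal tissue with an off-center tumor
#' disc, a smooth left-right B0 ramp, and the default pool sets with the
#' tumor rNOE(-1.6) amplitude reduced relative to normal.
#'
#' @param shape Image grid as `c(rows, cols)`.
#' @param tumor_rnoe16 rNOE(-1.6) amplitude in the tumor region.
#' @param normal_rnoe16 rNOE(-1.6) amplitude in the normal region.
#' @param b0_range Total peak-to-peak amplitude in ppm of the left-right B0
#'   ramp (0 for a homogeneous field).
#' @param noise_sd Additive noise standard deviation (fraction of S0).
#' @param seed Integer seed.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(shape = c(64, 64), tumor_rnoe16 = 0.005,
                                 normal_rnoe16 = 0.015, b0_range = 0,
                                 noise_sd = 0.002, seed = 1L) {
  nr <- shape[1]; nc <- shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  brain <- sqrt((rows - cr)^2 + (cols - cc)^2) <= min(nr, nc) * 0.42
  tumor <- sqrt((rows - cr * 0.7)^2 + (cols - cc * 1.35)^2) <= min(nr, nc) * 0.14
  masks <- matrix("background", nr, nc)
  masks[brain] <- "normal"
  masks[brain & tumor] <- "tumor"
  b0 <- matrix(0, nr, nc)
  if (b0_range != 0) {
    b0 <- (cols - cc) / (nc - 1) * b0_range
  }
  phantom_spec(
    region_masks = masks,
    pools_by_region = list(
      normal = default_brain_pools("normal", rnoe16_amplitude = normal_rnoe16),
      tumor = default_brain_pools("tumor", rnoe16_amplitude = tumor_rnoe16)
    ),
    t1_by_region = c(normal = 1.8, tumor = 2.1),
    b0_field = b0, noise_sd = noise_sd, seed = seed
  )
}

# Low-power WASSR saturation is emulated with a narrowed, attenuated direct
# water line; only its center (the B0 offset) matters downstream.
wassr_pool <- function(water) {
  pool_spec(water$center, water$amplitude * 0.6, water$fwhm * 0.5, "water")
}

#' Simulate a phantom acquisition
#'
#' Produces, from one seeded specification, everything the voxelwise
#' pipeline consumes: a per-offset CEST image stack (with the far-offset
#' reference volume), a WASSR stack on the -1 to 1 ppm sweep, a T1 map, and
#' a ground-truth record carrying every injected parameter for
#' parameter-recovery tests.  Voxel intensities are `S0 * Z` with `S0 =
#' 1000` inside tissue and 0 in the background; noise is additive Gaussian
#' on the normalized signal.
#'
#' @param spec A [phantom_spec()].
#' @param offsets CEST saturation offsets in ppm; the first entry is the
#'   reference (default [cest_offsets_invivo()]).
#' @param wassr_offs WASSR sweep offsets (default [wassr_offsets()]).
#' @param s0 Unsaturated signal level in tissue.
#' @return A list with `stack` (an [offset_image_stack()]), `wassr` (an
#'   [offset_image_stack()] without reference), `t1_map` (matrix, s), and
#'   `truth` (the spec plus per-region noiseless spectra).
#' @export
simulate_phantom <- function(spec, offsets = cest_offsets_invivo(),
                             wassr_offs = wassr_offsets(), s0 = 1000) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  ref_idx <- which.max(abs(offsets))
  if (abs(offsets[ref_idx]) < 100) {
    stop("offset list must include a far-offset reference (|dw| >= 100 ppm)")
  }
  with_seed(spec$seed, {
    vols <- array(0, dim = c(nr, nc, length(offsets)))
    wvols <- array(0, dim = c(nr, nc, length(wassr_offs)))
    t1_map <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        region <- spec$region_masks[i, j]
        if (region == "background") next
        pools <- spec$pools_by_region[[region]]
        b0 <- spec$b0_field[i, j]
        z <- simulate_zspectrum(pools, offsets, noise_sd = 0, b0_offset = b0)
        sig <- z$signal
        wp <- wassr_pool(pools[[1]])
        wz <- simulate_zspectrum(list(wp), wassr_offs, noise_sd = 0,
                                 b0_offset = b0)
        wsig <- wz$signal
        if (spec$noise_sd > 0) {
          sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sd)
          wsig <- wsig + stats::rnorm(length(wsig), 0, spec$noise_sd)
        }
        vols[i, j, ] <- pmax(sig, 0) * s0
        wvols[i, j, ] <- pmax(wsig, 0) * s0
        t1_map[i, j] <- spec$t1_by_region[[region]]
      }
    }
    truth_spectra <- lapply(spec$pools_by_region, function(p) {
      simulate_zspectrum(p, offsets, noise_sd = 0)
    })
    list(
      stack = offset_image_stack(vols, offsets, reference_index = ref_idx),
      wassr = offset_image_stack(wvols, wassr_offs, reference_index = NA),
      t1_map = t1_map,
      truth = list(spec = spec, offsets = offsets, wassr_offsets = wassr_offs,
                   s0 = s0, region_spectra = truth_spectra)
    )
  })
}
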
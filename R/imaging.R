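#' Per-offset image stack
#'
#' Container for a CEST (or WASSR) acquisition: one image per saturation
#' offset plus the index of the far-offset reference volume used for
#' normalization (NA for stacks acquired without one, e.g. WASSR sweeps).
#' Coordinates are 0-based nowhere: all indices are standard 1-based R
#' row/column indices on the array as stored.
#'
#' @param volumes Numeric array `rows x cols x n_offsets`.
#' @param offsets Offsets in ppm, one per volume.
#' @param reference_index Index of the reference volume, or `NA`.
#' @return An object of class `offset_image_stack`.
#' @export
offset_image_stack <- function(volumes, offsets, reference_index = NA) {
  stopifnot(is.array(volumes), length(dim(volumes)) == 3L)
  if (dim(volumes)[3] != length(offsets)) {
    stop("volume count (", dim(volumes)[3], ") does not match offset count (",
         length(offsets), ")")
  }
  if (!is.na(reference_index)) {
    stopifnot(reference_index >= 1, reference_index <= length(offsets))
  }
  structure(list(volumes = volumes, offsets = as.numeric(offsets),
                 reference_index = reference_index),
            class = "offset_image_stack")
}

#' @export
print.offset_image_stack <- function(x, ...) {
  cat(sprintf("<offset_image_stack> %d x %d voxels, %d offsets in [%g, %g] ppm\n",
              dim(x$volumes)[1], dim(x$volumes)[2], length(x$offsets),
              min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighborhood; image edges
#' are handled by replicating the border row/column.  `NA` pixels (e.g.
#' failed fits or background) are ignored within each neighborhood; a pixel
#' whose whole neighborhood is `NA` stays `NA`.
#'
#' @param img Numeric matrix (one 2-D slice).
#' @return A matrix of the same shape.
#' @export
median_filter_3x3 <- function(img) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  stackn <- array(NA_real_, dim = c(nr, nc, 9))
  k <- 0
  for (di in 0:2) {
    for (dj in 0:2) {
      k <- k + 1
      stackn[, , k] <- pad[di + seq_len(nr), dj + seq_len(nc)]
    }
  }
  out <- apply(stackn, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  out
}

#' Build a square ROI around a center voxel
#'
#' @param center Length-2 vector `c(row, col)`.
#' @param size Side length in voxels (default 5, i.e. a 25-voxel ROI).
#' @return A two-column integer matrix of (row, col) voxel coordinates.
#' @export
square_roi <- function(center, size = 5) {
  stopifnot(length(center) == 2L, size >= 1)
  half <- (size - 1) %/% 2
  rows <- center[1] + (-half):(size - 1 - half)
  cols <- center[2] + (-half):(size - 1 - half)
  as.matrix(expand.grid(row = rows, col = cols))
}

#' ROI-averaged z-spectrum
#'
#' Averages the raw signal over a set of voxels at each offset, then
#' normalizes by the ROI mean of the reference volume, producing one
#' representative z-spectrum for the region.
#'
#' @param stack An [offset_image_stack()] with a reference volume.
#' @param voxels Two-column matrix of (row, col) voxel coordinates; all in
#'   bounds.
#' @return A [zspectrum()] on the non-reference offsets.
#' @export
roi_mean_zspectrum <- function(stack, voxels) {
  stopifnot(inherits(stack, "offset_image_stack"), is.matrix(voxels),
            ncol(voxels) == 2L, nrow(voxels) >= 1L)
  if (is.na(stack$reference_index)) {
    stop("stack has no reference volume to normalize against")
  }
  d <- dim(stack$volumes)
  if (any(voxels[, 1] < 1 | voxels[, 1] > d[1] |
          voxels[, 2] < 1 | voxels[, 2] > d[2])) {
    stop("ROI contains out-of-bounds voxel coordinates")
  }
  means <- vapply(seq_along(stack$offsets), function(k) {
    mean(stack$volumes[cbind(voxels[, 1], voxels[, 2], k)])
  }, numeric(1))
  ref <- means[stack$reference_index]
  if (ref <= 0) stop("reference ROI mean is not positive")
  keep <- seq_along(stack$offsets) != stack$reference_index
  normalize_zspectrum(stack$offsets[keep], means[keep], ref,
                      reference_offset = stack$offsets[stack$reference_index])
}

#' Voxelwise AREX parameter maps
#'
#' Runs the full scalar signal chain on every tissue voxel of a CEST stack:
#' normalization to the reference volume, WASSR B0 estimation and
#' correction, two-pool Lorentzian background fit, AREX residual (using the
#' voxel's T1), and single-Gaussian rNOE isolation.  Emits maps of the
#' rNOE(-3.5) and rNOE(-1.6) AUCs and amplitudes, the MT pool size `f_m`
#' and the fitted B0 offset.  By default each parameter map is smoothed
#' with a 3x3 median filter after fitting (`filter_stage = "maps"`);
#' `filter_stage = "raw"` instead filters every offset image before any
#' fitting, and `"none"` disables filtering.  Per-voxel failures are
#' recorded in the failure mask, never fatal.
#'
#' @param stack CEST [offset_image_stack()] with reference volume.
#' @param wassr_stack WASSR [offset_image_stack()] on the water sweep.
#' @param t1_map Matrix of per-voxel T1 values in seconds (`NA` = skip).
#' @param mask Optional logical matrix restricting which voxels are fitted.
#' @param band16 rNOE(-1.6) residual band in ppm.
#' @param filter_stage `"maps"`, `"raw"` or `"none"`.
#' @return A list with matrices `auc_rnoe35`, `auc_rnoe16`, `amp_rnoe35`,
#'   `amp_rnoe16`, `f_m`, `b0`, and logical `failure_mask`.
#' @export
voxelwise_arex_maps <- function(stack, wassr_stack, t1_map, mask = NULL,
                                band16 = c(-1.9, -1.3),
                                filter_stage = c("maps", "raw", "none")) {
  filter_stage <- match.arg(filter_stage)
  stopifnot(inherits(stack, "offset_image_stack"),
            inherits(wassr_stack, "offset_image_stack"),
            is.matrix(t1_map))
  d <- dim(stack$volumes)
  if (!all(dim(wassr_stack$volumes)[1:2] == d[1:2]) ||
      !all(dim(t1_map) == d[1:2])) {
    stop("stack, WASSR stack and T1 map geometries do not agree")
  }
  if (is.na(stack$reference_index)) stop("CEST stack must carry a reference volume")
  if (!is.null(mask)) stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  vols <- stack$volumes
  wvols <- wassr_stack$volumes
  if (filter_stage == "raw") {
    for (k in seq_len(d[3])) vols[, , k] <- median_filter_3x3(vols[, , k])
    for (k in seq_len(dim(wvols)[3])) wvols[, , k] <- median_filter_3x3(wvols[, , k])
  }
  nr <- d[1]; nc <- d[2]
  maps <- list(auc_rnoe35 = matrix(NA_real_, nr, nc),
               auc_rnoe16 = matrix(NA_real_, nr, nc),
               amp_rnoe35 = matrix(NA_real_, nr, nc),
               amp_rnoe16 = matrix(NA_real_, nr, nc),
               f_m = matrix(NA_real_, nr, nc),
               b0 = matrix(NA_real_, nr, nc))
  fail <- matrix(TRUE, nr, nc)
  ref_idx <- stack$reference_index
  keep <- seq_len(d[3]) != ref_idx
  offs <- stack$offsets[keep]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is.null(mask) && !mask[i, j]) next
      ref <- vols[i, j, ref_idx]
      t1 <- t1_map[i, j]
      if (!is.finite(ref) || ref <= 0 || !is.finite(t1) || t1 <= 0) next
      res <- tryCatch(suppressWarnings({
        z <- normalize_zspectrum(offs, vols[i, j, keep], ref,
                                 reference_offset = stack$offsets[ref_idx])
        wsig <- wvols[i, j, ]
        wz <- zspectrum(wassr_stack$offsets, wsig / max(wsig),
                        reference_offset = stack$offsets[ref_idx])
        b0 <- as.numeric(fit_wassr(wz))
        zc <- apply_b0_correction(z, b0)
        tp <- fit_two_pool(zc)
        ar <- arex_resid(zc, tp, t1)
        dec <- deconvolve_invivo(ar, band16 = band16)
        list(dec = dec, tp = tp, b0 = b0)
      }), error = function(e) NULL)
      if (is.null(res)) next
      maps$auc_rnoe35[i, j] <- res$dec$auc_by_label$rnoe35
      maps$auc_rnoe16[i, j] <- res$dec$auc_by_label$rnoe16
      maps$amp_rnoe35[i, j] <- res$dec$amplitude_by_label$rnoe35
      maps$amp_rnoe16[i, j] <- res$dec$amplitude_by_label$rnoe16
      maps$f_m[i, j] <- res$tp$f_m
      maps$b0[i, j] <- res$b0
      fail[i, j] <- FALSE
    }
  }
  if (filter_stage == "maps") {
    maps <- lapply(maps, median_filter_3x3)
  }
  c(maps, list(failure_mask = fail))
}
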
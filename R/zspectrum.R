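#' Z-spectrum container
#'
#' A z-spectrum holds the normalized water signal `S/S0` on a grid of
#' saturation offsets (ppm, water = 0).  `reference_offset` records where
#' the unsaturated normalizer `S0` was acquired (far from water, e.g. 333 or
#' 250 ppm); `b0_shift` records any B0 correction already applied (0 if
#' uncorrected).
#'
#' @param offsets Saturation offsets in ppm, finite.
#' @param signal Normalized intensities, same length as `offsets`,
#'   non-negative.
#' @param reference_offset Offset of the S0 acquisition in ppm;
#'   `abs(reference_offset)` must be at least 100 ppm.
#' @param b0_shift Applied B0 correction in ppm.
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets, signal, reference_offset = 333, b0_shift = 0) {
  stopifnot(is.numeric(offsets), is.numeric(signal),
            length(offsets) == length(signal), all(is.finite(offsets)))
  if (any(signal < -1e-12, na.rm = TRUE)) {
    stop("z-spectrum signal values must be non-negative")
  }
  if (abs(reference_offset) < 100) {
    stop("reference_offset must be far from water (|ref| >= 100 ppm), got ",
         reference_offset)
  }
  structure(list(offsets = as.numeric(offsets), signal = as.numeric(signal),
                 reference_offset = reference_offset, b0_shift = b0_shift),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets in [%.2f, %.2f] ppm, ref %g ppm, b0 shift %+.3f ppm\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              x$reference_offset, x$b0_shift))
  invisible(x)
}

#' Normalize raw saturation intensities to a reference acquisition
#'
#' Divides the raw per-offset water intensities by the intensity measured at
#' a far-offset reference (e.g. 333 ppm in vivo, 250 ppm for homogenates),
#' yielding the z-spectrum `S/S0`.
#'
#' @param offsets Saturation offsets in ppm.
#' @param raw Raw intensities, one per offset.
#' @param reference Raw intensity of the reference acquisition; must be
#'   positive.
#' @param reference_offset Offset of the reference acquisition in ppm.
#' @return A [zspectrum()] object.
#' @examples
#' normalize_zspectrum(c(-1, 0, 1), c(0.3, 0.1, 0.3), reference = 0.6)
#' @export
normalize_zspectrum <- function(offsets, raw, reference, reference_offset = 333) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("reference intensity must be a single positive number")
  }
  zspectrum(offsets, raw / reference, reference_offset = reference_offset)
}

#' Fit a WASSR sweep for the B0 offset
#'
#' Fits a single Lorentzian dip `Z = b - L(dw; A, center, fwhm)` to a
#' low-power water saturation shift referencing (WASSR) spectrum and returns
#' the fitted center, i.e. the per-voxel B0 offset in ppm at sub-grid
#' resolution.
#'
#' @param z A [zspectrum()] sampled on a narrow grid around water
#'   (typically -1 to 1 ppm at 0.1-ppm steps); the sampled minimum must be
#'   interior to the grid.
#' @return The fitted Lorentzian center in ppm (single numeric), with the
#'   full fit attached as attribute `"fit"`.
#' @export
fit_wassr <- function(z) {
  stopifnot(inherits(z, "zspectrum"))
  x <- z$offsets; y <- z$signal
  ord <- order(x); x <- x[ord]; y <- y[ord]
  imin <- which.min(y)
  if (imin == 1L || imin == length(x)) {
    stop("unreliable WASSR fit: spectrum minimum lies at the grid edge")
  }
  start <- c(A = max(y) - min(y), center = x[imin], fwhm = 0.5,
             base = max(y))
  resid_fn <- function(p) {
    y - (p[4] - lorentzian(x, p[1], p[2], p[3]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       lower = c(A = 0, center = min(x), fwhm = 0.01, base = 0),
                       upper = c(A = 2, center = max(x), fwhm = 10, base = 2),
                       fn = resid_fn, control = lm_control(200)),
    error = function(e) stop("WASSR Lorentzian fit failed: ", conditionMessage(e))
  )
  center <- unname(fit$par["center"])
  if (center <= min(x) + 1e-9 || center >= max(x) - 1e-9) {
    stop("unreliable WASSR fit: fitted center pinned at the grid edge")
  }
  structure(center, fit = fit)
}

#' Apply a B0 correction to a z-spectrum
#'
#' Re-interpolates the measured signal onto the nominal offset grid shifted
#' by the fitted B0 offset, so that pool centers return to their nominal
#' positions.  Interpolation is cubic (natural spline) on the sampled grid;
#' offsets whose shifted position falls outside the sampled range are filled
#' with the nearest edge value and a warning is raised.
#'
#' @param z A [zspectrum()].
#' @param b0_offset Fitted B0 offset in ppm; values beyond 1 ppm in
#'   magnitude are accepted but flagged with a warning.
#' @return A [zspectrum()] on the same nominal offsets with `b0_shift`
#'   recorded.
#' @export
apply_b0_correction <- function(z, b0_offset) {
  stopifnot(inherits(z, "zspectrum"), is.numeric(b0_offset),
            length(b0_offset) == 1L, is.finite(b0_offset))
  if (abs(b0_offset) > 1) {
    warning("B0 offset of ", b0_offset, " ppm exceeds 1 ppm; correction applied but flagged")
  }
  if (b0_offset == 0) {
    out <- z
    out$b0_shift <- z$b0_shift + 0
    return(out)
  }
  ord <- order(z$offsets)
  x <- z$offsets[ord]; y <- z$signal[ord]
  target <- z$offsets + b0_offset
  out_of_range <- target < min(x) | target > max(x)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " offset(s) fall outside the sampled range after the B0 shift; ",
            "edge values extrapolated flat")
  }
  sf <- stats::splinefun(x, y, method = "natural")
  corrected <- sf(pmin(pmax(target, min(x)), max(x)))
  corrected[corrected < 0] <- 0
  zspectrum(z$offsets, corrected, reference_offset = z$reference_offset,
            b0_shift = z$b0_shift + b0_offset)
}

#' Two-pool Lorentzian background fit
#'
#' Fits the direct water saturation plus the broad semisolid MT background,
#' `Z = 1 - L_water - L_MT`, to a B0-corrected z-spectrum, using only
#' offsets near water and in the far wings (by default `|dw| <= 0.8` ppm
#' plus `|dw| >= 6` ppm) so that the labile bands at 3.5, 2, -1.6 and
#' -3.5 ppm do not bias the background.  The water center is fixed at 0
#' after B0 correction; the MT center is fitted within `[-3, 0]` ppm.  The
#' MT amplitude is identified with the MT pool size `f_m` used by the AREX
#' correction.
#'
#' @param z A B0-corrected [zspectrum()] whose grid includes both
#'   `|dw| <= 1` ppm and `|dw| >= 6` ppm samples.
#' @param mask_near Half-width in ppm of the near-water mask (default 0.8).
#' @param mask_far Minimum `|dw|` in ppm of the wing mask (default 6).
#' @return An object of class `two_pool_fit` with fields `water_amp`,
#'   `water_fwhm`, `water_center`, `mt_amp`, `mt_fwhm`, `mt_center`,
#'   `f_m`, `fitted_curve` (on the full input grid), `fit_mask` and
#'   `residual_norm`.
#' @export
fit_two_pool <- function(z, mask_near = 0.8, mask_far = 6) {
  stopifnot(inherits(z, "zspectrum"))
  x <- z$offsets; y <- z$signal
  mask <- abs(x) <= mask_near | abs(x) >= mask_far
  if (sum(mask) < 6) stop("too few offsets in the two-pool fit mask")
  if (!any(abs(x) <= 1) || !any(abs(x) >= 6)) {
    stop("two-pool fit requires offsets both near water (|dw| <= 1 ppm) and in the wings (|dw| >= 6 ppm)")
  }
  xm <- x[mask]; ym <- y[mask]
  model <- function(p, xx) {
    1 - lorentzian(xx, p[1], 0, p[2]) - lorentzian(xx, p[3], p[5], p[4])
  }
  resid_fn <- function(p) ym - model(p, xm)
  lower <- c(wa = 0,   wf = 0.2, ma = 0,   mf = 5,   mc = -3)
  upper <- c(wa = 1,   wf = 5,   ma = 0.5, mf = 150, mc = 0)
  amp0 <- max(0.05, 1 - min(ym))
  starts <- list(
    c(wa = min(amp0, 0.95), wf = 1.5, ma = 0.05, mf = 25, mc = -1),
    c(wa = min(amp0 * 0.8, 0.9), wf = 1.0, ma = 0.1, mf = 50, mc = -2.5)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = resid_fn,
                         control = lm_control(300)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("two-pool Lorentzian fit failed to converge from all starts")
  p <- best$par
  structure(list(
    water_amp = unname(p[1]), water_fwhm = unname(p[2]), water_center = 0,
    mt_amp = unname(p[3]), mt_fwhm = unname(p[4]), mt_center = unname(p[5]),
    f_m = unname(p[3]),
    fitted_curve = model(p, x),
    fit_mask = mask,
    residual_norm = sqrt(best$deviance)
  ), class = "two_pool_fit")
}

#' @export
print.two_pool_fit <- function(x, ...) {
  cat(sprintf(paste0("<two_pool_fit> water: amp %.4f fwhm %.2f ppm | ",
                     "MT: amp %.4f fwhm %.1f ppm center %+.2f ppm | resid %.3g\n"),
              x$water_amp, x$water_fwhm, x$mt_amp, x$mt_fwhm, x$mt_center,
              x$residual_norm))
  invisible(x)
}

#' AREX residual spectrum
#'
#' Converts the gap between the measured z-spectrum and the fitted two-pool
#' background into an exchange-rate-like quantity, correcting for the water
#' longitudinal relaxation time and the MT pool size:
#' `AREX_resid(dw) = (S0/S_meas - S0/S_fit) / (T1 * (1 + f_m))`,
#' reported in percent per second.  With normalized spectra, `S0 = 1`.
#' Offsets where the measured signal is zero are set to `NA` and flagged.
#'
#' @param z A (B0-corrected) [zspectrum()].
#' @param fit The [fit_two_pool()] result for `z`.
#' @param t1 Water T1 in seconds, positive.
#' @return An object of class `arex_spectrum` with fields `offsets`, `arex`
#'   (percent per second), `t1`, `f_m` and `flag` (logical, TRUE where the
#'   value could not be computed).
#' @export
arex_resid <- function(z, fit, t1) {
  stopifnot(inherits(z, "zspectrum"), inherits(fit, "two_pool_fit"),
            is.numeric(t1), length(t1) == 1L)
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be a positive number of seconds")
  s_meas <- z$signal
  s_fit <- fit$fitted_curve
  bad <- s_meas <= 0 | s_fit <= 0
  arex <- rep(NA_real_, length(s_meas))
  arex[!bad] <- (1 / s_meas[!bad] - 1 / s_fit[!bad]) /
    (t1 * (1 + fit$f_m)) * 100
  structure(list(offsets = z$offsets, arex = arex, t1 = t1, f_m = fit$f_m,
                 flag = bad),
            class = "arex_spectrum")
}

#' @export
print.arex_spectrum <- function(x, ...) {
  cat(sprintf("<arex_spectrum> %d offsets, T1 %.3f s, f_m %.4f, range [%.3g, %.3g] %% s^-1\n",
              length(x$offsets), x$t1, x$f_m,
              min(x$arex, na.rm = TRUE), max(x$arex, na.rm = TRUE)))
  invisible(x)
}
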
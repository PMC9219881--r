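#' Saturable pool specification
#'
#' A `pool_spec` describes one saturable proton pool as it appears in a
#' z-spectrum: a Lorentzian dip with a given `center` (ppm relative to water
#' at 0), peak saturation `amplitude` (fraction of the normalized signal,
#' 0--1) and full width at half maximum `fwhm` (ppm).  Pools are labelled by
#' their conventional CEST assignment: direct water saturation, the broad
#' semisolid magnetization-transfer (MT) background, amide (+3.5 ppm),
#' amine (+2 ppm), and the relayed NOE bands at -3.5 and -1.6 ppm.
#'
#' @param center Chemical-shift offset of the pool in ppm (water = 0).
#' @param amplitude Peak saturation fraction, in `[0, 1]`.
#' @param fwhm Full width at half maximum in ppm; must be positive.
#' @param label One of `"water"`, `"mt"`, `"amide"`, `"amine"`,
#'   `"rnoe35"`, `"rnoe16"`.
#' @return An object of class `pool_spec`.
#' @examples
#' pool_spec(0, 0.85, 1.4, "water")
#' @export
pool_spec <- function(center, amplitude, fwhm,
                      label = c("water", "mt", "amide", "amine", "rnoe35", "rnoe16")) {
  label <- match.arg(label)
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(fwhm), length(fwhm) == 1L)
  if (amplitude < 0 || amplitude > 1) {
    stop("pool amplitude must lie in [0, 1], got ", amplitude)
  }
  if (fwhm <= 0) stop("pool fwhm must be positive, got ", fwhm)
  structure(list(center = center, amplitude = amplitude, fwhm = fwhm,
                 label = label),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("<pool %s>  center %+.2f ppm  amplitude %.4f  fwhm %.2f ppm\n",
              x$label, x$center, x$amplitude, x$fwhm))
  invisible(x)
}

validate_pool_list <- function(pools) {
  if (inherits(pools, "pool_spec")) pools <- list(pools)
  if (!length(pools) || !all(vapply(pools, inherits, logical(1), "pool_spec"))) {
    stop("`pools` must be a list of pool_spec objects")
  }
  # The saturated fractions must never exceed 1 anywhere: pools at separated
  # centers may have amplitudes summing above 1 without the combined
  # Lorentzian sum ever reaching 1, so the check is on a dense grid rather
  # than on the raw amplitude sum.
  centers <- vapply(pools, `[[`, numeric(1), "center")
  fwhms <- vapply(pools, `[[`, numeric(1), "fwhm")
  grid <- sort(unique(c(
    seq(min(centers - 3 * fwhms), max(centers + 3 * fwhms), length.out = 2001),
    centers
  )))
  sat <- rowSums(vapply(
    pools, function(p) lorentzian(grid, p$amplitude, p$center, p$fwhm),
    numeric(length(grid))
  ))
  if (max(sat) > 1 + 1e-9) {
    stop("invalid pool specification: combined saturation reaches ",
         signif(max(sat), 4), " > 1 near ",
         signif(grid[which.max(sat)], 3),
         " ppm; the noiseless signal would go negative")
  }
  pools
}

#' Default brain pool sets
#'
#' Six-pool parameter sets used by the simulators as stand-ins for normal
#' and tumor brain tissue: water and MT backgrounds plus amide (3.5 ppm),
#' amine (2 ppm), rNOE(-3.5) and rNOE(-1.6) dips.  The tumor set carries a
#' reduced rNOE(-1.6) amplitude, emulating the hypointensity of the -1.6 ppm
#' band in glioma.  In-vivo linewidths are not tabulated in the literature
#' this emulates; these values are plausible fixture defaults, not
#' measurements.
#'
#' @param region `"normal"` or `"tumor"`.
#' @param rnoe16_amplitude Override for the rNOE(-1.6) amplitude.
#' @return A list of [pool_spec()] objects.
#' @export
default_brain_pools <- function(region = c("normal", "tumor"),
                                rnoe16_amplitude = NULL) {
  region <- match.arg(region)
  amp16 <- rnoe16_amplitude %||% switch(region, normal = 0.015, tumor = 0.005)
  list(
    pool_spec(0.0, 0.85, 1.4, "water"),
    pool_spec(-2.5, 0.08, 25, "mt"),
    pool_spec(3.5, 0.03, 1.0, "amide"),
    pool_spec(2.0, 0.02, 1.5, "amine"),
    pool_spec(-3.5, 0.04, 1.5, "rnoe35"),
    pool_spec(-1.6, amp16, 0.6, "rnoe16")
  )
}

#' Scale pool amplitudes by label
#'
#' Saturation-amplitude dependence (e.g. acquisitions at 0.3, 0.6 and
#' 0.9 uT) is emulated by rescaling pool amplitudes with a user-supplied
#' table rather than by spin physics: the B1 level is treated purely as an
#' acquisition setting.
#'
#' @param pools List of [pool_spec()] objects.
#' @param factors Named numeric vector of multiplicative factors keyed by
#'   pool label; labels absent from the table are left unchanged.
#' @return A list of rescaled [pool_spec()] objects.
#' @export
scale_pools <- function(pools, factors) {
  pools <- validate_pool_list(pools)
  stopifnot(is.numeric(factors), !is.null(names(factors)))
  lapply(pools, function(p) {
    f <- if (p$label %in% names(factors)) factors[[p$label]] else 1
    pool_spec(p$center, p$amplitude * f, p$fwhm, p$label)
  })
}

#' Standard acquisition schedules
#'
#' Offset and delay schedules matching the acquisitions the simulators
#' emulate: the in-vivo CEST offset list (333-ppm reference, coarse wings,
#' and -4 to 4 ppm at 0.1-ppm steps), the WASSR sweep (-1 to 1 ppm at
#' 0.1 ppm), the homogenate CEST offset list (250-ppm reference with
#' variable spacing), the RARE-VTR repetition-time list, and the
#' inversion-recovery delay list.
#'
#' @return Numeric vector of offsets in ppm, or times in seconds.
#' @name schedules
NULL

#' @rdname schedules
#' @export
cest_offsets_invivo <- function() {
  c(333, -10, -8, -6, -5, seq(-4, 4, by = 0.1), 5, 6, 8, 10)
}

#' @rdname schedules
#' @export
wassr_offsets <- function() seq(-1, 1, by = 0.1)

#' @rdname schedules
#' @export
cest_offsets_homogenate <- function() {
  c(250, -20, -15, -10, -6, -5, -4.5, seq(-4, -3, by = 0.1),
    seq(-2.8, -2, by = 0.2), seq(-1.9, -1, by = 0.1),
    seq(-0.8, 4, by = 0.2), 4.5, 5, 6, 10, 15, 20)
}

#' @rdname schedules
#' @export
tr_schedule_vtr <- function() c(0.05, 0.2, 0.5, 0.8, 1, 2, 4, 6)

#' @rdname schedules
#' @export
inversion_delays <- function() c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 6, 10)
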
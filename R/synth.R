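#' Simulate a multi-pool z-spectrum
#'
#' Generates a normalized saturation spectrum as unity minus a sum of
#' Lorentzian dips, one per pool: `Z(dw) = 1 - sum_i L_i(dw)`, optionally
#' shifted as a whole by a B0 offset and corrupted with additive Gaussian
#' noise.  This parametric form matches the two-pool Lorentzian background
#' model used downstream; it deliberately does not integrate the
#' Bloch-McConnell equations.
#'
#' @param pools List of [pool_spec()] objects; amplitudes must sum to <= 1.
#' @param offsets Saturation offsets in ppm (water = 0); non-empty.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   normalized intensity; `0` for a noiseless spectrum.
#' @param seed Integer seed controlling the noise draw; the global RNG
#'   state is preserved.  Identical `(pools, offsets, seed)` reproduce
#'   bit-identical output.
#' @param b0_offset Frequency offset in ppm added to every pool center,
#'   emulating B0 inhomogeneity.
#' @param reference_offset Offset recorded as the normalization reference.
#' @return A [zspectrum()] object.
#' @examples
#' z <- simulate_zspectrum(default_brain_pools("normal"), cest_offsets_invivo())
#' @export
simulate_zspectrum <- function(pools, offsets, noise_sd = 0, seed = NULL,
                               b0_offset = 0, reference_offset = 333) {
  pools <- validate_pool_list(pools)
  stopifnot(is.numeric(offsets), length(offsets) >= 1L, all(is.finite(offsets)),
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(b0_offset), length(b0_offset) == 1L, is.finite(b0_offset))
  sat <- numeric(length(offsets))
  for (p in pools) {
    sat <- sat + lorentzian(offsets, p$amplitude, p$center + b0_offset, p$fwhm)
  }
  signal <- 1 - sat
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(length(offsets), 0, noise_sd))
  }
  zspectrum(offsets, signal, reference_offset = reference_offset)
}

#' Simulate a T1 recovery curve
#'
#' Saturation-recovery curves follow `I(t) = I0 * (1 - exp(-t / T1))`.
#' Inversion-recovery curves are normalized so the fully relaxed signal is 1
#' and follow the bi-exponential form
#' `I(t) = 1 - 2 * (x_a * exp(-t / T1_a) + (1 - x_a) * exp(-t / T1_b))`,
#' with `x_a` the fraction of pool a (a mono-exponential curve is `x_a = 1`).
#'
#' @param kind `"saturation"` or `"inversion"`.
#' @param params For saturation: list with `I0` and `T1` (s).  For
#'   inversion: list with `x_a`, `T1_a` and (unless `x_a = 1`) `T1_b`.
#' @param times Recovery delays in seconds, strictly positive.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed for the noise draw.
#' @return A [recovery_curve()] object.
#' @export
simulate_recovery_curve <- function(kind = c("saturation", "inversion"),
                                    params, times, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times), length(times) >= 1L, all(times > 0),
            is.numeric(noise_sd), noise_sd >= 0)
  intensities <- if (kind == "saturation") {
    stopifnot(!is.null(params$I0), !is.null(params$T1), params$T1 > 0)
    params$I0 * (1 - exp(-times / params$T1))
  } else {
    x_a <- params$x_a
    if (is.null(x_a) || x_a < 0 || x_a > 1) {
      stop("inversion recovery requires x_a in [0, 1]")
    }
    T1_a <- params$T1_a
    T1_b <- if (x_a == 1) T1_a else params$T1_b
    stopifnot(T1_a > 0, T1_b > 0)
    1 - 2 * (x_a * exp(-times / T1_a) + (1 - x_a) * exp(-times / T1_b))
  }
  if (noise_sd > 0) {
    intensities <- intensities +
      with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  }
  recovery_curve(times, intensities, kind)
}

#' Simulate a 1H-NMR spectrum
#'
#' Builds a spectrum as a sum of area-parameterized Lorentzian or Gaussian
#' peaks on an arbitrary ppm axis, plus additive Gaussian noise.  Peak
#' heights are chosen so the analytic area of each lineshape equals the
#' requested `area`; a peak whose center falls outside the axis range is
#' truncated with a warning.
#'
#' @param peaks List of [nmr_peak_spec()] objects.
#' @param ppm_axis Strictly monotone chemical-shift axis (either direction).
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param seed Integer seed for the noise draw.
#' @return An [nmr_spectrum()] object.
#' @export
simulate_nmr_spectrum <- function(peaks, ppm_axis, noise_sd = 0, seed = NULL) {
  if (inherits(peaks, "nmr_peak_spec")) peaks <- list(peaks)
  stopifnot(all(vapply(peaks, inherits, logical(1), "nmr_peak_spec")),
            is.numeric(ppm_axis), length(ppm_axis) >= 2L)
  d <- diff(ppm_axis)
  if (!(all(d > 0) || all(d < 0))) stop("ppm_axis must be strictly monotone")
  lo <- min(ppm_axis); hi <- max(ppm_axis)
  intensity <- numeric(length(ppm_axis))
  for (p in peaks) {
    if (p$center < lo || p$center > hi) {
      warning("peak at ", p$center, " ppm lies outside the axis range [",
              lo, ", ", hi, "] and is truncated")
    }
    intensity <- intensity + if (p$lineshape == "gaussian") {
      sigma <- fwhm_to_sigma(p$fwhm)
      gaussian_peak(ppm_axis, p$area / (sigma * sqrt(2 * pi)), p$center, sigma)
    } else {
      # Lorentzian with unit area has height 2 / (pi * fwhm)
      lorentzian(ppm_axis, p$area * 2 / (pi * p$fwhm), p$center, p$fwhm)
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity +
      with_seed(seed, stats::rnorm(length(ppm_axis), 0, noise_sd))
  }
  nmr_spectrum(ppm_axis, intensity)
}

#' NMR peak specification
#'
#' @param center Peak center in ppm.
#' @param area Analytic peak area in arbitrary units; non-negative.
#' @param fwhm Full width at half maximum in ppm; positive.
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @return An object of class `nmr_peak_spec`.
#' @export
nmr_peak_spec <- function(center, area, fwhm,
                          lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  stopifnot(is.numeric(center), is.numeric(area), is.numeric(fwhm))
  if (area < 0) stop("peak area must be non-negative")
  if (fwhm <= 0) stop("peak fwhm must be positive")
  structure(list(center = center, area = area, fwhm = fwhm,
                 lineshape = lineshape),
            class = "nmr_peak_spec")
}

#' Default lipid-extract NMR peaks
#'
#' Peak set emulating a lipid-extract spectrum in deuterated chloroform:
#' the TMS internal standard at 0 ppm, the cholesterol C18 methyl at
#' 0.68 ppm, alkyl-chain protons near 1.5 ppm, and the phosphatidylcholine
#' choline methyl near 3.35 ppm.  Areas are in arbitrary units with TMS
#' fixed at 12 (its proton count) so that per-proton areas are directly
#' comparable.  Lineshapes are Gaussian so that essentially the whole peak
#' area falls inside the default +-0.03-ppm integration bands.
#'
#' @param chol_area Area of the cholesterol methyl peak.
#' @param pc_area Area of the choline methyl peak.
#' @param lipid_area Area of the alkyl envelope.
#' @param tms_area Area of the TMS reference peak.
#' @return A list of [nmr_peak_spec()] objects.
#' @export
default_extract_peaks <- function(chol_area = 3, pc_area = 4,
                                  lipid_area = 10, tms_area = 12) {
  list(
    nmr_peak_spec(0.00, tms_area, 0.01, "gaussian"),
    nmr_peak_spec(0.68, chol_area, 0.012, "gaussian"),
    nmr_peak_spec(1.00, chol_area / 3, 0.012, "gaussian"),
    nmr_peak_spec(1.52, lipid_area, 0.06, "gaussian"),
    nmr_peak_spec(3.35, pc_area, 0.015, "gaussian")
  )
}
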
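#' 1H-NMR spectrum container
#'
#' @param ppm Chemical-shift axis in ppm, strictly monotone (either
#'   direction).
#' @param intensity Intensities in arbitrary units, same length as `ppm`.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity) {
  stopifnot(is.numeric(ppm), is.numeric(intensity),
            length(ppm) == length(intensity), length(ppm) >= 2L)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f to %.3f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Integrate a chemical-shift band
#'
#' Trapezoidal integral of the spectrum over a ppm band, optionally after
#' subtracting a straight baseline anchored at the band endpoints.  The
#' result is independent of the direction of the ppm axis.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param band Length-2 ppm interval, inside the axis range.
#' @param baseline `"none"` or `"linear"` (straight line through the
#'   spectrum values at the band endpoints).
#' @return Area in intensity units times ppm.
#' @export
integrate_band <- function(spectrum, band, baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spectrum, "nmr_spectrum"), length(band) == 2L)
  x <- spectrum$ppm; y <- spectrum$intensity
  ord <- order(x); x <- x[ord]; y <- y[ord]
  if (baseline == "linear") {
    lo <- min(band); hi <- max(band)
    y_lo <- stats::approx(x, y, xout = lo, rule = 2)$y
    y_hi <- stats::approx(x, y, xout = hi, rule = 2)$y
    slope <- (y_hi - y_lo) / (hi - lo)
    y <- y - (y_lo + slope * (x - lo))
  }
  band_trapz(x, y, band)
}

#' Molarity of a volume-fraction internal standard
#'
#' Converts a volume/volume fraction of a liquid internal standard to a
#' molar concentration: `c [mM] = fraction * density [g/mL] * 1e6 / M
#' [g/mol] / 1000`.  The defaults are tetramethylsilane (TMS, density
#' 0.648 g/mL, molar mass 88.22 g/mol) at 0.05 percent v/v, the usual
#' reference level in deuterated chloroform, which works out to about
#' 3.67 mM.
#'
#' @param volume_fraction Volume fraction of the standard (0.0005 for
#'   0.05 percent v/v).
#' @param density Density of the standard in g/mL.
#' @param molar_mass Molar mass in g/mol.
#' @return Concentration in mM.
#' @examples
#' tms_molarity()  # about 3.67
#' @export
tms_molarity <- function(volume_fraction = 5e-4, density = 0.648,
                         molar_mass = 88.22) {
  stopifnot(volume_fraction > 0, density > 0, molar_mass > 0)
  volume_fraction * density * 1000 / molar_mass * 1000
}

#' Cholesterol concentration by internal-standard integration
#'
#' Quantifies cholesterol against the TMS internal standard by comparing
#' the AUC of the cholesterol C18 methyl resonance (0.68 ppm) to the AUC of
#' TMS at 0 ppm, assuming resonance AUCs proportional to concentration:
#' `c_chol = (AUC_chol / AUC_TMS) * c_standard`, optionally multiplied by
#' 12/3 to account for TMS having 12 equivalent protons against the 3 of
#' the C18 methyl.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param c_standard Internal-standard concentration in mM (default
#'   [tms_molarity()]).
#' @param apply_proton_correction Multiply the ratio by 12/3 (default
#'   `TRUE`).
#' @param chol_band,tms_band Integration bands in ppm.
#' @param baseline Baseline handling passed to [integrate_band()].
#' @return An object of class `quant_result` with fields `band`, `auc`,
#'   `ratio_to_standard`, `concentration` (mM) and
#'   `proton_correction_applied`.
#' @export
cholesterol_concentration <- function(spectrum, c_standard = tms_molarity(),
                                      apply_proton_correction = TRUE,
                                      chol_band = c(0.65, 0.71),
                                      tms_band = c(-0.03, 0.03),
                                      baseline = "none") {
  stopifnot(inherits(spectrum, "nmr_spectrum"), c_standard > 0)
  auc_chol <- integrate_band(spectrum, chol_band, baseline)
  auc_tms <- integrate_band(spectrum, tms_band, baseline)
  if (auc_tms <= 0) stop("cannot quantify: TMS reference AUC is not positive")
  ratio <- auc_chol / auc_tms
  conc <- ratio * c_standard * if (apply_proton_correction) 12 / 3 else 1
  structure(list(band = chol_band, auc = auc_chol,
                 ratio_to_standard = ratio, concentration = conc,
                 proton_correction_applied = apply_proton_correction),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> band [%.2f, %.2f] ppm  AUC %.4g  ratio %.4g  conc %.4g mM%s\n",
              x$band[1], x$band[2], x$auc, x$ratio_to_standard,
              x$concentration,
              if (x$proton_correction_applied) " (proton-corrected)" else ""))
  invisible(x)
}

#' Ratio of two band integrals
#'
#' AUC of a target band divided by the AUC of a reference band; used for
#' relative phosphatidylcholine content (choline methyl band, 3.28--3.38
#' ppm) and relative total lipid (alkyl band, 1.45--1.65 ppm) against the
#' TMS reference.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param target_band,reference_band Length-2 ppm intervals.
#' @param baseline Baseline handling passed to [integrate_band()].
#' @return Dimensionless ratio.
#' @export
relative_band_ratio <- function(spectrum, target_band,
                                reference_band = c(-0.03, 0.03),
                                baseline = "none") {
  auc_t <- integrate_band(spectrum, target_band, baseline)
  auc_r <- integrate_band(spectrum, reference_band, baseline)
  if (auc_r <= 0) stop("cannot quantify: reference band AUC is not positive")
  auc_t / auc_r
}

#' Standard quantification bands
#'
#' Named list of default integration bands in ppm: TMS (0 +- 0.03),
#' cholesterol methyl (0.68 +- 0.03), phosphatidylcholine choline methyl
#' (3.28--3.38) and total lipid alkyl protons (1.45--1.65).
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_nmr_bands <- function() {
  list(tms = c(-0.03, 0.03),
       cholesterol = c(0.65, 0.71),
       phosphatidylcholine = c(3.28, 3.38),
       total_lipid = c(1.45, 1.65))
}
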
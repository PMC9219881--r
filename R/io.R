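#' Read and write pipeline tables and image stacks
#'
#' Z-spectra and recovery curves travel as two-column CSVs with header
#' `offset_ppm,intensity` or `time_s,intensity`; NMR spectra as
#' `ppm,intensity` (descending ppm allowed).  Image stacks are NIfTI files
#' (one volume per offset) paired with a JSON manifest listing the offsets
#' in ppm and the reference offset.
#'
#' @param path File path.
#' @param z,curve,spectrum,stack Object to write.
#' @param reference_offset Reference offset recorded when reading a
#'   z-spectrum CSV.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_zspectrum_csv <- function(z, path) {
  stopifnot(inherits(z, "zspectrum"))
  utils::write.csv(data.frame(offset_ppm = z$offsets, intensity = z$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_zspectrum_csv <- function(path, reference_offset = 333) {
  df <- utils::read.csv(path)
  stopifnot(all(c("offset_ppm", "intensity") %in% names(df)))
  zspectrum(df$offset_ppm, df$intensity, reference_offset = reference_offset)
}

#' @rdname pipeline_io
#' @export
write_recovery_csv <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  utils::write.csv(data.frame(time_s = curve$times,
                              intensity = curve$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param kind Recovery kind recorded when reading (`"saturation"` or
#'   `"inversion"`).
#' @export
read_recovery_csv <- function(path, kind = "saturation") {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "intensity") %in% names(df)))
  recovery_curve(df$time_s, df$intensity, kind)
}

#' @rdname pipeline_io
#' @export
write_nmr_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_nmr_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("ppm", "intensity") %in% names(df)))
  nmr_spectrum(df$ppm, df$intensity)
}

#' @rdname pipeline_io
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @export
write_stack_nifti <- function(stack, prefix) {
  stopifnot(inherits(stack, "offset_image_stack"))
  nii_path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(stack$volumes), nii_path)
  manifest <- list(
    offsets_ppm = stack$offsets,
    reference_offset_ppm = if (is.na(stack$reference_index)) NULL else
      stack$offsets[stack$reference_index],
    reference_index = if (is.na(stack$reference_index)) NULL else
      stack$reference_index,
    orientation = "volumes stored rows x cols x offset, 1-based indices"
  )
  jsonlite::write_json(manifest, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname pipeline_io
#' @export
read_stack_nifti <- function(prefix) {
  vols <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  manifest <- jsonlite::read_json(paste0(prefix, ".json"),
                                  simplifyVector = TRUE)
  ref_idx <- manifest$reference_index %||% NA
  offset_image_stack(vols, manifest$offsets_ppm, reference_index = ref_idx)
}

#' @rdname pipeline_io
#' @export
write_t1_map_nifti <- function(t1_map, path) {
  stopifnot(is.matrix(t1_map))
  m <- t1_map
  m[!is.finite(m)] <- 0
  RNifti::writeNifti(RNifti::asNifti(m), path)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML configuration for the voxelwise pipeline: integration band
#' definitions (`band16`, NMR bands), the map filter stage, and the group
#' comparison test.  Missing keys fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `band16`, `nmr_bands`, `filter_stage`,
#'   `test_method`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    band16 = as.numeric(cfg$band16 %||% c(-1.9, -1.3)),
    nmr_bands = utils::modifyList(default_nmr_bands(),
                                  lapply(cfg$nmr_bands %||% list(), as.numeric)),
    filter_stage = cfg$filter_stage %||% "maps",
    test_method = cfg$test_method %||% "welch"
  )
}
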
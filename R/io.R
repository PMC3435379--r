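#' Write a Jones volume to a JSON container
#'
#' Plain-text container for Jones-matrix volumes: a single JSON document
#' holding the acquisition metadata and the real/imaginary parts of the
#' `(z, x, y, 2, 2)` matrix field. Intended for small fixtures and
#' interchange; volumes at acquisition scale should be regenerated in code.
#'
#' @param vol A `jones_volume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jones_volume <- function(vol, path) {
  stopifnot(inherits(vol, "jones_volume"))
  obj <- list(
    format = "optrheo-jones-volume",
    version = 1L,
    dims = dim(vol),
    wavelength_m = vol$wavelength,
    axial_pitch_m = vol$axial_pitch,
    lateral_pitch_m = vol$lateral_pitch,
    noise_floor = vol$noise_floor,
    separation_pixels = vol$separation_pixels,
    jones_real = as.numeric(Re(vol$j)),
    jones_imag = as.numeric(Im(vol$j)),
    valid = as.logical(vol$valid)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Jones volume from a JSON container
#' @param path File written by [write_jones_volume()].
#' @return A `jones_volume`.
#' @export
read_jones_volume <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "optrheo-jones-volume")) {
    stop("not an optrheo Jones-volume container: ", path, call. = FALSE)
  }
  d <- as.integer(obj$dims)
  j <- array(complex(real = obj$jones_real, imaginary = obj$jones_imag), c(d, 4L))
  jones_volume(j,
    wavelength = obj$wavelength_m,
    axial_pitch = obj$axial_pitch_m,
    lateral_pitch = obj$lateral_pitch_m,
    noise_floor = obj$noise_floor,
    separation_pixels = obj$separation_pixels,
    valid = array(as.logical(obj$valid), d)
  )
}

#' Read a tensile record from CSV plus metadata JSON
#'
#' The CSV must have a header with columns `time_s`, `displacement_mm`,
#' `force_N`. The JSON supplies the sample geometry: `gauge_length_mm`,
#' `area_mm2`, and optionally `width_mm`, `pre_load_n`, `speed_mm_min`,
#' `region_label`.
#'
#' @param csv_path Path to the record CSV.
#' @param meta_path Path to the metadata JSON.
#' @return A `stress_strain_record`.
#' @export
read_stress_strain_csv <- function(csv_path, meta_path) {
  dat <- utils::read.csv(csv_path)
  need <- c("time_s", "displacement_mm", "force_N")
  if (!all(need %in% names(dat))) {
    stop("record CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stress_strain_record(
    dat,
    gauge_length_mm = meta$gauge_length_mm %||% 5,
    area_mm2 = meta$area_mm2,
    width_mm = meta$width_mm %||% 4,
    pre_load_n = meta$pre_load_n %||% 0.04,
    speed_mm_min = meta$speed_mm_min %||% 1.8,
    region = meta$region_label %||% NA_character_
  )
}

#' Write a tensile record to CSV plus metadata JSON
#' @param rec A `stress_strain_record`.
#' @param csv_path,meta_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_stress_strain_csv <- function(rec, csv_path, meta_path) {
  stopifnot(inherits(rec, "stress_strain_record"))
  utils::write.csv(rec$data, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(gauge_length_mm = rec$gauge_length_mm, area_mm2 = rec$area_mm2,
         width_mm = rec$width_mm, pre_load_n = rec$pre_load_n,
         speed_mm_min = rec$speed_mm_min, region_label = rec$region),
    meta_path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(csv_path)
}

#' Write a per-volume processing summary as JSON
#'
#' Records the gated volume mean, the contributing-pixel count and an echo of
#' the configuration, so a run can be audited and reproduced.
#'
#' @param result Output of [process_volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume_summary <- function(result, path) {
  cfg <- result$config
  jsonlite::write_json(
    list(
      mean_birefringence = result$mean_birefringence,
      n_valid = result$n_valid,
      config = list(
        avg_kernel = cfg$avg_kernel,
        separation_pixels = cfg$separation_pixels,
        snr_threshold_db = cfg$snr_threshold_db,
        doau_kernel = cfg$doau_kernel,
        doau_threshold = cfg$doau_threshold,
        bias_correction = cfg$bias_correction,
        rng_seed = cfg$rng_seed
      )
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
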
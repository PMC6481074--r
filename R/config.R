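#' Optical configuration of a phase-only SLM system
#'
#' Bundles the physical constants of the holographic projection path: the
#' laser wavelength, the equivalent focal length of the optical train between
#' the SLM (pupil plane) and the sample, and the SLM pixel lattice. All
#' lengths are given in the conventional boundary units (nm, mm, um) and are
#' converted once to a single internal base unit (micrometres).
#'
#' Defaults describe a typical two-photon photostimulation setup: a Ti:Sapphire
#' beam at 800 nm, a 1920 x 1152 SLM with 9.2 um pixel pitch imaged onto the
#' back aperture of a 20x objective (f_obj = 9 mm) through a 2x pupil relay,
#' giving an equivalent focal length of 18 mm.
#'
#' @param wavelength_nm Laser wavelength in nanometres. Must be positive.
#' @param focal_length_mm Equivalent focal length `f` of the optical system in
#'   millimetres: the focal length that maps a phase tilt at the SLM to a
#'   lateral displacement in the sample.
#' @param pixel_pitch_um Centre-to-centre SLM pixel spacing in micrometres.
#' @param slm_rows,slm_cols Number of SLM pixel rows and columns.
#' @param aperture Pupil support: `"full"` uses the whole rectangular active
#'   area (a collimated beam overfilling the SLM); `"circular"` restricts the
#'   active pixels to the largest inscribed disc.
#' @return An object of class `"optical_config"`.
#' @seealso [pupil_grid()], [benchmark_config()], [read_optical_config()]
#' @examples
#' cfg <- optical_config()
#' cfg
#' @export
optical_config <- function(wavelength_nm = 800, focal_length_mm = 18,
                           pixel_pitch_um = 9.2, slm_rows = 1152,
                           slm_cols = 1920, aperture = c("full", "circular")) {
  aperture <- match.arg(aperture)
  for (v in c("wavelength_nm", "focal_length_mm", "pixel_pitch_um")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("'%s' must be a single positive number", v), call. = FALSE)
  }
  for (v in c("slm_rows", "slm_cols")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < 1 || val != as.integer(val))
      stop(sprintf("'%s' must be a positive whole number", v), call. = FALSE)
  }
  structure(list(
    wavelength_nm  = wavelength_nm,
    focal_length_mm = focal_length_mm,
    pixel_pitch_um = pixel_pitch_um,
    slm_rows = as.integer(slm_rows),
    slm_cols = as.integer(slm_cols),
    aperture = aperture,
    # internal base unit: micrometres
    wavelength_um   = wavelength_nm * 1e-3,
    focal_length_um = focal_length_mm * 1e3
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration (phase-only SLM)\n")
  cat(sprintf("  wavelength:    %g nm\n", x$wavelength_nm))
  cat(sprintf("  focal length:  %g mm (equivalent)\n", x$focal_length_mm))
  cat(sprintf("  SLM:           %d x %d px, pitch %g um, %s aperture\n",
              x$slm_rows, x$slm_cols, x$pixel_pitch_um, x$aperture))
  invisible(x)
}

#' Scaled-down square benchmark configuration
#'
#' Square simulated pupils used throughout the computational benchmarks.
#' The pupil downsamples the short side of the reference SLM (1152 px at
#' 9.2 um) at a fixed physical aperture of about 10.6 mm: the pixel pitch is
#' scaled up as the pixel count shrinks. Keeping the aperture fixed preserves
#' the diffraction-limited spot size and the depth of focus of the full-size
#' system, so axially displaced (z != 0) spots remain meaningful on small
#' simulated pupils; only the accessible lateral field shrinks (its Nyquist
#' half-width is lambda*f / (2*pitch), about 174 um at 256 px).
#'
#' @param n_pixels Pixels per pupil side.
#' @return An [optical_config()] with an `n_pixels` x `n_pixels` grid.
#' @examples
#' benchmark_config(256)
#' @export
benchmark_config <- function(n_pixels = 256) {
  optical_config(pixel_pitch_um = 9.2 * 1152 / n_pixels,
                 slm_rows = n_pixels, slm_cols = n_pixels)
}

#' Read / write an optical configuration file
#'
#' YAML (`.yml`, `.yaml`) or JSON (`.json`) files with keys `wavelength_nm`,
#' `focal_length_mm`, `pixel_pitch_um`, `slm_rows`, `slm_cols` and optionally
#' `aperture` (`"full"` or `"circular"`, default full).
#'
#' @param path File path; the extension selects the format.
#' @return `read_optical_config()` returns an [optical_config()];
#'   `write_optical_config()` returns `path` invisibly.
#' @export
read_optical_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  vals <- switch(.config_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  req <- c("wavelength_nm", "focal_length_mm", "pixel_pitch_um",
           "slm_rows", "slm_cols")
  missing <- setdiff(req, names(vals))
  if (length(missing))
    stop("configuration is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  optical_config(wavelength_nm = vals$wavelength_nm,
                 focal_length_mm = vals$focal_length_mm,
                 pixel_pitch_um = vals$pixel_pitch_um,
                 slm_rows = vals$slm_rows, slm_cols = vals$slm_cols,
                 aperture = if (is.null(vals$aperture)) "full" else vals$aperture)
}

#' @rdname read_optical_config
#' @param config An [optical_config()] object.
#' @export
write_optical_config <- function(config, path) {
  stopifnot(inherits(config, "optical_config"))
  vals <- config[c("wavelength_nm", "focal_length_mm", "pixel_pitch_um",
                   "slm_rows", "slm_cols", "aperture")]
  switch(.config_format(path),
    yaml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  )
  invisible(path)
}

.config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported configuration format '.", ext,
       "' (use .yaml, .yml or .json)", call. = FALSE)
}
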
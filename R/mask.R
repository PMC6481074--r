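#' Export a hologram as an SLM phase mask image
#'
#' Writes the phase map as a single-channel grey-scale image ready for SLM
#' upload. This is the only place where the phase is wrapped: each pixel is
#' mapped to `round(wrap(phase, 2*pi) / (2*pi) * grey_levels)`, so grey 0 is
#' phase 0 and grey `grey_levels` is a full 2*pi retardation (real SLMs often
#' calibrate 2*pi below the full bit depth, hence the configurable level).
#' A phase just below 2*pi rounds up to grey `grey_levels`, never to 0.
#' Row 1 of the phase matrix is written as the top image row.
#'
#' PNG output is 8-bit (`grey_levels` at most 255); TIFF output (`.tif` /
#' `.tiff`) is 8-bit or, when `grey_levels` exceeds 255, 16-bit. Export is
#' deterministic: equal inputs give byte-identical files.
#'
#' @param phase A [cgh()] fit or a numeric phase matrix (radians).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param grey_levels The grey level representing a full 2*pi phase
#'   (default 255).
#' @return `path`, invisibly.
#' @seealso [read_phase_mask()]
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_phase_mask(matrix(pi, 4, 4), f)
#' @export
write_phase_mask <- function(phase, path, grey_levels = 255) {
  if (inherits(phase, "cgh")) phase <- phase$phase
  if (!is.matrix(phase) || !is.numeric(phase) || any(!is.finite(phase)))
    stop("'phase' must be a finite numeric matrix", call. = FALSE)
  if (grey_levels < 1) stop("'grey_levels' must be at least 1", call. = FALSE)
  grey <- phase_to_grey(phase, grey_levels)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (grey_levels > 255)
      stop("PNG export is 8-bit; use a .tiff path for grey_levels > 255",
           call. = FALSE)
    png::writePNG(grey / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    bits <- if (grey_levels > 255) 16L else 8L
    tiff::writeTIFF(grey / (2^bits - 1), path, bits.per.sample = bits,
                    compression = "none")
  } else {
    stop("unsupported mask format '.", ext, "' (use .png, .tif or .tiff)",
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_phase_mask
#' @return `read_phase_mask()` returns the integer grey-level matrix with the
#'   corresponding wrapped phase (radians) in attribute `"phase"`.
#' @export
read_phase_mask <- function(path, grey_levels = 255) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '.", ext, "'", call. = FALSE))
  depth <- if (grey_levels > 255 && ext != "png") 65535 else 255
  grey <- round(img * depth)
  attr(grey, "phase") <- grey / grey_levels * 2 * pi
  grey
}

# wrap to [0, 2*pi) and quantize to integer grey levels in [0, grey_levels]
phase_to_grey <- function(phase, grey_levels = 255) {
  wrapped <- phase %% (2 * pi)
  round(wrapped / (2 * pi) * grey_levels)
}
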
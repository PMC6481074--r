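#' Pupil-plane pixel grid of an SLM
#'
#' Physical coordinates of every SLM pixel centre, with the origin at the
#' geometric centre of the active area. Pixel (i, j) (row i, column j, both
#' 1-based) sits at
#' `x = (j - 1 - (n_cols - 1)/2) * pitch`, `y = (i - 1 - (n_rows - 1)/2) * pitch`,
#' so the coordinates are symmetric about zero up to the half-pixel parity
#' offset of even-sized grids. Row 1 is the top row of the SLM.
#'
#' Pixels are stored in R's column-major matrix order. With a circular
#' aperture, only pixels inside the largest inscribed disc are active; the
#' active pixel count defines `M`, the pupil size entering all algorithms.
#'
#' @param config An [optical_config()].
#' @return An object of class `"pupil_grid"`: a list with the full coordinate
#'   vectors `x`, `y` (um, length `slm_rows * slm_cols`), the integer indices
#'   `active` of pixels inside the aperture, the active pixel count `M`, the
#'   grid shape `n_rows`, `n_cols` and the originating `config`.
#' @examples
#' g <- pupil_grid(benchmark_config(64))
#' g$M
#' @export
pupil_grid <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  nr <- config$slm_rows
  nc <- config$slm_cols
  p <- config$pixel_pitch_um
  xc <- (seq_len(nc) - 1 - (nc - 1) / 2) * p
  yc <- (seq_len(nr) - 1 - (nr - 1) / 2) * p
  x <- rep(xc, each = nr)   # column-major: row index varies fastest
  y <- rep(yc, times = nc)
  active <- if (config$aperture == "circular") {
    radius <- min(nc, nr) * p / 2
    which(x * x + y * y <= radius * radius)
  } else {
    seq_len(nr * nc)
  }
  structure(list(config = config, x = x, y = y, active = active,
                 M = length(active), n_rows = nr, n_cols = nc),
            class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("Pupil grid: %d x %d px (%s aperture), M = %d active pixels\n",
              x$n_rows, x$n_cols, x$config$aperture, x$M))
  cat(sprintf("  extent: x in [%.1f, %.1f] um, y in [%.1f, %.1f] um\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Sample a random subset of pupil pixels
#'
#' Draws the fixed random pixel subset on which the compressed iterations of
#' CS-GS / CS-WGS operate: `max(1, round(fraction * M))` distinct active-pixel
#' indices, uniformly without replacement. `fraction = 1` returns all pixels
#' in canonical order without consuming random numbers.
#'
#' @param grid A [pupil_grid()].
#' @param fraction Compression factor c in (0, 1]: the fraction of pupil
#'   pixels retained.
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   used (and advanced); otherwise the global RNG state is left untouched.
#' @return A sorted integer vector of indices into the active pixels
#'   (`1..M`), with the realized fraction in attribute `"fraction"`.
#' @examples
#' g <- pupil_grid(benchmark_config(32))
#' length(sample_pupil_subset(g, 1 / 32, seed = 1))
#' @export
sample_pupil_subset <- function(grid, fraction, seed = NULL) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be a single number in (0, 1]", call. = FALSE)
  M <- grid$M
  idx <- if (fraction == 1) {
    seq_len(M)
  } else {
    size <- max(1L, as.integer(round(fraction * M)))
    with_seed(seed, sort(sample.int(M, size)))
  }
  attr(idx, "fraction") <- length(idx) / M
  idx
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; with
# seed = NULL the ambient stream is used and advanced.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
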
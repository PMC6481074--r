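#' Target spot sets
#'
#' A spot set is an ordered table of target foci in image space: lateral
#' coordinates `x_um`, `y_um` and axial defocus `z_um` (all micrometres,
#' `z_um = 0` is the nominal focal plane), plus an optional strictly positive
#' `weight` column of relative target intensities (uniform when absent).
#'
#' @param x_um,y_um,z_um Numeric coordinate vectors (recycled to a common
#'   length); all values must be finite.
#' @param weight Optional positive per-spot target weights.
#' @return A data frame of class `"spot_set"`.
#' @examples
#' spot_set(c(-20, 20), 0, c(0, 10))
#' @export
spot_set <- function(x_um, y_um, z_um = 0, weight = NULL) {
  n <- max(length(x_um), length(y_um), length(z_um))
  spots <- data.frame(x_um = rep_len(as.numeric(x_um), n),
                      y_um = rep_len(as.numeric(y_um), n),
                      z_um = rep_len(as.numeric(z_um), n))
  if (!is.null(weight)) spots$weight <- rep_len(as.numeric(weight), n)
  as_spot_set(spots)
}

#' @rdname spot_set
#' @param x A data frame with columns `x_um`, `y_um`, `z_um` (and optionally
#'   `weight`), or an existing spot set.
#' @export
as_spot_set <- function(x) {
  if (inherits(x, "spot_set")) return(x)
  if (!is.data.frame(x))
    stop("spots must be a data frame with columns x_um, y_um, z_um", call. = FALSE)
  missing <- setdiff(c("x_um", "y_um", "z_um"), names(x))
  if (length(missing))
    stop("spot table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(x) < 1L) stop("a spot set needs at least one spot", call. = FALSE)
  for (col in intersect(c("x_um", "y_um", "z_um", "weight"), names(x))) {
    v <- x[[col]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("column '%s' has a non-finite value in row %d", col, bad[1L]),
           call. = FALSE)
  }
  if (!is.null(x$weight) && any(x$weight <= 0))
    stop(sprintf("weights must be strictly positive (row %d)",
                 which(x$weight <= 0)[1L]), call. = FALSE)
  structure(x[, intersect(c("x_um", "y_um", "z_um", "weight"), names(x))],
            class = c("spot_set", "data.frame"))
}

#' Read / write a spot list as CSV
#'
#' The on-disk format is a headed CSV with numeric columns `x_um`, `y_um`,
#' `z_um` and an optional `weight` column; row order is preserved. Parse
#' failures report the offending row.
#'
#' @param path CSV file path.
#' @return `read_spots_csv()` returns a [spot_set()]; `write_spots_csv()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_spots_csv(grid_pattern(2, 2), f)
#' read_spots_csv(f)
#' @export
read_spots_csv <- function(path) {
  if (!file.exists(path)) stop("spot file not found: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("cannot parse spot CSV '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("spot file '", path, "' contains no spots", call. = FALSE)
  for (col in intersect(c("x_um", "y_um", "z_um", "weight"), names(tab))) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                     v[bad[1L]], col, bad[1L], path), call. = FALSE)
      tab[[col]] <- coerced
    }
  }
  as_spot_set(tab)
}

#' @rdname read_spots_csv
#' @param spots A [spot_set()] (or coercible data frame).
#' @export
write_spots_csv <- function(spots, path) {
  spots <- as_spot_set(spots)
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE)
  invisible(path)
}

#' Random three-dimensional spot cloud
#'
#' Draws `n` spots uniformly in the box
#' `[-lateral_extent_um, lateral_extent_um]^2 x [-axial_extent_um, axial_extent_um]`,
#' emulating a sparse 3D set of photostimulation targets. The defaults (100
#' spots in a 200 x 200 x 100 um volume) represent a realistic optogenetics
#' workload and fit inside the accessible field of the benchmark pupils.
#'
#' @param n Number of spots.
#' @param lateral_extent_um Half-width of the lateral box (um).
#' @param axial_extent_um Half-depth of the axial range (um); 0 gives a planar
#'   pattern.
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @return A [spot_set()].
#' @examples
#' random_spot_cloud(5, seed = 1)
#' @export
random_spot_cloud <- function(n = 100, lateral_extent_um = 100,
                              axial_extent_um = 50, seed = NULL) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (lateral_extent_um < 0 || axial_extent_um < 0)
    stop("extents must be non-negative", call. = FALSE)
  with_seed(seed, {
    x <- stats::runif(n, -lateral_extent_um, lateral_extent_um)
    y <- stats::runif(n, -lateral_extent_um, lateral_extent_um)
    z <- if (axial_extent_um > 0) {
      stats::runif(n, -axial_extent_um, axial_extent_um)
    } else {
      rep(0, n)
    }
    spot_set(x, y, z)
  })
}

#' Regular in-plane spot grid
#'
#' `rows * cols` spots on a centred rectangular lattice in the focal plane
#' (`z = 0`). Regular grids are the worst case for hologram uniformity:
#' the periodic spot arrangement makes the per-spot fields interfere
#' coherently, so plain GS produces strongly unequal intensities and the
#' weighted algorithms have the most to gain.
#'
#' @param rows,cols Lattice dimensions.
#' @param spacing_um Lattice constant (um).
#' @return A [spot_set()] in row-major order.
#' @examples
#' grid_pattern(2, 3, 10)
#' @export
grid_pattern <- function(rows = 10, cols = 10, spacing_um = 20) {
  if (rows < 1 || cols < 1) stop("'rows' and 'cols' must be at least 1", call. = FALSE)
  xo <- (seq_len(cols) - (cols + 1) / 2) * spacing_um
  yo <- (seq_len(rows) - (rows + 1) / 2) * spacing_um
  spot_set(rep(xo, times = rows), rep(yo, each = cols), 0)
}

#' Letter-shaped spot pattern
#'
#' Samples `n_points` planar spots along the stroke paths of simple
#' block-letter glyphs, equally spaced in arc length over the whole text and
#' scaled to a given width. Used to emulate patterns that span the accessible
#' field of view, such as initials projected across a sample. The glyph
#' geometry is a package-defined single-stroke font; only the resulting spot
#' coordinates matter.
#'
#' @param text Uppercase letters (A-Z except Q) and spaces.
#' @param n_points Number of spots to distribute along the strokes.
#' @param extent_um Total pattern width (um).
#' @return A [spot_set()] with `z_um = 0`.
#' @examples
#' glyph_pattern("TUD", n_points = 25)
#' @export
glyph_pattern <- function(text, n_points = 25, extent_um = 500) {
  if (!is.character(text) || length(text) != 1L || nchar(text) < 1L)
    stop("'text' must be a non-empty string", call. = FALSE)
  if (n_points < 1) stop("'n_points' must be at least 1", call. = FALSE)
  chars <- strsplit(toupper(text), "")[[1]]
  unknown <- setdiff(chars, c(names(.glyph_font), " "))
  if (length(unknown))
    stop("unsupported character(s) ", paste0("'", unknown, "'", collapse = ", "),
         "; supported: ", paste(names(.glyph_font), collapse = ""), " and space",
         call. = FALSE)
  advance <- 1.3
  segs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == " ") next
    for (stroke in .glyph_font[[chars[i]]]) {
      s <- stroke
      s[, 1] <- s[, 1] + (i - 1) * advance
      for (j in seq_len(nrow(s) - 1))
        segs[[length(segs) + 1L]] <- rbind(s[j, ], s[j + 1, ])
    }
  }
  if (!length(segs)) stop("'text' contains no drawable glyphs", call. = FALSE)
  len <- vapply(segs, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  cum <- cumsum(len)
  total <- cum[length(cum)]
  pos <- if (n_points == 1) 0 else (seq_len(n_points) - 1) / (n_points - 1) * total
  pts <- t(vapply(pos, function(p) {
    k <- which(cum >= p - 1e-12)[1L]
    t0 <- (p - c(0, cum)[k]) / len[k]
    segs[[k]][1, ] + t0 * (segs[[k]][2, ] - segs[[k]][1, ])
  }, numeric(2)))
  # centre and scale to the requested width
  pts[, 1] <- pts[, 1] - (min(pts[, 1]) + max(pts[, 1])) / 2
  pts[, 2] <- pts[, 2] - (min(pts[, 2]) + max(pts[, 2])) / 2
  width <- max(pts[, 1]) - min(pts[, 1])
  scale <- if (width > 0) extent_um / width else extent_um
  spot_set(pts[, 1] * scale, pts[, 2] * scale, 0)
}

# single-stroke block-letter font on a 1 x 1.4 em box (x right, y up)
.ellipse_arc <- function(cx, cy, rx, ry, a0, a1, n = 10) {
  a <- seq(a0, a1, length.out = n) * pi / 180
  cbind(cx + rx * cos(a), cy + ry * sin(a))
}

.glyph_font <- local({
  seg <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    A = list(seg(0, 0, 0.5, 1.4, 1, 0), seg(0.2, 0.55, 0.8, 0.55)),
    B = list(seg(0, 0, 0, 1.4),
             rbind(seg(0, 1.4, 0.5, 1.4), .ellipse_arc(0.5, 1.05, 0.45, 0.35, 90, -90),
                   seg(0.5, 0.7, 0, 0.7)),
             rbind(seg(0, 0.7, 0.5, 0.7), .ellipse_arc(0.5, 0.35, 0.5, 0.35, 90, -90),
                   seg(0.5, 0, 0, 0))),
    C = list(.ellipse_arc(0.5, 0.7, 0.5, 0.7, 45, 315, 14)),
    D = list(seg(0, 0, 0, 1.4),
             rbind(seg(0, 1.4, 0.5, 1.4), .ellipse_arc(0.5, 0.7, 0.5, 0.7, 90, -90, 12),
                   seg(0.5, 0, 0, 0))),
    E = list(seg(1, 1.4, 0, 1.4, 0, 0, 1, 0), seg(0, 0.7, 0.8, 0.7)),
    F = list(seg(1, 1.4, 0, 1.4, 0, 0), seg(0, 0.7, 0.8, 0.7)),
    G = list(rbind(.ellipse_arc(0.5, 0.7, 0.5, 0.7, 45, 315, 14), seg(1, 0.45, 0.55, 0.45))),
    H = list(seg(0, 0, 0, 1.4), seg(1, 0, 1, 1.4), seg(0, 0.7, 1, 0.7)),
    I = list(seg(0.5, 0, 0.5, 1.4)),
    J = list(rbind(seg(0.7, 1.4, 0.7, 0.35), .ellipse_arc(0.35, 0.35, 0.35, 0.35, 0, -180, 8))),
    K = list(seg(0, 0, 0, 1.4), seg(1, 1.4, 0, 0.6), seg(0.35, 0.88, 1, 0)),
    L = list(seg(0, 1.4, 0, 0, 1, 0)),
    M = list(seg(0, 0, 0, 1.4, 0.5, 0.6, 1, 1.4, 1, 0)),
    N = list(seg(0, 0, 0, 1.4, 1, 0, 1, 1.4)),
    O = list(.ellipse_arc(0.5, 0.7, 0.5, 0.7, 90, 450, 17)),
    P = list(seg(0, 0, 0, 1.4),
             rbind(seg(0, 1.4, 0.5, 1.4), .ellipse_arc(0.5, 1.05, 0.45, 0.35, 90, -90),
                   seg(0.5, 0.7, 0, 0.7))),
    R = list(seg(0, 0, 0, 1.4),
             rbind(seg(0, 1.4, 0.5, 1.4), .ellipse_arc(0.5, 1.05, 0.45, 0.35, 90, -90),
                   seg(0.5, 0.7, 0, 0.7)),
             seg(0.3, 0.7, 1, 0)),
    S = list(seg(0.95, 1.2, 0.7, 1.4, 0.3, 1.4, 0.05, 1.15, 0.15, 0.85, 0.5, 0.7,
                 0.85, 0.55, 0.95, 0.25, 0.7, 0, 0.3, 0, 0.05, 0.2)),
    T = list(seg(0, 1.4, 1, 1.4), seg(0.5, 1.4, 0.5, 0)),
    U = list(rbind(seg(0, 1.4, 0, 0.4), .ellipse_arc(0.5, 0.4, 0.5, 0.4, 180, 360, 10),
                   seg(1, 0.4, 1, 1.4))),
    V = list(seg(0, 1.4, 0.5, 0, 1, 1.4)),
    W = list(seg(0, 1.4, 0.25, 0, 0.5, 0.9, 0.75, 0, 1, 1.4)),
    X = list(seg(0, 1.4, 1, 0), seg(1, 1.4, 0, 0)),
    Y = list(seg(0, 1.4, 0.5, 0.7), seg(1, 1.4, 0.5, 0.7), seg(0.5, 0.7, 0.5, 0)),
    Z = list(seg(0, 1.4, 1, 1.4, 0, 0, 1, 0))
  )
})
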
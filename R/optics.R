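#' Single-spot hologram phase (tip, tilt and defocus)
#'
#' The pupil phase that focuses the beam to a single point `(x, y, z)` in
#' image space is the combination of tip/tilt (lateral displacement) and a
#' quadratic defocus term (axial displacement):
#'
#' \deqn{\phi(x', y') = \frac{\pi z}{\lambda f^2}(x'^2 + y'^2) +
#'       \frac{2\pi}{\lambda f}(x x' + y y')}
#'
#' with \eqn{(x', y')} the physical pupil coordinates, \eqn{\lambda} the
#' wavelength and \eqn{f} the equivalent focal length. The phase is returned
#' unwrapped; wrapping modulo \eqn{2\pi} is deferred to mask export.
#'
#' @param grid A [pupil_grid()] (or an [optical_config()], converted).
#' @param x_um,y_um,z_um Spot coordinates in image space (um).
#' @return A numeric `n_rows x n_cols` matrix of phases (radians) over the
#'   full rectangular pixel grid.
#' @examples
#' ph <- spot_phase(benchmark_config(16), 50, 0, 0)
#' dim(ph)
#' @export
spot_phase <- function(grid, x_um, y_um, z_um = 0) {
  grid <- as_pupil_grid(grid)
  for (v in c(x_um, y_um, z_um))
    if (!is.finite(v)) stop("spot coordinates must be finite", call. = FALSE)
  matrix(.spot_phase_vec(grid$x, grid$y, x_um, y_um, z_um, grid$config),
         grid$n_rows, grid$n_cols)
}

# unwrapped spot phase over arbitrary pixel coordinate vectors (um)
.spot_phase_vec <- function(px, py, sx, sy, sz, config) {
  lam <- config$wavelength_um
  f <- config$focal_length_um
  pi * sz / (lam * f^2) * (px * px + py * py) +
    2 * pi / (lam * f) * (sx * px + sy * py)
}

as_pupil_grid <- function(x) {
  if (inherits(x, "pupil_grid")) return(x)
  if (inherits(x, "optical_config")) return(pupil_grid(x))
  stop("expected a pupil_grid or optical_config", call. = FALSE)
}

# M x N complex matrix of per-spot unit phasors exp(i * phi_n) over the
# active pupil pixels. This is the dense forward operator the iterative
# engine multiplies with; it is built once per run and freed afterwards
# (16 * M * N bytes while a run is in flight).
.spot_phasors <- function(grid, spots, subset = NULL) {
  px <- grid$x[grid$active]
  py <- grid$y[grid$active]
  if (!is.null(subset)) {
    px <- px[subset]
    py <- py[subset]
  }
  P <- matrix(0i, length(px), nrow(spots))
  for (n in seq_len(nrow(spots)))
    P[, n] <- exp(1i * .spot_phase_vec(px, py, spots$x_um[n], spots$y_um[n],
                                       spots$z_um[n], grid$config))
  P
}

#' Per-spot complex amplitudes of a hologram
#'
#' The normalized field that a phase-only hologram delivers to each target
#' spot: the pupil average
#' \deqn{c_n = \frac{1}{|D|} \sum_{m \in D} e^{i(\phi_{cgh,m} - \phi_{n,m})}}
#' over the active pixels (or a pixel subset \eqn{D}). The modulus is bounded
#' by 1, with equality exactly when the hologram matches the spot phase up to
#' a constant. `spot_intensities()` returns \eqn{I_n = |c_n|^2}, the
#' normalized spot intensity on the scale where a perfect single-spot
#' hologram scores 1.
#'
#' @param phase A fitted [cgh()] object, or a phase matrix / vector in
#'   radians (then `config` is required).
#' @param spots A [spot_set()] (or coercible data frame).
#' @param config An [optical_config()]; ignored when `phase` is a `cgh` fit.
#' @param subset Optional integer subset of active-pixel indices (as from
#'   [sample_pupil_subset()]); `NULL` means the full pupil.
#' @return A complex (`spot_amplitudes`) or numeric (`spot_intensities`)
#'   vector with one entry per spot.
#' @examples
#' cfg <- benchmark_config(32)
#' fit <- cgh(spot_set(10, -5, 0), cfg, method = "rs", seed = 1)
#' spot_intensities(fit, spot_set(10, -5, 0))
#' @export
spot_amplitudes <- function(phase, spots, config = NULL, subset = NULL) {
  if (inherits(phase, "cgh")) {
    config <- phase$config
    phase <- phase$phase
  }
  if (is.null(config)) stop("'config' is required for a raw phase map", call. = FALSE)
  grid <- pupil_grid(config)
  ph <- as.vector(phase)[grid$active]
  if (length(ph) != grid$M || anyNA(ph))
    stop("phase map does not cover the active pupil", call. = FALSE)
  spots <- as_spot_set(spots)
  px <- grid$x[grid$active]
  py <- grid$y[grid$active]
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("pixel subset is empty", call. = FALSE)
    if (any(subset < 1 | subset > grid$M))
      stop("pixel subset indices out of range", call. = FALSE)
    ph <- ph[subset]
    px <- px[subset]
    py <- py[subset]
  }
  u <- exp(1i * ph)
  vapply(seq_len(nrow(spots)), function(n) {
    phi_n <- .spot_phase_vec(px, py, spots$x_um[n], spots$y_um[n],
                             spots$z_um[n], grid$config)
    mean(u * exp(-1i * phi_n))
  }, complex(1))
}

#' @rdname spot_amplitudes
#' @export
spot_intensities <- function(phase, spots, config = NULL, subset = NULL) {
  Mod(spot_amplitudes(phase, spots, config, subset))^2
}

#' Random initial phase offsets
#'
#' The per-spot constant phases \eqn{\theta_n} are initialized uniformly on
#' \eqn{[0, 2\pi)}; all iterative algorithms start from this random draw,
#' which is why replicate runs differ.
#'
#' @param n Number of offsets.
#' @param seed Optional integer seed (global RNG state preserved).
#' @return Numeric vector of `n` phases in radians.
#' @examples
#' random_offsets(3, seed = 1)
#' @export
random_offsets <- function(n, seed = NULL) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  with_seed(seed, stats::runif(n, 0, 2 * pi))
}

#' Phase of a weighted superposition of spot fields
#'
#' The multi-spot hologram phase
#' \deqn{\phi_{cgh} = \arg \sum_n \omega_n e^{i(\phi_n + \theta_n)}}
#' evaluated pixel by pixel. Pixels where the superposed field cancels
#' exactly get phase 0 (the `Arg(0)` convention); pixels outside `subset`
#' are returned as `NA`.
#'
#' @param grid A [pupil_grid()] (or [optical_config()]).
#' @param spots A [spot_set()].
#' @param theta Per-spot phase offsets (radians), length `N`.
#' @param omega Optional positive per-spot amplitude weights (default
#'   uniform); must not all be zero.
#' @param subset Optional active-pixel subset.
#' @return An `n_rows x n_cols` phase matrix (radians), `NA` outside the
#'   subset / aperture.
#' @examples
#' g <- pupil_grid(benchmark_config(8))
#' sp <- grid_pattern(1, 2, 4)
#' ph <- superpose(g, sp, theta = c(0, 1))
#' @export
superpose <- function(grid, spots, theta, omega = NULL, subset = NULL) {
  grid <- as_pupil_grid(grid)
  spots <- as_spot_set(spots)
  N <- nrow(spots)
  if (length(theta) != N) stop("'theta' must have one entry per spot", call. = FALSE)
  if (is.null(omega)) omega <- rep(1 / N, N)
  if (length(omega) != N) stop("'omega' must have one entry per spot", call. = FALSE)
  if (all(omega == 0))
    stop("degenerate superposition: all weights are zero", call. = FALSE)
  px <- grid$x[grid$active]
  py <- grid$y[grid$active]
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("pixel subset is empty", call. = FALSE)
    px <- px[subset]
    py <- py[subset]
  }
  field <- complex(real = numeric(length(px)))
  for (n in seq_len(N)) {
    phi_n <- .spot_phase_vec(px, py, spots$x_um[n], spots$y_um[n],
                             spots$z_um[n], grid$config)
    field <- field + omega[n] * exp(1i * (phi_n + theta[n]))
  }
  out <- rep(NA_real_, grid$n_rows * grid$n_cols)
  at <- if (is.null(subset)) grid$active else grid$active[subset]
  out[at] <- Arg(field)
  matrix(out, grid$n_rows, grid$n_cols)
}
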
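# Independent brute-force oracle for the discretized forward model.
# Everything here is scalar arithmetic in plain loops, written directly from
# the defining formulas and kept independent of the package's vectorized /
# BLAS compute paths. Full rectangular aperture assumed.

oracle_phase_at <- function(cfg, xp, yp, sx, sy, sz) {
  lam <- cfg$wavelength_nm * 1e-3          # um
  f <- cfg$focal_length_mm * 1e3           # um
  pi * sz / (lam * f^2) * (xp^2 + yp^2) +
    2 * pi / (lam * f) * (sx * xp + sy * yp)
}

oracle_pixel_xy <- function(cfg, i, j) {   # 1-based row i, column j
  p <- cfg$pixel_pitch_um
  c((j - 1 - (cfg$slm_cols - 1) / 2) * p,
    (i - 1 - (cfg$slm_rows - 1) / 2) * p)
}

# per-spot complex amplitudes <exp(i(phase - phi_n))> by naive double loop
oracle_amplitudes <- function(cfg, phase, spots) {
  acc <- rep(0 + 0i, nrow(spots))
  M <- cfg$slm_rows * cfg$slm_cols
  for (i in seq_len(cfg$slm_rows)) for (j in seq_len(cfg$slm_cols)) {
    xy <- oracle_pixel_xy(cfg, i, j)
    for (n in seq_len(nrow(spots))) {
      phin <- oracle_phase_at(cfg, xy[1], xy[2],
                              spots$x_um[n], spots$y_um[n], spots$z_um[n])
      acc[n] <- acc[n] + exp(1i * (phase[i, j] - phin))
    }
  }
  acc / M
}

oracle_intensities <- function(cfg, phase, spots) {
  Mod(oracle_amplitudes(cfg, phase, spots))^2
}

# superposition phase arg(sum_n omega_n exp(i(phi_n + theta_n))), pixel loop
oracle_superpose <- function(cfg, spots, theta, omega = NULL) {
  N <- nrow(spots)
  if (is.null(omega)) omega <- rep(1 / N, N)
  out <- matrix(0, cfg$slm_rows, cfg$slm_cols)
  for (i in seq_len(cfg$slm_rows)) for (j in seq_len(cfg$slm_cols)) {
    xy <- oracle_pixel_xy(cfg, i, j)
    field <- 0 + 0i
    for (n in seq_len(N)) {
      phin <- oracle_phase_at(cfg, xy[1], xy[2],
                              spots$x_um[n], spots$y_um[n], spots$z_um[n])
      field <- field + omega[n] * exp(1i * (phin + theta[n]))
    }
    out[i, j] <- Arg(field)
  }
  out
}

# spots guaranteed inside the accessible (Nyquist) field of benchmark pupils:
# half-field = lambda * f / (2 * pitch) ~ 0.679 * n_pixels um
field_spots <- function(n, n_pixels, axial_um = 10, seed = 1) {
  random_spot_cloud(n, lateral_extent_um = 0.3 * n_pixels,
                    axial_extent_um = axial_um, seed = seed)
}

wrap_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
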
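#' Fit a multi-spot computer-generated hologram
#'
#' Computes a phase-only hologram that focuses a coherent beam into the given
#' set of target spots, using one of five synthesis algorithms:
#'
#' * `"rs"` — random superposition: a single superposition with random
#'   per-spot phase offsets \eqn{\theta_n}. Fastest, lowest quality.
#' * `"gs"` — Gerchberg-Saxton: alternating projections that refine the
#'   \eqn{\theta_n} over `iterations` passes on the full pupil. High
#'   efficiency, cost proportional to `K * N * M`.
#' * `"wgs"` — weighted GS: additionally updates per-spot amplitude weights
#'   \eqn{\omega_n} each iteration to equalize the spot intensities.
#' * `"cs-gs"` — compressive-sensing GS: the first `K - 1` iterations run on
#'   a fixed random subset of `compression * M` pupil pixels; only the final
#'   superposition is evaluated on the full pupil. Near-GS quality at close
#'   to RS cost.
#' * `"cs-wgs"` — CS-GS for `K - 1` compressed iterations followed by a
#'   single full-pupil weighted iteration, recovering most of the WGS
#'   uniformity gain.
#'
#' One iteration is a projection step (per-spot amplitudes
#' \eqn{c_n = \langle e^{i(\phi_{cgh} - \phi_n)}\rangle} over the iteration's
#' pixel domain, then \eqn{\theta_n \leftarrow \arg c_n}) followed by a
#' superposition \eqn{\phi_{cgh} = \arg\sum_n \omega_n e^{i(\phi_n+\theta_n)}};
#' iteration 1 is the random initialization, so `gs` with `iterations = 1`
#' is exactly `rs`. In the weighted update the \eqn{\omega_n} are multiplied
#' by the ratio of the mean to the per-spot modulus of \eqn{c_n} (clamped to
#' at most 10x per iteration, with the modulus floored at 1e-12), which
#' drives all spots toward equal intensity; spot `weight`s, when present,
#' set the targeted intensity ratios instead of equality.
#'
#' @param spots A [spot_set()] or data frame with columns `x_um`, `y_um`,
#'   `z_um` and optionally `weight`.
#' @param config An [optical_config()].
#' @param method Algorithm variant; see Details.
#' @param iterations Iteration count `K` (at least 1; at least 2 for
#'   `"cs-wgs"`; forced to 1 for `"rs"`).
#' @param compression Compression factor `c` in (0, 1]: fraction of pupil
#'   pixels visited by the compressed iterations. Only used by the `cs-*`
#'   variants. A warning is issued when `c * M < N` (below the
#'   compressive-sensing regime `N/M < c < 1`).
#' @param seed Optional integer seed. One seeded generator drives the run:
#'   first the `N` initial offsets \eqn{\theta_n}, then the pixel subset
#'   draw(s), in that order. The ambient RNG state is preserved.
#' @param trace If `TRUE`, record full-pupil efficiency and uniformity after
#'   every iteration (diagnostic; roughly doubles the run time and is not
#'   counted in `op_count`).
#' @param resample_subset If `TRUE`, the `cs-*` variants draw a fresh pixel
#'   subset at every compressed iteration instead of holding one fixed
#'   measurement subset per run.
#' @return An object of class `"cgh"`: a list with the phase matrix `phase`
#'   (radians, unwrapped, row 1 = top of SLM), the final `theta` and `omega`,
#'   per-spot `intensities`, scalar `efficiency` and `uniformity`, the
#'   operation count `op_count` (spot-pixel visits of superposition
#'   evaluations, matching `K*N*M` for GS/WGS, `(K-1)*N*cM + N*M` for CS-GS
#'   and `(K-1)*N*cM + 2*N*M` for CS-WGS), the realized `compression` and
#'   `subset_size`, the convergence `trace` (or `NULL`), and the inputs.
#' @seealso [summary.cgh()], [predict.cgh()], [write_phase_mask()],
#'   [evaluate_hologram()], [compression_sweep()]
#' @examples
#' cfg <- benchmark_config(64)
#' fit <- cgh(random_spot_cloud(10, 50, 20, seed = 1), cfg,
#'            method = "gs", iterations = 20, seed = 1)
#' fit
#' @export
cgh <- function(spots, config, method = c("gs", "rs", "wgs", "cs-gs", "cs-wgs"),
                iterations = 50, compression = 1 / 32, seed = NULL,
                trace = FALSE, resample_subset = FALSE) {
  method <- match.arg(method)
  spots <- as_spot_set(spots)
  stopifnot(inherits(config, "optical_config"))
  grid <- pupil_grid(config)
  N <- nrow(spots)
  M <- grid$M
  K <- as.integer(iterations)
  if (is.na(K) || K < 1L) stop("'iterations' must be at least 1", call. = FALSE)
  if (method == "rs") K <- 1L
  compressed <- method %in% c("cs-gs", "cs-wgs")
  if (method == "cs-wgs" && K < 2L)
    stop("'cs-wgs' needs at least 2 iterations (K - 1 compressed + 1 weighted)",
         call. = FALSE)
  if (compressed) {
    if (!is.numeric(compression) || length(compression) != 1L ||
        !is.finite(compression) || compression <= 0 || compression > 1)
      stop("'compression' must be a single number in (0, 1]", call. = FALSE)
    if (compression * M < N)
      warning(sprintf(paste0("compression %.4g gives only %d subset pixels for %d spots, ",
                             "below the compressive-sensing regime (N/M < c)"),
                      compression, max(1L, as.integer(round(compression * M))), N),
              call. = FALSE)
  }

  # intensity targets (uniform unless per-spot weights are given) and the
  # corresponding initial amplitude weights
  target <- if (is.null(spots$weight)) rep(1 / N, N) else spots$weight / sum(spots$weight)
  amp_target <- sqrt(target)
  omega <- amp_target / sum(amp_target)
  theta <- NULL
  subset <- NULL

  with_seed(seed, {
    theta <- stats::runif(N, 0, 2 * pi)
    if (compressed)
      subset <- sample_pupil_subset(grid, compression)
    if (compressed && resample_subset && K > 2L) {
      # pre-draw the per-iteration subsets so the RNG usage is documented
      # and independent of trace evaluation
      subset <- c(list(subset),
                  lapply(seq_len(K - 2L), function(i)
                    sample_pupil_subset(grid, compression)))
    } else if (compressed) {
      subset <- list(subset)
    }
  })

  P <- .spot_phasors(grid, spots)
  fit <- .cgh_engine(P, method, K, subset, theta, omega, amp_target, trace)

  a <- .cgh_amplitudes(P, fit$phase_vec)
  I <- Mod(a)^2
  phase <- rep(0, grid$n_rows * grid$n_cols)
  phase[grid$active] <- fit$phase_vec
  structure(list(
    phase = matrix(phase, grid$n_rows, grid$n_cols),
    config = config, spots = spots, method = method,
    iterations = K,
    compression = if (compressed) attr(subset[[1L]], "fraction") else NA_real_,
    subset_size = if (compressed) length(subset[[1L]]) else NA_integer_,
    theta = fit$theta, omega = fit$omega,
    op_count = fit$op_count,
    intensities = I,
    efficiency = sum(I),
    uniformity = if (any(I > 0)) 1 - (max(I) - min(I)) / (max(I) + min(I)) else NA_real_,
    trace = fit$trace, seed = seed, call = match.call()
  ), class = "cgh")
}

# superposition phase over the rows of phasor matrix P
.cgh_superpose <- function(P, omega, theta) {
  Arg(drop(P %*% (omega * exp(1i * theta))))
}

# per-spot amplitudes <exp(i(phase - phi_n))> over the rows of P
.cgh_amplitudes <- function(P, phase) {
  Conj(drop(exp(-1i * phase) %*% P)) / length(phase)
}

# weighted-GS weight update: multiply by the mean-to-spot ratio of the
# projection modulus |c_n| (relative to the per-spot amplitude targets),
# floored at 1e-12 and clamped to a 10x boost per iteration to keep the
# update stable when a spot intensity collapses
.cgh_update_weights <- function(omega, a, amp_target) {
  m <- pmax(Mod(a) / amp_target, 1e-12)
  omega <- omega * pmin(mean(m) / m, 10)
  omega / sum(omega)
}

.cgh_engine <- function(P, method, K, subsets, theta, omega, amp_target, trace) {
  N <- ncol(P)
  M <- nrow(P)
  op <- 0
  tr_e <- tr_u <- if (trace) numeric(K) else numeric(0)
  record <- function(k) {
    if (!trace) return()
    ph_full <- .cgh_superpose(P, omega, theta)
    I <- Mod(.cgh_amplitudes(P, ph_full))^2
    tr_e[k] <<- sum(I)
    tr_u[k] <<- 1 - (max(I) - min(I)) / (max(I) + min(I))
  }

  if (!method %in% c("cs-gs", "cs-wgs")) {
    ph <- .cgh_superpose(P, omega, theta)
    op <- op + N * M
    record(1L)
    if (K >= 2L) for (k in 2:K) {
      a <- .cgh_amplitudes(P, ph)
      theta <- Arg(a)
      if (method == "wgs") omega <- .cgh_update_weights(omega, a, amp_target)
      ph <- .cgh_superpose(P, omega, theta)
      op <- op + N * M
      record(k)
    }
  } else {
    Kc <- K - 1L                         # compressed iterations
    sub <- subsets[[1L]]
    PD <- P[sub, , drop = FALSE]
    S <- length(sub)
    if (Kc >= 1L) {
      phD <- .cgh_superpose(PD, omega, theta)
      op <- op + N * S
      record(1L)
      if (Kc >= 2L) for (k in 2:Kc) {
        a <- .cgh_amplitudes(PD, phD)
        theta <- Arg(a)
        if (length(subsets) > 1L) {      # per-iteration resampling
          sub <- subsets[[k]]
          PD <- P[sub, , drop = FALSE]
        }
        phD <- .cgh_superpose(PD, omega, theta)
        op <- op + N * S
        record(k)
      }
    }
    if (method == "cs-gs") {
      # final theta from the compressed state, then one full-pupil synthesis
      if (Kc >= 1L) theta <- Arg(.cgh_amplitudes(PD, phD))
      ph <- .cgh_superpose(P, omega, theta)
      op <- op + N * M
      record(K)
    } else {
      # cs-wgs: reconstruct the full-pupil hologram of the compressed state,
      # then perform exactly one weighted iteration on the full pupil
      ph0 <- .cgh_superpose(P, omega, theta)
      op <- op + N * M
      a <- .cgh_amplitudes(P, ph0)
      theta <- Arg(a)
      omega <- .cgh_update_weights(omega, a, amp_target)
      ph <- .cgh_superpose(P, omega, theta)
      op <- op + N * M
      record(K)
    }
  }

  list(phase_vec = ph, theta = theta, omega = omega, op_count = op,
       trace = if (trace)
         data.frame(iteration = seq_len(K), efficiency = tr_e, uniformity = tr_u)
       else NULL)
}
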
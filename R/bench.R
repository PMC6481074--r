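#' Compression sweep benchmark
#'
#' Replicates the quality-versus-compression protocol: for each compression
#' level, the chosen algorithm is run `replicates` times with different
#' random initializations (replicate `r` uses seed `seed + r`, for
#' auditability), and the mean and standard deviation of efficiency and
#' uniformity are recorded together with the cost-model operation count.
#' The default levels span 1 down to 1/256, covering the extreme
#' compression regime.
#'
#' @param spots A [spot_set()].
#' @param config An [optical_config()].
#' @param method Algorithm variant (normally `"cs-gs"` or `"cs-wgs"`;
#'   `compression = 1` reproduces the plain GS / WGS statistics).
#' @param iterations Iterations per run.
#' @param c_levels Compression factors to sweep, each in (0, 1].
#' @param replicates Seeded repeats per level (at least 2).
#' @param seed Base seed.
#' @return A data frame of class `"cgh_sweep"` with one row per level:
#'   `compression`, `inv_c`, `efficiency_mean/sd`, `uniformity_mean/sd`,
#'   `op_count`, `replicates`.
#' @examples
#' sw <- compression_sweep(random_spot_cloud(5, 20, 0, seed = 1),
#'                         benchmark_config(32), iterations = 5,
#'                         c_levels = c(1, 0.5), replicates = 2, seed = 1)
#' sw
#' @export
compression_sweep <- function(spots, config, method = c("cs-gs", "cs-wgs"),
                              iterations = 50,
                              c_levels = 1 / c(1, 2, 4, 8, 16, 32, 64, 128, 256),
                              replicates = 10, seed = 1) {
  method <- match.arg(method)
  if (replicates < 2) stop("'replicates' must be at least 2", call. = FALSE)
  if (any(c_levels <= 0 | c_levels > 1))
    stop("'c_levels' must lie in (0, 1]", call. = FALSE)
  rows <- lapply(c_levels, function(cl) {
    fits <- lapply(seq_len(replicates), function(r)
      cgh(spots, config, method = method, iterations = iterations,
          compression = cl, seed = seed + r))
    e <- vapply(fits, `[[`, numeric(1), "efficiency")
    u <- vapply(fits, `[[`, numeric(1), "uniformity")
    data.frame(compression = cl, inv_c = 1 / cl,
               efficiency_mean = mean(e), efficiency_sd = stats::sd(e),
               uniformity_mean = mean(u), uniformity_sd = stats::sd(u),
               op_count = fits[[1L]]$op_count, replicates = replicates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cgh_sweep", "data.frame")
  attr(out, "method") <- method
  attr(out, "iterations") <- iterations
  out
}

#' @export
plot.cgh_sweep <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (metric in c("efficiency", "uniformity")) {
    m <- x[[paste0(metric, "_mean")]]
    s <- x[[paste0(metric, "_sd")]]
    graphics::plot(x$inv_c, m, log = "x", type = "b", pch = 16,
                   ylim = range(c(m - s, m + s, 0, 1)),
                   xlab = "subsampling 1/c", ylab = metric, ...)
    graphics::arrows(x$inv_c, m - s, x$inv_c, m + s,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Per-iteration convergence trace
#'
#' Runs one seeded fit with tracing enabled and returns the per-iteration
#' full-pupil efficiency and uniformity. For `"cs-wgs"` the last entry
#' reflects the single weighted full-pupil iteration, which appears as an
#' abrupt uniformity jump relative to iteration `K - 1`.
#'
#' @inheritParams compression_sweep
#' @param compression Compression factor for the `cs-*` variants.
#' @return A data frame with columns `iteration`, `efficiency`,
#'   `uniformity` (one row per iteration).
#' @examples
#' convergence_curves(random_spot_cloud(5, 20, 0, seed = 1),
#'                    benchmark_config(32), method = "gs", iterations = 5,
#'                    seed = 1)
#' @export
convergence_curves <- function(spots, config,
                               method = c("gs", "rs", "wgs", "cs-gs", "cs-wgs"),
                               iterations = 50, compression = 1 / 32, seed = 1) {
  method <- match.arg(method)
  fit <- cgh(spots, config, method = method, iterations = iterations,
             compression = compression, seed = seed, trace = TRUE)
  fit$trace
}
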
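#' @export
print.cgh <- function(x, ...) {
  cat(sprintf("Multi-spot hologram (%s), %d x %d pupil, N = %d spots\n",
              x$method, x$config$slm_rows, x$config$slm_cols, nrow(x$spots)))
  cat(sprintf("  iterations: %d", x$iterations))
  if (!is.na(x$compression))
    cat(sprintf(", compression: %.4g (%d subset pixels)",
                x$compression, x$subset_size))
  cat("\n")
  cat(sprintf("  op_count: %s spot-pixel visits\n",
              format(x$op_count, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  efficiency: %.4f   uniformity: %.4f\n",
              x$efficiency, x$uniformity))
  invisible(x)
}

#' Summarize a fitted hologram
#'
#' @param object A [cgh()] fit.
#' @param ... Unused.
#' @return A `summary.cgh` object: quality metrics, the spot intensity
#'   distribution and the run parameters.
#' @export
summary.cgh <- function(object, ...) {
  I <- object$intensities
  structure(list(
    method = object$method, iterations = object$iterations,
    compression = object$compression, subset_size = object$subset_size,
    n_spots = nrow(object$spots),
    pupil = c(object$config$slm_rows, object$config$slm_cols),
    op_count = object$op_count,
    efficiency = object$efficiency, uniformity = object$uniformity,
    intensity_range = range(I), intensity_mean = mean(I),
    intensity_sd = stats::sd(I),
    seed = object$seed
  ), class = "summary.cgh")
}

#' @export
print.summary.cgh <- function(x, ...) {
  cat(sprintf("Hologram fit: %s, %d iteration(s), %d x %d pupil, %d spots\n",
              x$method, x$iterations, x$pupil[1], x$pupil[2], x$n_spots))
  if (!is.na(x$compression))
    cat(sprintf("  compression %.4g -> %d subset pixels\n",
                x$compression, x$subset_size))
  cat(sprintf("  op_count:   %s\n",
              format(x$op_count, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  efficiency: %.4f\n", x$efficiency))
  cat(sprintf("  uniformity: %.4f\n", x$uniformity))
  cat(sprintf("  spot intensity: mean %.4g, sd %.2g, range [%.4g, %.4g]\n",
              x$intensity_mean, x$intensity_sd,
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' Extract fitted algorithm parameters
#'
#' The degrees of freedom the iterative algorithms optimize: the per-spot
#' phase offsets `theta` (radians) and amplitude weights `omega`.
#'
#' @param object A [cgh()] fit.
#' @param ... Unused.
#' @return A two-column matrix with one row per spot.
#' @export
coef.cgh <- function(object, ...) {
  cbind(theta = object$theta, omega = object$omega)
}

#' @export
fitted.cgh <- function(object, ...) object$intensities

#' Predict spot intensities from a fitted hologram
#'
#' Evaluates the normalized intensity the fitted hologram delivers at
#' arbitrary probe positions (defaulting to the fitted target spots).
#'
#' @param object A [cgh()] fit.
#' @param newdata Optional [spot_set()] of probe positions.
#' @param ... Unused.
#' @return Numeric vector of intensities, one per probe spot.
#' @export
predict.cgh <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$intensities)
  spot_intensities(object, newdata)
}

#' Plot a fitted hologram
#'
#' `type = "phase"` shows the wrapped phase mask as a grey-scale image
#' (row 1 at the top, matching the exported mask orientation);
#' `type = "trace"` plots the per-iteration efficiency and uniformity
#' (requires a fit with `trace = TRUE`).
#'
#' @param x A [cgh()] fit.
#' @param type Plot kind.
#' @param ... Passed to [graphics::image()] (phase) or ignored (trace).
#' @return `x`, invisibly.
#' @export
plot.cgh <- function(x, type = c("phase", "trace"), ...) {
  type <- match.arg(type)
  if (type == "phase") {
    wrapped <- x$phase %% (2 * pi)
    nr <- nrow(wrapped)
    graphics::image(seq_len(ncol(wrapped)), seq_len(nr),
                    t(wrapped[nr:1, , drop = FALSE]),
                    col = grDevices::gray.colors(256, 0, 1),
                    asp = 1, xlab = "SLM column", ylab = "SLM row",
                    main = sprintf("%s phase mask", x$method), ...)
  } else {
    if (is.null(x$trace))
      stop("no convergence trace: refit with trace = TRUE", call. = FALSE)
    tr <- x$trace
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    graphics::plot(tr$iteration, tr$efficiency, type = "b", pch = 16,
                   xlab = "iteration", ylab = "efficiency", ylim = c(0, 1))
    graphics::plot(tr$iteration, tr$uniformity, type = "b", pch = 16,
                   xlab = "iteration", ylab = "uniformity", ylim = c(0, 1))
  }
  invisible(x)
}
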
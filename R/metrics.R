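#' Hologram quality metrics: efficiency and uniformity
#'
#' `efficiency()` is the fraction of the delivered light landing on the
#' target spots. On the normalization used throughout the package (per-spot
#' intensity = squared modulus of the pupil-averaged field, so a perfect
#' single-spot hologram scores 1 and total pupil throughput is 1) it is the
#' plain sum \eqn{e = \sum_n I_n}.
#'
#' `uniformity()` measures how evenly the light is shared among the spots:
#' \deqn{u = 1 - \frac{I_{max} - I_{min}}{I_{max} + I_{min}}}
#' which is 1 exactly when all spot intensities are equal and 0 when the
#' dimmest spot receives nothing.
#'
#' @param intensities Numeric vector of non-negative per-spot intensities
#'   (e.g. from [spot_intensities()] or a fitted [cgh()] object's
#'   `intensities`), or a `cgh` fit itself.
#' @return A single number in `[0, 1]`.
#' @examples
#' uniformity(c(0.8, 0.4))  # 2/3
#' efficiency(c(0.8, 0.4))
#' @export
efficiency <- function(intensities) {
  I <- .as_intensities(intensities)
  sum(I)
}

#' @rdname efficiency
#' @export
uniformity <- function(intensities) {
  I <- .as_intensities(intensities)
  if (all(I == 0))
    stop("uniformity is undefined when all spot intensities are zero",
         call. = FALSE)
  1 - (max(I) - min(I)) / (max(I) + min(I))
}

.as_intensities <- function(x) {
  if (inherits(x, "cgh")) x <- x$intensities
  if (!is.numeric(x) || length(x) < 1L)
    stop("expected a numeric vector of spot intensities", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("spot intensities must be finite and non-negative", call. = FALSE)
  x
}

#' Evaluate a hologram against a spot pattern
#'
#' Computes the per-spot intensities of a hologram on the full pupil and the
#' two quality metrics in one call.
#'
#' @param phase A fitted [cgh()] object or a phase matrix (then `config` is
#'   required).
#' @param spots The spot pattern to score against; defaults to the fitted
#'   spots when `phase` is a `cgh` object.
#' @param config An [optical_config()] for raw phase maps.
#' @return A list with `efficiency`, `uniformity` and the `intensities`
#'   vector.
#' @examples
#' cfg <- benchmark_config(32)
#' sp <- random_spot_cloud(3, 20, 0, seed = 1)
#' evaluate_hologram(cgh(sp, cfg, method = "rs", seed = 1))
#' @export
evaluate_hologram <- function(phase, spots = NULL, config = NULL) {
  if (is.null(spots)) {
    if (!inherits(phase, "cgh"))
      stop("'spots' is required for a raw phase map", call. = FALSE)
    spots <- phase$spots
  }
  I <- spot_intensities(phase, spots, config)
  list(efficiency = efficiency(I), uniformity = uniformity(I),
       intensities = I)
}
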
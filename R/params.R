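#' Operator parameters
#'
#' Bundles the parameters of the tone-mapping operator. A single value `p` --
#' the size, in pixels, of the largest object of interest -- drives everything:
#' the Gaussian used for the pseudo-flat-field division has standard deviation
#' `sigma = 2 * p` and the rolling-ball background subtraction uses
#' `ball_radius = p`. Both can be overridden independently.
#'
#' `division_scale` is the multiplier applied to the divided image before the
#' square root. The raw ratio image is O(1), which is far below the default
#' conversion bounds, so the default `"auto"` calibrates the scale on the
#' noise-free synthetic disk phantom so that disks of intensity 20 keep their
#' mean intensity (amplification 1); see [calibrate_scale()]. Pass a number for
#' a fixed, reproducible scale.
#'
#' @param p Size of the largest object in the image, in pixels (> 0).
#' @param sigma Standard deviation of the division Gaussian in pixels;
#'   default `2 * p`.
#' @param ball_radius Rolling-ball radius in pixels; default `p`.
#' @param division_scale Positive number, or `"auto"` to calibrate on the
#'   default disk phantom.
#' @param epsilon Guard added to the blurred denominator. `NULL` (default)
#'   resolves per plane to `1e-6 * mean(blurred)` (or 1 if that mean is 0),
#'   i.e. a scale-aware protection against division by zero.
#' @param presmooth If `TRUE` (default), the background estimate inside
#'   [devils_transform()] is the opening of a 3x3-mean-smoothed copy of the
#'   plane (subtracted from the unsmoothed plane). This is the behaviour of
#'   Fiji's Subtract Background, which the operator follows: without it the
#'   erosion latches onto downward noise spikes and the whole noise floor
#'   survives the subtraction as a constant offset.
#' @param conv_min,conv_max Intensity bounds used when converting the
#'   real-valued result to 8- or 16-bit output; defaults -100 and 10000.
#' @param out_depth Output bit depth: 8, 16 (default) or 32. At 32 bit no
#'   conversion is applied.
#'
#' @return An object of class `devils_params`.
#' @examples
#' devils_params(p = 25)
#' devils_params(p = 25, division_scale = 1500)
#' @export
devils_params <- function(p,
                          sigma = 2 * p,
                          ball_radius = p,
                          division_scale = "auto",
                          epsilon = NULL,
                          presmooth = TRUE,
                          conv_min = -100,
                          conv_max = 10000,
                          out_depth = 16) {
  assert_scalar(p, "p", positive = TRUE)
  assert_scalar(sigma, "sigma", positive = TRUE)
  assert_scalar(ball_radius, "ball_radius", positive = TRUE)
  if (is.character(division_scale)) {
    if (!identical(division_scale, "auto")) {
      stop("`division_scale` must be a positive number or \"auto\"", call. = FALSE)
    }
  } else {
    assert_scalar(division_scale, "division_scale", positive = TRUE)
  }
  if (!is.null(epsilon)) assert_scalar(epsilon, "epsilon", positive = TRUE)
  if (!is.logical(presmooth) || length(presmooth) != 1L || is.na(presmooth)) {
    stop("`presmooth` must be TRUE or FALSE", call. = FALSE)
  }
  assert_scalar(conv_min, "conv_min")
  assert_scalar(conv_max, "conv_max")
  if (conv_max <= conv_min) stop("`conv_max` must be > `conv_min`", call. = FALSE)
  if (!out_depth %in% c(8, 16, 32)) {
    stop("`out_depth` must be one of 8, 16, 32", call. = FALSE)
  }
  structure(
    list(
      p = as.numeric(p),
      sigma = as.numeric(sigma),
      ball_radius = as.numeric(ball_radius),
      division_scale = division_scale,
      epsilon = epsilon,
      presmooth = presmooth,
      conv_min = as.numeric(conv_min),
      conv_max = as.numeric(conv_max),
      out_depth = as.integer(out_depth)
    ),
    class = "devils_params"
  )
}

#' @export
print.devils_params <- function(x, ...) {
  cat("devils_params\n")
  cat(sprintf("  p:              %g px\n", x$p))
  cat(sprintf("  sigma:          %g px\n", x$sigma))
  cat(sprintf("  ball_radius:    %g px\n", x$ball_radius))
  cat(sprintf("  division_scale: %s\n",
              if (is.character(x$division_scale)) x$division_scale
              else format(x$division_scale)))
  cat(sprintf("  epsilon:        %s\n",
              if (is.null(x$epsilon)) "auto (1e-6 x mean blur)" else format(x$epsilon)))
  cat(sprintf("  presmooth:      %s\n", x$presmooth))
  cat(sprintf("  conversion:     [%g, %g] -> %d-bit\n", x$conv_min, x$conv_max, x$out_depth))
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "devils_params")) {
    stop("`params` must be created with devils_params()", call. = FALSE)
  }
  invisible(params)
}

# A numeric division scale for `params`: either the user-supplied number or
# the phantom-calibrated value for this p/sigma/ball_radius.
resolve_scale <- function(params) {
  if (is.numeric(params$division_scale)) return(params$division_scale)
  calibrate_scale(disk_grid_spec(), params)
}
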
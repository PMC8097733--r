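#' Gaussian blur of a plane
#'
#' Convolves a plane with a normalized, separable 2D Gaussian kernel. The
#' kernel support is truncated at `4 * sigma` and image borders are handled by
#' edge replication, so a constant plane is preserved exactly. Implemented as
#' two banded convolution matrices applied by matrix multiplication, which is
#' fast even for the large sigmas this operator uses (`sigma = 2 * p` can be a
#' sizeable fraction of the plane).
#'
#' @param plane Numeric matrix of finite intensities.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return A numeric matrix of the same dimensions.
#' @examples
#' m <- matrix(rnorm(64, 100, 10), 8, 8)
#' b <- gaussian_blur(m, 2)
#' @export
gaussian_blur <- function(plane, sigma) {
  assert_plane(plane)
  assert_scalar(sigma, "sigma", positive = TRUE)
  k <- gaussian_kernel_1d(sigma)
  kr <- conv_matrix(nrow(plane), k)
  kc <- conv_matrix(ncol(plane), k)
  kr %*% plane %*% t(kc)
}

# Normalized 1D Gaussian taps on integer offsets -R..R, R = floor(4 sigma)
# (support truncated at 4 sigma), R >= 1.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(floor(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# n x n matrix K with K %*% x performing 1D convolution of the length-n
# vector x with taps w under replicate (clamp-to-edge) boundary handling.
conv_matrix <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  k <- matrix(0, n, n)
  i <- seq_len(n)
  for (off in -r:r) {
    j <- pmin(pmax(i + off, 1L), n)
    idx <- cbind(i, j)
    k[idx] <- k[idx] + w[off + r + 1L]
  }
  k
}

#' Divide a plane by its own Gaussian blur
#'
#' The pseudo-flat-field step of the tone-mapping operator: the plane is
#' divided by a Gaussian-blurred copy of itself, which acts as a high-pass
#' filter and removes smooth shading. The result is multiplied by `scale`
#' (the ratio image itself is O(1)). `epsilon` guards the denominator.
#'
#' @inheritParams gaussian_blur
#' @param scale Positive multiplier applied after the division.
#' @param epsilon Positive guard added to the blurred denominator, or `NULL`
#'   for the scale-aware default `1e-6 * mean(blur)` (1 if that mean is 0).
#' @return A real-valued plane `scale * plane / (blur + epsilon)`.
#' @examples
#' m <- matrix(50, 16, 16)
#' divide_by_blur(m, sigma = 4, scale = 1)  # ~1 everywhere
#' @export
divide_by_blur <- function(plane, sigma, scale = 1, epsilon = NULL) {
  assert_plane(plane)
  assert_scalar(scale, "scale", positive = TRUE)
  if (any(plane < 0)) stop("`plane` must be nonnegative", call. = FALSE)
  g <- gaussian_blur(plane, sigma)
  if (is.null(epsilon)) {
    m <- mean(g)
    epsilon <- if (m > 0) 1e-6 * m else 1
  } else {
    assert_scalar(epsilon, "epsilon", positive = TRUE)
  }
  scale * plane / (g + epsilon)
}

#' Square-root intensity compression
#'
#' Pointwise square root, the nonlinear compression step of the operator.
#' Equivalent to gamma correction with gamma 0.5 up to the display-max
#' normalization (see [gamma_transform()]). Negative values, which can arise
#' from floating-point round-off upstream, are clamped to 0 first.
#'
#' @inheritParams gaussian_blur
#' @return A plane of square-rooted intensities.
#' @export
sqrt_transform <- function(plane) {
  assert_plane(plane)
  sqrt(pmax(plane, 0))
}

#' Gamma display transform
#'
#' Classical gamma correction: intensities are normalized by `display_max`,
#' raised to the power `gamma` and rescaled. `gamma > 1` suppresses dim
#' background; `gamma < 1` lifts faint structures (`gamma = 0.5` is the square
#' root up to normalization). Input is clamped to `[0, display_max]`.
#'
#' @inheritParams gaussian_blur
#' @param gamma Positive exponent.
#' @param display_max Positive normalization (the display maximum).
#' @return The gamma-adjusted plane, on the same intensity scale as the input.
#' @examples
#' gamma_transform(matrix(50, 2, 2), gamma = 2, display_max = 100)  # 25
#' @export
gamma_transform <- function(plane, gamma, display_max) {
  assert_plane(plane)
  assert_scalar(gamma, "gamma", positive = TRUE)
  assert_scalar(display_max, "display_max", positive = TRUE)
  x <- pmin(pmax(plane, 0), display_max)
  ((x / display_max)^gamma) * display_max
}

#' The tone-mapping operator
#'
#' Applies the full local tone-mapping chain to one plane: division by a
#' Gaussian-blurred copy of itself (sigma = `params$sigma`), multiplication by
#' the division scale, square root, and rolling-ball background subtraction
#' (radius = `params$ball_radius`). With the default `params$presmooth` the
#' background is estimated from a 3x3-mean-smoothed copy and subtracted from
#' the unsmoothed plane, the behaviour of the background subtraction in Fiji
#' that keeps noise spikes out of the estimate. The output is real-valued and
#' unconverted; apply [convert_bit_depth()] (or let [process_stack()] do it)
#' for integer output.
#'
#' A constant plane maps to the zero plane: the division yields a constant,
#' the square root a constant, and the opening of a constant is itself.
#'
#' With `division_scale = "auto"` the scale is calibrated on the default disk
#' phantom on every call, which is expensive; resolve it once with
#' [calibrate_scale()] when processing many planes ([process_stack()] does).
#'
#' @inheritParams gaussian_blur
#' @param params A [devils_params()] object.
#' @return The tone-mapped plane (real-valued, nonnegative up to round-off).
#' @examples
#' pl <- matrix(10, 32, 32)
#' pl[12:20, 12:20] <- 200
#' out <- devils_transform(pl, devils_params(p = 6, division_scale = 100))
#' @export
devils_transform <- function(plane, params) {
  assert_plane(plane)
  assert_params(params)
  if (any(plane < 0)) stop("`plane` must be nonnegative", call. = FALSE)
  s <- resolve_scale(params)
  d <- divide_by_blur(plane, params$sigma, scale = s, epsilon = params$epsilon)
  q <- sqrt_transform(d)
  bg_src <- if (isTRUE(params$presmooth)) mean3x3(q) else q
  q - rolling_ball_background(bg_src, params$ball_radius)
}

#' Display bounds from tail saturation
#'
#' Chooses display bounds (low, high) so that at most `saturated_percent / 2`
#' percent of the pixels fall below `low` and at most that many above `high`,
#' in the manner of an auto-contrast adjustment. Bounds are exact order
#' statistics of the pixel values. Degenerate planes (all values equal, or a
#' collapsed range) return `(min, min + 1)` so `low < high` always holds.
#'
#' @inheritParams gaussian_blur
#' @param saturated_percent Total percentage of pixels allowed to saturate,
#'   split equally between the two tails; in `[0, 100)`.
#' @return Numeric vector `c(low, high)` with `low < high`.
#' @examples
#' auto_contrast_range(matrix(1:100, 10, 10), 2)  # c(2, 99)
#' @export
auto_contrast_range <- function(plane, saturated_percent = 0.35) {
  assert_plane(plane)
  if (!is.numeric(saturated_percent) || length(saturated_percent) != 1L ||
      saturated_percent < 0 || saturated_percent >= 100) {
    stop("`saturated_percent` must be in [0, 100)", call. = FALSE)
  }
  v <- sort(as.vector(plane))
  n <- length(v)
  clip <- floor(n * saturated_percent / 200)
  low <- v[clip + 1L]
  high <- v[n - clip]
  if (high <= low) {
    low <- v[1L]
    high <- low + 1
  }
  c(low = low, high = high)
}

#' Linear display mapping
#'
#' Maps intensities linearly so that `low` becomes 0 and `high` becomes 1;
#' values outside the range saturate (clip) at 0 or 1.
#'
#' @inheritParams gaussian_blur
#' @param low,high Display bounds with `high > low`.
#' @return A plane of display values in `[0, 1]`.
#' @export
linear_display_map <- function(plane, low, high) {
  assert_plane(plane)
  assert_scalar(low, "low")
  assert_scalar(high, "high")
  if (high <= low) stop("`high` must be > `low`", call. = FALSE)
  pmin(pmax((plane - low) / (high - low), 0), 1)
}

#' Convert a real-valued plane to a fixed bit depth
#'
#' For 8- and 16-bit output, intensities are mapped linearly from
#' `[conv_min, conv_max]` onto the full integer range, clipped, and rounded;
#' the defaults (-100, 10000) suit the tone-mapped output. At 32 bit the
#' plane is returned unchanged (real-valued output needs no conversion).
#'
#' @inheritParams gaussian_blur
#' @param conv_min,conv_max Conversion bounds, `conv_max > conv_min`.
#' @param out_depth 8, 16 or 32.
#' @return An integer-valued plane in `[0, 2^out_depth - 1]` (8/16 bit), or
#'   the input itself (32 bit).
#' @examples
#' convert_bit_depth(matrix(c(-100, 10000), 1, 2), -100, 10000, 16)  # 0, 65535
#' @export
convert_bit_depth <- function(plane, conv_min = -100, conv_max = 10000,
                              out_depth = 16) {
  assert_plane(plane)
  assert_scalar(conv_min, "conv_min")
  assert_scalar(conv_max, "conv_max")
  if (conv_max <= conv_min) stop("`conv_max` must be > `conv_min`", call. = FALSE)
  if (!out_depth %in% c(8, 16, 32)) {
    stop("`out_depth` must be one of 8, 16, 32", call. = FALSE)
  }
  if (out_depth == 32) return(plane)
  top <- 2^out_depth - 1
  round(pmin(pmax((plane - conv_min) / (conv_max - conv_min), 0), 1) * top)
}
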
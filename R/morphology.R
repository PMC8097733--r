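#' Rolling-ball background estimate
#'
#' Estimates the smooth background of a plane as the surface traced by a ball
#' rolled under the intensity landscape: the grayscale morphological opening
#' (erosion followed by dilation) of the plane with a spherical-cap
#' structuring element. A feature narrower than the ball cannot be entered by
#' it and is excluded from the background; broad, smooth intensity is kept.
#'
#' The structuring element is the lower surface of a ball of radius `radius`,
#' with height profile `sqrt(radius^2 - d^2) - radius` over all integer
#' offsets with `d <= radius` (so the cap spans exactly the given XY radius
#' and its apex sits at height 0). This is the exact opening: no
#' shrink-and-interpolate approximation is applied, so the estimate is
#' pointwise below the plane and the operation is idempotent. At image
#' borders the element is clipped to the image.
#'
#' @inheritParams gaussian_blur
#' @param radius Ball radius in pixels (>= 1).
#' @return The background plane, pointwise `<= plane`.
#' @examples
#' pl <- matrix(10, 64, 64); pl[30:36, 30:36] <- 110
#' bg <- rolling_ball_background(pl, 25)   # ~10 everywhere
#' @export
rolling_ball_background <- function(plane, radius) {
  assert_plane(plane)
  assert_scalar(radius, "radius")
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  se <- ball_element(radius)
  .ball_dilate(.ball_erode(plane, se$dx, se$dy, se$h), se$dx, se$dy, se$h)
}

# Integer offsets and heights of the ball structuring element.
ball_element <- function(radius) {
  r <- floor(radius)
  dx <- rep(-r:r, times = 2L * r + 1L)
  dy <- rep(-r:r, each = 2L * r + 1L)
  keep <- dx^2 + dy^2 <= radius^2
  dx <- dx[keep]
  dy <- dy[keep]
  list(dx = as.integer(dx), dy = as.integer(dy),
       h = sqrt(radius^2 - dx^2 - dy^2) - radius)
}

#' Rolling-ball background subtraction
#'
#' Subtracts the [rolling_ball_background()] estimate from the plane. With the
#' exact opening used here the result is nonnegative and the background
#' estimate of an already-subtracted plane is zero (opening idempotence), so
#' applying the subtraction twice changes nothing.
#'
#' @inheritParams rolling_ball_background
#' @return `plane - rolling_ball_background(plane, radius)`.
#' @export
subtract_background <- function(plane, radius) {
  plane - rolling_ball_background(plane, radius)
}

# 3x3 mean filter with replicate borders. Used by devils_transform() when
# params$presmooth is TRUE: the background is estimated on the smoothed copy
# (erosion otherwise tracks downward noise spikes, so the noise floor would
# survive subtraction as a constant offset) but subtracted from the original.
mean3x3 <- function(plane) {
  kr <- conv_matrix(nrow(plane), rep(1 / 3, 3))
  kc <- conv_matrix(ncol(plane), rep(1 / 3, 3))
  kr %*% plane %*% t(kc)
}
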
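#' Polar pixel grid for stimulus construction
#'
#' Builds the polar coordinate frame used by all stimulus generators: for
#' every pixel, the rotation angle \code{theta} (polar angle around fixation,
#' degrees in [0, 360)) and the eccentricity \code{r} (distance from fixation
#' in degrees of visual angle). The default geometry matches an 800 x 600
#' head-mounted display with 0.035 deg/pixel.
#'
#' The rotation-angle origin is the upper vertical meridian (straight up from
#' fixation), increasing clockwise by default. Only the symmetry about the
#' vertical meridian matters for the stimuli built on top of this grid, so
#' the origin convention is configurable.
#'
#' @param width_px,height_px grid size in pixels.
#' @param deg_per_px visual degrees spanned by one pixel.
#' @param origin fixation center as c(x, y) in pixel coordinates
#'   (column, row). Defaults to the central pixel so that \code{r} is exactly
#'   0 at the origin.
#' @param clockwise logical; if \code{TRUE} (default) theta increases
#'   clockwise from the upper vertical meridian.
#' @return An object of class \code{polar_grid} with matrices \code{theta}
#'   (rotation angle, deg) and \code{r} (eccentricity, deg) of dimension
#'   \code{height_px x width_px}, plus the geometry fields.
#' @examples
#' g <- polar_grid(64, 48, 0.25)
#' range(g$theta)
#' @export
polar_grid <- function(width_px = 800L, height_px = 600L, deg_per_px = 0.035,
                       origin = c(width_px / 2, height_px / 2),
                       clockwise = TRUE) {
  stopifnot(width_px >= 1, height_px >= 1, deg_per_px > 0, length(origin) == 2)
  x <- (seq_len(width_px) - origin[1]) * deg_per_px
  y <- (origin[2] - seq_len(height_px)) * deg_per_px # screen-up positive
  dx <- matrix(x, height_px, width_px, byrow = TRUE)
  dy <- matrix(y, height_px, width_px)
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dx, dy) * 180 / pi # 0 at up, +90 at right
  if (!clockwise) theta <- -theta
  theta <- theta %% 360
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         deg_per_px = deg_per_px, origin = origin, clockwise = clockwise,
         theta = theta, r = r),
    class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid> %d x %d px, %.4f deg/px, max eccentricity %.2f deg\n",
              x$width_px, x$height_px, x$deg_per_px, max(x$r)))
  invisible(x)
}
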
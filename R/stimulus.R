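#' Radial grating stimulus parameters
#'
#' Parameter container for the radial sinusoidal gratings. The spatial
#' frequency \code{f} is in cycles per degree of *rotation* angle (polar
#' angle), not visual angle: f = 0.1 gives 36 cycles around the full 360
#' degree pattern. The annular window is a Gaussian raised to the power
#' \code{P}; \code{P = 3} gives the soft-edged crescents used for the main
#' stimuli and \code{P = 1000} the sharp-edged localizer ring.
#'
#' @param B mean luminance, normalized (0, 1].
#' @param C Michelson contrast in [0, 1].
#' @param f spatial frequency, cycles per degree of rotation angle.
#' @param r_E eccentricity of the annular window center, deg visual angle.
#' @param sigma_r radial width parameter of the window, deg.
#' @param P power applied to the Gaussian exponent (>= 1).
#' @param mask_halfwidth half-width of the vertical-meridian mask, deg of
#'   rotation angle.
#' @return list of class \code{grating_params}.
#' @export
grating_params <- function(B = 0.5, C = 0.5, f = 0.1, r_E = 8, sigma_r = 1,
                           P = 3, mask_halfwidth = 30) {
  if (!(B > 0 && B <= 1)) stop("B must be in (0, 1]")
  if (!(C >= 0 && C <= 1)) stop("C must be in [0, 1]")
  if (!(f > 0)) stop("f must be positive")
  if (!(sigma_r > 0)) stop("sigma_r must be positive")
  if (!(P >= 1)) stop("P must be >= 1")
  if (!(mask_halfwidth > 0 && mask_halfwidth < 90))
    stop("mask_halfwidth must be in (0, 90)")
  structure(list(B = B, C = C, f = f, r_E = r_E, sigma_r = sigma_r, P = P,
                 mask_halfwidth = mask_halfwidth),
            class = "grating_params")
}

new_stimulus_image <- function(values, grid, kind) {
  structure(list(values = values, grid = grid, kind = kind),
            class = "stimulus_image")
}

#' Full-field radial sinusoidal grating
#'
#' Luminance at each pixel is \code{B + B * C * cos(2 * pi * f * theta)} with
#' theta the rotation angle in degrees, so the grating forms spokes radiating
#' from fixation.
#'
#' @param grid a \code{\link{polar_grid}}.
#' @param params a \code{\link{grating_params}}.
#' @param phase phase offset in cycles (default 0).
#' @return a \code{stimulus_image} of kind \code{"full_field"}.
#' @export
radial_grating <- function(grid, params, phase = 0) {
  stopifnot(inherits(grid, "polar_grid"), inherits(params, "grating_params"))
  v <- params$B + params$B * params$C *
    cos(2 * pi * (params$f * grid$theta + phase))
  new_stimulus_image(v, grid, "full_field")
}

#' Annular Gaussian-power window
#'
#' Radial weighting \code{exp(-(((r - r_E)^2 / (2 * sigma_r^2))^P)}, maximal
#' (exactly 1) on the circle r = r_E and symmetric in (r - r_E). Larger P
#' flattens the top and sharpens the flanks; P = 1000 is effectively a
#' hard-edged annulus.
#'
#' @param grid a \code{\link{polar_grid}} (or any numeric r values).
#' @param r_E window center eccentricity, deg.
#' @param sigma_r radial width, deg (> 0).
#' @param P power (>= 1).
#' @return matrix (or vector) of weights in (0, 1].
#' @export
radial_window <- function(grid, r_E = 8, sigma_r = 1, P = 3) {
  if (!(sigma_r > 0)) stop("sigma_r must be positive")
  if (!(P >= 1)) stop("P must be >= 1")
  r <- if (inherits(grid, "polar_grid")) grid$r else grid
  exp(-(((r - r_E)^2 / (2 * sigma_r^2))^P))
}

#' Vertical-meridian mask
#'
#' Zero within \code{halfwidth_deg} of rotation angle of both the upper and
#' lower vertical meridian, one elsewhere. With the 30 deg default each
#' surviving lateral sector spans 120 deg of rotation angle, one crescent in
#' each hemifield.
#'
#' @param grid a \code{\link{polar_grid}}.
#' @param halfwidth_deg mask half-width in rotation degrees, in (0, 90).
#' @return binary matrix (0 = masked, 1 = kept).
#' @export
meridian_mask <- function(grid, halfwidth_deg = 30) {
  stopifnot(inherits(grid, "polar_grid"))
  if (!(halfwidth_deg >= 0 && halfwidth_deg < 90))
    stop("halfwidth_deg must be in [0, 90)")
  th <- grid$theta
  d_up <- pmin(th, 360 - th)        # distance to upper meridian (0 deg)
  d_down <- abs(th - 180)           # distance to lower meridian (180 deg)
  m <- matrix(1, nrow(th), ncol(th))
  m[d_up < halfwidth_deg | d_down < halfwidth_deg] <- 0
  m
}

#' Compose the experiment's stimulus set
#'
#' Builds the four stimulus images from one grating phase: the unwindowed
#' full-field grating; the center grating (grating modulation restricted to
#' the two crescents by window x mask); the scotoma grating, the pixelwise
#' complement of the center grating (modulation everywhere *except* the
#' crescents, which are at mean luminance); and the localizer, a high
#' contrast radial checkerboard confined to the crescents by the same window
#' with P = 1000 for a sharp edge.
#'
#' Complementarity holds by construction: (center - B) + (scotoma - B)
#' equals (full_field - B) at every pixel.
#'
#' @param grid a \code{\link{polar_grid}}.
#' @param params a \code{\link{grating_params}} (P applies to the main
#'   stimuli; the localizer always uses \code{localizer_P}).
#' @param localizer_P window power for the localizer edge (default 1000).
#' @param localizer_radial_freq radial frequency of the checkerboard rings,
#'   cycles per deg of visual angle.
#' @return list with elements \code{full_field}, \code{center},
#'   \code{scotoma}, \code{localizer} (each a \code{stimulus_image}) and the
#'   \code{window} and \code{mask} matrices used.
#' @export
compose_stimuli <- function(grid, params = grating_params(),
                            localizer_P = 1000, localizer_radial_freq = 1) {
  stopifnot(inherits(grid, "polar_grid"), inherits(params, "grating_params"))
  B <- params$B
  mod <- params$B * params$C * cos(2 * pi * params$f * grid$theta)
  W <- radial_window(grid, params$r_E, params$sigma_r, params$P)
  M <- meridian_mask(grid, params$mask_halfwidth)
  WM <- W * M
  full <- new_stimulus_image(B + mod, grid, "full_field")
  center <- new_stimulus_image(B + mod * WM, grid, "center")
  scotoma <- new_stimulus_image(B + mod * (1 - WM), grid, "scotoma")
  W_loc <- radial_window(grid, params$r_E, params$sigma_r, localizer_P)
  chk <- sign(cos(2 * pi * params$f * grid$theta)) *
    sign(cos(2 * pi * localizer_radial_freq * grid$r))
  localizer <- new_stimulus_image(B + B * chk * W_loc * M, grid, "localizer")
  list(full_field = full, center = center, scotoma = scotoma,
       localizer = localizer, window = W, mask = M)
}

#' Crescent geometry implied by the window and mask
#'
#' The radial width of a crescent is defined at the 1/e contour of the
#' Gaussian-power window, where the exponent equals 1: this gives
#' \code{2 * sqrt(2) * sigma_r} (about 2.8 deg for sigma_r = 1) for every
#' power P, since \code{((r - r_E)^2 / (2 sigma_r^2))^P = 1} independently of
#' P. The arc length of a lateral sector spanning \code{180 - 2 * halfwidth}
#' rotation degrees at eccentricity r_E is the corresponding circular arc in
#' visual degrees.
#'
#' @param params a \code{\link{grating_params}}.
#' @return list with \code{width_deg} (radial, at the 1/e contour),
#'   \code{sector_deg} (rotation-angle span of each crescent) and
#'   \code{arc_length_deg} (visual-angle length of each crescent at r_E).
#' @export
crescent_geometry <- function(params = grating_params()) {
  stopifnot(inherits(params, "grating_params"))
  sector <- 180 - 2 * params$mask_halfwidth
  list(width_deg = 2 * sqrt(2) * params$sigma_r,
       sector_deg = sector,
       arc_length_deg = params$r_E * sector * pi / 180)
}

#' Counterphase flicker sign sequence
#'
#' Per-frame contrast signs for counterphase flicker. "5 Hz" is interpreted
#' as five full contrast-reversal cycles per second (ten reversals), so at a
#' 60 Hz refresh the sign changes every 6 frames.
#'
#' @param duration_s stimulus duration, seconds.
#' @param flicker_hz full reversal cycles per second.
#' @param refresh_hz display refresh rate.
#' @return integer vector of +1/-1, one per frame (empty for duration 0).
#' @export
flicker_sequence <- function(duration_s, flicker_hz = 5, refresh_hz = 60) {
  stopifnot(duration_s >= 0, flicker_hz > 0, refresh_hz > 0)
  if (flicker_hz > refresh_hz / 2)
    stop("flicker_hz must not exceed refresh_hz / 2")
  n <- round(duration_s * refresh_hz)
  if (n == 0) return(integer(0))
  half_period <- refresh_hz / (2 * flicker_hz) # frames per phase
  i <- seq_len(n) - 1
  ifelse(floor(i / half_period) %% 2 == 0, 1L, -1L)
}

#' Write a stimulus image as PNG
#'
#' Luminance values are clipped to [0, 1] and written as an 8-bit grayscale
#' PNG.
#'
#' @param img a \code{stimulus_image}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  stopifnot(inherits(img, "stimulus_image"))
  v <- pmin(pmax(img$values, 0), 1)
  png::writePNG(v, path)
  invisible(path)
}

#' Write a stimulus image as a raw matrix dump plus JSON sidecar
#'
#' The matrix goes to a TSV (rows = pixel rows), the geometry and kind to a
#' JSON sidecar next to it.
#'
#' @param img a \code{stimulus_image}.
#' @param prefix path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return character vector of the two paths, invisibly.
#' @export
write_stimulus_matrix <- function(img, prefix) {
  stopifnot(inherits(img, "stimulus_image"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(img$values, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = img$kind, width_px = img$grid$width_px,
         height_px = img$grid$height_px, deg_per_px = img$grid$deg_per_px,
         origin = img$grid$origin),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
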
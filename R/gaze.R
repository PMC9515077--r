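#' Gaze record
#'
#' Timestamped horizontal/vertical eye positions in visual degrees relative
#' to fixation, with a per-sample validity flag. Invalid samples are
#' excluded from every statistic.
#'
#' @param t_s strictly increasing timestamps, s.
#' @param x_deg,y_deg gaze positions, deg (NA allowed on invalid samples).
#' @param valid logical validity flags.
#' @param rate_hz nominal sampling rate (metadata; 60 Hz in-scanner,
#'   1000 Hz lab systems share the same pipeline).
#' @return object of class \code{gaze_record}.
#' @export
gaze_record <- function(t_s, x_deg, y_deg, valid = TRUE, rate_hz = NULL) {
  n <- length(t_s)
  stopifnot(length(x_deg) == n, length(y_deg) == n)
  valid <- rep_len(as.logical(valid), n)
  if (n > 1 && is.unsorted(t_s, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  valid <- valid & !is.na(x_deg) & !is.na(y_deg)
  if (is.null(rate_hz) && n > 1) rate_hz <- 1 / stats::median(diff(t_s))
  structure(list(t_s = t_s, x_deg = x_deg, y_deg = y_deg, valid = valid,
                 rate_hz = rate_hz),
            class = "gaze_record")
}

#' @export
print.gaze_record <- function(x, ...) {
  cat(sprintf("<gaze_record> %d samples (%d valid), %.3g s at %.0f Hz\n",
              length(x$t_s), sum(x$valid), diff(range(x$t_s)), x$rate_hz))
  invisible(x)
}

#' Clean a gaze record
#'
#' Three filters, applied in order: (1) invalid/missing samples (blinks,
#' dropouts); (2) positions beyond the stimulus screen; (3) samples
#' terminating an eye movement faster than \code{vmax_deg_s} between two
#' consecutive recorded frames (large saccades). Velocity is only evaluated
#' between samples that are adjacent in the original recording and both
#' still valid: the first interval after a removed gap is not
#' velocity-tested, so gaps cannot create spurious giant velocities.
#'
#' @param g a \code{\link{gaze_record}}.
#' @param screen_bounds c(xmin, xmax, ymin, ymax) in deg; positions outside
#'   are removed. NULL skips the screen filter.
#' @param vmax_deg_s velocity threshold, deg/s.
#' @return a \code{gaze_record} with offending samples flagged invalid;
#'   errors if nothing survives.
#' @export
clean_gaze <- function(g, screen_bounds = NULL, vmax_deg_s = 30) {
  stopifnot(inherits(g, "gaze_record"), vmax_deg_s > 0)
  keep <- g$valid
  if (!is.null(screen_bounds)) {
    stopifnot(length(screen_bounds) == 4)
    keep <- keep & !is.na(g$x_deg) & !is.na(g$y_deg) &
      g$x_deg >= screen_bounds[1] & g$x_deg <= screen_bounds[2] &
      g$y_deg >= screen_bounds[3] & g$y_deg <= screen_bounds[4]
  }
  idx <- which(keep)
  if (length(idx) >= 2) {
    prev <- idx[1]
    for (i in idx[-1]) {
      if (i - prev == 1) { # consecutive recorded frames, both surviving
        dt <- g$t_s[i] - g$t_s[prev]
        v <- sqrt((g$x_deg[i] - g$x_deg[prev])^2 +
                    (g$y_deg[i] - g$y_deg[prev])^2) / dt
        if (v > vmax_deg_s) {
          keep[i] <- FALSE # sample terminating the movement is removed
          next             # prev unchanged: next interval spans a gap
        }
      }
      prev <- i
    }
  }
  if (!any(keep)) stop("no samples survive cleaning")
  g$valid <- keep
  g
}

#' Bivariate contour ellipse area of fixation
#'
#' BCEA = 2 k pi sigma_H sigma_V sqrt(1 - rho^2), where sigma_H and sigma_V
#' are the SDs of the valid horizontal and vertical positions and rho their
#' Pearson correlation; the constant k sets the probability area
#' P = 1 - exp(-k) (k = 1 covers about 63.2\% of fixations). Ellipse axes
#' and orientation come from the eigendecomposition of the sample
#' covariance; the axis-aligned area formula and the covariance ellipse
#' agree because the determinant is rotation-invariant.
#'
#' @param g a \code{\link{gaze_record}} (only valid samples are used).
#' @param k probability-area constant (> 0).
#' @return object of class \code{bcea_result}: \code{sigma_h},
#'   \code{sigma_v}, \code{rho}, \code{k}, \code{bcea} (deg^2),
#'   \code{prob_area}, \code{center}, \code{cov}, \code{axes} (semi-axis
#'   lengths), \code{orientation_deg}, \code{n}, \code{degenerate}.
#' @export
bcea <- function(g, k = 1) {
  stopifnot(inherits(g, "gaze_record"), k > 0)
  x <- g$x_deg[g$valid]; y <- g$y_deg[g$valid]
  if (length(x) < 3) stop("need at least 3 valid samples")
  sh <- stats::sd(x); sv <- stats::sd(y)
  rho <- if (sh == 0 || sv == 0) 0 else stats::cor(x, y)
  degenerate <- sh == 0 || sv == 0 || abs(rho) >= 1
  area <- if (degenerate) 0 else 2 * k * pi * sh * sv * sqrt(1 - rho^2)
  S <- stats::cov(cbind(x, y))
  eg <- eigen(S, symmetric = TRUE)
  axes <- sqrt(pmax(2 * k * eg$values, 0))
  orientation <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  structure(list(sigma_h = sh, sigma_v = sv, rho = rho, k = k, bcea = area,
                 prob_area = 1 - exp(-k), center = c(mean(x), mean(y)),
                 cov = S, axes = axes, orientation_deg = orientation,
                 n = length(x), degenerate = degenerate),
            class = "bcea_result")
}

#' @export
print.bcea_result <- function(x, ...) {
  cat(sprintf("<bcea_result> BCEA %.4f deg^2 (k = %g, %.1f%% area), n = %d\n",
              x$bcea, x$k, 100 * x$prob_area, x$n))
  invisible(x)
}

#' Does a BCEA ellipse contain a point?
#'
#' TRUE iff the point's squared Mahalanobis distance with respect to the
#' ellipse's covariance is at most 2k (the contour enclosing probability
#' 1 - exp(-k) for bivariate normal data).
#'
#' @param b a \code{\link{bcea}} result.
#' @param point c(x, y) in deg.
#' @return logical.
#' @export
ellipse_contains <- function(b, point) {
  stopifnot(inherits(b, "bcea_result"), length(point) == 2)
  if (b$degenerate) stop("degenerate ellipse")
  d <- point - b$center
  md2 <- drop(t(d) %*% solve(b$cov, d))
  md2 <= 2 * b$k
}

#' Bootstrap contrast of paired per-participant values
#'
#' The observed statistic is the mean within-participant difference a - b.
#' The null distribution is built by resampling participants with
#' replacement and randomly exchanging each sampled participant's condition
#' pair (a sign flip of the difference), i.e. exchangeability of conditions
#' within participant. Tail probabilities use add-one estimators; the
#' reported \code{p} is the smaller tail (compare to alpha = 0.025 per tail
#' for a two-tailed test at 0.05).
#'
#' @param values_a,values_b paired per-participant values.
#' @param n_iter bootstrap iterations (study-scale default 10000).
#' @param seed RNG seed.
#' @return list with \code{mean_diff}, \code{p} (smaller tail), \code{p_lower},
#'   \code{p_upper}, \code{null}, \code{n_iter}.
#' @export
bootstrap_contrast <- function(values_a, values_b, n_iter = 10000,
                               seed = NULL) {
  stopifnot(length(values_a) == length(values_b), n_iter >= 100)
  n <- length(values_a)
  if (n < 2) stop("need at least 2 participants")
  d <- values_a - values_b
  obs <- mean(d)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), n_iter, n)
    signs <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), n_iter, n)
    null <- rowMeans(matrix(d[idx], n_iter, n) * signs)
    p_up <- (1 + sum(null >= obs)) / (1 + n_iter)
    p_lo <- (1 + sum(null <= obs)) / (1 + n_iter)
    list(mean_diff = obs, p = min(p_up, p_lo), p_lower = p_lo,
         p_upper = p_up, null = null, n_iter = n_iter)
  })
}

#' Two-level one-way repeated-measures ANOVA
#'
#' One-way repeated-measures ANOVA with two condition levels and
#' participant as the repeated factor; algebraically, F(1, n-1) equals the
#' squared paired t statistic with the identical p-value.
#'
#' @param values_a,values_b paired per-participant values.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{degenerate}.
#' @export
rm_anova_2 <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  n <- length(values_a)
  if (stats::sd(values_a - values_b) == 0) {
    eq <- mean(values_a - values_b) == 0
    return(list(F = if (eq) 0 else Inf, df1 = 1, df2 = n - 1,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  dat <- data.frame(y = c(values_a, values_b),
                    cond = factor(rep(c("a", "b"), each = n)),
                    subj = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(y ~ cond + Error(subj), data = dat)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["cond", "F value"], df1 = tab["cond", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["cond", "Pr(>F)"],
       degenerate = FALSE)
}

#' Fixation density map
#'
#' 2-D histogram of the valid gaze samples, smoothed with a separable
#' Gaussian kernel and normalized so the maximum is 1 (white = 1, black = 0
#' in the usual rendering).
#'
#' @param g a \code{\link{gaze_record}}.
#' @param xlim,ylim map extent in deg.
#' @param n_bins bins per axis.
#' @param bandwidth Gaussian kernel SD, deg.
#' @return \code{n_bins x n_bins} matrix (rows = y from low to high) with
#'   attributes \code{x} and \code{y} holding the bin centers.
#' @export
density_map <- function(g, xlim = c(-2, 2), ylim = c(-2, 2), n_bins = 81,
                        bandwidth = 0.1) {
  stopifnot(inherits(g, "gaze_record"), n_bins >= 3, bandwidth > 0)
  x <- g$x_deg[g$valid]; y <- g$y_deg[g$valid]
  if (length(x) == 0) stop("no valid samples")
  xb <- seq(xlim[1], xlim[2], length.out = n_bins + 1)
  yb <- seq(ylim[1], ylim[2], length.out = n_bins + 1)
  ix <- findInterval(x, xb, rightmost.closed = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= n_bins & iy >= 1 & iy <= n_bins
  counts <- matrix(0, n_bins, n_bins)
  for (i in which(ok)) counts[iy[i], ix[i]] <- counts[iy[i], ix[i]] + 1
  bw_bins <- bandwidth / ((xlim[2] - xlim[1]) / n_bins)
  half <- max(1L, ceiling(3 * bw_bins))
  kern <- stats::dnorm(-half:half, sd = bw_bins)
  kern <- kern / sum(kern)
  smooth_1d <- function(m) { # convolve each column with kern, zero padding
    pad <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -half:half)
      out <- out + kern[o + half + 1] *
        pad[(half + 1 + o):(half + nrow(m) + o), , drop = FALSE]
    out
  }
  sm <- t(smooth_1d(t(smooth_1d(counts))))
  if (max(sm) > 0) sm <- sm / max(sm)
  attr(sm, "x") <- (xb[-1] + xb[-length(xb)]) / 2
  attr(sm, "y") <- (yb[-1] + yb[-length(yb)]) / 2
  sm
}

#' Write a density map as grayscale PNG
#'
#' @param map matrix from \code{\link{density_map}} (values in [0, 1]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_density_png <- function(map, path) {
  png::writePNG(pmin(pmax(map[rev(seq_len(nrow(map))), ], 0), 1), path)
  invisible(path)
}

#' Write a gaze record as CSV
#'
#' Columns: t, x_deg, y_deg, valid.
#'
#' @param g a \code{\link{gaze_record}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gaze_csv <- function(g, path) {
  stopifnot(inherits(g, "gaze_record"))
  utils::write.csv(data.frame(t = g$t_s, x_deg = g$x_deg, y_deg = g$y_deg,
                              valid = g$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a gaze record from CSV
#'
#' Accepts the degree dialect (columns t, x_deg, y_deg and optionally
#' valid) or a pixel dialect (t, x_px, y_px) converted through
#' \code{deg_per_px} and a pixel \code{origin}.
#'
#' @param path CSV path.
#' @param deg_per_px,origin pixel-dialect conversion: degrees per pixel and
#'   the fixation position in pixel coordinates c(x, y).
#' @param rate_hz optional nominal sampling rate.
#' @return a \code{\link{gaze_record}}.
#' @export
read_gaze_csv <- function(path, deg_per_px = NULL, origin = c(0, 0),
                          rate_hz = NULL) {
  d <- utils::read.csv(path)
  if (!"t" %in% names(d)) stop("gaze file ", path, " has no 't' column")
  if (all(c("x_deg", "y_deg") %in% names(d))) {
    x <- d$x_deg; y <- d$y_deg
  } else if (all(c("x_px", "y_px") %in% names(d))) {
    if (is.null(deg_per_px))
      stop("pixel-coordinate gaze file needs deg_per_px")
    x <- (d$x_px - origin[1]) * deg_per_px
    y <- (d$y_px - origin[2]) * deg_per_px
  } else stop("gaze file ", path, " needs x_deg/y_deg or x_px/y_px columns")
  valid <- if ("valid" %in% names(d)) {
    if (is.logical(d$valid)) d$valid else d$valid %in% c(1, "TRUE", "true")
  } else TRUE
  gaze_record(d$t, x, y, valid, rate_hz)
}
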
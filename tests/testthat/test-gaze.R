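test_that("gaze cleaning applies validity, screen and velocity rules", {
  # stationary gaze, no blinks: identity
  g <- gaze_record(0:9 / 60, rep(0.1, 10), rep(-0.2, 10), rate_hz = 60)
  expect_equal(clean_gaze(g)$valid, rep(TRUE, 10))
  # a 1-deg jump in one frame (60 deg/s) removes the terminating sample
  x <- rep(0, 10); x[5] <- 1
  g2 <- gaze_record(0:9 / 60, x, rep(0, 10))
  cg2 <- clean_gaze(g2, vmax_deg_s = 30)
  expect_false(cg2$valid[5])
  # the interval following the removed sample spans a gap: not tested,
  # so the return to fixation survives
  expect_true(cg2$valid[6])
  # off-screen samples removed
  g3 <- gaze_record(0:4 / 60, c(0, 0, 30, 0, 0), rep(0, 5))
  expect_equal(clean_gaze(g3, screen_bounds = c(-14, 14, -10, 10))$valid,
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # everything removed is an error
  g4 <- gaze_record(0:2 / 60, rep(100, 3), rep(0, 3))
  expect_error(clean_gaze(g4, screen_bounds = c(-1, 1, -1, 1)), "survive")
})

test_that("cleaning survivor count matches a brute-force oracle", {
  g <- simulate_gaze(duration_s = 60, blink_rate = 0.3, saccade_rate = 0.2,
                     seed = 91)
  sb <- c(-2, 2, -2, 2)
  got <- clean_gaze(g, screen_bounds = sb, vmax_deg_s = 30)$valid
  # oracle: sequential scan with the same rules, written independently
  n <- length(g$t_s)
  keep <- g$valid & !is.na(g$x_deg) & !is.na(g$y_deg)
  keep[keep] <- g$x_deg[keep] >= sb[1] & g$x_deg[keep] <= sb[2] &
    g$y_deg[keep] >= sb[3] & g$y_deg[keep] <= sb[4]
  prev <- NA_integer_
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (!is.na(prev) && i - prev == 1) {
      v <- sqrt(sum((c(g$x_deg[i], g$y_deg[i]) -
                       c(g$x_deg[prev], g$y_deg[prev]))^2)) /
        (g$t_s[i] - g$t_s[prev])
      if (v > 30) { keep[i] <- FALSE; next }
    }
    prev <- i
  }
  expect_equal(got, keep)
})

test_that("BCEA follows the closed form and its invariances", {
  set.seed(14)
  xy <- MASS::mvrnorm(5000, c(0.3, -0.1),
                      matrix(c(0.09, 0.02, 0.02, 0.04), 2))
  g <- gaze_record(seq_len(5000) / 60, xy[, 1], xy[, 2])
  b <- bcea(g, k = 1)
  sh <- sd(xy[, 1]); sv <- sd(xy[, 2]); rho <- cor(xy[, 1], xy[, 2])
  expect_equal(b$bcea, 2 * pi * sh * sv * sqrt(1 - rho^2), tolerance = 1e-12)
  expect_equal(b$prob_area, 1 - exp(-1))
  expect_equal(b$center, c(mean(xy[, 1]), mean(xy[, 2])))
  # k scaling and probability area
  expect_equal(bcea(g, k = 2)$bcea, 2 * b$bcea, tolerance = 1e-12)
  expect_equal(round(100 * b$prob_area, 1), 63.2)
  # axis swap invariance
  gs <- gaze_record(g$t_s, g$y_deg, g$x_deg)
  expect_equal(bcea(gs, 1)$bcea, b$bcea, tolerance = 1e-12)
  # scale: positions scaled by s -> area scaled by s^2
  g2 <- gaze_record(g$t_s, 2 * g$x_deg, 2 * g$y_deg)
  expect_equal(bcea(g2, 1)$bcea, 4 * b$bcea, tolerance = 1e-12)
  # rotation invariance holds when sigma_h = sigma_v
  set.seed(15)
  iso <- MASS::mvrnorm(4000, c(0, 0), diag(c(0.04, 0.04)))
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- iso %*% R
  gi <- gaze_record(seq_len(4000), iso[, 1], iso[, 2])
  gr <- gaze_record(seq_len(4000), rot[, 1], rot[, 2])
  expect_equal(bcea(gr, 1)$bcea, bcea(gi, 1)$bcea, tolerance = 1e-10)
  # degenerate variance
  gd <- gaze_record(1:10, rep(1, 10), rnorm(10))
  bd <- bcea(gd, 1)
  expect_equal(bd$bcea, 0)
  expect_true(bd$degenerate)
})

test_that("unit-circle example gives BCEA = 2*pi", {
  # sigma_h = sigma_v = 1, rho = 0 exactly, by construction
  n <- 400
  x <- rep(c(-1, 1), each = n / 2)
  y <- rep(c(-1, 1), times = n / 2)
  g <- gaze_record(seq_len(n), x / sd(x), y / sd(y))
  expect_equal(bcea(g, k = 1)$bcea, 2 * pi, tolerance = 1e-10)
})

test_that("ellipse containment matches Mahalanobis and a polygon oracle", {
  set.seed(16)
  xy <- MASS::mvrnorm(2000, c(0.1, 0.2),
                      matrix(c(0.05, 0.03, 0.03, 0.08), 2))
  g <- gaze_record(seq_len(2000), xy[, 1], xy[, 2])
  b <- bcea(g, k = 1)
  expect_true(ellipse_contains(b, b$center))
  expect_false(ellipse_contains(b, b$center + 10 * c(sqrt(0.05), 0)))
  # polygon oracle: rasterize the ellipse boundary from axes/orientation
  theta <- seq(0, 2 * pi, length.out = 2000)
  ang <- b$orientation_deg * pi / 180
  ex <- b$center[1] + b$axes[1] * cos(theta) * cos(ang) -
    b$axes[2] * sin(theta) * sin(ang)
  ey <- b$center[2] + b$axes[1] * cos(theta) * sin(ang) +
    b$axes[2] * sin(theta) * cos(ang)
  in_poly <- function(px, py) { # even-odd rule
    cross <- (ey > py) != (c(ey[-1], ey[1]) > py)
    xs <- ex + (py - ey) * (c(ex[-1], ex[1]) - ex) /
      (c(ey[-1], ey[1]) - ey)
    sum(cross & px < xs) %% 2 == 1
  }
  pts <- MASS::mvrnorm(200, b$center, 2 * b$cov)
  for (i in seq_len(200)) {
    md2 <- drop(t(pts[i, ] - b$center) %*%
                  solve(b$cov, pts[i, ] - b$center))
    if (abs(md2 - 2 * b$k) < 0.05) next # skip boundary-ambiguous points
    expect_equal(ellipse_contains(b, pts[i, ]),
                 in_poly(pts[i, 1], pts[i, 2]))
  }
})

test_that("bootstrap contrast is calibrated and detects separation", {
  set.seed(71)
  a <- rnorm(6, 1, 0.1)
  same <- bootstrap_contrast(a, a + rnorm(6, 0, 1e-12), n_iter = 500,
                             seed = 2)
  expect_gt(same$p, 0.2)
  # sign-flip null floors the p-value near 2^-n per tail at n = 6
  far <- bootstrap_contrast(a + 100, a, n_iter = 500, seed = 3)
  expect_lte(far$p, 0.025)
  # null rejection rate at the per-tail alpha over 500 replicates
  rej <- vapply(1:500, function(r) {
    set.seed(10000 + r)
    x <- rnorm(6); y <- rnorm(6)
    bootstrap_contrast(x, y, n_iter = 199, seed = 20000 + r)$p < 0.025
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("repeated-measures ANOVA equals the squared paired t", {
  set.seed(23)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(6)
    res <- rm_anova_2(a, b)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, unname(tt$p.value), tolerance = 1e-10)
    expect_equal(res$df1, 1)
    expect_equal(res$df2, 5) # F(1, 5) structure at n = 6
  }
  expect_equal(rm_anova_2(1:4, 1:4)$F, 0)
})

test_that("density map normalizes to 1 and centers on the data", {
  # single repeated point -> peak 1 at that bin
  g <- gaze_record(1:50, rep(0.5, 50), rep(-0.5, 50))
  m <- density_map(g, n_bins = 41)
  expect_equal(max(m), 1)
  peak <- which(m == 1, arr.ind = TRUE)
  expect_equal(attr(m, "x")[peak[1, 2]], 0.5, tolerance = 0.1)
  expect_equal(attr(m, "y")[peak[1, 1]], -0.5, tolerance = 0.1)
  # centroid matches the sample mean within a bin width
  g2 <- simulate_gaze(duration_s = 60, blink_rate = 0, saccade_rate = 0,
                      seed = 31)
  m2 <- density_map(g2, n_bins = 81)
  wx <- sum(outer(rep(1, 81), attr(m2, "x")) * m2) / sum(m2)
  wy <- sum(outer(attr(m2, "y"), rep(1, 81)) * m2) / sum(m2)
  bin_w <- diff(attr(m2, "x"))[1]
  expect_lt(abs(wx - mean(g2$x_deg)), bin_w)
  expect_lt(abs(wy - mean(g2$y_deg)), bin_w)
})

test_that("gaze CSV round-trips in both dialects", {
  g <- simulate_gaze(duration_s = 2, blink_rate = 1, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_gaze_csv(g, path)
  back <- read_gaze_csv(path, rate_hz = 60)
  expect_equal(back$t_s, g$t_s)
  expect_equal(back$x_deg, g$x_deg)
  expect_equal(back$valid, g$valid)
  # pixel dialect
  px <- data.frame(t = 0:4 / 60, x_px = c(400, 410, 420, 400, 390),
                   y_px = rep(300, 5))
  path2 <- tempfile(fileext = ".csv")
  write.csv(px, path2, row.names = FALSE)
  gp <- read_gaze_csv(path2, deg_per_px = 0.035, origin = c(400, 300))
  expect_equal(gp$x_deg, c(0, 10, 20, 0, -10) * 0.035)
  expect_equal(gp$y_deg, rep(0, 5))
})
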
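test_that("design matrix has boxcar structure and HRF lag", {
  ev <- data.frame(onset_s = 0, duration_s = 10, condition = "Center")
  d <- design_spec(2, 24, ev)
  dm <- build_design(d)
  expect_equal(colnames(dm$X), c("Center", "baseline"))
  expect_equal(dm$X[, "baseline"], rep(1, 24))
  # regressor peak lags boxcar onset by roughly the HRF peak + half duration
  peak_t <- (which.max(dm$X[, "Center"]) - 1) * 2
  expect_gte(peak_t, 8)
  expect_lte(peak_t, 14)
  expect_equal(max(dm$X[, "Center"]), 1, tolerance = 0.05)
  # intercept-only design for an empty event table
  d0 <- design_spec(2, 10, data.frame(onset_s = numeric(0),
                                      duration_s = numeric(0),
                                      condition = character(0)))
  expect_equal(colnames(build_design(d0)$X), "baseline")
  # unlabeled scotoma trials are rejected
  ev_bad <- data.frame(onset_s = 0, duration_s = 10, condition = "Scotoma")
  expect_error(build_design(design_spec(2, 24, ev_bad)), "unlabeled")
})

test_that("OLS fit equals the normal-equations oracle on small instances", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(10:20, 1)
    k <- sample(2:3, 1)
    X <- cbind(matrix(rnorm(n * (k - 1)), n, k - 1), 1)
    colnames(X) <- c(paste0("c", seq_len(k - 1)), "baseline")
    Ymat <- matrix(rnorm(n * 4), n, 4)
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     condition = character(0))
    d <- design_spec(1, n, ev)
    dm <- structure(list(X = X[, seq_len(k - 1), drop = FALSE],
                         tr_s = 1, conditions = colnames(X)[seq_len(k - 1)],
                         design = d), class = "design_matrix")
    dm$X <- X[, seq_len(k - 1), drop = FALSE]
    # feed through fit_glm via a one-run container
    Y <- roi_timeseries(list(Ymat), list(d),
                        data.frame(run = integer(0), trial = integer(0),
                                   onset_s = numeric(0),
                                   condition = character(0),
                                   label = character(0)))
    fit <- fit_glm(Y, dm)
    # independent oracle: solve the normal equations directly
    Xfull <- cbind(X[, seq_len(k - 1), drop = FALSE], run1 = 1)
    beta_oracle <- solve(t(Xfull) %*% Xfull, t(Xfull) %*% Ymat)
    expect_equal(unname(fit$beta), unname(beta_oracle), tolerance = 1e-10)
    res <- Ymat - Xfull %*% beta_oracle
    expect_equal(fit$sigma2, colSums(res^2) / (n - k), tolerance = 1e-10)
    expect_equal(fit$df, n - k)
  }
})

test_that("contrast t agrees with a reference least-squares fit on a toy", {
  # 6-point toy regression, cross-checked against stats::lm
  x <- c(0, 1, 2, 3, 4, 5)
  yv <- c(1.1, 1.9, 3.2, 3.9, 5.1, 5.8)
  d <- design_spec(1, 6, data.frame(onset_s = numeric(0),
                                    duration_s = numeric(0),
                                    condition = character(0)))
  dm <- structure(list(X = matrix(x, 6, 1, dimnames = list(NULL, "slope")),
                       tr_s = 1, conditions = "slope", design = d),
                  class = "design_matrix")
  Y <- roi_timeseries(list(matrix(yv, 6, 1)), list(d),
                      data.frame(run = integer(0), trial = integer(0),
                                 onset_s = numeric(0),
                                 condition = character(0),
                                 label = character(0)))
  fit <- fit_glm(Y, dm)
  t_pkg <- contrast_t(fit, c(slope = 1))
  ref <- summary(stats::lm(yv ~ x))$coefficients
  expect_equal(unname(t_pkg[1]), ref["x", "t value"], tolerance = 1e-10)
  expect_equal(unname(fit$beta["slope", 1]), ref["x", "Estimate"],
               tolerance = 1e-10)
  # invariance to positive scaling of the contrast
  expect_equal(unname(contrast_t(fit, c(slope = 2.5))[1]),
               unname(t_pkg[1]), tolerance = 1e-12)
  # zero contrast -> t = 0
  expect_equal(unname(contrast_t(fit, c(slope = 0))[1]), 0)
})

test_that("fit matching a design column gives beta 1 and zero variance", {
  ev <- data.frame(onset_s = c(0, 24), duration_s = 10,
                   condition = c("Center", "FullField"))
  d <- design_spec(2, 24, ev)
  dm <- build_design(d)
  Ymat <- matrix(dm$X[, "Center"], 24, 1)
  Y <- roi_timeseries(list(Ymat), list(d),
                      data.frame(run = 1L, trial = 1:2, onset_s = c(0, 24),
                                 condition = c("Center", "FullField"),
                                 label = NA_character_))
  fit <- fit_glm(Y, dm)
  expect_equal(unname(fit$beta["Center", 1]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$beta["FullField", 1]), 0, tolerance = 1e-10)
  expect_lt(fit$sigma2[1], 1e-20)
  # exactly zero residual variance with nonzero numerator is flagged
  fit0 <- structure(list(beta = matrix(2, 1, 1,
                                       dimnames = list("Center", NULL)),
                         sigma2 = 0, df = 10, XtXinv = matrix(1),
                         cols = "Center", cond_cols = "Center",
                         run_cols = character(0), n_rows = 11),
                    class = "glm_fit")
  t0 <- contrast_t(fit0, c(Center = 1))
  expect_true(is.infinite(t0[1]) && t0[1] > 0)
  expect_true(attr(t0, "degenerate")[1])
})

test_that("rank-deficient designs raise an error naming the columns", {
  ev <- data.frame(onset_s = 0, duration_s = 10, condition = "Center")
  d <- design_spec(2, 24, ev)
  dm <- build_design(d)
  dm$X <- cbind(dm$X[, "Center", drop = FALSE],
                Dup = dm$X[, "Center"], baseline = 1)
  dm$conditions <- c("Center", "Dup")
  Y <- roi_timeseries(list(matrix(rnorm(24), 24, 1)), list(d),
                      data.frame(run = 1L, trial = 1L, onset_s = 0,
                                 condition = "Center",
                                 label = NA_character_))
  expect_error(fit_glm(Y, dm), "collinear")
})

test_that("normalized betas divide by baseline and are scale invariant", {
  Y <- test_bold(n_runs = 2, n_voxels = 5, seed = 60)
  fit <- fit_glm(Y)
  nb <- normalize_beta(fit)
  v <- 3
  expect_equal(nb$normalized["Center", v],
               fit$beta["Center", v] / mean(fit$beta[c("run1", "run2"), v]))
  # scaling the data leaves normalized amplitudes unchanged
  Yk <- Y
  Yk$data <- lapply(Yk$data, function(m) 3.7 * m)
  nbk <- normalize_beta(fit_glm(Yk))
  expect_equal(nbk$normalized, nb$normalized, tolerance = 1e-10)
  # simulated amp/baseline ratio recovered
  expect_equal(unname(nb$roi_mean["Center"]), 1.5 / 100, tolerance = 0.3)
})

test_that("group test matches t.test and the d = t/sqrt(n) identity", {
  set.seed(5)
  for (rep in 1:10) {
    v <- rnorm(12, mean = runif(1, -1, 1))
    gt <- group_test(v, tail = "less")
    ref <- t.test(v, alternative = "less")
    expect_equal(gt$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(gt$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(gt$d, gt$t / sqrt(12), tolerance = 1e-12)
  }
  # worked example: |d| for t = -6.13 at n = 12
  expect_equal(abs(cohens_d_from_t(-6.13, 12)), 1.77, tolerance = 0.005)
  # degenerate all-zero case
  gt0 <- group_test(rep(0, 5), tail = "less")
  expect_equal(gt0$t, 0)
  expect_equal(gt0$p, 0.5)
  expect_true(gt0$degenerate)
})

test_that("group test type-I error is nominal under the null", {
  set.seed(2026)
  rej <- mean(replicate(2000, group_test(rnorm(12), tail = "less")$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Bonferroni alphas reproduce the corrected levels", {
  expect_equal(bonferroni_alpha(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_alpha(0.05, 12), 4), 0.0042)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
})

test_that("suppression detection power exceeds 0.8 at calibrated SNR", {
  # small cohorts: 6 participants, 2 runs, 8 voxels; group one-tail test
  alpha <- bonferroni_alpha(0.05, 12)
  detected <- vapply(1:100, function(r) {
    vals <- vapply(1:6, function(p) {
      Y <- test_bold(n_runs = 2, n_voxels = 8, seed = 1000 * r + p)
      mean(contrast_t(fit_glm(Y), c(FullField = 1, Center = -1)))
    }, numeric(1))
    group_test(vals, tail = "less")$p < alpha
  }, logical(1))
  expect_gt(mean(detected), 0.8)
})
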
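test_that("run-wise normalization gives unit z-scores then [0,1] rescale", {
  Y <- test_bold(n_runs = 2, n_voxels = 4, seed = 80)
  Yz <- normalize_runwise(Y, rescale = "none")
  for (j in 1:2) {
    expect_equal(colMeans(Yz$data[[j]]), rep(0, 4), tolerance = 1e-10)
    expect_equal(apply(Yz$data[[j]], 2, sd), rep(1, 4), tolerance = 1e-10)
  }
  Yn <- normalize_runwise(Y)
  for (j in 1:2) {
    expect_equal(apply(Yn$data[[j]], 2, min), rep(0, 4))
    expect_equal(apply(Yn$data[[j]], 2, max), rep(1, 4))
  }
  # hand-computed 5-value z-score example
  v <- c(2, 4, 4, 4, 6)
  ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                   condition = character(0))
  d <- design_spec(1, 5, ev)
  Y5 <- roi_timeseries(list(matrix(v, 5, 1)), list(d),
                       data.frame(run = integer(0), trial = integer(0),
                                  onset_s = numeric(0),
                                  condition = character(0),
                                  label = character(0)))
  z <- normalize_runwise(Y5, rescale = "none")$data[[1]][, 1]
  expect_equal(z, (v - 4) / sd(v))
  # zero-variance voxel-run flagged and NA'd
  Yc <- Y
  Yc$data[[1]][, 2] <- 5
  expect_warning(Yzv <- normalize_runwise(Yc), "zero-variance")
  expect_true(all(is.na(Yzv$data[[1]][, 2])))
})

test_that("trial features average TRs 3-7 and match a slice-mean oracle", {
  Y <- test_bold(n_runs = 2, n_voxels = 5, seed = 81)
  Yn <- normalize_runwise(Y)
  f <- trial_features(Yn)
  n_scot <- sum(grepl("^Scotoma", Y$trials$condition))
  expect_equal(nrow(f$x), n_scot)
  expect_equal(ncol(f$x), 5)
  expect_setequal(levels(f$y), c("Fill", "NoFill"))
  # brute-force slice-mean oracle for one trial
  run <- 2
  tr <- Y$trials[Y$trials$run == run, ]
  i <- which(grepl("^Scotoma", tr$condition))[3]
  i0 <- tr$onset_s[i] / 2 + 1
  oracle <- colMeans(Yn$data[[run]][(i0 + 2):(i0 + 6), ])
  row <- sum(grepl("^Scotoma", Y$trials$condition[Y$trials$run < run])) + 3
  expect_equal(unname(f$x[row, ]), unname(oracle))
  # feature equals c when the averaged TRs are constant at c
  Yc <- Y
  for (j in seq_along(Yc$data)) Yc$data[[j]][] <- 0.4
  fc <- trial_features(Yc)
  expect_true(all(fc$x == 0.4))
})

test_that("feature construction is invariant to per-voxel-run affine maps", {
  Y <- test_bold(n_runs = 2, n_voxels = 4, seed = 82)
  Ya <- Y
  for (j in seq_along(Ya$data)) {
    a <- runif(4, 0.5, 3); b <- rnorm(4)
    Ya$data[[j]] <- sweep(sweep(Ya$data[[j]], 2, a, "*"), 2, b, "+")
  }
  f1 <- trial_features(normalize_runwise(Y))
  f2 <- trial_features(normalize_runwise(Ya))
  expect_equal(f1$x, f2$x, tolerance = 1e-10)
})

test_that("leave-one-run-out CV separates separable classes and honors folds", {
  set.seed(12)
  f <- chance_features(n_runs = 8, trials_per_run = 10, n_voxels = 10)
  f$x <- f$x + ifelse(f$y == "Fill", 10, -10) # 10-SD separation
  cv <- loro_cv(f)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(nrow(cv$folds), 8)
  expect_equal(cv$folds$n_train, rep(70L, 8))
  expect_equal(cv$folds$n_test, rep(10L, 8))
  # single-class training split is skipped with a warning
  f2 <- chance_features(n_runs = 2, trials_per_run = 4, n_voxels = 3)
  f2$y <- factor(c("Fill", "Fill", "Fill", "Fill",
                   "Fill", "NoFill", "NoFill", "NoFill"))
  expect_warning(cv2 <- loro_cv(f2), "single-class")
  expect_true(is.na(cv2$folds$accuracy[2]))
})

test_that("CV accuracy is at chance for label-independent features", {
  set.seed(77)
  acc <- replicate(50, loro_cv(chance_features())$mean_accuracy)
  se <- sd(acc) / sqrt(50)
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 1e-12)
})

test_that("permutation test p-values behave at the extremes", {
  set.seed(55)
  f <- chance_features(n_runs = 4, trials_per_run = 6, n_voxels = 4)
  f$x <- f$x + ifelse(f$y == "Fill", 10, -10)
  pt <- permutation_test(list(f), n_iter = 100, seed = 1)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 1 / 101, tolerance = 1e-12) # observed beats every null
  expect_length(pt$null, 100)
  expect_true(all(pt$null >= 0 & pt$null <= 1))
  # permutations preserve run-wise class counts
  fp <- scotomafmri:::permute_within_run(f)
  for (r in unique(f$run))
    expect_equal(table(fp$y[fp$run == r]), table(f$y[f$run == r]))
})

test_that("permutation null is centered at chance for balanced labels", {
  set.seed(66)
  flist <- lapply(1:4, function(i)
    chance_features(n_runs = 2, trials_per_run = 10, n_voxels = 5))
  pt <- permutation_test(flist, n_iter = 200, seed = 9)
  expect_equal(mean(pt$null), 0.5, tolerance = 0.03)
  # approximate symmetry about the center
  expect_lt(abs(mean(pt$null > 0.5) - mean(pt$null < 0.5)), 0.2)
  # determinism given the seed
  pt2 <- permutation_test(flist, n_iter = 200, seed = 9)
  expect_identical(pt$null, pt2$null)
})
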
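#' Run-wise normalization for pattern analysis
#'
#' Per voxel, per run: transform the time series to z-scores across the
#' run's time points, then min-max rescale the z-scores to [0, 1] (the
#' rescaling scope is per voxel per run by default; alternatives are
#' available for sensitivity checks). A zero-variance voxel-run is flagged
#' and its values set to NA; feature construction then drops such voxels.
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param rescale \code{"voxel_run"} (default), \code{"run"} (min-max over
#'   the whole run), or \code{"none"} (z-scores only).
#' @return a \code{roi_timeseries} with normalized values.
#' @export
normalize_runwise <- function(Y, rescale = c("voxel_run", "run", "none")) {
  stopifnot(inherits(Y, "roi_timeseries"))
  rescale <- match.arg(rescale)
  for (j in seq_along(Y$data)) {
    m <- Y$data[[j]]
    if (nrow(m) < 2) stop("run ", j, " has fewer than 2 TRs")
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    degen <- sd == 0
    if (any(degen)) {
      warning(sum(degen), " zero-variance voxel-run(s) in run ", j,
              " set to NA")
      sd[degen] <- NA_real_
    }
    z <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
    if (rescale == "voxel_run") {
      lo <- apply(z, 2, min); hi <- apply(z, 2, max)
      z <- sweep(sweep(z, 2, lo, "-"), 2, hi - lo, "/")
    } else if (rescale == "run") {
      lo <- min(z, na.rm = TRUE); hi <- max(z, na.rm = TRUE)
      z <- (z - lo) / (hi - lo)
    }
    Y$data[[j]] <- z
  }
  Y
}

#' Trial feature vectors for classification
#'
#' One feature vector per scotoma trial: the mean of TRs 3 to 7 (1-based,
#' TR 1 = onset TR, i.e. 4-12 s after onset, targeting the response peak)
#' of the normalized signal, per voxel. Voxels with any NA in the used TRs
#' (zero-variance voxel-runs) are dropped with a warning.
#'
#' @param Y a normalized \code{\link{roi_timeseries}} (see
#'   \code{\link{normalize_runwise}}).
#' @param tr_window 1-based TR indices averaged per trial.
#' @param conditions conditions to keep (default: labeled scotoma trials).
#' @return object of class \code{trial_features}: list with \code{x}
#'   (trials x voxels), \code{y} (factor of labels), \code{run},
#'   \code{trial}.
#' @export
trial_features <- function(Y, tr_window = 3:7,
                           conditions = c("ScotomaFill", "ScotomaNoFill")) {
  stopifnot(inherits(Y, "roi_timeseries"))
  feats <- list(); labs <- character(0); runs <- integer(0)
  trial_ids <- integer(0); k <- 0
  for (j in seq_along(Y$data)) {
    d <- Y$design[[j]]
    tr <- Y$trials[Y$trials$run == d$run_id, , drop = FALSE]
    keep <- tr$condition %in% conditions
    for (i in which(keep)) {
      onset_tr <- tr$onset_s[i] / d$tr_s
      if (abs(onset_tr - round(onset_tr)) > 1e-9)
        stop("trial onset not aligned to TR grid")
      idx <- round(onset_tr) + tr_window
      if (max(idx) > d$n_trs) stop("feature window exceeds run length")
      k <- k + 1
      feats[[k]] <- colMeans(Y$data[[j]][idx, , drop = FALSE])
      labs[k] <- tr$label[i]
      runs[k] <- d$run_id
      trial_ids[k] <- tr$trial[i]
    }
  }
  if (k == 0) stop("no trials match the requested conditions")
  x <- do.call(rbind, feats)
  bad <- colSums(is.na(x)) > 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with undefined normalized values dropped")
    x <- x[, !bad, drop = FALSE]
  }
  structure(list(x = x, y = factor(labs), run = runs, trial = trial_ids),
            class = "trial_features")
}

#' Leave-one-run-out linear SVM cross-validation
#'
#' One fold per run: a linear-kernel SVM (regularization cost C = 1, no
#' additional feature scaling beyond the run-wise normalization) is trained
#' on all other runs' trials and tested on the held-out run; fold accuracy
#' is the fraction of correctly predicted labels. A training split with only
#' one class is skipped with a warning and recorded as NA.
#'
#' @param features a \code{\link{trial_features}}.
#' @param cost SVM regularization parameter.
#' @param balanced if \code{TRUE}, fold accuracy is the mean of per-class
#'   accuracies instead of raw accuracy.
#' @return object of class \code{cv_result}: \code{folds} data.frame (run,
#'   n_train, n_test, accuracy) and \code{mean_accuracy} over non-skipped
#'   folds.
#' @export
loro_cv <- function(features, cost = 1, balanced = FALSE) {
  stopifnot(inherits(features, "trial_features"))
  runs <- sort(unique(features$run))
  if (length(runs) < 2) stop("need at least 2 runs for cross-validation")
  acc <- rep(NA_real_, length(runs))
  n_train <- integer(length(runs)); n_test <- integer(length(runs))
  for (i in seq_along(runs)) {
    test <- features$run == runs[i]
    ytr <- droplevels(features$y[!test])
    n_train[i] <- sum(!test); n_test[i] <- sum(test)
    if (nlevels(ytr) < 2) {
      warning("fold ", runs[i], " skipped: single-class training split")
      next
    }
    fit <- e1071::svm(features$x[!test, , drop = FALSE], ytr,
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, features$x[test, , drop = FALSE])
    truth <- features$y[test]
    acc[i] <- if (balanced) {
      mean(vapply(levels(features$y), function(l) {
        if (!any(truth == l)) return(NA_real_)
        mean(pred[truth == l] == l)
      }, numeric(1)), na.rm = TRUE)
    } else mean(pred == truth)
  }
  structure(list(folds = data.frame(run = runs, n_train = n_train,
                                    n_test = n_test, accuracy = acc),
                 mean_accuracy = mean(acc, na.rm = TRUE)),
            class = "cv_result")
}

# Permute labels within each run, preserving each run's class counts.
permute_within_run <- function(features) {
  y <- features$y
  for (r in unique(features$run)) {
    idx <- which(features$run == r)
    y[idx] <- y[idx][sample.int(length(idx))]
  }
  features$y <- y
  features
}

#' Group-level permutation test of classification accuracy
#'
#' The observed statistic is the group mean (across participants) of each
#' participant's leave-one-run-out mean accuracy. Each null iteration
#' freshly permutes trial labels within every run of every participant
#' (preserving run-wise class counts), reruns the full cross-validation,
#' and averages across participants. The p-value uses the add-one
#' estimator p = (1 + #\{null >= observed\}) / (1 + n_iter), so it is never
#' zero.
#'
#' @param features_list list with one \code{\link{trial_features}} per
#'   participant.
#' @param n_iter permutation iterations (study-scale default 5000).
#' @param seed RNG seed for the permutations.
#' @param cost SVM regularization parameter.
#' @return object of class \code{permutation_null}: \code{observed},
#'   \code{null} (length n_iter), \code{p}, \code{n_iter},
#'   \code{participant_accuracy}.
#' @export
permutation_test <- function(features_list, n_iter = 5000, seed = NULL,
                             cost = 1) {
  stopifnot(n_iter >= 100)
  stopifnot(all(vapply(features_list, inherits, logical(1),
                       "trial_features")))
  per_part <- vapply(features_list,
                     function(f) loro_cv(f, cost = cost)$mean_accuracy,
                     numeric(1))
  observed <- mean(per_part)
  with_seed(seed, {
    null <- vapply(seq_len(n_iter), function(i) {
      mean(vapply(features_list, function(f)
        loro_cv(permute_within_run(f), cost = cost)$mean_accuracy,
        numeric(1)))
    }, numeric(1))
    structure(list(observed = observed, null = null,
                   p = (1 + sum(null >= observed)) / (1 + n_iter),
                   n_iter = n_iter, participant_accuracy = per_part),
              class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> observed %.3f, null mean %.3f, p = %.4g (%d iterations)\n",
              x$observed, mean(x$null), x$p, x$n_iter))
  invisible(x)
}
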
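#' Extract per-trial ROI-mean epochs
#'
#' One epoch per trial: \code{epoch_trs} TRs of the ROI-mean signal starting
#' at the stimulus-onset TR (12 TRs for the 10 s on / 14 s off design at TR
#' 2 s: 5 on + 7 off). Onsets must lie on the TR grid; trials truncated by
#' the run end are dropped with a warning.
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param epoch_trs epoch length in TRs.
#' @return object of class \code{trial_epochs}: list with \code{values}
#'   (trials x epoch_trs matrix) and \code{trials} (data.frame run, trial,
#'   condition, label).
#' @export
epoch_trials <- function(Y, epoch_trs = 12) {
  stopifnot(inherits(Y, "roi_timeseries"), epoch_trs >= 1)
  rows <- list(); meta <- list(); k <- 0
  for (j in seq_along(Y$data)) {
    d <- Y$design[[j]]
    roi_mean <- rowMeans(Y$data[[j]])
    tr_trials <- Y$trials[Y$trials$run == d$run_id, , drop = FALSE]
    for (i in seq_len(nrow(tr_trials))) {
      onset_tr <- tr_trials$onset_s[i] / d$tr_s
      if (abs(onset_tr - round(onset_tr)) > 1e-9)
        stop("trial onset ", tr_trials$onset_s[i],
             " s is not aligned to the TR grid (TR = ", d$tr_s, " s)")
      i0 <- round(onset_tr) + 1
      if (i0 + epoch_trs - 1 > d$n_trs) {
        warning("dropping trial ", tr_trials$trial[i], " in run ", d$run_id,
                ": epoch truncated by run end")
        next
      }
      k <- k + 1
      rows[[k]] <- roi_mean[i0:(i0 + epoch_trs - 1)]
      meta[[k]] <- tr_trials[i, c("run", "trial", "condition", "label")]
    }
  }
  if (k == 0) stop("no complete epochs")
  structure(list(values = do.call(rbind, rows),
                 trials = do.call(rbind, meta)),
            class = "trial_epochs")
}

#' Percent signal change relative to the first TR
#'
#' 100 * (x_t - x_1) / x_1 for each trial epoch; the first value is always
#' 0. Trials whose first-TR value is zero are excluded with a warning.
#'
#' @param epochs a \code{\link{epoch_trials}} result.
#' @return a \code{trial_epochs} whose values are percent signal change.
#' @export
percent_change <- function(epochs) {
  stopifnot(inherits(epochs, "trial_epochs"))
  first <- epochs$values[, 1]
  bad <- first == 0
  if (any(bad)) {
    warning(sum(bad), " trial(s) with zero first-TR value excluded")
    epochs$values <- epochs$values[!bad, , drop = FALSE]
    epochs$trials <- epochs$trials[!bad, , drop = FALSE]
    first <- first[!bad]
  }
  if (nrow(epochs$values) == 0) stop("no trials left after exclusion")
  epochs$values <- 100 * sweep(sweep(epochs$values, 1, first, "-"),
                               1, first, "/")
  epochs
}

#' Time to peak of a trial epoch
#'
#' 1-based TR index of the maximum over TRs 2..end ("after stimulus onset":
#' the first, reference TR is excluded from the search). Ties resolve to the
#' earliest TR. Invariant under positive affine transforms of the epoch.
#'
#' @param epochs a \code{trial_epochs} or a numeric vector / matrix of epoch
#'   values.
#' @return integer vector of peak TR indices (one per trial).
#' @export
time_to_peak <- function(epochs) {
  v <- if (inherits(epochs, "trial_epochs")) epochs$values else epochs
  if (is.null(dim(v))) v <- matrix(v, 1)
  if (ncol(v) < 2) stop("epoch must have at least 2 TRs")
  apply(v[, -1, drop = FALSE], 1, which.max) + 1L
}

#' Paired comparison of mean time-to-peak between conditions
#'
#' Two-tailed paired t-test on per-participant mean time-to-peak values
#' (Fill vs NoFill). Zero variance of the paired differences is flagged
#' degenerate instead of producing a t statistic.
#'
#' @param fill_means,nofill_means paired per-participant means.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
compare_ttp <- function(fill_means, nofill_means) {
  stopifnot(length(fill_means) == length(nofill_means),
            length(fill_means) >= 2)
  d <- fill_means - nofill_means
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(fill_means, nofill_means, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_diff = mean(d), degenerate = FALSE)
}

#' Write per-trial epoch values and time-to-peak as TSV
#'
#' @param epochs a \code{trial_epochs}.
#' @param path output path.
#' @param roi_name ROI label column.
#' @return \code{path}, invisibly.
#' @export
write_epochs_tsv <- function(epochs, path, roi_name = "ROI") {
  stopifnot(inherits(epochs, "trial_epochs"))
  v <- epochs$values
  colnames(v) <- paste0("tr", seq_len(ncol(v)))
  out <- cbind(roi = roi_name, epochs$trials, as.data.frame(v),
               time_to_peak = time_to_peak(epochs))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n/a")
  invisible(path)
}
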
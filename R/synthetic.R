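#' Simulation parameters for synthetic ROI BOLD data
#'
#' Defaults are chosen as plausible event-related BOLD conditions on a
#' percent-signal-change scale: baseline 100, single-trial peak amplitudes
#' around 1-2, voxel noise SD 1 with mild temporal autocorrelation. The
#' full-field amplitude is the center amplitude minus \code{suppression}
#' (surround suppression lowers the response in the crescent projection
#' zones when the surround is added). Fill and NoFill scotoma trials share
#' one mean amplitude; they differ only through two fixed, orthogonal,
#' zero-sum voxel pattern vectors scaled by \code{pattern_strength}, so the
#' ROI-mean signal carries no report information while the multivoxel
#' pattern does. \code{pattern_strength} is calibrated so that
#' leave-one-run-out decoding reaches the 60-75\% accuracy range.
#'
#' @param n_voxels voxels per ROI.
#' @param amp_center peak amplitude of the Center condition, \% signal.
#' @param suppression amplitude decrement of FullField relative to Center.
#' @param amp_scotoma shared mean amplitude of Fill and NoFill trials.
#' @param amp_localizer amplitude of the localizer checkerboard blocks.
#' @param pattern_strength per-voxel SD of the zero-sum Fill/NoFill pattern
#'   vectors, \% signal.
#' @param noise_sd marginal SD of the voxel noise, \% signal.
#' @param ar1_phi lag-1 autocorrelation of the noise (|phi| < 1).
#' @param baseline constant signal level.
#' @param p_fill probability that a scotoma trial is reported filled-in.
#' @param drift linear drift amplitude over a run (0 = off).
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_voxels = 60, amp_center = 1.5, suppression = 0.3,
                       amp_scotoma = 1.2, amp_localizer = 2,
                       pattern_strength = 0.15, noise_sd = 1, ar1_phi = 0.3,
                       baseline = 100, p_fill = 0.5, drift = 0) {
  stopifnot(n_voxels >= 2, noise_sd >= 0, abs(ar1_phi) < 1,
            p_fill > 0, p_fill < 1)
  structure(list(n_voxels = as.integer(n_voxels), amp_center = amp_center,
                 suppression = suppression, amp_scotoma = amp_scotoma,
                 amp_localizer = amp_localizer,
                 pattern_strength = pattern_strength, noise_sd = noise_sd,
                 ar1_phi = ar1_phi, baseline = baseline, p_fill = p_fill,
                 drift = drift),
            class = "sim_params")
}

#' ROI time-series container
#'
#' Runs x TRs x voxels BOLD values with the run designs and trial labels
#' that downstream stages need.
#'
#' @param data list with one TRs x voxels matrix per run.
#' @param design list with one \code{\link{design_spec}} per run.
#' @param trials data.frame with columns run, trial, onset_s, condition,
#'   label (Fill/NoFill for scotoma trials, NA otherwise).
#' @param roi_name ROI label.
#' @param tr_s repetition time, s.
#' @return object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(data, design, trials, roi_name = "ROI",
                           tr_s = design[[1]]$tr_s) {
  stopifnot(is.list(data), is.list(design), length(data) == length(design))
  for (j in seq_along(data)) {
    if (nrow(data[[j]]) != design[[j]]$n_trs)
      stop("run ", j, ": data rows do not match design n_trs")
  }
  sc <- trials$condition %in% c("Scotoma", "ScotomaFill", "ScotomaNoFill")
  if (any(sc & is.na(trials$label)))
    stop("every scotoma trial must carry a Fill/NoFill label")
  structure(list(data = data, design = design, trials = trials,
                 roi_name = roi_name, tr_s = tr_s),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s: %d run(s), %d TRs/run, %d voxels, TR %g s\n",
              x$roi_name, length(x$data), nrow(x$data[[1]]),
              ncol(x$data[[1]]), x$tr_s))
  invisible(x)
}

# Mean peak amplitude for a resolved condition label.
condition_amplitude <- function(condition, params) {
  switch(condition,
         Center = params$amp_center,
         FullField = params$amp_center - params$suppression,
         ScotomaFill = params$amp_scotoma,
         ScotomaNoFill = params$amp_scotoma,
         checkerboard = params$amp_localizer,
         stop("no amplitude defined for condition '", condition, "'"))
}

# Two orthogonal zero-sum voxel patterns with unit per-voxel SD.
zero_sum_patterns <- function(n_voxels) {
  v1 <- stats::rnorm(n_voxels); v1 <- v1 - mean(v1)
  v2 <- stats::rnorm(n_voxels); v2 <- v2 - mean(v2)
  v2 <- v2 - v1 * sum(v1 * v2) / sum(v1^2)
  list(fill = v1 / stats::sd(v1), nofill = v2 / stats::sd(v2))
}

# Stationary AR(1) + white noise matrix (n x v), marginal SD = sd.
ar1_noise <- function(n, v, sd, phi, burn = 50) {
  if (sd == 0) return(matrix(0, n, v))
  innov <- matrix(stats::rnorm((n + burn) * v, sd = sd * sqrt(1 - phi^2)),
                  n + burn, v)
  x <- stats::filter(innov, phi, method = "recursive")
  matrix(x[burn + seq_len(n), ], n, v)
}

#' Simulate event-related ROI BOLD time series
#'
#' Generates the signal the analysis stages assume: for each voxel,
#' baseline + sum over conditions of (condition amplitude + zero-sum pattern
#' term for labeled scotoma trials) x HRF-convolved unit-peak boxcar, plus
#' AR(1) Gaussian noise. Unlabeled Scotoma trials are labeled
#' Fill/NoFill by independent Bernoulli(\code{p_fill}) draws. The generator
#' and \code{\link{fit_glm}} share \code{\link{build_design}}, so in the
#' noiseless limit the fitted amplitudes equal the injected ones exactly.
#'
#' @param design a \code{\link{trial_sequence}}, a single
#'   \code{\link{design_spec}}, or a list of \code{design_spec}.
#' @param params a \code{\link{sim_params}}.
#' @param seed RNG seed (labels, patterns and noise all flow from it).
#' @param roi_name ROI label for the output.
#' @param design_matrices optional list with one prebuilt
#'   \code{\link{build_design}} result per run (columns must match the
#'   labeled conditions); avoids rebuilding identical designs when several
#'   ROIs share one trial sequence.
#' @return a \code{\link{roi_timeseries}} with attribute \code{"patterns"}
#'   holding the injected Fill/NoFill pattern vectors.
#' @export
simulate_bold <- function(design, params = sim_params(), seed = NULL,
                          roi_name = "ROI", design_matrices = NULL) {
  if (inherits(design, "trial_sequence")) {
    designs <- design$designs
  } else if (inherits(design, "design_spec")) {
    designs <- list(design)
  } else designs <- design
  stopifnot(all(vapply(designs, inherits, logical(1), "design_spec")))
  with_seed(seed, {
    # resolve scotoma labels
    labeled <- lapply(designs, function(d) {
      ev <- d$events
      lab <- rep(NA_character_, nrow(ev))
      sc <- ev$condition == "Scotoma"
      if (any(sc)) {
        fill <- stats::runif(sum(sc)) < params$p_fill
        ev$condition[sc] <- ifelse(fill, "ScotomaFill", "ScotomaNoFill")
      }
      lab[ev$condition == "ScotomaFill"] <- "Fill"
      lab[ev$condition == "ScotomaNoFill"] <- "NoFill"
      list(design = design_spec(d$tr_s, d$n_trs, ev, d$run_id), label = lab)
    })
    pat <- zero_sum_patterns(params$n_voxels)
    v <- params$n_voxels
    data <- vector("list", length(labeled))
    trials <- vector("list", length(labeled))
    for (j in seq_along(labeled)) {
      d <- labeled[[j]]$design
      X <- if (!is.null(design_matrices)) design_matrices[[j]]$X else
        build_design(d)$X
      if (length(setdiff(unique(d$events$condition), colnames(X))) > 0)
        stop("design_matrices columns do not cover the labeled conditions")
      amp <- matrix(0, ncol(X), v,
                    dimnames = list(colnames(X), NULL))
      for (cond in setdiff(colnames(X), "baseline")) {
        a <- rep(condition_amplitude(cond, params), v)
        if (cond == "ScotomaFill")
          a <- a + params$pattern_strength * pat$fill
        if (cond == "ScotomaNoFill")
          a <- a + params$pattern_strength * pat$nofill
        amp[cond, ] <- a
      }
      amp["baseline", ] <- params$baseline
      sig <- X %*% amp
      if (params$drift != 0)
        sig <- sig + params$drift * seq(0, 1, length.out = nrow(sig))
      data[[j]] <- sig + ar1_noise(nrow(sig), v, params$noise_sd,
                                   params$ar1_phi)
      ev <- d$events
      trials[[j]] <- data.frame(run = d$run_id, trial = seq_len(nrow(ev)),
                                onset_s = ev$onset_s,
                                condition = ev$condition,
                                label = labeled[[j]]$label)
    }
    out <- roi_timeseries(data, lapply(labeled, `[[`, "design"),
                          do.call(rbind, trials), roi_name)
    attr(out, "patterns") <- pat
    out
  })
}

#' Simulate a fixation gaze record
#'
#' Fixation samples from a bivariate normal around the fixation point with
#' the given SDs and correlation. Temporal structure is a slow AR(1) drift
#' (\code{drift_phi} per sample) whose stationary marginal is exactly the
#' requested bivariate normal, so consecutive-sample velocities stay in the
#' physiological few-deg/s range instead of tripping the 30 deg/s saccade
#' filter; the effective number of independent samples is about
#' n (1 - phi) / (1 + phi). Samples are interleaved with blink gaps (samples
#' flagged invalid with missing positions) and occasional saccadic spikes:
#' single samples displaced by 1.5-4 deg, producing sample-to-sample
#' velocities far above the 30 deg/s cleaning threshold. Spikes are kept to
#' one sample because the velocity filter only tests intervals between
#' consecutive surviving samples; a longer excursion would partially
#' survive cleaning by hiding behind its own removed leading edge.
#'
#' @param sigma_h,sigma_v SDs of horizontal/vertical gaze position, deg.
#' @param rho correlation between horizontal and vertical position.
#' @param rate_hz sampling rate.
#' @param duration_s record duration, s.
#' @param blink_rate blinks per second (Poisson).
#' @param saccade_rate saccadic excursions per second (Poisson).
#' @param blink_dur_s blink duration, s.
#' @param drift_phi per-sample AR(1) coefficient of the fixation drift.
#' @param seed RNG seed.
#' @return a \code{\link{gaze_record}}.
#' @export
simulate_gaze <- function(sigma_h = 0.3, sigma_v = 0.3, rho = 0.1,
                          rate_hz = 60, duration_s = 10, blink_rate = 0.1,
                          saccade_rate = 0.05, blink_dur_s = 0.15,
                          drift_phi = 0.9, seed = NULL) {
  stopifnot(sigma_h > 0, sigma_v > 0, abs(rho) < 1, rate_hz > 0,
            duration_s > 0, blink_rate >= 0, saccade_rate >= 0,
            drift_phi >= 0, drift_phi < 1)
  with_seed(seed, {
    n <- round(duration_s * rate_hz)
    Sigma <- matrix(c(sigma_h^2, rho * sigma_h * sigma_v,
                      rho * sigma_h * sigma_v, sigma_v^2), 2, 2)
    innov <- MASS::mvrnorm(n, c(0, 0), Sigma) * sqrt(1 - drift_phi^2)
    x0 <- MASS::mvrnorm(1, c(0, 0), Sigma)
    x <- as.numeric(stats::filter(innov[, 1], drift_phi,
                                  method = "recursive", init = x0[1]))
    y <- as.numeric(stats::filter(innov[, 2], drift_phi,
                                  method = "recursive", init = x0[2]))
    valid <- rep(TRUE, n)
    n_blink <- stats::rpois(1, blink_rate * duration_s)
    blink_len <- max(1, round(blink_dur_s * rate_hz))
    for (b in seq_len(n_blink)) {
      at <- sample.int(n, 1)
      idx <- at:min(n, at + blink_len - 1)
      valid[idx] <- FALSE
      x[idx] <- NA_real_; y[idx] <- NA_real_
    }
    n_sacc <- stats::rpois(1, saccade_rate * duration_s)
    for (s in seq_len(n_sacc)) {
      at <- sample.int(n, 1)
      ampl <- stats::runif(1, 1.5, 4)
      ang <- stats::runif(1, 0, 2 * pi)
      x[at] <- x[at] + ampl * cos(ang)
      y[at] <- y[at] + ampl * sin(ang)
    }
    gaze_record(t_s = (seq_len(n) - 1) / rate_hz, x_deg = x, y_deg = y,
                valid = valid, rate_hz = rate_hz)
  })
}

#' Resolve filling-in reports for a trial sequence
#'
#' Draws a Bernoulli(\code{p_fill}) filling-in report for every Scotoma
#' trial and rewrites its condition to ScotomaFill / ScotomaNoFill. A
#' participant's reports are a property of the trial, so this is done once
#' per participant and shared by all of that participant's ROIs.
#'
#' @param sequence a \code{\link{main_experiment_sequence}} result.
#' @param p_fill filling-in probability per scotoma trial.
#' @param seed RNG seed.
#' @return the \code{trial_sequence} with resolved conditions and a
#'   \code{response} column (fill/nofill).
#' @export
label_filling_in <- function(sequence, p_fill = 0.5, seed = NULL) {
  stopifnot(inherits(sequence, "trial_sequence"))
  with_seed(seed, {
    tr <- sequence$trials
    sc <- tr$condition == "Scotoma"
    fill <- stats::runif(sum(sc)) < p_fill
    tr$condition[sc] <- ifelse(fill, "ScotomaFill", "ScotomaNoFill")
    tr$response[sc] <- ifelse(fill, "fill", "nofill")
    sequence$trials <- tr
    for (j in seq_along(sequence$designs)) {
      d <- sequence$designs[[j]]
      d$events$condition <- tr$condition[tr$run == d$run_id]
      sequence$designs[[j]] <- d
    }
    sequence
  })
}

#' Subset the voxels of an ROI time series
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param voxels column indices to keep.
#' @param roi_name optional new ROI name.
#' @return a \code{roi_timeseries} restricted to \code{voxels}.
#' @export
subset_voxels <- function(Y, voxels, roi_name = Y$roi_name) {
  stopifnot(inherits(Y, "roi_timeseries"), length(voxels) >= 1)
  Y$data <- lapply(Y$data, function(m) m[, voxels, drop = FALSE])
  Y$roi_name <- roi_name
  Y
}
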
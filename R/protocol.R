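#' Event-related run design
#'
#' A run design: repetition time, number of volumes, and an events table with
#' onsets (seconds), durations and condition labels. Onsets must be
#' non-negative and strictly increasing, and every event must end within the
#' run.
#'
#' @param tr_s repetition time in seconds.
#' @param n_trs number of volumes in the run.
#' @param events data.frame with columns \code{onset_s}, \code{duration_s},
#'   \code{condition} (character).
#' @param run_id integer run identifier.
#' @return object of class \code{design_spec}.
#' @export
design_spec <- function(tr_s, n_trs, events, run_id = 1L) {
  stopifnot(tr_s > 0, n_trs >= 1)
  events <- as.data.frame(events)
  req <- c("onset_s", "duration_s", "condition")
  if (!all(req %in% names(events)))
    stop("events must have columns onset_s, duration_s, condition")
  if (nrow(events) > 0) {
    if (any(events$onset_s < 0)) stop("onsets must be non-negative")
    if (is.unsorted(events$onset_s, strictly = TRUE))
      stop("onsets must be strictly increasing")
    if (any(events$onset_s + events$duration_s > n_trs * tr_s + 1e-9))
      stop("events must end within the run")
  }
  structure(list(tr_s = tr_s, n_trs = as.integer(n_trs), events = events,
                 run_id = as.integer(run_id)),
            class = "design_spec")
}

#' Retinotopic-mapping timing arithmetic
#'
#' Cycle durations and repetition counts for a combined rotating-wedge /
#' expanding-ring retinotopy run. The wedge advances \code{wedge_step_deg}
#' per TR, so one full rotation takes \code{360 / wedge_step_deg} TRs. The
#' ring expands from \code{ring_start_deg} to \code{ring_end_deg} in steps of
#' \code{ring_step_deg} per TR; the number of steps per cycle is the nearest
#' integer of range/step (the final step may be truncated at the edge of the
#' mapped field). With a 22.5 deg wedge step and 0.25-10.6 deg ring at
#' 0.86 deg/TR (TR 3 s), this gives 48 s wedge and 36 s ring cycles; a 96-TR
#' run then holds 6 wedge and 8 ring cycles.
#'
#' @param wedge_step_deg wedge rotation per TR, deg.
#' @param ring_start_deg,ring_end_deg ring eccentricity range, deg.
#' @param ring_step_deg ring expansion per TR, deg.
#' @param tr_s repetition time, s.
#' @param n_trs volumes per run.
#' @return list with \code{wedge_cycle_s}, \code{ring_cycle_s},
#'   \code{wedge_cycles}, \code{ring_cycles}, \code{run_s}.
#' @export
retinotopy_timing <- function(wedge_step_deg = 22.5, ring_start_deg = 0.25,
                              ring_end_deg = 10.6, ring_step_deg = 0.86,
                              tr_s = 3, n_trs = 96) {
  stopifnot(wedge_step_deg > 0, ring_step_deg > 0, tr_s > 0, n_trs >= 1,
            ring_end_deg > ring_start_deg)
  wedge_steps <- 360 / wedge_step_deg
  if (abs(wedge_steps - round(wedge_steps)) > 1e-9) {
    warning("360 is not a multiple of wedge_step_deg; rounding step count")
    wedge_steps <- round(wedge_steps)
  }
  ring_steps <- round((ring_end_deg - ring_start_deg) / ring_step_deg)
  run_s <- n_trs * tr_s
  wedge_cycle_s <- wedge_steps * tr_s
  ring_cycle_s <- ring_steps * tr_s
  list(wedge_cycle_s = wedge_cycle_s, ring_cycle_s = ring_cycle_s,
       wedge_cycles = run_s / wedge_cycle_s,
       ring_cycles = run_s / ring_cycle_s, run_s = run_s)
}

#' Block design for the scotoma localizer
#'
#' On/off checkerboard block design: \code{n_blocks} repetitions of
#' \code{on_trs} stimulation TRs followed by \code{off_trs} rest TRs. The
#' default (6 on, 6 off, 6 blocks, TR 3 s) gives 72 TRs per run.
#'
#' @param on_trs,off_trs TRs per on and off period.
#' @param n_blocks number of on/off repetitions.
#' @param tr_s repetition time, s.
#' @param condition label for the on blocks.
#' @param run_id run identifier.
#' @return a \code{\link{design_spec}}.
#' @export
localizer_design <- function(on_trs = 6, off_trs = 6, n_blocks = 6, tr_s = 3,
                             condition = "checkerboard", run_id = 1L) {
  stopifnot(on_trs >= 1, off_trs >= 0, n_blocks >= 1)
  block_s <- (on_trs + off_trs) * tr_s
  events <- data.frame(
    onset_s = (seq_len(n_blocks) - 1) * block_s,
    duration_s = on_trs * tr_s,
    condition = condition)
  design_spec(tr_s, (on_trs + off_trs) * n_blocks, events, run_id)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomized trial sequence for the main experiment
#'
#' Each run holds a seeded random permutation of 5 Center, 5 FullField and
#' 10 Scotoma trials; each trial is 10 s of counterphase flicker followed by
#' a 14 s blank (24 s period, 12 TRs at TR 2 s). Eight runs give 40 Center,
#' 40 FullField and 80 Scotoma trials. Scotoma trials carry a filling-in
#' response slot (\code{NA} until a report is attached).
#'
#' @param n_runs number of runs.
#' @param seed RNG seed for the permutation (one generator per participant).
#' @param n_center,n_fullfield,n_scotoma trials per condition per run.
#' @param on_s,off_s stimulus-on and blank durations, s.
#' @param tr_s repetition time, s.
#' @return object of class \code{trial_sequence}: list with \code{designs}
#'   (one \code{\link{design_spec}} per run) and \code{trials} (data.frame
#'   run, trial, onset_s, condition, response).
#' @export
main_experiment_sequence <- function(n_runs = 8, seed = NULL,
                                     n_center = 5, n_fullfield = 5,
                                     n_scotoma = 10, on_s = 10, off_s = 14,
                                     tr_s = 2) {
  stopifnot(n_runs >= 1)
  labels <- c(rep("Center", n_center), rep("FullField", n_fullfield),
              rep("Scotoma", n_scotoma))
  n_trial <- length(labels)
  period_s <- on_s + off_s
  n_trs <- n_trial * period_s / tr_s
  if (abs(n_trs - round(n_trs)) > 1e-9)
    stop("trial period must be a multiple of tr_s")
  with_seed(seed, {
    designs <- vector("list", n_runs)
    rows <- vector("list", n_runs)
    for (run in seq_len(n_runs)) {
      cond <- sample(labels)
      onsets <- (seq_len(n_trial) - 1) * period_s
      ev <- data.frame(onset_s = onsets, duration_s = on_s, condition = cond)
      designs[[run]] <- design_spec(tr_s, n_trs, ev, run)
      rows[[run]] <- data.frame(run = run, trial = seq_len(n_trial),
                                onset_s = onsets, condition = cond,
                                response = NA_character_)
    }
    structure(list(designs = designs, trials = do.call(rbind, rows),
                   tr_s = tr_s, on_s = on_s, off_s = off_s),
              class = "trial_sequence")
  })
}

#' Pre-test contrast staircase rule
#'
#' Given the number of filling-in reports out of \code{n_trials} scotoma
#' trials in a pre-test run: more than six of ten means the inducer contrast
#' increases on the next run, fewer than four means it decreases, otherwise
#' it is kept.
#'
#' @param n_fill filling-in reports in the run.
#' @param n_trials trials in the run (default 10).
#' @param upper,lower report-count bounds for increasing/decreasing.
#' @return one of \code{"increase"}, \code{"decrease"}, \code{"keep"}.
#' @export
pretest_staircase <- function(n_fill, n_trials = 10, upper = 6, lower = 4) {
  stopifnot(n_fill >= 0, n_fill <= n_trials)
  if (n_fill > upper) "increase" else if (n_fill < lower) "decrease" else "keep"
}

#' Write events as BIDS-style TSV
#'
#' Columns: onset, duration, trial_type, response, run.
#'
#' @param x a \code{trial_sequence} or a data.frame with those columns
#'   (under the \code{trial_sequence} naming: onset_s, condition, ...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(x, path) {
  if (inherits(x, "trial_sequence")) {
    tr <- x$trials
    out <- data.frame(onset = tr$onset_s, duration = x$on_s,
                      trial_type = tr$condition, response = tr$response,
                      run = tr$run)
  } else {
    out <- as.data.frame(x)
    stopifnot(all(c("onset", "duration", "trial_type", "run") %in% names(out)))
    if (is.null(out$response)) out$response <- NA_character_
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Validates that trials do not overlap within a run.
#'
#' @param path TSV path with columns onset, duration, trial_type, run and
#'   optionally response.
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type", "run")
  miss <- setdiff(req, names(ev))
  if (length(miss))
    stop("events file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (run in unique(ev$run)) {
    e <- ev[ev$run == run, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1 &&
        any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping trials in run ", run, " of ", path)
  }
  ev
}
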
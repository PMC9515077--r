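#' Study run configuration
#'
#' Every analysis constant is surfaced here with the study's value as
#' default: localizer threshold t = 5.09, Bonferroni alphas 0.05/12 =
#' 0.0042 (univariate family: 6 ROIs x 2 contrasts) and 0.05/3 = 0.017
#' (MVPA family: 3 ROIs), 5000 permutation and 10000 bootstrap iterations,
#' 30 deg/s saccade-velocity cutoff, BCEA k = 1, MVPA TR window 3-7. A run
#' is reproducible from its config alone: every random draw flows from
#' \code{seed} via named substreams.
#'
#' @param seed master seed.
#' @param n_participants cohort size (12 in the study design).
#' @param n_runs main-experiment runs per participant.
#' @param sim a \code{\link{sim_params}}.
#' @param rois univariate ROI names (hemisphere x area).
#' @param t_crit localizer activation threshold.
#' @param alpha family-wise alpha.
#' @param n_univariate_tests,n_mvpa_tests Bonferroni family sizes.
#' @param mvpa_n_iter permutation iterations.
#' @param bootstrap_n_iter bootstrap iterations.
#' @param tr_window 1-based TR window for MVPA features.
#' @param vmax_deg_s gaze velocity cutoff, deg/s.
#' @param bcea_k BCEA probability constant.
#' @param n_gaze_participants participants with eye tracking (6 in the
#'   study).
#' @param gaze_duration_s simulated gaze record length per condition, s.
#' @param gaze_sigma_h,gaze_sigma_v,gaze_rho fixation scatter parameters.
#' @param out_dir optional output directory for tables and the JSON report.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1, n_participants = 12, n_runs = 8,
                       sim = sim_params(),
                       rois = c("lV1", "rV1", "lV2", "rV2", "lV3", "rV3"),
                       t_crit = 5.09, alpha = 0.05,
                       n_univariate_tests = 12, n_mvpa_tests = 3,
                       mvpa_n_iter = 5000, bootstrap_n_iter = 10000,
                       tr_window = 3:7, vmax_deg_s = 30, bcea_k = 1,
                       n_gaze_participants = 6, gaze_duration_s = 100,
                       gaze_sigma_h = 0.3, gaze_sigma_v = 0.3,
                       gaze_rho = 0.1, out_dir = NULL) {
  structure(list(seed = seed, n_participants = n_participants,
                 n_runs = n_runs, sim = sim, rois = rois, t_crit = t_crit,
                 alpha = alpha, n_univariate_tests = n_univariate_tests,
                 n_mvpa_tests = n_mvpa_tests, mvpa_n_iter = mvpa_n_iter,
                 bootstrap_n_iter = bootstrap_n_iter,
                 tr_window = tr_window, vmax_deg_s = vmax_deg_s,
                 bcea_k = bcea_k,
                 n_gaze_participants = n_gaze_participants,
                 gaze_duration_s = gaze_duration_s,
                 gaze_sigma_h = gaze_sigma_h, gaze_sigma_v = gaze_sigma_v,
                 gaze_rho = gaze_rho, out_dir = out_dir),
            class = "run_config")
}

# Named substream seeds derived deterministically from the master seed.
derive_seeds <- function(seed, names) {
  with_seed(seed, stats::setNames(sample.int(.Machine$integer.max,
                                             length(names)), names))
}

#' Simulate one participant's session
#'
#' Trial sequence, filling-in reports (shared across ROIs), one BOLD time
#' series per univariate ROI, and one localizer time series per ROI; voxel
#' ids are namespaced by ROI so merged ROIs stay disjoint.
#'
#' @param config a \code{\link{run_config}}.
#' @param participant participant index (used to derive substream seeds).
#' @return list with \code{sequence}, \code{bold} (named list per ROI) and
#'   \code{localizer} (named list per ROI).
#' @export
simulate_participant <- function(config, participant) {
  seeds <- derive_seeds(config$seed,
                        c("seq", "label", "bold", "loc", "mvpa", "gaze",
                          "boot"))
  pseed <- function(base) (base + participant * 131071L) %% .Machine$integer.max
  sequence <- main_experiment_sequence(config$n_runs,
                                       seed = pseed(seeds["seq"]))
  sequence <- label_filling_in(sequence, config$sim$p_fill,
                               seed = pseed(seeds["label"]))
  loc_design <- localizer_design()
  bold <- list(); localizer <- list()
  for (i in seq_along(config$rois)) {
    roi <- config$rois[i]
    bold[[roi]] <- simulate_bold(sequence, config$sim,
                                 seed = pseed(seeds["bold"] + i),
                                 roi_name = roi)
    localizer[[roi]] <- simulate_bold(loc_design, config$sim,
                                      seed = pseed(seeds["loc"] + i),
                                      roi_name = roi)
  }
  list(sequence = sequence, bold = bold, localizer = localizer)
}

# ROI voxel selection for one participant: localizer threshold, then
# center-dominance pruning against the main-experiment fit.
select_roi_voxels <- function(loc_fit, main_fit, t_crit) {
  t_loc <- contrast_t(loc_fit, c(checkerboard = 1))
  active <- threshold_localizer(t_loc, t_crit)
  if (length(active) == 0) return(integer(0))
  beta_center <- main_fit$beta["Center", active]
  beta_scotoma <- colMeans(
    main_fit$beta[c("ScotomaFill", "ScotomaNoFill"), active, drop = FALSE])
  restrict_center_dominant(beta_center, beta_scotoma, active)
}

#' Run the full synthetic study
#'
#' Simulates the cohort and executes every analysis stage: voxelwise GLM
#' and the two univariate group contrasts per ROI (Full-Field minus Center,
#' one-tail; Fill minus NoFill), trial time courses and time-to-peak
#' comparisons, localizer-based ROI voxel selection, leave-one-run-out SVM
#' decoding of the filling-in report with a group permutation null per
#' merged ROI, and the BCEA fixation-stability control with bootstrap and
#' repeated-measures tests. Stages run independently: a failing stage is
#' recorded under \code{errors} and downstream stages with satisfied inputs
#' still run. Rerunning with the same config reproduces the report.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{study_report} with elements \code{config},
#'   \code{univariate}, \code{timecourse}, \code{roi_selection},
#'   \code{mvpa}, \code{gaze}, \code{behavior}, \code{errors}.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  seeds <- derive_seeds(config$seed, c("mvpa_perm", "gaze", "boot"))
  alpha_uni <- bonferroni_alpha(config$alpha, config$n_univariate_tests)
  alpha_mvpa <- bonferroni_alpha(config$alpha, config$n_mvpa_tests)

  participants <- stage("simulate", lapply(
    seq_len(config$n_participants),
    function(p) simulate_participant(config, p)))

  fits <- NULL; selections <- NULL
  if (!is.null(participants)) {
    fits <- stage("glm_fit", lapply(participants, function(part)
      lapply(part$bold, fit_glm)))
    if (!is.null(fits))
      selections <- stage("roi_selection", lapply(
        seq_along(participants), function(p) {
          lapply(stats::setNames(config$rois, config$rois), function(roi) {
            loc_fit <- fit_glm(participants[[p]]$localizer[[roi]])
            select_roi_voxels(loc_fit, fits[[p]][[roi]], config$t_crit)
          })
        }))
  }

  univariate <- stage("univariate", {
    stopifnot(!is.null(fits))
    per_roi <- lapply(stats::setNames(config$rois, config$rois),
                      function(roi) {
      ff_c <- vapply(seq_along(fits), function(p) {
        sel <- selections[[p]][[roi]]
        t <- contrast_t(fits[[p]][[roi]], c(FullField = 1, Center = -1))
        mean(if (length(sel)) t[sel] else t)
      }, numeric(1))
      fill <- vapply(seq_along(fits), function(p) {
        sel <- selections[[p]][[roi]]
        t <- contrast_t(fits[[p]][[roi]],
                        c(ScotomaFill = 1, ScotomaNoFill = -1))
        mean(if (length(sel)) t[sel] else t)
      }, numeric(1))
      conds <- fits[[1]][[roi]]$cond_cols
      norm_beta <- rowMeans(vapply(seq_along(fits), function(p)
        normalize_beta(fits[[p]][[roi]])$roi_mean[conds],
        numeric(length(conds))))
      names(norm_beta) <- conds
      list(fullfield_minus_center = c(
             group_test(ff_c, tail = "less"),
             list(roi_mean_t = ff_c, significant = NA)),
           fill_minus_nofill = c(
             group_test(fill, tail = "two.sided"),
             list(roi_mean_t = fill)),
           mean_normalized_beta = norm_beta)
    })
    for (roi in names(per_roi)) {
      per_roi[[roi]]$fullfield_minus_center$significant <-
        per_roi[[roi]]$fullfield_minus_center$p < alpha_uni
      per_roi[[roi]]$fill_minus_nofill$significant <-
        per_roi[[roi]]$fill_minus_nofill$p < alpha_uni
    }
    list(alpha = alpha_uni, rois = per_roi)
  })

  timecourse <- stage("timecourse", {
    stopifnot(!is.null(participants))
    per_roi <- lapply(stats::setNames(config$rois, config$rois),
                      function(roi) {
      curves_fill <- NULL; curves_nofill <- NULL
      ttp_fill <- numeric(0); ttp_nofill <- numeric(0)
      for (p in seq_along(participants)) {
        Y <- participants[[p]]$bold[[roi]]
        sel <- selections[[p]][[roi]]
        if (length(sel)) Y <- subset_voxels(Y, sel)
        pc <- percent_change(epoch_trials(Y))
        is_fill <- pc$trials$label == "Fill" & !is.na(pc$trials$label)
        is_nofill <- pc$trials$label == "NoFill" & !is.na(pc$trials$label)
        curves_fill <- rbind(curves_fill,
                             colMeans(pc$values[is_fill, , drop = FALSE]))
        curves_nofill <- rbind(curves_nofill,
                               colMeans(pc$values[is_nofill, , drop = FALSE]))
        ttp <- time_to_peak(pc)
        ttp_fill[p] <- mean(ttp[is_fill])
        ttp_nofill[p] <- mean(ttp[is_nofill])
      }
      list(group_curve_fill = colMeans(curves_fill),
           group_curve_nofill = colMeans(curves_nofill),
           ttp_fill_mean = mean(ttp_fill),
           ttp_nofill_mean = mean(ttp_nofill),
           ttp_test = compare_ttp(ttp_fill, ttp_nofill))
    })
    list(alpha = alpha_uni, rois = per_roi)
  })

  mvpa <- stage("mvpa", {
    stopifnot(!is.null(participants))
    areas <- unique(sub("^[lr]", "", config$rois))
    features <- lapply(seq_along(participants), function(p) {
      lapply(stats::setNames(areas, areas), function(area) {
        hemis <- config$rois[sub("^[lr]", "", config$rois) == area]
        mats <- lapply(hemis, function(roi) {
          Y <- participants[[p]]$bold[[roi]]
          sel <- selections[[p]][[roi]]
          if (length(sel)) Y <- subset_voxels(Y, sel)
          trial_features(normalize_runwise(Y), tr_window = config$tr_window)
        })
        f <- mats[[1]]
        if (length(mats) > 1)
          f$x <- do.call(cbind, lapply(mats, `[[`, "x"))
        f
      })
    })
    per_area <- lapply(stats::setNames(areas, areas), function(area) {
      pt <- permutation_test(lapply(features, `[[`, area),
                             n_iter = config$mvpa_n_iter,
                             seed = seeds["mvpa_perm"])
      list(mean_accuracy = pt$observed, p = pt$p,
           significant = pt$p < alpha_mvpa,
           participant_accuracy = pt$participant_accuracy,
           null_mean = mean(pt$null), n_iter = pt$n_iter)
    })
    list(alpha = alpha_mvpa, areas = per_area)
  })

  gaze <- stage("gaze", {
    conds <- c("Center", "FullField", "Fill", "NoFill")
    vals <- matrix(NA_real_, config$n_gaze_participants, length(conds),
                   dimnames = list(NULL, conds))
    records <- list()
    contain <- c(center_fullfield = 0, fill_nofill = 0)
    for (p in seq_len(config$n_gaze_participants)) {
      records[[p]] <- lapply(stats::setNames(conds, conds), function(cond) {
        g <- simulate_gaze(sigma_h = config$gaze_sigma_h,
                           sigma_v = config$gaze_sigma_v,
                           rho = config$gaze_rho,
                           duration_s = config$gaze_duration_s,
                           seed = (seeds["gaze"] + p * 17 +
                                     match(cond, conds)) %%
                             .Machine$integer.max)
        clean_gaze(g, screen_bounds = c(-14, 14, -10.5, 10.5),
                   vmax_deg_s = config$vmax_deg_s)
      })
      bc <- lapply(records[[p]], bcea, k = config$bcea_k)
      vals[p, ] <- vapply(bc, `[[`, numeric(1), "bcea")
      if (ellipse_contains(bc$Center, bc$FullField$center) &&
          ellipse_contains(bc$FullField, bc$Center$center))
        contain["center_fullfield"] <- contain["center_fullfield"] + 1
      if (ellipse_contains(bc$Fill, bc$NoFill$center) &&
          ellipse_contains(bc$NoFill, bc$Fill$center))
        contain["fill_nofill"] <- contain["fill_nofill"] + 1
    }
    list(
      bcea = vals,
      center_fullfield = list(
        anova = rm_anova_2(vals[, "Center"], vals[, "FullField"]),
        bootstrap = bootstrap_contrast(vals[, "Center"], vals[, "FullField"],
                                       n_iter = config$bootstrap_n_iter,
                                       seed = seeds["boot"])[
                                         c("mean_diff", "p", "n_iter")]),
      fill_nofill = list(
        anova = rm_anova_2(vals[, "Fill"], vals[, "NoFill"]),
        bootstrap = bootstrap_contrast(vals[, "Fill"], vals[, "NoFill"],
                                       n_iter = config$bootstrap_n_iter,
                                       seed = seeds["boot"] + 1)[
                                         c("mean_diff", "p", "n_iter")]),
      mutual_containment = contain,
      density_map_peak = max(density_map(records[[1]]$Center)))
  })

  behavior <- stage("behavior", {
    stopifnot(!is.null(participants))
    rates <- vapply(participants, function(part) {
      tr <- part$sequence$trials
      sc <- tr$condition %in% c("ScotomaFill", "ScotomaNoFill")
      mean(tr$condition[sc] == "ScotomaFill")
    }, numeric(1))
    list(fill_rate = rates, mean_fill_rate = mean(rates))
  })

  report <- structure(list(config = config, univariate = univariate,
                           timecourse = timecourse,
                           roi_selection = if (is.null(selections)) NULL else
                             lapply(selections, function(s)
                               vapply(s, length, integer(1))),
                           mvpa = mvpa, gaze = gaze, behavior = behavior,
                           errors = errors),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serialize the report (minus bulky intermediates) to JSON.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report
  slim$config$out_dir <- NULL
  class(slim) <- NULL
  class(slim$config) <- NULL
  class(slim$config$sim) <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file.path(out_dir, "report.json"))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$univariate)) {
    sig <- vapply(x$univariate$rois,
                  function(r) r$fullfield_minus_center$significant,
                  logical(1))
    cat(sprintf("  Full-Field - Center: %d/%d ROIs significant at alpha %.4f\n",
                sum(sig), length(sig), x$univariate$alpha))
  }
  if (!is.null(x$mvpa)) {
    acc <- vapply(x$mvpa$areas, `[[`, numeric(1), "mean_accuracy")
    cat(sprintf("  MVPA mean accuracy: %s\n",
                paste(sprintf("%s %.2f", names(acc), acc), collapse = ", ")))
  }
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
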
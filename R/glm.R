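#' Build an HRF-convolved design matrix for one run
#'
#' One boxcar regressor per condition, convolved with the HRF on a fine time
#' grid and sampled at the TR grid, plus an intercept column (\code{baseline})
#' last. Each condition regressor is scaled to unit single-trial peak so that
#' its coefficient is the peak percent-signal-change of one trial. Scotoma
#' trials must already be split by perceptual report into ScotomaFill /
#' ScotomaNoFill (or any other resolved label): an event labeled plain
#' \code{"Scotoma"} is an error.
#'
#' @param design a \code{\link{design_spec}}.
#' @param hrf HRF function of time in seconds.
#' @param dt fine-grid step for the convolution, s.
#' @param hrf_span_s length of the HRF kernel, s.
#' @return object of class \code{design_matrix}: list with \code{X}
#'   (n_trs x (conditions + 1) matrix, column names = condition labels plus
#'   \code{"baseline"}), \code{tr_s}, \code{conditions}, \code{design}.
#' @export
build_design <- function(design, hrf = hrf_double_gamma, dt = 0.1,
                         hrf_span_s = 32) {
  stopifnot(inherits(design, "design_spec"))
  ev <- design$events
  if (any(ev$condition == "Scotoma"))
    stop("unlabeled Scotoma trial: split into ScotomaFill / ScotomaNoFill ",
         "before building the design")
  run_s <- design$n_trs * design$tr_s
  t_fine <- seq(0, run_s - dt, by = dt)
  kern <- hrf(seq(0, hrf_span_s, by = dt))
  conds <- unique(ev$condition)
  tr_idx <- round(((seq_len(design$n_trs) - 1) * design$tr_s) / dt) + 1
  X <- matrix(0, design$n_trs, length(conds) + 1,
              dimnames = list(NULL, c(conds, "baseline")))
  X[, "baseline"] <- 1
  for (cond in conds) {
    e <- ev[ev$condition == cond, , drop = FALSE]
    box <- numeric(length(t_fine))
    for (j in seq_len(nrow(e)))
      box[t_fine >= e$onset_s[j] - 1e-9 &
            t_fine < e$onset_s[j] + e$duration_s[j] - 1e-9] <- 1
    reg <- dt * stats::convolve(box, rev(kern), type = "open")[seq_along(t_fine)]
    # unit single-trial peak: scale by the peak of the first event alone
    box1 <- numeric(length(t_fine))
    box1[t_fine >= e$onset_s[1] - 1e-9 &
           t_fine < e$onset_s[1] + e$duration_s[1] - 1e-9] <- 1
    peak1 <- max(dt * stats::convolve(box1, rev(kern),
                                      type = "open")[seq_along(t_fine)])
    X[, cond] <- reg[tr_idx] / peak1
  }
  structure(list(X = X, tr_s = design$tr_s, conditions = conds,
                 design = design),
            class = "design_matrix")
}

# Assemble the multi-run regression matrix: shared condition columns,
# one intercept per run.
assemble_design <- function(X_list) {
  conds <- unique(unlist(lapply(X_list, `[[`, "conditions")))
  n_runs <- length(X_list)
  rows_per_run <- vapply(X_list, function(x) nrow(x$X), integer(1))
  total <- sum(rows_per_run)
  X <- matrix(0, total, length(conds) + n_runs,
              dimnames = list(NULL, c(conds, paste0("run", seq_len(n_runs)))))
  at <- 0
  for (j in seq_len(n_runs)) {
    idx <- at + seq_len(rows_per_run[j])
    present <- intersect(conds, X_list[[j]]$conditions)
    X[idx, present] <- X_list[[j]]$X[, present, drop = FALSE]
    X[idx, paste0("run", j)] <- 1
    at <- at + rows_per_run[j]
  }
  list(X = X, cond_cols = conds, run_cols = paste0("run", seq_len(n_runs)))
}

#' Voxelwise ordinary least squares fit
#'
#' Fits every voxel of an ROI time series against the HRF-convolved design.
#' Runs are concatenated with one intercept per run (per-run intercepts
#' absorb offset drift between runs); condition regressors are shared across
#' runs. Estimation is ordinary least squares; no prewhitening is applied by
#' default.
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param X optional design: a single \code{design_matrix} or a list with
#'   one per run. Built from \code{Y$design} when omitted.
#' @return object of class \code{glm_fit}: \code{beta} (columns x voxels),
#'   \code{sigma2} (residual variance per voxel), \code{df}, \code{XtXinv},
#'   \code{cond_cols}, \code{run_cols}.
#' @export
fit_glm <- function(Y, X = NULL) {
  stopifnot(inherits(Y, "roi_timeseries"))
  if (is.null(X)) X <- lapply(Y$design, build_design)
  if (inherits(X, "design_matrix")) X <- list(X)
  stopifnot(length(X) == length(Y$data))
  asm <- assemble_design(X)
  Ymat <- do.call(rbind, Y$data)
  if (nrow(Ymat) != nrow(asm$X))
    stop("design rows (", nrow(asm$X), ") do not match time series rows (",
         nrow(Ymat), ")")
  qrX <- qr(asm$X)
  if (qrX$rank < ncol(asm$X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(asm$X))]
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(asm$X)[drop_idx], collapse = ", "))
  }
  beta <- qr.coef(qrX, Ymat)
  resid <- Ymat - asm$X %*% beta
  df <- nrow(asm$X) - ncol(asm$X)
  sigma2 <- colSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 XtXinv = chol2inv(chol(crossprod(asm$X))),
                 cols = colnames(asm$X), cond_cols = asm$cond_cols,
                 run_cols = asm$run_cols, n_rows = nrow(asm$X)),
            class = "glm_fit")
}

# Expand a (possibly named, partial) contrast vector over the fit columns.
expand_contrast <- function(fit, contrast) {
  full <- stats::setNames(numeric(length(fit$cols)), fit$cols)
  if (!is.null(names(contrast))) {
    bad <- setdiff(names(contrast), fit$cols)
    if (length(bad)) stop("unknown contrast columns: ",
                          paste(bad, collapse = ", "))
    full[names(contrast)] <- contrast
  } else {
    if (length(contrast) == length(fit$cond_cols)) {
      full[fit$cond_cols] <- contrast
    } else if (length(contrast) == length(fit$cols)) {
      full[] <- contrast
    } else stop("contrast length matches neither the condition columns nor ",
                "the full design")
  }
  full
}

#' Per-voxel contrast t-statistics
#'
#' t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c) with the fit's residual df.
#' A zero contrast gives t = 0; zero residual variance with a nonzero
#' numerator gives +/-Inf, flagged via the \code{"degenerate"} attribute.
#'
#' @param fit a \code{\link{fit_glm}} result.
#' @param contrast numeric contrast weights, either named (over any subset
#'   of design columns), of length = number of condition columns, or of full
#'   design length.
#' @return numeric vector of per-voxel t values with attributes \code{df}
#'   and \code{degenerate} (logical per voxel).
#' @export
contrast_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  cvec <- expand_contrast(fit, contrast)
  num <- drop(crossprod(cvec, fit$beta))
  qf <- drop(crossprod(cvec, fit$XtXinv %*% cvec))
  se <- sqrt(fit$sigma2 * qf)
  t <- ifelse(se == 0, ifelse(num == 0, 0, sign(num) * Inf), num / se)
  attr(t, "df") <- fit$df
  attr(t, "degenerate") <- se == 0 & num != 0
  t
}

#' Baseline-normalized condition amplitudes
#'
#' Divides each condition coefficient by the voxel's baseline (intercept)
#' coefficient; with per-run intercepts the baseline is their mean. Voxels
#' with zero baseline are excluded (set to NA) with a warning. Scale
#' invariance follows: multiplying the data by k > 0 leaves normalized
#' amplitudes unchanged.
#'
#' @param fit a \code{\link{fit_glm}} result.
#' @return list with \code{normalized} (condition x voxel matrix),
#'   \code{baseline} (per voxel) and \code{roi_mean} (mean normalized
#'   amplitude per condition across voxels, NA-excluded).
#' @export
normalize_beta <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  base <- colMeans(fit$beta[fit$run_cols, , drop = FALSE])
  bad <- base == 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with zero baseline excluded")
    base[bad] <- NA_real_
  }
  normalized <- sweep(fit$beta[fit$cond_cols, , drop = FALSE], 2, base, "/")
  list(normalized = normalized, baseline = base,
       roi_mean = rowMeans(normalized, na.rm = TRUE))
}

#' Group-level one-sample t-test on per-participant ROI statistics
#'
#' One-sample t-test of the per-participant values against zero, with the
#' requested tail, plus Cohen's d = mean/SD = t/sqrt(n). For the Full-Field
#' minus Center contrast the hypothesized direction is \code{"less"}
#' (surround suppression lowers the full-field response).
#'
#' @param values one value per participant (e.g. ROI-mean contrast t).
#' @param tail \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @param mu null value (default 0).
#' @return list with \code{t}, \code{df}, \code{p}, \code{d}, \code{n},
#'   \code{mean}, \code{sd}, \code{degenerate}.
#' @export
group_test <- function(values, tail = c("two.sided", "less", "greater"),
                       mu = 0) {
  tail <- match.arg(tail)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  s <- stats::sd(values)
  m <- mean(values)
  if (s == 0) {
    t <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) {
      if (tail == "two.sided") 1 else 0.5
    } else if (tail == "two.sided") 0 else if (tail == "less") {
      if (m < mu) 0 else 1
    } else {
      if (m > mu) 0 else 1
    }
    return(list(t = t, df = n - 1, p = p, d = if (is.finite(t)) 0 else t,
                n = n, mean = m, sd = s, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = mu, alternative = tail)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), d = unname(ht$statistic) / sqrt(n),
       n = n, mean = m, sd = s, degenerate = FALSE)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the family (12 for the univariate ROI
#'   contrasts, 3 for the MVPA ROIs).
#' @return per-test alpha.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Cohen's d from a one-sample t statistic
#'
#' For a one-sample t-test, d = mean/SD = t / sqrt(n).
#'
#' @param t t statistic.
#' @param n sample size.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) {
  stopifnot(n >= 1)
  t / sqrt(n)
}
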
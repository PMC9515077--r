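#' ROI definition
#'
#' A named set of voxel ids with the selection metadata that produced it.
#' Names follow the retinotopic convention: hemisphere prefix l/r, area V1,
#' V2 or V3, optional d/v suffix for the dorsal/ventral subregion (e.g.
#' "lV2d"); merged ROIs drop the suffix and, for the MVPA scheme, the
#' hemisphere prefix.
#'
#' @param name ROI name.
#' @param voxels vector of unique voxel ids (integer or character).
#' @param thresholds list of selection thresholds applied (metadata).
#' @param provenance free-text provenance label.
#' @return object of class \code{roi_definition}.
#' @export
roi_definition <- function(name, voxels, thresholds = list(),
                           provenance = "simulated") {
  if (anyDuplicated(voxels)) stop("voxel ids must be unique")
  structure(list(name = name, voxels = voxels, thresholds = thresholds,
                 provenance = provenance, empty = length(voxels) == 0),
            class = "roi_definition")
}

#' Localizer-activation voxel selection
#'
#' Keeps voxels whose localizer regression t exceeds \code{t_crit}
#' (strictly). The default 5.09 is the criterion corresponding to a
#' one-tail Bonferroni-corrected alpha of 0.05 over the gray-matter voxel
#' count; see \code{\link{localizer_t_criterion}} to recompute it for a
#' known voxel count. An empty result is flagged (attribute and warning),
#' not fatal.
#'
#' @param t_map per-voxel t values (optionally named by voxel id).
#' @param t_crit threshold (> 0).
#' @return indices (or names) of surviving voxels, with attribute
#'   \code{"empty"}.
#' @export
threshold_localizer <- function(t_map, t_crit = 5.09) {
  stopifnot(t_crit > 0)
  keep <- which(t_map > t_crit)
  out <- if (!is.null(names(t_map))) names(t_map)[keep] else keep
  if (length(out) == 0) warning("no voxels survive t > ", t_crit)
  attr(out, "empty") <- length(out) == 0
  out
}

#' Recompute the localizer t criterion from a voxel count
#'
#' One-tail Bonferroni criterion: the upper-alpha/n quantile of the t
#' distribution with the localizer's residual df.
#'
#' @param n_voxels gray-matter voxel count entering the correction.
#' @param df residual degrees of freedom of the localizer GLM.
#' @param alpha family-wise alpha.
#' @return critical t value.
#' @export
localizer_t_criterion <- function(n_voxels, df, alpha = 0.05) {
  stopifnot(n_voxels >= 1, df > 0)
  stats::qt(1 - alpha / n_voxels, df)
}

#' Convert a t statistic to a correlation magnitude
#'
#' r = t / sqrt(t^2 + df); the regression-t / correlation identity for a
#' single regressor. \code{\link{r_to_t}} is its exact inverse.
#'
#' @param t t statistic.
#' @param df residual degrees of freedom (> 0).
#' @return correlation coefficient.
#' @export
t_to_r <- function(t, df) {
  stopifnot(df > 0)
  t / sqrt(t^2 + df)
}

#' Convert a correlation to a t statistic
#'
#' t = r * sqrt(df / (1 - r^2)); inverse of \code{\link{t_to_r}}.
#'
#' @param r correlation, |r| < 1.
#' @param df residual degrees of freedom (> 0).
#' @return t statistic.
#' @export
r_to_t <- function(r, df) {
  stopifnot(df > 0)
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  r * sqrt(df / (1 - r^2))
}

#' Keep voxels responding at least as much to Center as to Scotoma
#'
#' Removes voxels whose Scotoma activation strictly exceeds their Center
#' activation (the removal rule is strict, so ties are kept), pruning
#' voxels dominated by the surround region.
#'
#' @param beta_center,beta_scotoma aligned per-voxel amplitudes.
#' @param voxels voxel ids aligned with the betas (default indices).
#' @return surviving voxel ids.
#' @export
restrict_center_dominant <- function(beta_center, beta_scotoma,
                                     voxels = seq_along(beta_center)) {
  stopifnot(length(beta_center) == length(beta_scotoma),
            length(voxels) == length(beta_center))
  voxels[beta_center >= beta_scotoma]
}

# "lV2d" -> list(hemi = "l", area = "V2", sub = "d")
parse_roi_name <- function(name) {
  m <- regmatches(name, regexec("^([lr]?)(V[123])([dv]?)$", name))[[1]]
  if (length(m) == 0) stop("cannot parse ROI name '", name, "'")
  list(hemi = m[2], area = m[3], sub = m[4])
}

#' Merge ROI subregions into the analysis ROIs
#'
#' \code{scheme = "univariate"} merges the dorsal and ventral subregions of
#' V2 and V3 within each hemisphere, giving six ROIs (lV1, rV1, lV2, rV2,
#' lV3, rV3). \code{scheme = "mvpa"} further merges hemispheres, giving
#' three (V1, V2, V3), so each ROI keeps enough voxels for pattern
#' classification. Inputs must be disjoint; voxel sets are unions.
#'
#' @param rois list of \code{\link{roi_definition}}.
#' @param scheme \code{"univariate"} or \code{"mvpa"}.
#' @return named list of merged \code{roi_definition}, ordered V1, V2, V3
#'   (left before right for the univariate scheme).
#' @export
merge_rois <- function(rois, scheme = c("univariate", "mvpa")) {
  scheme <- match.arg(scheme)
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_definition")))
  parsed <- lapply(rois, function(r) parse_roi_name(r$name))
  key <- vapply(seq_along(rois), function(i) {
    p <- parsed[[i]]
    if (scheme == "univariate") paste0(p$hemi, p$area) else p$area
  }, character(1))
  groups <- split(seq_along(rois), key)
  out <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    vox <- unlist(lapply(rois[idx], `[[`, "voxels"), use.names = FALSE)
    if (anyDuplicated(vox))
      stop("overlapping voxel ids when merging into ", k)
    roi_definition(k, vox,
                   thresholds = rois[[idx[1]]]$thresholds,
                   provenance = paste0("merged:", scheme))
  })
  names(out) <- names(groups)
  areas <- c("V1", "V2", "V3")
  ord <- if (scheme == "mvpa") areas else
    as.vector(outer(c("l", "r"), areas, paste0))
  out[intersect(ord, names(out))]
}

#' Write ROI definitions as JSON
#'
#' @param rois list of \code{roi_definition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_rois_json <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(name = r$name, voxels = r$voxels, thresholds = r$thresholds,
         provenance = r$provenance))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI definitions from JSON
#'
#' @param path JSON path written by \code{\link{write_rois_json}}.
#' @return list of \code{roi_definition}.
#' @export
read_rois_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(p)
    roi_definition(p$name, unlist(p$voxels),
                   thresholds = p$thresholds,
                   provenance = p$provenance))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
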
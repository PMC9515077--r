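#' Write an ROI time series as a matrix dump plus JSON sidecar
#'
#' Writes \code{<prefix>_bold.tsv} (all runs' TRs stacked, one column per
#' voxel) and \code{<prefix>.json} holding the run designs, trial table and
#' metadata needed to reconstruct the object.
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_timeseries <- function(Y, prefix) {
  stopifnot(inherits(Y, "roi_timeseries"))
  tsv <- paste0(prefix, "_bold.tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(do.call(rbind, Y$data), tsv, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(
    roi_name = Y$roi_name, tr_s = Y$tr_s,
    runs = lapply(Y$design, function(d)
      list(run_id = d$run_id, n_trs = d$n_trs, tr_s = d$tr_s,
           events = d$events)),
    trials = Y$trials)
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tsv, js))
}

#' Read an ROI time series written by \code{\link{write_timeseries}}
#'
#' @param prefix path prefix used at write time.
#' @return a \code{\link{roi_timeseries}}.
#' @export
read_timeseries <- function(prefix) {
  tsv <- paste0(prefix, "_bold.tsv")
  js <- paste0(prefix, ".json")
  side <- jsonlite::read_json(js, simplifyVector = FALSE)
  mat <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  unlist_col <- function(x) {
    x <- unlist(lapply(x, function(v) if (is.null(v)) NA else v))
    if (is.null(x)) character(0) else x
  }
  designs <- lapply(side$runs, function(run) {
    ev <- as.data.frame(lapply(run$events, unlist_col))
    if (nrow(ev) == 0)
      ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                       condition = character(0))
    design_spec(run$tr_s, run$n_trs, ev, run$run_id)
  })
  n_trs <- vapply(designs, `[[`, integer(1), "n_trs")
  if (sum(n_trs) != nrow(mat))
    stop("matrix rows (", nrow(mat), ") do not match the sidecar designs (",
         sum(n_trs), " TRs)")
  ends <- cumsum(n_trs)
  starts <- c(1, utils::head(ends, -1) + 1)
  data <- lapply(seq_along(designs),
                 function(j) mat[starts[j]:ends[j], , drop = FALSE])
  trials <- as.data.frame(lapply(side$trials, unlist_col))
  trials$label <- as.character(trials$label)
  trials$label[trials$label == "NA"] <- NA_character_
  roi_timeseries(data, designs, trials, side$roi_name, side$tr_s)
}

#' Write an ROI time series as NIfTI
#'
#' Voxels are unfolded on the first spatial axis (voxels x 1 x 1 x TRs);
#' run structure and trials go to a \code{<prefix>.json} sidecar identical
#' to \code{\link{write_timeseries}}'s.
#'
#' @param Y a \code{\link{roi_timeseries}}.
#' @param prefix output path prefix (writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>.json}).
#' @return character vector of the two paths, invisibly.
#' @export
write_timeseries_nifti <- function(Y, prefix) {
  stopifnot(inherits(Y, "roi_timeseries"))
  mat <- do.call(rbind, Y$data) # TRs x voxels
  arr <- array(t(mat), dim = c(ncol(mat), 1, 1, nrow(mat)))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, Y$tr_s)), nii)
  side <- write_timeseries(Y, paste0(prefix, "_sidecar"))
  invisible(c(nii, side[2]))
}

#' Read a NIfTI ROI time series written by \code{\link{write_timeseries_nifti}}
#'
#' @param prefix path prefix used at write time.
#' @return a \code{\link{roi_timeseries}}.
#' @export
read_timeseries_nifti <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  ref <- read_timeseries(paste0(prefix, "_sidecar"))
  mat <- t(matrix(arr, dim(arr)[1], dim(arr)[4]))
  n_trs <- vapply(ref$design, `[[`, integer(1), "n_trs")
  ends <- cumsum(n_trs); starts <- c(1, utils::head(ends, -1) + 1)
  ref$data <- lapply(seq_along(ref$design),
                     function(j) mat[starts[j]:ends[j], , drop = FALSE])
  ref
}
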
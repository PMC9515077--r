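#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5 s, undershoot
#' near 15 s), normalized so the peak response is 1. Shape parameters follow
#' the widely used canonical form: peak gamma shape 6, undershoot shape 16,
#' unit scale, undershoot ratio 1/6.
#'
#' @param t_s time since event onset, seconds (vectorized; values < 0 give 0).
#' @param peak_shape,under_shape gamma shape parameters of the response and
#'   undershoot components.
#' @param scale common gamma scale parameter, s.
#' @param under_ratio undershoot amplitude relative to the response.
#' @return HRF amplitude at \code{t_s}, peak-normalized to 1.
#' @examples
#' hrf_double_gamma(c(0, 5, 15))
#' @export
hrf_double_gamma <- function(t_s, peak_shape = 6, under_shape = 16,
                             scale = 1, under_ratio = 1 / 6) {
  raw <- function(t) {
    h <- stats::dgamma(t, shape = peak_shape, scale = scale) -
      under_ratio * stats::dgamma(t, shape = under_shape, scale = scale)
    h[t < 0] <- 0
    h
  }
  peak <- max(raw(seq(0, 30, by = 0.01)))
  raw(t_s) / peak
}
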
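#' Canonical double-gamma hemodynamic response kernel
#'
#' Samples the canonical double-gamma HRF (response gamma peaking near 5 s,
#' undershoot gamma peaking near 15 s with 1/6 relative amplitude) on the TR
#' grid and rescales it to unit peak. The synthetic-data generator convolves
#' stimulus drives with this kernel; the analysis side never uses it — there
#' the hemodynamic delay is handled by a fixed 5-10 s lag window.
#'
#' @param tr_seconds Sampling interval in seconds.
#' @param length_seconds Kernel support in seconds (sampled on
#'   `seq(0, length_seconds, by = tr_seconds)`).
#' @return A numeric vector of kernel weights with unit peak; its sum is
#'   attached as attribute `"sum"`.
#' @examples
#' h <- hrf_kernel()
#' which.max(h) # peak ~5 s after onset at 1 s TR
#' @export
hrf_kernel <- function(tr_seconds = 1, length_seconds = 32) {
  if (!is.finite(tr_seconds) || tr_seconds <= 0)
    abort("`tr_seconds` must be a positive duration")
  if (!is.finite(length_seconds) || length_seconds <= 0)
    abort("`length_seconds` must be a positive duration")
  t <- seq(0, length_seconds, by = tr_seconds)
  # shape/rate pairs: peaks at (a-1)/b = 5 s and 15 s
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  attr(h, "sum") <- sum(h)
  h
}
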
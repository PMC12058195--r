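#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a response gamma peaking at 5 s
#' (shape 6, rate 1) minus an undershoot gamma (shape 16, rate 1)
#' scaled by 1/6.
#'
#' @param t Time in seconds (>= 0).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  stopifnot(is.numeric(t))
  out <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  out[t < 0] <- 0
  out
}

#' Convolve a series with the canonical HRF
#'
#' Causal convolution with the double-gamma HRF sampled on the TR
#' grid, truncated to the input length; this lags the behavioral
#' target to match the hemodynamic delay of the BOLD signal.
#'
#' @param x Numeric series on the TR grid.
#' @param tr_s TR in seconds.
#' @param duration_s Length of the sampled HRF kernel in seconds
#'   (default 32, well past the undershoot).
#' @return Convolved series, same length as `x`.
#' @export
convolve_hrf <- function(x, tr_s, duration_s = 32) {
  assert_scalar(tr_s, "tr_s", lower = 1e-9)
  n <- length(x)
  kern <- hrf_double_gamma(seq(0, duration_s, by = tr_s))
  full <- as.numeric(stats::convolve(x, rev(kern), type = "open"))
  full[seq_len(n)]
}
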
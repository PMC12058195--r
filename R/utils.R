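# Shared numerical helpers. Conventions used throughout the package:
# sample sd always uses the n-1 denominator; correlations are clipped
# before atanh so Fisher-z values stay finite.

#' z-score a numeric series
#'
#' Centers and scales to unit sample standard deviation (denominator
#' `n - 1`). A constant series has no z-score and is an error, because a
#' zero-variance target or rating carries no usable signal downstream.
#'
#' @param x Numeric vector.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2L) abort("zscore() needs at least two values.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("zscore(): series is constant (zero variance); cannot standardize.")
  }
  (x - mean(x)) / s
}

#' Fisher z-transform with clipping
#'
#' `atanh()` applied after clipping the correlation to `±(1 - eps)` so
#' that perfectly correlated inputs stay finite. The default clip for
#' summary statistics is `1 - 1e-15`; dynamic-FC values use a coarser
#' `1 - 1e-7` (see [compute_dynfc()]).
#'
#' @param r Correlations in `[-1, 1]`.
#' @param eps Clip margin.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, eps = 1e-15) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Inverse Fisher z-transform
#' @param z Fisher-z values.
#' @return Correlations.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Summarize a set of correlations via Fisher z
#'
#' Correlations are Fisher z-transformed, averaged, and transformed
#' back, the standard variance-stabilized average used for fold
#' accuracies and intersubject correlations.
#'
#' @param r Correlations.
#' @param na.rm Drop missing values before averaging.
#' @return A single averaged correlation.
#' @export
mean_r_fisher <- function(r, na.rm = FALSE) {
  fisher_z_inv(mean(fisher_z(r), na.rm = na.rm))
}

# Derive a child RNG seed from a master seed and a stream index.
# Fixed multipliers keep streams stable when more subjects/raters are
# added; result kept within the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, stream, salt = 0L) {
  as.integer((as.double(seed) * 48271 + stream * 7919 + salt * 104729) %%
    2147483587)
}

# round half away from zero (slider values; R's round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
    x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
    x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
      name, format(lower), format(upper)))
  }
  invisible(as.numeric(x))
}
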
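#' Dataset acquisition/analysis constants
#'
#' Bundles the constants that define one dataset's TR grid and the
#' tapered sliding window shared by the behavioral and connectivity
#' streams: window length, Gaussian taper sd, and step (one window per
#' TR). The rating scale is fixed at 1--25 with 13 neutral, matching
#' the continuous slider task.
#'
#' @param tr_s Repetition time in seconds (> 0).
#' @param segment_tr Integer vector of segment lengths in TRs; the
#'   total series length is `sum(segment_tr)`.
#' @param window_tr Sliding-window length in TRs (>= 3). Typical values
#'   are `round(45 / tr_s)`.
#' @param taper_sigma_tr Gaussian taper sd in TRs (default 3).
#' @param step_tr Window step in TRs (default 1; one output per TR).
#' @param rating_scale Two-element slider range (default `c(1, 25)`).
#' @param neutral Neutral slider value (default 13).
#' @param crop_tr Optional 1-based TR indices to drop before
#'   concatenation (e.g. non-movie filler segments).
#' @return A `dataset_spec` list.
#' @examples
#' dataset_spec(tr_s = 1.5, segment_tr = c(500, 446), window_tr = 30)
#' @export
dataset_spec <- function(tr_s, segment_tr, window_tr,
                         taper_sigma_tr = 3, step_tr = 1,
                         rating_scale = c(1, 25), neutral = 13,
                         crop_tr = integer()) {
  assert_scalar(tr_s, "tr_s", lower = 1e-9)
  if (!is.numeric(segment_tr) || any(segment_tr < 1)) {
    abort("`segment_tr` must be positive segment lengths in TRs.")
  }
  assert_count(window_tr, "window_tr", min = 3L)
  assert_scalar(taper_sigma_tr, "taper_sigma_tr", lower = 1e-9)
  assert_count(step_tr, "step_tr", min = 1L)
  if (length(rating_scale) != 2L || rating_scale[1] >= rating_scale[2]) {
    abort("`rating_scale` must be an increasing pair.")
  }
  if (neutral < rating_scale[1] || neutral > rating_scale[2]) {
    abort("`neutral` must lie within `rating_scale`.")
  }
  structure(
    list(
      tr_s = as.numeric(tr_s),
      segment_tr = as.integer(segment_tr),
      n_tr = as.integer(sum(segment_tr)),
      window_tr = as.integer(window_tr),
      taper_sigma_tr = as.numeric(taper_sigma_tr),
      step_tr = as.integer(step_tr),
      rating_scale = as.numeric(rating_scale),
      neutral = as.numeric(neutral),
      crop_tr = as.integer(crop_tr)
    ),
    class = "dataset_spec"
  )
}

#' Window length in TRs from a window length in seconds
#' @param window_s Window length in seconds.
#' @param tr_s TR in seconds.
#' @return `round(window_s / tr_s)` as an integer.
#' @export
window_tr_from_seconds <- function(window_s, tr_s) {
  assert_scalar(window_s, "window_s", lower = 1e-9)
  assert_scalar(tr_s, "tr_s", lower = 1e-9)
  as.integer(round(window_s / tr_s))
}

#' Tapered sliding-window weights at one TR
#'
#' Gaussian weights (sd `taper_sigma_tr`) over a window of
#' `window_tr` TRs centered on `center`. At the series boundaries the
#' out-of-range tail of the kernel is cropped and the remaining
#' weights renormalized to sum to one, so every TR gets a full-mass
#' window and the output grid has the same length as the input.
#'
#' @param center 1-based TR index of the window center.
#' @param spec A [dataset_spec()] (uses `window_tr`, `taper_sigma_tr`).
#' @param series_len Series length in TRs.
#' @return A tibble with columns `tr` (in-bounds TR indices) and `w`
#'   (weights summing to 1).
#' @export
taper_weights <- function(center, spec, series_len) {
  assert_count(center, "center")
  assert_count(series_len, "series_len")
  if (center > series_len) abort("`center` beyond the series end.")
  w <- spec$window_tr
  offsets <- seq.int(-((w - 1L) %/% 2L), w %/% 2L)
  tr <- center + offsets
  keep <- tr >= 1L & tr <= series_len
  tr <- tr[keep]
  g <- exp(-offsets[keep]^2 / (2 * spec$taper_sigma_tr^2))
  tibble(tr = tr, w = g / sum(g))
}

#' Taper-smooth a series
#'
#' Applies the tapered sliding window as a smoother: the value at each
#' TR is the Gaussian-weighted mean of the window centered there, with
#' boundary truncation and renormalization as in [taper_weights()].
#' The same operation smooths the HRF-convolved behavioral target and
#' (via the weighted correlation) the connectivity stream, which keeps
#' the two on a common timescale.
#'
#' @param x Numeric series.
#' @param spec A [dataset_spec()].
#' @return Smoothed series, same length as `x`.
#' @export
taper_smooth <- function(x, spec) {
  n <- length(x)
  if (spec$window_tr > n) {
    abort("taper_smooth(): window longer than the series.")
  }
  kern <- taper_kernel(spec)
  half_lo <- (spec$window_tr - 1L) %/% 2L
  half_hi <- spec$window_tr %/% 2L
  vapply(seq_len(n), function(t) {
    lo <- max(1L, t - half_lo)
    hi <- min(n, t + half_hi)
    g <- kern[(lo - t + half_lo + 1L):(hi - t + half_lo + 1L)]
    sum(g * x[lo:hi]) / sum(g)
  }, numeric(1))
}

# unnormalized Gaussian kernel over the window offsets
taper_kernel <- function(spec) {
  w <- spec$window_tr
  offsets <- seq.int(-((w - 1L) %/% 2L), w %/% 2L)
  exp(-offsets^2 / (2 * spec$taper_sigma_tr^2))
}
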
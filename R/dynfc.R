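# Tapered sliding-window dynamic functional connectivity.
#
# One window per TR, centered, with boundary truncation, so the FC
# stream has exactly the length of the BOLD input and lines up with
# the taper-smoothed behavioral target. The within-window correlation
# is fully weighted (Gaussian taper weights enter the means and
# variances), not an unweighted correlation over a masked window.

# weighted Pearson correlation matrix of the rows idx of x (T x ROI)
weighted_corr_matrix <- function(x, idx, w) {
  xs <- x[idx, , drop = FALSE]
  mu <- colSums(w * xs)
  xc <- sweep(xs, 2L, mu, "-") * sqrt(w)
  cv <- crossprod(xc)
  v <- diag(cv)
  list(corr = cv / sqrt(outer(v, v)), var = v)
}

#' Weighted Pearson correlation of two series
#'
#' Correlation under non-negative weights summing to one: weighted
#' means, variances, and covariance. This is the primitive inside the
#' tapered sliding window.
#'
#' @param x,y Numeric series of equal length.
#' @param w Non-negative weights (renormalized internally).
#' @return Weighted correlation; `NA` if either weighted variance is 0.
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w >= 0))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Dynamic functional connectivity of one subject
#'
#' For every TR, the Fisher-z transformed weighted Pearson correlation
#' of every ROI pair within the tapered window centered there.
#' Correlations are clipped to `±(1 - 1e-7)` before `atanh`; a cell
#' whose window has zero weighted variance is set to 0 and counted in
#' a warning, so downstream feature selection stays total.
#'
#' @param roi_ts TR x ROI matrix of BOLD-like series.
#' @param spec A [dataset_spec()].
#' @return An edges x TR matrix of Fisher-z values, with the edge
#'   index of `ncol(roi_ts)` ROIs as attribute `edge_index` and the
#'   parcellation fingerprint as attribute `edge_hash`.
#' @export
compute_dynfc <- function(roi_ts, spec) {
  roi_ts <- as.matrix(roi_ts)
  n_tr <- nrow(roi_ts)
  n_roi <- ncol(roi_ts)
  if (n_tr < spec$window_tr) {
    abort("compute_dynfc(): series shorter than the window.")
  }
  ei <- edge_index(n_roi)
  # linear positions of the canonical (row-major upper triangle) pairs
  lin <- (ei$j - 1L) * n_roi + ei$i
  out <- matrix(NA_real_, nrow(ei), n_tr)
  kern <- taper_kernel(spec)
  half_lo <- (spec$window_tr - 1L) %/% 2L
  half_hi <- spec$window_tr %/% 2L
  n_degenerate <- 0L
  for (t in seq_len(n_tr)) {
    lo <- max(1L, t - half_lo)
    hi <- min(n_tr, t + half_hi)
    g <- kern[(lo - t + half_lo + 1L):(hi - t + half_lo + 1L)]
    wc <- weighted_corr_matrix(roi_ts, lo:hi, g / sum(g))
    r <- wc$corr[lin]
    bad <- !is.finite(r)
    if (any(bad)) {
      n_degenerate <- n_degenerate + sum(bad)
      r[bad] <- 0
    }
    out[, t] <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  }
  if (n_degenerate > 0L) {
    warn(sprintf(
      "compute_dynfc(): %d zero-variance window cells set to 0.",
      n_degenerate))
  }
  attr(out, "edge_index") <- ei
  attr(out, "edge_hash") <- edge_index_hash(n_roi)
  out
}

#' Dynamic FC for a list of subjects
#'
#' @param bold List of TR x ROI matrices (one per subject).
#' @param spec A [dataset_spec()].
#' @return A `dynfc_set`: list with `fc` (list of edges x TR
#'   matrices), `edge_index`, `edge_hash`, `spec`, `subjects`.
#' @export
dynfc_set <- function(bold, spec) {
  stopifnot(is.list(bold), length(bold) >= 1L)
  fc <- lapply(bold, compute_dynfc, spec = spec)
  structure(
    list(
      fc = fc,
      edge_index = attr(fc[[1]], "edge_index"),
      edge_hash = attr(fc[[1]], "edge_hash"),
      spec = spec,
      subjects = names(bold) %||% sprintf("sub%02d", seq_along(bold))
    ),
    class = "dynfc_set"
  )
}

#' Regress nuisance series out of BOLD data
#'
#' Ordinary least-squares residualization of each ROI series against
#' an intercept plus the nuisance series (e.g. ten low-level stimulus
#' features). Collinear nuisance columns are dropped with a warning.
#'
#' @param roi_ts TR x ROI matrix.
#' @param nuisance TR x features matrix.
#' @return Residual TR x ROI matrix (orthogonal to every retained
#'   nuisance series).
#' @export
regress_confounds_bold <- function(roi_ts, nuisance) {
  roi_ts <- as.matrix(roi_ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(roi_ts)) {
    abort("regress_confounds_bold(): row mismatch between data and nuisance.")
  }
  design <- cbind(intercept = 1, nuisance)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    warn(sprintf(
      "regress_confounds_bold(): dropped %d collinear nuisance column(s).",
      ncol(design) - qd$rank))
  }
  qr.resid(qd, roi_ts)
}

#' Regress framewise displacement out of a dynamic-FC matrix
#'
#' The FD series is taper-smoothed with the same window spec as the FC
#' stream (both live on the windowed timescale), then each edge's
#' Fisher-z series is OLS-residualized against intercept + smoothed FD.
#'
#' @param fc Edges x TR matrix from [compute_dynfc()].
#' @param fd Framewise-displacement series, length `ncol(fc)`.
#' @param spec A [dataset_spec()].
#' @return Residual edges x TR matrix (attributes preserved).
#' @export
regress_confounds_fc <- function(fc, fd, spec) {
  if (length(fd) != ncol(fc)) {
    abort("regress_confounds_fc(): FD length does not match the FC grid.")
  }
  fd_s <- taper_smooth(fd, spec)
  if (sd(fd_s) < 1e-12 * (abs(mean(fd_s)) + 1)) {
    warn("regress_confounds_fc(): constant FD; returning demeaned FC.")
    res <- fc - rowMeans(fc)
  } else {
    qd <- qr(cbind(1, fd_s))
    res <- t(qr.resid(qd, t(fc)))
  }
  attributes(res)[c("edge_index", "edge_hash")] <-
    attributes(fc)[c("edge_index", "edge_hash")]
  res
}
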
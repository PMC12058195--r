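# From raw continuous rating logs to the model target.
#
# Order of target transforms: per-rater resampling to the TR grid ->
# segment concatenation (with optional TR cropping) -> z-score ->
# group average -> HRF convolution -> taper smoothing. Positivity /
# negativity segments are extracted from the *raw* group mean before
# any standardization.

#' Resample a timestamped rating log to the TR grid
#'
#' Slider logs record value changes at arbitrary times; fMRI analysis
#' needs one value per TR. The slider is a right-continuous step
#' function, and each TR is assigned the value prevailing at the end
#' of its interval `[k*tr, (k+1)*tr)` (last value carried forward).
#'
#' @param events A data frame with columns `rater_id`, `time_s`,
#'   `value`, sorted by time within rater; the first event of each
#'   rater must be at or before `t = 0` (initial slider position).
#' @param spec A [dataset_spec()]; `sum(segment_tr)` TRs are produced.
#' @return A tibble `rater_id`, `tr` (1-based), `value`.
#' @export
resample_ratings <- function(events, spec) {
  events <- as_tibble(events)
  if (nrow(events) == 0L) abort("resample_ratings(): no events.")
  if (!all(c("rater_id", "time_s", "value") %in% names(events))) {
    abort("`events` needs columns rater_id, time_s, value.")
  }
  n_tr <- spec$n_tr
  t_end <- seq_len(n_tr) * spec$tr_s - 1e-9
  movie_end <- n_tr * spec$tr_s
  if (any(events$time_s >= movie_end)) {
    warn("resample_ratings(): events beyond the movie end were ignored.")
    events <- dplyr::filter(events, .data$time_s < movie_end)
    if (nrow(events) == 0L) abort("resample_ratings(): no usable events.")
  }
  out <- events |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_s)
      if (df$time_s[1] > 0) {
        abort(sprintf(
          "resample_ratings(): rater '%s' has no initial position at t <= 0.",
          key$rater_id[[1]]))
      }
      idx <- findInterval(t_end, df$time_s)
      tibble(tr = seq_len(n_tr), value = df$value[idx])
    }) |>
    dplyr::ungroup()
  out
}

#' z-score a set of per-segment series after concatenation
#'
#' Segments from the same rater are concatenated in order (after
#' dropping any cropped TRs given in the spec) and z-scored across the
#' full concatenated length with the `n - 1` sd convention.
#'
#' @param segments A list of numeric series (or a single series).
#' @param crop_tr Optional 1-based indices (into the concatenated
#'   series) to drop before z-scoring.
#' @return One z-scored series.
#' @export
normalize_and_concat <- function(segments, crop_tr = integer()) {
  if (is.numeric(segments)) segments <- list(segments)
  x <- unlist(segments, use.names = FALSE)
  if (length(crop_tr)) x <- x[-crop_tr]
  if (length(unique(x)) < 2L) {
    abort("normalize_and_concat(): constant series has no z-score.")
  }
  zscore(x)
}

#' Build a rater panel from a rating log
#'
#' Resamples every rater, applies cropping/concatenation, and returns
#' both the raw and the z-scored panel.
#'
#' @param events Rating log (see [resample_ratings()]).
#' @param spec A [dataset_spec()].
#' @return A `rater_panel`: list with `raw` and `z` (rater x TR
#'   matrices with rater ids as rownames) and `spec`.
#' @export
rater_panel <- function(events, spec) {
  long <- resample_ratings(events, spec)
  wide <- tidyr::pivot_wider(long, names_from = "tr",
    values_from = "value")
  ids <- wide$rater_id
  raw <- as.matrix(wide[, -1, drop = FALSE])
  rownames(raw) <- ids
  if (length(spec$crop_tr)) raw <- raw[, -spec$crop_tr, drop = FALSE]
  z <- t(apply(raw, 1L, function(r) {
    if (length(unique(r)) < 2L) {
      abort("rater_panel(): a rater's series is constant; cannot z-score.")
    }
    zscore(r)
  }))
  rownames(z) <- ids
  structure(list(raw = raw, z = z, spec = spec), class = "rater_panel")
}

#' Group-average rating series
#'
#' @param panel A [rater_panel()] (>= 2 raters) or a rater x TR matrix
#'   of z-scored series.
#' @return Elementwise mean across raters.
#' @export
group_average <- function(panel) {
  z <- if (inherits(panel, "rater_panel")) panel$z else as.matrix(panel)
  if (nrow(z) < 2L) abort("group_average(): need at least 2 raters.")
  colMeans(z)
}

#' Leave-one-out intersubject correlation with a sign-flip null
#'
#' Each rater's z-scored series is correlated with the group average
#' of the remaining raters; the per-rater correlations are summarized
#' by the Fisher-z mean. The null flips the sign of each rater's
#' similarity with probability 1/2 before averaging; the one-tailed
#' p-value is `(1 + #(|null mean| computed as flipped mean >= observed
#' mean)) / (1 + n_perm)`.
#'
#' @param panel A [rater_panel()] or z-scored rater x TR matrix with
#'   >= 3 raters.
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @return An `isc_result`: tibble of per-rater `r`, the Fisher-z
#'   summary `mean_r`, sign-flip `p`, and `n_perm`.
#' @export
leave_one_out_isc <- function(panel, n_perm = 10000, seed = 1L) {
  z <- if (inherits(panel, "rater_panel")) panel$z else as.matrix(panel)
  n <- nrow(z)
  if (n < 3L) abort("leave_one_out_isc(): need at least 3 raters.")
  ids <- rownames(z) %||% sprintf("rater%02d", seq_len(n))
  total <- colSums(z)
  r <- vapply(seq_len(n), function(k) {
    loo_mean <- (total - z[k, ]) / (n - 1)
    if (sd(loo_mean) == 0) {
      abort(sprintf(
        "leave_one_out_isc(): leave-one-out mean constant for rater '%s'.",
        ids[k]))
    }
    cor(z[k, ], loo_mean)
  }, numeric(1))
  zr <- fisher_z(r)
  obs <- mean(zr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 7L))
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  null_means <- as.numeric(flips %*% zr) / n
  p <- (1 + sum(null_means >= obs)) / (1 + n_perm)
  structure(
    list(
      raters = tibble(rater_id = ids, r = r),
      mean_r = fisher_z_inv(obs),
      p = p, n_perm = as.integer(n_perm)
    ),
    class = "isc_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap ISC stability as a function of panel size
#'
#' For each size `k`, draws `k` raters with replacement `n_boot`
#' times and records the Fisher-z group ISC of the resampled panel,
#' tracing how the group-average rating stabilizes with more raters.
#'
#' @param panel A [rater_panel()] or z-scored matrix.
#' @param sizes Panel sizes to probe (each >= 2).
#' @param n_boot Bootstrap draws per size (default 1000).
#' @param seed RNG seed.
#' @return A tibble `size`, `mean_z_isc`, `sd_z_isc`.
#' @export
isc_vs_samplesize <- function(panel, sizes, n_boot = 1000, seed = 1L) {
  z <- if (inherits(panel, "rater_panel")) panel$z else as.matrix(panel)
  if (any(sizes < 2L) || any(sizes > nrow(z))) {
    abort("isc_vs_samplesize(): sizes must lie in [2, n_raters].")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 8L))
  purrr::map_dfr(as.integer(sizes), function(k) {
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(z), k, replace = TRUE)
      sub <- z[idx, , drop = FALSE]
      tot <- colSums(sub)
      zr <- vapply(seq_len(k), function(m) {
        loo <- (tot - sub[m, ]) / (k - 1)
        s <- sd(loo)
        if (s == 0) return(NA_real_)
        fisher_z(cor(sub[m, ], loo))
      }, numeric(1))
      mean(zr, na.rm = TRUE)
    }, numeric(1))
    tibble(size = k, mean_z_isc = mean(vals), sd_z_isc = sd(vals))
  })
}

#' Build the group model target from a rating log
#'
#' The full behavioral chain: resample, crop/concatenate, z-score per
#' rater, group-average, HRF-convolve, taper-smooth. The taper-smoothed
#' series is what the connectome model is trained to predict.
#'
#' @param events Rating log (see [resample_ratings()]).
#' @param spec A [dataset_spec()].
#' @return A `group_target` list: `raw_mean` (mean of raw resampled
#'   ratings, on the slider scale), `group_z`, `hrf`, `smoothed`, and
#'   `spec`.
#' @export
build_group_target <- function(events, spec) {
  panel <- rater_panel(events, spec)
  gz <- group_average(panel)
  hrfed <- convolve_hrf(gz, spec$tr_s)
  structure(
    list(
      raw_mean = colMeans(panel$raw),
      group_z = gz,
      hrf = hrfed,
      smoothed = taper_smooth(hrfed, spec),
      spec = spec
    ),
    class = "group_target"
  )
}

#' Extract positivity / negativity segments from raw group ratings
#'
#' Keeps the TRs where the raw (1--25 scale) group-average rating is
#' above the neutral point (`mode = "positive"`) or below it
#' (`mode = "negative"`); TRs exactly at neutral belong to neither.
#' The retained TRs are concatenated in order and sent through the
#' usual target chain (z-score, HRF convolution, taper smoothing).
#'
#' @param raw_mean Raw group-average series on the slider scale.
#' @param spec A [dataset_spec()].
#' @param mode `"positive"` or `"negative"`.
#' @return A list: `index` (1-based retained TR indices), `series`
#'   (processed concatenated series; `NULL` when the selection is
#'   empty or shorter than the window).
#' @export
extract_valence_segments <- function(raw_mean, spec,
                                     mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  idx <- if (mode == "positive") {
    which(raw_mean > spec$neutral)
  } else {
    which(raw_mean < spec$neutral)
  }
  if (length(idx) == 0L) {
    return(list(index = integer(), series = NULL))
  }
  sub <- raw_mean[idx]
  if (length(unique(sub)) < 2L || length(sub) < spec$window_tr) {
    return(list(index = idx, series = NULL))
  }
  z <- zscore(sub)
  h <- convolve_hrf(z, spec$tr_s)
  list(index = idx, series = taper_smooth(h, spec))
}
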
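# Synthetic data with known ground truth.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: a slow latent "arousal" state; a planted set of
# ROI pairs whose instantaneous correlation follows that state via a
# shared-component construction with analytically known correlation;
# panels of noisy step-function raters on the 1-25 slider scale; and
# nuisance series (low-level stimulus features, framewise
# displacement). One master seed drives fixed per-subject / per-rater
# sub-streams, so adding subjects never perturbs existing ones.

#' Configuration for the synthetic-data generator
#'
#' @param n_subjects Number of simulated scanner subjects.
#' @param n_roi Number of ROIs.
#' @param n_tr Number of TRs.
#' @param tr_s TR in seconds.
#' @param n_planted Number of planted arousal-coupled edges (used when
#'   `planted_edges` is `NULL`; pairs are sampled ROI-disjoint so the
#'   shared-component correlation is exact).
#' @param planted_edges Optional tibble/data.frame with columns `i`,
#'   `j` giving the planted ROI pairs explicitly.
#' @param coupling Gain in `[0, 1]` mapping the latent state to the
#'   planted-edge target correlation; 0 removes the planted signal.
#' @param noise_sd Per-ROI observation noise sd.
#' @param smoothness_tr Gaussian-kernel sd (in TRs) of the latent
#'   state; controls its autocorrelation.
#' @param n_raters Number of simulated continuous raters.
#' @param rater_noise_sd Rater noise sd in slider units (AR(1),
#'   stationary sd).
#' @param rater_press_rate Expected slider adjustments per minute.
#' @param seed Master seed; fixed seed gives bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 16, n_roi = 60, n_tr = 500,
                         tr_s = 1.5, n_planted = 20,
                         planted_edges = NULL, coupling = 0.6,
                         noise_sd = 1, smoothness_tr = 10,
                         n_raters = 10, rater_noise_sd = 1,
                         rater_press_rate = 6, seed = 1L) {
  assert_count(n_subjects, "n_subjects")
  assert_count(n_roi, "n_roi", min = 2L)
  assert_count(n_tr, "n_tr")
  assert_scalar(tr_s, "tr_s", lower = 1e-9)
  assert_scalar(coupling, "coupling", lower = 0, upper = 1)
  assert_scalar(noise_sd, "noise_sd", lower = 1e-12)
  assert_scalar(smoothness_tr, "smoothness_tr", lower = 1e-9)
  assert_count(n_raters, "n_raters")
  assert_scalar(rater_noise_sd, "rater_noise_sd", lower = 0)
  assert_scalar(rater_press_rate, "rater_press_rate", lower = 1e-9)
  assert_count(seed, "seed", min = 0L)
  if (!is.null(planted_edges)) {
    planted_edges <- as_tibble(planted_edges)
    if (!all(c("i", "j") %in% names(planted_edges))) {
      abort("`planted_edges` needs columns `i` and `j`.")
    }
    if (any(planted_edges$i >= planted_edges$j) ||
      any(planted_edges$j > n_roi) || any(planted_edges$i < 1)) {
      abort("`planted_edges` must have 1 <= i < j <= n_roi.")
    }
    n_planted <- nrow(planted_edges)
  } else {
    assert_count(n_planted, "n_planted", min = 0L)
    if (2L * n_planted > n_roi) {
      abort("Need `2 * n_planted <= n_roi` for ROI-disjoint planted edges.")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_roi = as.integer(n_roi),
      n_tr = as.integer(n_tr), tr_s = as.numeric(tr_s),
      n_planted = as.integer(n_planted), planted_edges = planted_edges,
      coupling = as.numeric(coupling), noise_sd = as.numeric(noise_sd),
      smoothness_tr = as.numeric(smoothness_tr),
      n_raters = as.integer(n_raters),
      rater_noise_sd = as.numeric(rater_noise_sd),
      rater_press_rate = as.numeric(rater_press_rate),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a smooth latent state series
#'
#' Gaussian white noise convolved with a Gaussian kernel
#' (sd = `smoothness_tr` TRs, truncated at 4 sd) and then z-scored.
#' The kernel sd directly controls the lag-1 autocorrelation, giving a
#' simple stand-in for a slow group-level arousal time course.
#'
#' @param n_tr Series length in TRs (requires
#'   `n_tr >= 10 * smoothness_tr` so the series holds several
#'   independent excursions).
#' @param smoothness_tr Kernel sd in TRs (> 0).
#' @param seed RNG seed.
#' @return Numeric series of length `n_tr`, mean 0, sample sd 1.
#' @export
generate_latent_state <- function(n_tr, smoothness_tr = 10, seed = 1L) {
  assert_count(n_tr, "n_tr")
  assert_scalar(smoothness_tr, "smoothness_tr", lower = 1e-9)
  if (n_tr < 10 * smoothness_tr) {
    abort("generate_latent_state(): need n_tr >= 10 * smoothness_tr.")
  }
  half <- as.integer(ceiling(4 * smoothness_tr))
  kern <- exp(-((-half):half)^2 / (2 * smoothness_tr^2))
  kern <- kern / sum(kern)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 1L))
  white <- rnorm(n_tr + 2L * half)
  sm <- stats::filter(white, kern, method = "convolution", sides = 2L)
  zscore(as.numeric(sm[(half + 1L):(half + n_tr)]))
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# latent -> target instantaneous correlation on planted edges,
# bounded in (0, 0.9 * coupling); the 0.9 ceiling keeps Fisher z tame.
latent_to_rho <- function(latent, coupling) {
  0.9 * coupling * stats::plogis(latent)
}

#' Ground truth of a synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @return A `synth_truth` list: `latent` (z-scored series), `planted`
#'   (tibble `edge`, `i`, `j`), and `rho` (planted-edges x TR matrix
#'   of target instantaneous correlations, all in `(-1, 1)`).
#' @export
synth_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  latent <- generate_latent_state(cfg$n_tr, cfg$smoothness_tr, cfg$seed)
  planted <- cfg$planted_edges
  if (is.null(planted)) {
    planted <- sample_planted_edges(cfg$n_roi, cfg$n_planted, cfg$seed)
  }
  rho_row <- latent_to_rho(latent, cfg$coupling)
  rho <- matrix(rho_row, nrow = max(nrow(planted), 1L),
    ncol = cfg$n_tr, byrow = TRUE)
  if (nrow(planted) == 0L) rho <- matrix(0, 0L, cfg$n_tr)
  structure(
    list(
      latent = latent,
      planted = tibble(
        edge = if (nrow(planted)) edge_id(planted$i, planted$j, cfg$n_roi)
          else integer(),
        i = as.integer(planted$i), j = as.integer(planted$j)
      ),
      rho = rho
    ),
    class = "synth_truth"
  )
}

# ROI-disjoint random pairs: shuffle the available ROIs and take
# consecutive pairs; `avoid` rejects whole draws that collide with an
# existing edge set, `avoid_rois` removes ROIs from the pool.
sample_planted_edges <- function(n_roi, n_planted, seed,
                                 avoid = NULL, avoid_rois = integer(),
                                 stream = 0L) {
  if (n_planted == 0L) return(tibble(i = integer(), j = integer()))
  pool <- setdiff(seq_len(n_roi), avoid_rois)
  if (length(pool) < 2L * n_planted) {
    abort("sample_planted_edges(): not enough free ROIs for disjoint pairs.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, stream, salt = 2L))
  avoid_key <- if (is.null(avoid)) character() else paste(avoid$i, avoid$j)
  for (try in 1:200) {
    perm <- sample(pool)
    a <- perm[seq(1L, 2L * n_planted, by = 2L)]
    b <- perm[seq(2L, 2L * n_planted, by = 2L)]
    i <- pmin(a, b)
    j <- pmax(a, b)
    if (!any(paste(i, j) %in% avoid_key)) {
      o <- order(i, j)
      return(tibble(i = as.integer(i[o]), j = as.integer(j[o])))
    }
  }
  abort("sample_planted_edges(): could not draw pairs avoiding the given set.")
}

#' Generate per-subject ROI time series
#'
#' Each ROI receives independent Gaussian noise (`noise_sd`). For every
#' planted edge (i, j) a shared standard-normal component with
#' time-varying amplitude `a(t) = noise_sd * sqrt(rho(t) / (1 - rho(t)))`
#' is added to both ROIs, so the instantaneous model correlation of the
#' pair is exactly `rho(t) = 0.9 * coupling * plogis(latent(t))`.
#' Non-planted pairs share no component. Subjects use fixed RNG
#' sub-streams of the master seed.
#'
#' @param cfg A [synth_config()].
#' @param truth A [synth_truth()] consistent with `cfg`.
#' @return A list of `n_subjects` matrices, each TR x ROI with column
#'   names `ROI001`, ...
#' @export
generate_roi_timeseries <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  if (length(truth$latent) != cfg$n_tr) {
    abort("`truth` latent length does not match `cfg$n_tr`.")
  }
  if (nrow(truth$planted) &&
    (max(truth$planted$j) > cfg$n_roi || min(truth$planted$i) < 1)) {
    abort("planted edge outside the ROI range of `cfg`.")
  }
  amp <- if (nrow(truth$rho)) {
    cfg$noise_sd * sqrt(truth$rho / (1 - truth$rho))
  } else {
    truth$rho
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  lapply(seq_len(cfg$n_subjects), function(s) {
    set.seed(derive_seed(cfg$seed, s, salt = 3L))
    x <- matrix(rnorm(cfg$n_tr * cfg$n_roi, sd = cfg$noise_sd),
      nrow = cfg$n_tr, ncol = cfg$n_roi)
    if (nrow(truth$planted)) {
      for (e in seq_len(nrow(truth$planted))) {
        shared <- amp[e, ] * rnorm(cfg$n_tr)
        x[, truth$planted$i[e]] <- x[, truth$planted$i[e]] + shared
        x[, truth$planted$j[e]] <- x[, truth$planted$j[e]] + shared
      }
    }
    colnames(x) <- sprintf("ROI%03d", seq_len(cfg$n_roi))
    x
  })
}

#' Simulate a panel of continuous raters
#'
#' Each rater is a right-continuous step function on the 1--25 slider
#' scale: the latent state is linearly rescaled to the slider range,
#' AR(1) rater noise (stationary sd `rater_noise_sd`, lag-1 0.5 between
#' consecutive presses) is added, and the slider is updated at Poisson
#' press times (`rater_press_rate` per minute). Values are rounded half
#' away from zero to the integer grid and clipped to the scale. Every
#' log starts with the initial slider position at `t = 0`.
#'
#' @param truth A [synth_truth()].
#' @param cfg A [synth_config()] (needs `n_raters >= 2`).
#' @return A tibble `rater_id`, `time_s`, `value`, sorted by rater and
#'   time.
#' @export
generate_raters <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  if (cfg$n_raters < 2L) abort("generate_raters(): need n_raters >= 2.")
  lat <- truth$latent
  span <- diff(range(lat))
  if (span == 0) abort("generate_raters(): latent state is constant.")
  v_cont <- 1 + 24 * (lat - min(lat)) / span
  duration <- cfg$n_tr * cfg$tr_s
  rate_s <- cfg$rater_press_rate / 60
  phi <- 0.5
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  logs <- lapply(seq_len(cfg$n_raters), function(k) {
    set.seed(derive_seed(cfg$seed, k, salt = 4L))
    gaps <- rexp(max(10L, stats::qpois(0.9999, duration * rate_s)),
      rate = rate_s)
    times <- c(0, cumsum(gaps))
    times <- times[times < duration]
    eps <- 0
    vals <- numeric(length(times))
    for (m in seq_along(times)) {
      innov <- rnorm(1, sd = cfg$rater_noise_sd * sqrt(1 - phi^2))
      eps <- if (m == 1L) rnorm(1, sd = cfg$rater_noise_sd) else
        phi * eps + innov
      tr_idx <- min(cfg$n_tr, floor(times[m] / cfg$tr_s) + 1L)
      vals[m] <- round_half_away(v_cont[tr_idx] + eps)
    }
    tibble(
      rater_id = sprintf("rater%02d", k),
      time_s = times,
      value = pmin(25, pmax(1, vals))
    )
  })
  dplyr::arrange(dplyr::bind_rows(logs), .data$rater_id, .data$time_s)
}

#' Simulate nuisance regressors
#'
#' Ten low-level stimulus feature series shared across subjects (six
#' continuous smoothed-noise series plus four 0/1 indicator series,
#' mirroring audiovisual annotations such as motion energy or the
#' presence of speech), and one non-negative framewise-displacement
#' series per subject.
#'
#' @param cfg A [synth_config()].
#' @param truth Optional [synth_truth()]; required when `leak = TRUE`.
#' @param leak If `TRUE`, the first feature becomes a deliberate
#'   stimulus confound: a white-noise series whose amplitude is
#'   modulated by the latent state. Added to every ROI (the returned
#'   `leak_series` attribute), it inflates windowed correlations
#'   everywhere in proportion to arousal — exactly the kind of
#'   low-level drive that confound regression must remove. Because the
#'   feature records the confound itself, OLS residualization removes
#'   it from the BOLD exactly.
#' @return A list with `features` (TR x 10 matrix, named columns) and
#'   `fd` (list of per-subject non-negative series). With
#'   `leak = TRUE` the features matrix carries the injected series as
#'   attribute `leak_series`.
#' @export
generate_nuisance <- function(cfg, truth = NULL, leak = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (leak && is.null(truth)) {
    abort("generate_nuisance(): `leak = TRUE` requires `truth`.")
  }
  cont_names <- c("hue", "saturation", "pixel_intensity", "motion_energy",
    "audio_amplitude", "luminance_change")
  ind_names <- c("speech_present", "face_present", "scene_cut",
    "music_present")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  feat <- sapply(seq_len(10L), function(f) {
    sm <- max(2, cfg$smoothness_tr / 2)
    x <- generate_latent_state(cfg$n_tr, sm, derive_seed(cfg$seed, f, 5L))
    if (f <= 6L) x else as.numeric(x > 0)
  })
  colnames(feat) <- c(cont_names, ind_names)
  if (leak) {
    set.seed(derive_seed(cfg$seed, 99L, salt = 5L))
    g <- stats::plogis(truth$latent) * rnorm(cfg$n_tr) * cfg$noise_sd
    feat[, 1L] <- g
    attr(feat, "leak_series") <- g
  }
  fd <- lapply(seq_len(cfg$n_subjects), function(s) {
    set.seed(derive_seed(cfg$seed, s, salt = 6L))
    drift <- stats::filter(rnorm(cfg$n_tr), 0.9, method = "recursive")
    0.15 * abs(as.numeric(drift)) / sd(drift) + 0.02
  })
  list(features = feat, fd = fd)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper tying the generators together: latent state,
#' planted edges, per-subject BOLD-like ROI series, rater logs, and
#' nuisance series, plus a matching [dataset_spec()].
#'
#' @param cfg A [synth_config()].
#' @param window_s Sliding-window length in seconds for the attached
#'   spec (default 45).
#' @param nuisance_leak Passed to [generate_nuisance()] as `leak`.
#' @return A `synth_dataset` list: `config`, `spec`, `truth`, `bold`,
#'   `ratings`, `nuisance`.
#' @export
simulate_dataset <- function(cfg, window_s = 45, nuisance_leak = FALSE) {
  truth <- synth_truth(cfg)
  spec <- dataset_spec(
    tr_s = cfg$tr_s, segment_tr = cfg$n_tr,
    window_tr = window_tr_from_seconds(window_s, cfg$tr_s)
  )
  structure(
    list(
      config = cfg, spec = spec, truth = truth,
      bold = generate_roi_timeseries(cfg, truth),
      ratings = generate_raters(truth, cfg),
      nuisance = generate_nuisance(cfg, truth, leak = nuisance_leak)
    ),
    class = "synth_dataset"
  )
}

#' Generate a matched pair of datasets with controllable edge overlap
#'
#' Builds two synthetic datasets whose planted arousal edge sets share
#' a controllable fraction of edges, the ground-truth analogue of two
#' movies engaging partially overlapping arousal networks. The latent
#' states of the two datasets are independent.
#'
#' @param cfg_a,cfg_b [synth_config()]s; must agree on `n_roi` and
#'   `n_planted`, may differ in TR, length, or subject count.
#' @param shared_fraction Fraction of planted edges common to both
#'   datasets (`round(shared_fraction * n_planted)` edges).
#' @param seed Seed for drawing the planted sets; each dataset keeps
#'   its own config seed for everything else.
#' @param window_s Window length in seconds for both attached specs.
#' @return A list with elements `a` and `b`, each a `synth_dataset`,
#'   plus `shared` (tibble of shared planted pairs).
#' @export
generate_dataset_pair <- function(cfg_a, cfg_b, shared_fraction,
                                  seed = 1L, window_s = 45) {
  stopifnot(inherits(cfg_a, "synth_config"), inherits(cfg_b, "synth_config"))
  if (cfg_a$n_roi != cfg_b$n_roi) {
    abort("generate_dataset_pair(): configs disagree on `n_roi`.")
  }
  if (cfg_a$n_planted != cfg_b$n_planted) {
    abort("generate_dataset_pair(): configs disagree on `n_planted`.")
  }
  assert_scalar(shared_fraction, "shared_fraction", lower = 0, upper = 1)
  n_p <- cfg_a$n_planted
  n_shared <- as.integer(round(shared_fraction * n_p))
  shared <- sample_planted_edges(cfg_a$n_roi, n_shared, seed, stream = 1L)
  shared_rois <- c(shared$i, shared$j)
  own_a <- sample_planted_edges(cfg_a$n_roi, n_p - n_shared, seed,
    avoid_rois = shared_rois, stream = 2L)
  own_b <- sample_planted_edges(cfg_b$n_roi, n_p - n_shared, seed,
    avoid = own_a, avoid_rois = shared_rois, stream = 3L)
  cfg_a$planted_edges <- dplyr::arrange(dplyr::bind_rows(shared, own_a),
    .data$i, .data$j)
  cfg_b$planted_edges <- dplyr::arrange(dplyr::bind_rows(shared, own_b),
    .data$i, .data$j)
  list(
    a = simulate_dataset(cfg_a, window_s = window_s),
    b = simulate_dataset(cfg_b, window_s = window_s),
    shared = shared
  )
}
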
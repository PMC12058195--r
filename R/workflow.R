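# End-to-end orchestration: simulate -> behavior -> dynamic FC ->
# CPM -> nulls -> network anatomy, with per-stage manifests. The
# package's functions (plus this driver) are its interface; every
# stage is also callable on its own.

#' Run the full pipeline on simulated data
#'
#' Orchestrates the complete analysis on one synthetic dataset:
#' simulate BOLD-like data and raters, build the group target
#' (resample, z-score, average, HRF, taper), optionally regress
#' nuisance series out of the BOLD data, compute dynamic FC
#' (optionally residualized on framewise displacement),
#' leave-one-subject-out CPM, a phase-randomized null for the summary
#' accuracy, and network-pair enrichment of the consensus edges.
#' Deterministic given the config and master seed.
#'
#' @param config Named list (or YAML path) with any of:
#'   `n_subjects`, `n_roi`, `n_tr`, `tr_s`, `n_planted`, `coupling`,
#'   `noise_sd`, `n_raters`, `window_s`, `alpha`, `n_perm`, `seed`,
#'   `regress_features`, `regress_fd`, `enrichment` (logical),
#'   `assignment` (path or data frame; required for enrichment when
#'   `n_roi != 122`), `output_dir` (optional; results written as
#'   CSV/JSON when given).
#' @return A `dyncpm_report` list: `config`, `isc`, `loso`, `null`,
#'   `null_p`, `enrichment` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(
    n_subjects = 8, n_roi = 30, n_tr = 200, tr_s = 1.5, n_planted = 10,
    coupling = 0.6, noise_sd = 1, n_raters = 8, window_s = 45,
    alpha = 0.01, n_perm = 20, seed = 1L,
    regress_features = FALSE, regress_fd = FALSE,
    enrichment = FALSE, assignment = NULL, output_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  scfg <- synth_config(
    n_subjects = cfg$n_subjects, n_roi = cfg$n_roi, n_tr = cfg$n_tr,
    tr_s = cfg$tr_s, n_planted = cfg$n_planted, coupling = cfg$coupling,
    noise_sd = cfg$noise_sd, n_raters = cfg$n_raters, seed = cfg$seed
  )
  ds <- simulate_dataset(scfg, window_s = cfg$window_s)
  target_obj <- build_group_target(ds$ratings, ds$spec)
  target <- target_obj$smoothed
  isc <- leave_one_out_isc(rater_panel(ds$ratings, ds$spec),
    n_perm = 1000, seed = derive_seed(cfg$seed, 1L, 20L))
  bold <- ds$bold
  if (isTRUE(cfg$regress_features)) {
    bold <- lapply(bold, regress_confounds_bold,
      nuisance = ds$nuisance$features)
  }
  fcset <- dynfc_set(bold, ds$spec)
  if (isTRUE(cfg$regress_fd)) {
    fcset$fc <- purrr::map2(fcset$fc, ds$nuisance$fd,
      function(fc, fd) regress_confounds_fc(fc, fd, ds$spec))
  }
  loso <- run_loso(fcset, target, alpha = cfg$alpha)
  nulls <- build_prediction_null(fcset, target, n_perm = cfg$n_perm,
    seed = derive_seed(cfg$seed, 2L, 20L), mode = "within",
    alpha = cfg$alpha)
  null_p <- permutation_pvalue(loso$mean_r, nulls$r[!is.na(nulls$r)],
    "greater")
  enr <- NULL
  if (isTRUE(cfg$enrichment) && nrow(loso$consensus) > 0L) {
    asn <- network_assignment(cfg$assignment, n_roi = cfg$n_roi)
    enr <- networkpair_enrichment(loso$consensus$edge, asn,
      n_perm = max(cfg$n_perm, 100L),
      seed = derive_seed(cfg$seed, 3L, 20L))
  }
  manifest <- list(
    seed = cfg$seed, edge_hash = fcset$edge_hash,
    n_subjects = scfg$n_subjects, n_roi = scfg$n_roi,
    n_tr = scfg$n_tr, window_tr = ds$spec$window_tr,
    alpha = cfg$alpha, n_perm = cfg$n_perm,
    n_failed_folds = sum(loso$folds$failed),
    n_sign_conflicts = loso$n_sign_conflicts
  )
  report <- structure(
    list(config = cfg, isc = isc, loso = loso, null = nulls,
      null_p = null_p, enrichment = enr, truth = ds$truth,
      manifest = manifest),
    class = "dyncpm_report"
  )
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

# write the report bundle as plain-text CSV/JSON files
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$loso$folds, file.path(dir, "fold_results.csv"))
  readr::write_csv(as_tibble(report$null), file.path(dir, "null_r.csv"))
  if (!is.null(report$enrichment)) {
    readr::write_csv(report$enrichment, file.path(dir, "enrichment.csv"))
  }
  jsonlite::write_json(
    c(report$manifest,
      list(mean_r = report$loso$mean_r,
        mean_rmse = report$loso$mean_rmse,
        null_p = report$null_p,
        isc_mean_r = report$isc$mean_r, isc_p = report$isc$p)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Window-size sweep
#'
#' Reruns dynamic FC + LOSO CPM for a list of window lengths in
#' seconds (converted to TRs by `round(window_s / tr_s)`), tracing
#' how predictive accuracy depends on the connectivity timescale.
#'
#' @param bold List of TR x ROI matrices.
#' @param ratings Rating-event tibble.
#' @param tr_s TR in seconds.
#' @param window_s_list Window lengths in seconds (default
#'   `c(15, 30, 45, 60, 75)`).
#' @param alpha Selection threshold.
#' @param hyper A [cpm_hyperparams()].
#' @return A tibble `window_s`, `window_tr`, `mean_r`, `mean_rmse`.
#' @export
window_sweep <- function(bold, ratings, tr_s,
                         window_s_list = c(15, 30, 45, 60, 75),
                         alpha = 0.01, hyper = cpm_hyperparams()) {
  n_tr <- nrow(bold[[1]])
  purrr::map_dfr(window_s_list, function(ws) {
    spec <- dataset_spec(tr_s = tr_s, segment_tr = n_tr,
      window_tr = window_tr_from_seconds(ws, tr_s))
    target <- build_group_target(ratings, spec)$smoothed
    fit <- run_loso(dynfc_set(bold, spec), target, alpha = alpha,
      hyper = hyper)
    tibble(window_s = ws, window_tr = spec$window_tr,
      mean_r = fit$mean_r, mean_rmse = fit$mean_rmse)
  })
}
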
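# Connectome-based predictive modeling on dynamic FC.
#
# Selection: edges whose Fisher-z FC/target correlations differ from
# zero across training subjects (one-sample t-test, p < alpha), signed
# by the mean correlation. Regression: radial-basis support vector
# regression on the selected edges, trained on all training subjects'
# windows with the group target tiled per subject. Evaluation:
# leave-one-subject-out within a dataset; a single consensus-feature
# model across datasets.

#' Hyperparameters of the CPM regressor
#'
#' Radial-basis support vector regression with the usual library
#' defaults: `cost = 1`, `epsilon = 0.1`, kernel scale
#' `gamma = 1 / n_features` on standardized features. Because
#' consecutive windows overlap heavily, the trainer thins the stacked
#' training windows to at most `max_train_rows` evenly spaced rows (default 600) — a
#' deterministic subsample that loses little information at the
#' window lengths used here and keeps the quadratic-cost SVR fast.
#'
#' @param cost SVR cost parameter.
#' @param epsilon Epsilon-insensitive tube width.
#' @param gamma RBF kernel scale; `NULL` means `1 / n_features`.
#' @param max_train_rows Cap on stacked training windows (>= 100).
#' @return A `cpm_hyperparams` list.
#' @export
cpm_hyperparams <- function(cost = 1, epsilon = 0.1, gamma = NULL,
                            max_train_rows = 600L) {
  assert_scalar(cost, "cost", lower = 1e-9)
  assert_scalar(epsilon, "epsilon", lower = 0)
  if (!is.null(gamma)) assert_scalar(gamma, "gamma", lower = 1e-12)
  assert_count(max_train_rows, "max_train_rows", min = 100L)
  structure(
    list(cost = cost, epsilon = epsilon, gamma = gamma,
      max_train_rows = as.integer(max_train_rows)),
    class = "cpm_hyperparams"
  )
}

#' Select behavior-correlated edges
#'
#' For each training subject and edge, the Pearson correlation between
#' the edge's Fisher-z FC series and the target; the per-subject
#' correlations are Fisher z-transformed and tested against zero
#' across subjects (one-sample two-tailed t-test). Edges with
#' `p < alpha` are kept, signed by the mean transformed correlation.
#'
#' @param fc_list List of edges x TR matrices (training subjects).
#' @param target Numeric target series, length `ncol(fc)`.
#' @param alpha Selection threshold (default 0.01).
#' @param fisher Apply the Fisher transform to the per-subject
#'   correlations before the t-test (default `TRUE`).
#' @return A `feature_mask`: tibble `edge`, `sign`, `mean_z`, `p` of
#'   the selected edges, with `alpha` and the edge hash as attributes.
#' @export
select_features <- function(fc_list, target, alpha = 0.01, fisher = TRUE) {
  stopifnot(is.list(fc_list))
  if (length(fc_list) < 2L) {
    abort("select_features(): need >= 2 training subjects for the t-test.")
  }
  rmat <- edge_target_corr(fc_list, target)
  if (fisher) rmat <- fisher_z(rmat, eps = 1e-12)
  mask_from_corr(rmat, alpha,
    edge_hash = attr(fc_list[[1]], "edge_hash"),
    n_edges_total = nrow(fc_list[[1]]))
}

# edges x subjects matrix of Pearson correlations between each edge's
# FC series and the target, via one matrix-vector product per subject
edge_target_corr <- function(fc_list, target) {
  tz <- zscore(target)
  n <- length(tz)
  vapply(fc_list, function(fc) {
    num <- as.numeric(fc %*% tz)
    mu <- rowMeans(fc)
    ss <- rowSums(fc^2) - n * mu^2
    sx <- sqrt(pmax(ss, 0) / (n - 1))
    r <- num / ((n - 1) * sx)
    r[sx == 0] <- 0
    pmin(pmax(r, -1), 1)
  }, numeric(nrow(fc_list[[1]])))
}

# one-sample two-tailed t-test per edge (rows) across subjects (cols)
mask_from_corr <- function(rmat, alpha, edge_hash = NULL,
                           n_edges_total = nrow(rmat)) {
  assert_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  n <- ncol(rmat)
  m <- rowMeans(rmat)
  s <- sqrt(pmax(0, (rowSums(rmat^2) - n * m^2) / (n - 1)))
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  keep <- which(p < alpha)
  out <- tibble(
    edge = keep,
    sign = as.integer(sign(m[keep])),
    mean_z = m[keep],
    p = p[keep]
  )
  attr(out, "alpha") <- alpha
  attr(out, "edge_hash") <- edge_hash
  attr(out, "n_edges_total") <- n_edges_total
  class(out) <- c("feature_mask", class(out))
  out
}

# stack selected-edge windows of several subjects into a design matrix
stack_features <- function(fc_list, edges) {
  do.call(rbind, lapply(fc_list, function(fc) t(fc[edges, , drop = FALSE])))
}

#' Fit the SVR on training subjects and predict a held-out subject
#'
#' Features are standardized with training-set statistics only (the
#' frozen scaler is applied to the test subject), stacked across
#' training subjects with the group target tiled, thinned to
#' `max_train_rows`, and fed to radial-basis
#' [e1071::svm()] (eps-regression). Deterministic given inputs and
#' hyperparameters.
#'
#' @param fc_list Training subjects' edges x TR matrices.
#' @param target Group target series (length = TRs).
#' @param mask A [select_features()] mask (non-empty).
#' @param test_fc Held-out subject's edges x TR matrix (or `NULL` to
#'   return the fitted model only).
#' @param hyper A [cpm_hyperparams()].
#' @return A list: `model` (class `cpm_fit`: svm fit + scaler + mask +
#'   hyperparameters) and `prediction` (numeric series or `NULL`).
#' @export
fit_predict <- function(fc_list, target, mask, test_fc = NULL,
                        hyper = cpm_hyperparams()) {
  if (nrow(mask) == 0L) {
    abort("fit_predict(): empty feature mask.", class = "dyncpm_no_features")
  }
  x <- stack_features(fc_list, mask$edge)
  y <- rep(target, times = length(fc_list))
  if (nrow(x) > hyper$max_train_rows) {
    idx <- unique(round(seq(1L, nrow(x), length.out = hyper$max_train_rows)))
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sg, "/")
  gamma <- hyper$gamma %||% (1 / ncol(xs))
  # a (near-)constant target leaves every point inside the epsilon
  # tube: no support vectors, so the model is the constant mean
  const <- if (sd(y) == 0) mean(y) else NULL
  fit <- if (is.null(const)) {
    e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
      cost = hyper$cost, epsilon = hyper$epsilon, gamma = gamma,
      scale = FALSE)
  } else {
    NULL
  }
  if (!is.null(fit) && fit$tot.nSV == 0L) {
    const <- mean(y)
    fit <- NULL
  }
  model <- structure(
    list(svm = fit, const = const, mu = mu, sigma = sg, mask = mask,
      hyper = hyper, gamma = gamma, edge_hash = attr(mask, "edge_hash")),
    class = "cpm_fit"
  )
  prediction <- if (!is.null(test_fc)) predict_cpm(model, test_fc) else NULL
  list(model = model, prediction = prediction)
}

#' Predict a subject's target series from a fitted CPM
#' @param model A `cpm_fit` from [fit_predict()].
#' @param fc Edges x TR matrix of the subject to predict.
#' @return Predicted series (one value per TR).
#' @export
predict_cpm <- function(model, fc) {
  test_hash <- attr(fc, "edge_hash")
  if (!is.null(test_hash) && !is.null(model$edge_hash) &&
    !identical(test_hash, model$edge_hash)) {
    abort("predict_cpm(): edge-index hash mismatch between model and data.")
  }
  if (!is.null(model$const)) {
    return(rep(model$const, ncol(fc)))
  }
  xt <- t(fc[model$mask$edge, , drop = FALSE])
  xt <- sweep(sweep(xt, 2L, model$mu, "-"), 2L, model$sigma, "/")
  as.numeric(predict(model$svm, xt))
}

#' Score a predicted series against the group target
#'
#' Accuracy is the Pearson correlation; error is the RMSE after
#' z-scoring the prediction with its own mean/sd (the target is
#' already z-scaled), so RMSE is on the standardized scale. A constant
#' prediction has undefined correlation and is recorded as `r = 0`
#' with `degenerate = TRUE`.
#'
#' @param pred Predicted series.
#' @param target Target series (z-scored scale).
#' @param standardize_pred z-score the prediction before RMSE
#'   (default `TRUE`; set `FALSE` for raw-scale RMSE).
#' @return A tibble with `r`, `rmse`, `degenerate`.
#' @export
score_prediction <- function(pred, target, standardize_pred = TRUE) {
  stopifnot(length(pred) == length(target))
  degenerate <- sd(pred) == 0
  r <- if (degenerate) 0 else cor(pred, target)
  ps <- if (standardize_pred) {
    if (degenerate) rep(0, length(pred)) else zscore(pred)
  } else {
    pred
  }
  tibble(r = r, rmse = sqrt(mean((ps - target)^2)), degenerate = degenerate)
}

#' Leave-one-subject-out cross-validated CPM
#'
#' In every fold the held-out subject contributes to neither feature
#' selection nor training. Fold accuracies are summarized by the
#' Fisher-z mean correlation and mean RMSE. The consensus mask is the
#' set of edges selected in *every* fold with a consistent sign (edges
#' with conflicting fold signs are dropped and counted).
#'
#' @param fcset A [dynfc_set()] with >= 3 subjects (or a plain list of
#'   edges x TR matrices).
#' @param target Group target series.
#' @param alpha Selection threshold.
#' @param hyper A [cpm_hyperparams()].
#' @return A `cpm_loso` object: `folds` tibble (`subject`, `r`,
#'   `rmse`, `n_features`, `failed`), `mean_r`, `mean_rmse`,
#'   `consensus` (signed tibble `edge`, `sign`), `n_sign_conflicts`,
#'   plus settings.
#' @export
run_loso <- function(fcset, target, alpha = 0.01,
                     hyper = cpm_hyperparams()) {
  fc_list <- if (inherits(fcset, "dynfc_set")) fcset$fc else fcset
  subjects <- if (inherits(fcset, "dynfc_set")) fcset$subjects else
    (names(fc_list) %||% sprintf("sub%02d", seq_along(fc_list)))
  n <- length(fc_list)
  if (n < 3L) abort("run_loso(): need >= 3 subjects.")
  # per-subject edge/target correlations computed once; each fold
  # tests the N-1 training columns (the held-out subject never enters)
  zmat <- fisher_z(edge_target_corr(fc_list, target), eps = 1e-12)
  folds <- vector("list", n)
  masks <- vector("list", n)
  for (k in seq_len(n)) {
    mask <- mask_from_corr(zmat[, -k, drop = FALSE], alpha,
      edge_hash = attr(fc_list[[1]], "edge_hash"))
    masks[[k]] <- mask
    if (nrow(mask) == 0L) {
      folds[[k]] <- tibble(subject = subjects[k], r = NA_real_,
        rmse = NA_real_, n_features = 0L, failed = TRUE)
      next
    }
    fp <- fit_predict(fc_list[-k], target, mask, test_fc = fc_list[[k]],
      hyper = hyper)
    sc <- score_prediction(fp$prediction, target)
    folds[[k]] <- tibble(subject = subjects[k], r = sc$r, rmse = sc$rmse,
      n_features = nrow(mask), failed = FALSE)
  }
  folds <- dplyr::bind_rows(folds)
  valid <- !folds$failed
  consensus <- consensus_mask(masks)
  structure(
    list(
      folds = folds,
      mean_r = if (any(valid)) mean_r_fisher(folds$r[valid]) else NA_real_,
      mean_rmse = if (any(valid)) mean(folds$rmse[valid]) else NA_real_,
      consensus = consensus$mask,
      n_sign_conflicts = consensus$n_conflicts,
      alpha = alpha, hyper = hyper,
      n_subjects = n,
      edge_hash = attr(fc_list[[1]], "edge_hash")
    ),
    class = "cpm_loso"
  )
}

# intersection of fold masks with sign consistency
consensus_mask <- function(masks) {
  non_empty <- masks[vapply(masks, nrow, integer(1)) > 0L]
  if (length(non_empty) < length(masks) || length(non_empty) == 0L) {
    return(list(mask = tibble(edge = integer(), sign = integer()),
      n_conflicts = 0L))
  }
  common <- Reduce(intersect, lapply(masks, function(m) m$edge))
  if (length(common) == 0L) {
    return(list(mask = tibble(edge = integer(), sign = integer()),
      n_conflicts = 0L))
  }
  signs <- vapply(masks, function(m) {
    m$sign[match(common, m$edge)]
  }, integer(length(common)))
  signs <- matrix(signs, nrow = length(common))
  consistent <- apply(signs, 1L, function(s) all(s == s[1]))
  list(
    mask = tibble(edge = as.integer(common[consistent]),
      sign = as.integer(signs[consistent, 1])) |>
      dplyr::arrange(.data$edge),
    n_conflicts = sum(!consistent)
  )
}

#' Across-dataset (and multi-dataset) CPM generalization
#'
#' Fits one model on all training subjects of one or more datasets,
#' restricted to a fixed feature set (typically the consensus mask of
#' within-dataset cross-validation, or an overlap network), and
#' evaluates it on every subject of an unseen dataset against that
#' dataset's own group target.
#'
#' @param train_sets A [dynfc_set()] or list of them.
#' @param train_targets Target series, one per training dataset.
#' @param test_set A [dynfc_set()] of the held-out dataset.
#' @param test_target The held-out dataset's group target.
#' @param mask A `feature_mask` or consensus tibble (`edge` column).
#' @param hyper A [cpm_hyperparams()].
#' @return A `cpm_cross` object: per-subject tibble (`subject`, `r`,
#'   `rmse`), `mean_r`, `mean_rmse`, `predictions` (list), `group_r`
#'   (correlation of the subject-averaged prediction with the target).
#' @export
run_cross_dataset <- function(train_sets, train_targets, test_set,
                              test_target, mask,
                              hyper = cpm_hyperparams()) {
  if (inherits(train_sets, "dynfc_set")) train_sets <- list(train_sets)
  if (is.numeric(train_targets)) train_targets <- list(train_targets)
  stopifnot(length(train_sets) == length(train_targets))
  if (nrow(mask) == 0L) {
    abort("run_cross_dataset(): empty feature set.",
      class = "dyncpm_no_features")
  }
  hashes <- c(vapply(train_sets, function(s) s$edge_hash, character(1)),
    test_set$edge_hash)
  if (length(unique(hashes)) != 1L) {
    abort("run_cross_dataset(): edge-index hash mismatch across datasets.")
  }
  fc_all <- unlist(lapply(train_sets, function(s) s$fc), recursive = FALSE)
  # tile each dataset's target over its own subjects
  y_all <- unlist(purrr::map2(train_sets, train_targets,
    function(s, tg) rep(tg, times = length(s$fc))))
  x <- do.call(rbind, lapply(fc_all, function(fc) {
    t(fc[mask$edge, , drop = FALSE])
  }))
  if (nrow(x) > hyper$max_train_rows) {
    idx <- unique(round(seq(1L, nrow(x), length.out = hyper$max_train_rows)))
    x <- x[idx, , drop = FALSE]
    y_all <- y_all[idx]
  }
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sg, "/")
  gamma <- hyper$gamma %||% (1 / ncol(xs))
  const <- if (sd(y_all) == 0) mean(y_all) else NULL
  fit <- if (is.null(const)) {
    e1071::svm(xs, y_all, type = "eps-regression", kernel = "radial",
      cost = hyper$cost, epsilon = hyper$epsilon, gamma = gamma,
      scale = FALSE)
  } else {
    NULL
  }
  if (!is.null(fit) && fit$tot.nSV == 0L) {
    const <- mean(y_all)
    fit <- NULL
  }
  model <- structure(
    list(svm = fit, const = const, mu = mu, sigma = sg,
      mask = tibble(edge = mask$edge), hyper = hyper, gamma = gamma,
      edge_hash = test_set$edge_hash),
    class = "cpm_fit"
  )
  preds <- lapply(test_set$fc, function(fc) predict_cpm(model, fc))
  scores <- purrr::map2_dfr(preds, test_set$subjects, function(p, id) {
    dplyr::mutate(score_prediction(p, test_target), subject = id,
      .before = 1L)
  })
  structure(
    list(
      subjects = scores[, c("subject", "r", "rmse")],
      mean_r = mean_r_fisher(scores$r),
      mean_rmse = mean(scores$rmse),
      predictions = preds,
      group_r = group_average_prediction(preds, test_target),
      model = model
    ),
    class = "cpm_cross"
  )
}

#' Correlation of the group-average prediction with the group target
#'
#' Averages the per-subject predicted series elementwise and
#' correlates the average with the target; subject-specific noise
#' cancels in the average, so this usually exceeds the typical
#' individual accuracy.
#'
#' @param predictions List of per-subject predicted series (>= 2).
#' @param target Group target series.
#' @return Pearson r (0 with a warning if the average is constant).
#' @export
group_average_prediction <- function(predictions, target) {
  stopifnot(is.list(predictions))
  if (length(predictions) < 2L) {
    abort("group_average_prediction(): need >= 2 subjects.")
  }
  lens <- lengths(predictions)
  if (any(lens != length(target))) {
    abort("group_average_prediction(): length mismatch with target.")
  }
  avg <- Reduce(`+`, predictions) / length(predictions)
  if (sd(avg) == 0) {
    warn("group_average_prediction(): constant average prediction; r = 0.")
    return(0)
  }
  cor(avg, target)
}

#' Paired comparison of two sets of per-fold accuracies
#'
#' Two-tailed paired t-test on the Fisher z-transformed fold
#' correlations (e.g. the same folds scored under two different
#' models).
#'
#' @param r_a,r_b Equal-length per-fold correlation vectors (n >= 3).
#' @return A tibble `t`, `df`, `p`, `mean_diff_z`, `degenerate`.
#' @export
paired_fold_comparison <- function(r_a, r_b) {
  stopifnot(length(r_a) == length(r_b))
  n <- length(r_a)
  if (n < 3L) abort("paired_fold_comparison(): need n >= 3 pairs.")
  d <- fisher_z(r_a) - fisher_z(r_b)
  if (sd(d) == 0) {
    t_val <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    return(tibble(t = t_val, df = n - 1L,
      p = if (t_val == 0) 1 else 0,
      mean_diff_z = mean(d), degenerate = TRUE))
  }
  tt <- t.test(d)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff_z = mean(d), degenerate = FALSE)
}
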
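# Feature selection, SVR fitting, scoring, LOSO, and cross-dataset
# generalization.

make_fc_fixture <- function(seed = 7, n_subjects = 8, n_roi = 12,
                            n_tr = 300, coupling = 0.8) {
  cfg <- small_cfg(seed = seed, n_subjects = n_subjects, n_roi = n_roi,
    n_tr = n_tr, coupling = coupling)
  truth <- synth_truth(cfg)
  spec <- small_spec(n_tr = n_tr)
  list(
    cfg = cfg, truth = truth, spec = spec,
    fcset = dynfc_set(generate_roi_timeseries(cfg, truth), spec),
    target = taper_smooth(truth$latent, spec)
  )
}

fx <- make_fc_fixture()

test_that("selection finds planted edges with the right sign", {
  sel <- select_features(fx$fcset$fc, fx$target, alpha = 0.01)
  planted <- fx$truth$planted$edge
  expect_true(all(planted %in% sel$edge))
  expect_true(all(sel$sign[match(planted, sel$edge)] == 1L))
  expect_error(select_features(fx$fcset$fc[1], fx$target), ">= 2")
})

test_that("an edge locked to minus the target is selected negative", {
  fc_list <- lapply(1:4, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(10 * 300), nrow = 10)
    m[3, ] <- -fx$target + rnorm(300, sd = 0.1)
    m
  })
  sel <- select_features(fc_list, fx$target, alpha = 0.01)
  expect_true(3L %in% sel$edge)
  expect_equal(sel$sign[sel$edge == 3L], -1L)
})

test_that("the SVR handles constant targets and refits sensibly", {
  mask <- select_features(fx$fcset$fc, fx$target)
  const <- fit_predict(fx$fcset$fc[-1], rep(0.5, 300), mask,
    test_fc = fx$fcset$fc[[1]])
  expect_lt(max(abs(const$prediction - 0.5)), 1e-3)
  # predicting a training subject works at least as well as chance
  fp <- fit_predict(fx$fcset$fc[-1], fx$target, mask,
    test_fc = fx$fcset$fc[[2]])
  expect_gt(cor(fp$prediction, fx$target), 0.3)
  empty <- mask[0, ]
  attr(empty, "edge_hash") <- attr(mask, "edge_hash")
  expect_error(fit_predict(fx$fcset$fc[-1], fx$target, empty),
    class = "dyncpm_no_features")
})

test_that("prediction scoring matches closed forms on z-scored series", {
  tz <- zscore(sin(seq_len(100) / 7))
  exact <- score_prediction(tz, tz)
  expect_equal(exact$r, 1)
  expect_equal(exact$rmse, 0, tolerance = 1e-12)
  anti <- score_prediction(-tz, tz)
  expect_equal(anti$r, -1)
  # z-scored antiphase: rmse = 2 * sqrt((n-1)/n)
  expect_equal(anti$rmse, 2 * sqrt(99 / 100), tolerance = 1e-12)
  set.seed(8)
  noisy <- score_prediction(tz + rnorm(100), tz, standardize_pred = FALSE)
  expect_equal(noisy$rmse, 1, tolerance = 0.2)
  flat <- score_prediction(rep(2, 100), tz)
  expect_true(flat$degenerate)
  expect_equal(flat$r, 0)
})

test_that("LOSO recovers the planted network and never leaks the fold", {
  fit <- run_loso(fx$fcset, fx$target)
  expect_gt(fit$mean_r, 0.3)
  # consensus is contained in every fold's own selection
  for (k in seq_len(fx$cfg$n_subjects)) {
    mk <- select_features(fx$fcset$fc[-k], fx$target, alpha = 0.01)
    expect_true(all(fit$consensus$edge %in% mk$edge))
  }
  # fold masks are reproducible from the N-1 subjects alone (no
  # leakage of the held-out subject into selection)
  m1 <- select_features(fx$fcset$fc[-1], fx$target)
  fit1 <- fit_predict(fx$fcset$fc[-1], fx$target, m1,
    test_fc = fx$fcset$fc[[1]])
  expect_equal(fit$folds$r[1],
    score_prediction(fit1$prediction, fx$target)$r)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("Fisher-z fold summaries are exactly zero for symmetric folds", {
  expect_equal(mean_r_fisher(c(-0.5, 0.5)), 0)
  expect_equal(mean_r_fisher(c(-0.8, -0.2, 0.2, 0.8)), 0)
})

test_that("without coupling the consensus network is essentially empty", {
  sizes <- vapply(1:20, function(s) {
    f <- make_fc_fixture(seed = 3000 + s, n_subjects = 6, n_roi = 10,
      n_tr = 200, coupling = 0)
    masks <- lapply(seq_len(6), function(k) {
      select_features(f$fcset$fc[-k], f$target, alpha = 0.01)
    })
    nrow(dyncpm:::consensus_mask(masks)$mask)
  }, numeric(1))
  expect_gte(mean(sizes <= 5), 0.9)
})

test_that("paired fold comparisons match the hand-computed t statistic", {
  same <- paired_fold_comparison(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  hand <- paired_fold_comparison(c(0.5, 0.6, 0.7), c(0.4, 0.5, 0.6))
  d <- atanh(c(0.5, 0.6, 0.7)) - atanh(c(0.4, 0.5, 0.6))
  expect_equal(hand$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  expect_equal(hand$t, 10.45, tolerance = 0.01)
  expect_equal(hand$df, 2)
  sym <- paired_fold_comparison(c(0.2, 0.5, 0.8), c(0.8, 0.5, 0.2))
  expect_equal(sym$t, 0, tolerance = 1e-12)
})

test_that("group-average predictions beat typical individual accuracy", {
  tz <- zscore(generate_latent_state(200, 8, seed = 21))
  set.seed(22)
  preds <- lapply(1:10, function(k) tz + rnorm(200, sd = 1.5))
  g <- group_average_prediction(preds, tz)
  indiv <- vapply(preds, cor, numeric(1), y = tz)
  expect_gt(g, median(indiv))
  expect_equal(group_average_prediction(list(tz, tz), tz), 1)
  expect_warning(
    flat <- group_average_prediction(list(tz, -tz), tz),
    "constant")
  expect_equal(flat, 0)
})

test_that("cross-dataset prediction transfers through shared edges", {
  pair_cfg <- function(seed) small_cfg(seed = seed, n_subjects = 5,
    n_roi = 16, n_tr = 250, n_planted = 5, n_raters = 2)
  pair <- generate_dataset_pair(pair_cfg(31), pair_cfg(32),
    shared_fraction = 1, seed = 33, window_s = 45)
  spec <- pair$a$spec
  fca <- dynfc_set(pair$a$bold, spec)
  fcb <- dynfc_set(pair$b$bold, spec)
  ta <- taper_smooth(pair$a$truth$latent, spec)
  tb <- taper_smooth(pair$b$truth$latent, spec)
  mask <- select_features(fca$fc, ta, alpha = 0.01)
  cr <- run_cross_dataset(fca, ta, fcb, tb, mask)
  expect_gt(cr$mean_r, 0)
  expect_equal(nrow(tidy(cr)), 5L)
  expect_true(is.finite(cr$group_r))
  # mismatched parcellations are refused
  fc_small <- dynfc_set(lapply(pair$b$bold, function(m) m[, 1:10]), spec)
  expect_error(run_cross_dataset(fca, ta, fc_small, tb, mask), "hash")
  expect_error(run_cross_dataset(fca, ta, fcb, tb, mask[0, ]),
    class = "dyncpm_no_features")
})
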
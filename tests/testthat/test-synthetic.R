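# Generators: determinism, normalization, and the planted-signal
# structure the downstream analysis assumes.

test_that("latent state is deterministic, standardized, and validated", {
  a <- generate_latent_state(500, 10, seed = 1)
  b <- generate_latent_state(500, 10, seed = 1)
  expect_identical(a, b)
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_equal(sd(a), 1, tolerance = 1e-12)
  expect_error(generate_latent_state(0, 10), "integer")
  expect_error(generate_latent_state(500, -1), "smoothness")
  expect_error(generate_latent_state(50, 10), "10 \\* smoothness")
})

test_that("latent autocorrelation increases with the kernel sd", {
  ac <- function(sm) {
    mean(vapply(1:50, function(s) {
      x <- generate_latent_state(300, sm, seed = s)
      cor(x[-1], x[-length(x)])
    }, numeric(1)))
  }
  expect_gt(ac(20), ac(2))
})

test_that("ROI series are deterministic and planted edges carry the signal", {
  cfg <- small_cfg(seed = 5, n_subjects = 16, n_roi = 10, n_tr = 500)
  truth <- synth_truth(cfg)
  b1 <- generate_roi_timeseries(cfg, truth)
  b2 <- generate_roi_timeseries(cfg, truth)
  expect_identical(b1, b2)
  spec <- small_spec(n_tr = 500)
  fc <- lapply(b1, compute_dynfc, spec = spec)
  lat_s <- taper_smooth(truth$latent, spec)
  # mean windowed planted-edge FC tracks the taper-smoothed latent
  tracked <- mean_edge_fc(fc, truth$planted$edge)
  expect_gt(cor(tracked, lat_s), 0.3)
  # realized windowed correlation follows the target rho profile
  rho_s <- taper_smooth(truth$rho[1, ], spec)
  realized <- rowMeans(sapply(fc, function(m) {
    tanh(m[truth$planted$edge[1], ])
  }))
  expect_gt(cor(realized, rho_s, method = "spearman"), 0.5)
})

test_that("coupling zero leaves planted pairs uncorrelated", {
  cfg <- small_cfg(seed = 9, coupling = 0, n_subjects = 20, n_roi = 10,
    n_tr = 300)
  truth <- synth_truth(cfg)
  bold <- generate_roi_timeseries(cfg, truth)
  spec <- small_spec()
  fc <- lapply(bold, compute_dynfc, spec = spec)
  planted_r <- sapply(fc, function(m) {
    mean(tanh(m[truth$planted$edge, ]))
  })
  expect_lt(mean(abs(planted_r)), 0.1)
})

test_that("non-planted edges stay near zero correlation on average", {
  cfg <- small_cfg(seed = 3, n_subjects = 20, n_roi = 10, n_tr = 300)
  truth <- synth_truth(cfg)
  bold <- generate_roi_timeseries(cfg, truth)
  spec <- small_spec()
  fc <- lapply(bold, compute_dynfc, spec = spec)
  others <- setdiff(seq_len(n_edges(cfg$n_roi)), truth$planted$edge)
  mean_r <- mean(sapply(fc, function(m) mean(tanh(m[others, ]))))
  expect_lt(abs(mean_r), 0.05)
})

test_that("planted edges outside the parcellation are rejected", {
  cfg <- small_cfg(n_roi = 10)
  truth <- synth_truth(cfg)
  truth$planted$j[1] <- 99L
  expect_error(generate_roi_timeseries(cfg, truth), "ROI range")
  expect_error(
    synth_config(n_roi = 10, planted_edges = data.frame(i = 1, j = 11)),
    "planted_edges")
})

test_that("rater logs are clipped, sorted, independent, and deterministic", {
  cfg <- small_cfg(seed = 2, n_raters = 4)
  truth <- synth_truth(cfg)
  r1 <- generate_raters(truth, cfg)
  r2 <- generate_raters(truth, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$value >= 1 & r1$value <= 25))
  expect_true(all(r1$value == floor(r1$value)))
  by_rater <- split(r1, r1$rater_id)
  expect_true(all(vapply(by_rater, function(d) !is.unsorted(d$time_s),
    logical(1))))
  expect_true(all(vapply(by_rater, function(d) d$time_s[1] == 0,
    logical(1))))
  # independent noise streams: raters differ
  v1 <- by_rater[[1]]$value
  v2 <- by_rater[[2]]$value
  expect_false(identical(v1[seq_len(min(length(v1), length(v2)))],
    v2[seq_len(min(length(v1), length(v2)))]))
})

test_that("a fast noiseless rater reproduces the latent state", {
  cfg <- small_cfg(seed = 4, rater_noise_sd = 0, rater_press_rate = 600,
    n_raters = 2)
  truth <- synth_truth(cfg)
  logs <- generate_raters(truth, cfg)
  spec <- small_spec(n_tr = cfg$n_tr, tr_s = cfg$tr_s)
  series <- resample_ratings(logs, spec)
  one <- dplyr::filter(series, rater_id == "rater01")
  expect_gt(cor(one$value, truth$latent), 0.95)
})

test_that("dataset pairs share the requested fraction of planted edges", {
  key <- function(p) paste(p$i, p$j)
  cfg <- function(seed) small_cfg(seed = seed, n_subjects = 2,
    n_roi = 80, n_tr = 100, n_planted = 40, smoothness_tr = 5,
    n_raters = 2)
  full <- generate_dataset_pair(cfg(1), cfg(2), shared_fraction = 1,
    seed = 3, window_s = 30)
  expect_identical(key(full$a$truth$planted), key(full$b$truth$planted))
  none <- generate_dataset_pair(cfg(1), cfg(2), shared_fraction = 0,
    seed = 3, window_s = 30)
  expect_length(intersect(key(none$a$truth$planted),
    key(none$b$truth$planted)), 0)
  half <- generate_dataset_pair(cfg(1), cfg(2), shared_fraction = 0.5,
    seed = 3, window_s = 30)
  expect_length(intersect(key(half$a$truth$planted),
    key(half$b$truth$planted)), 20)
  bad <- small_cfg(n_roi = 40, n_subjects = 2, n_tr = 100,
    n_planted = 3, smoothness_tr = 5)
  expect_error(generate_dataset_pair(cfg(1), bad, 0.5), "n_roi")
})

test_that("nuisance series have the advertised structure", {
  cfg <- small_cfg(seed = 6, n_subjects = 3)
  nuis <- generate_nuisance(cfg)
  expect_equal(dim(nuis$features), c(cfg$n_tr, 10L))
  ind <- nuis$features[, 7:10]
  expect_true(all(ind %in% c(0, 1)))
  expect_length(nuis$fd, 3L)
  expect_true(all(vapply(nuis$fd, function(f) all(f >= 0), logical(1))))
})

test_that("a leaked stimulus feature is removed by confound regression", {
  cfg <- small_cfg(seed = 8, n_subjects = 6, n_roi = 10, n_tr = 300)
  truth <- synth_truth(cfg)
  bold <- generate_roi_timeseries(cfg, truth)
  nuis <- generate_nuisance(cfg, truth, leak = TRUE)
  g <- attr(nuis$features, "leak_series")
  # inject the arousal-modulated global confound into every ROI
  leaked <- lapply(bold, function(x) x + g)
  spec <- small_spec()
  lat_s <- taper_smooth(truth$latent, spec)
  others <- setdiff(seq_len(n_edges(cfg$n_roi)), truth$planted$edge)
  track <- function(b) {
    fc <- lapply(b, compute_dynfc, spec = spec)
    cor(mean_edge_fc(fc, others), lat_s)
  }
  inflated <- track(leaked)
  expect_gt(inflated, 0.3)  # the confound fakes FC/arousal coupling
  clean <- lapply(leaked, regress_confounds_bold,
    nuisance = nuis$features)
  expect_lt(track(clean), inflated)
  expect_lt(abs(track(clean)), 0.25)
})
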
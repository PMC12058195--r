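# Rating logs -> model target: resampling, normalization, ISC,
# HRF, taper smoothing, valence segmentation.

test_that("resampling carries the slider value forward to TR ends", {
  spec <- dataset_spec(tr_s = 1.5, segment_tr = 4, window_tr = 3)
  const <- resample_ratings(rating_events(0, 13), spec)
  expect_equal(const$value, c(13, 13, 13, 13))
  stepped <- resample_ratings(rating_events(c(0, 3.1), c(10, 20)), spec)
  expect_equal(stepped$value, c(10, 10, 20, 20))
  expect_error(resample_ratings(rating_events(numeric(), numeric()), spec),
    "no events")
  expect_error(
    resample_ratings(rating_events(1.0, 13), spec),
    "initial position")
  expect_warning(
    late <- resample_ratings(rating_events(c(0, 99), c(10, 20)), spec),
    "ignored")
  expect_equal(late$value, rep(10, 4))
})

test_that("normalization uses the n-1 convention and rejects constants", {
  expect_equal(normalize_and_concat(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(normalize_and_concat(c(5, 5, 5)), "constant")
  z <- normalize_and_concat(list(c(1, 2), c(3, 4)))
  expect_equal(z, (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)))
  expect_equal(sd(z), 1)
  # idempotence
  x <- rnorm(50)
  expect_equal(normalize_and_concat(normalize_and_concat(x)),
    normalize_and_concat(x), tolerance = 1e-12)
  # cropping drops TRs before z-scoring
  zc <- normalize_and_concat(c(1, 2, 100, 3), crop_tr = 3)
  expect_equal(length(zc), 3)
  expect_equal(mean(zc), 0, tolerance = 1e-12)
})

test_that("group averaging is the elementwise mean of z-scored raters", {
  z <- zscore(c(1, 3, 2, 5, 4))
  expect_equal(group_average(rbind(z, z)), z)
  expect_equal(group_average(rbind(z, -z)), rep(0, 5))
  m <- rbind(a = c(1, 2, 3), b = c(4, 6, 5), c = c(0, -1, 1))
  expect_equal(group_average(m), colMeans(m))
  expect_error(group_average(m[1, , drop = FALSE]), "2 raters")
})

test_that("leave-one-out ISC matches identity and simulation oracles", {
  z <- zscore(seq_len(20) + sin(seq_len(20)))
  panel <- rbind(r1 = z, r2 = z, r3 = z)
  res <- leave_one_out_isc(panel, n_perm = 200, seed = 1)
  expect_equal(res$raters$r, rep(1, 3), tolerance = 1e-12)
  expect_gt(res$mean_r, 0.999999)
  # coherent synthetic panel: strong ISC, p at the permutation floor
  lat <- generate_latent_state(200, 8, seed = 2)
  set.seed(42)
  panel2 <- t(sapply(1:10, function(k) zscore(lat + rnorm(200, sd = 0.5))))
  res2 <- leave_one_out_isc(panel2, n_perm = 10000, seed = 3)
  expect_gt(res2$mean_r, 0.5)
  expect_lte(res2$p, 0.001)
})

test_that("a rater with a degenerate leave-one-out mean is named", {
  z <- zscore(seq_len(10) + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0.1, 0, -0.1))
  panel <- rbind(r1 = z, r2 = -z, r3 = rev(z))
  # r1 and r2 cancel exactly, so rater 3 sees a constant group mean
  expect_error(leave_one_out_isc(panel, n_perm = 10, seed = 1), "r3")
})

test_that("the sign-flip null matches its enumeration on balanced panels", {
  # alternating +a/-a similarities: flipped means are sums of 4 iid
  # signs, so P(flipped mean >= 0) = 11/16 by enumeration
  zs <- c(0.4, -0.4, 0.4, -0.4)
  n_perm <- 4000
  old <- if (exists(".Random.seed")) .Random.seed else NULL
  set.seed(9)
  flips <- matrix(sample(c(-1, 1), n_perm * 4, replace = TRUE), n_perm, 4)
  p_mc <- (1 + sum((flips %*% zs) / 4 >= 0)) / (1 + n_perm)
  expect_equal(p_mc, 11 / 16, tolerance = 0.03)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
})

test_that("ISC on independent raters is honestly null", {
  res <- vapply(1:50, function(s) {
    set.seed(s + 1000)
    panel <- t(sapply(1:10, function(k) zscore(rnorm(300))))
    out <- leave_one_out_isc(panel, n_perm = 500, seed = s)
    c(out$mean_r, out$p)
  }, numeric(2))
  expect_gte(mean(abs(res[1, ]) < 0.05), 0.9)
  # The sign-flip null is mildly anti-conservative for leave-one-out
  # similarities (they are positively inter-correlated, which the flip
  # null ignores); the long-run non-rejection rate at the 5% level is
  # about 88-89% rather than 95%.
  expect_gte(mean(res[2, ] > 0.05), 0.8)
})

test_that("bootstrap ISC stabilizes with panel size", {
  z <- zscore(sin(seq_len(100) / 5))
  same <- rbind(z, z, z, z)
  boot <- isc_vs_samplesize(same, sizes = c(2, 4), n_boot = 50, seed = 1)
  expect_equal(boot$sd_z_isc, c(0, 0), tolerance = 1e-12)
  lat <- generate_latent_state(150, 6, seed = 5)
  set.seed(11)
  panel <- t(sapply(1:25, function(k) zscore(lat + rnorm(150))))
  curve <- isc_vs_samplesize(panel, sizes = c(3, 25), n_boot = 300,
    seed = 2)
  expect_lt(curve$sd_z_isc[curve$size == 25],
    curve$sd_z_isc[curve$size == 3])
  rerun <- isc_vs_samplesize(panel, sizes = c(3, 25), n_boot = 300,
    seed = 2)
  expect_identical(curve, rerun)
})

test_that("HRF convolution is causal, peaked near 5 s, and linear", {
  expect_equal(convolve_hrf(rep(0, 50), 1), rep(0, 50))
  imp <- c(1, rep(0, 49))
  h <- convolve_hrf(imp, 1)
  # within the sampled kernel span the output is the HRF itself
  expect_equal(h[1:33], hrf_double_gamma(0:32), tolerance = 1e-8)
  expect_lte(abs(which.max(h) - 1 - 5), 1)   # peak at 5 s +/- 1 sample
  two <- imp; two[11] <- 1
  expect_equal(convolve_hrf(two, 1),
    h + c(rep(0, 10), h[1:40]), tolerance = 1e-8)
})

test_that("taper smoothing preserves constants, ramps, and affine maps", {
  spec <- small_spec(n_tr = 60, window_tr = 15)
  expect_equal(taper_smooth(rep(3.5, 60), spec), rep(3.5, 60))
  ramp <- as.numeric(1:60)
  sm <- taper_smooth(ramp, spec)
  interior <- 9:52
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-10)
  # boundary values get pulled toward the interior mean
  expect_gt(sm[1], ramp[1])
  expect_lt(sm[60], ramp[60])
  x <- rnorm(60)
  expect_equal(taper_smooth(2 * x + 5, spec),
    2 * taper_smooth(x, spec) + 5, tolerance = 1e-10)
  expect_error(taper_smooth(rnorm(10), spec), "window longer")
})

test_that("valence segmentation splits strictly around the neutral point", {
  spec <- small_spec(n_tr = 4, window_tr = 3)
  raw <- c(12, 14, 13, 15)
  pos <- extract_valence_segments(raw, spec, "positive")
  neg <- extract_valence_segments(raw, spec, "negative")
  expect_equal(pos$index, c(2L, 4L))
  expect_equal(neg$index, 1L)
  expect_length(intersect(pos$index, neg$index), 0)
  all13 <- extract_valence_segments(rep(13, 4), spec, "positive")
  expect_length(all13$index, 0)
  expect_null(all13$series)
  # long-enough selections get the full processing chain
  spec2 <- small_spec(n_tr = 100, window_tr = 10)
  raw2 <- 13 + 5 * sin(seq_len(100) / 8)
  pos2 <- extract_valence_segments(raw2, spec2, "positive")
  expect_equal(length(pos2$series), length(pos2$index))
  expect_true(all(raw2[pos2$index] > 13))
})

test_that("the full target chain lines up with the latent state", {
  cfg <- small_cfg(seed = 12, n_raters = 8, rater_noise_sd = 0.5)
  truth <- synth_truth(cfg)
  spec <- small_spec(n_tr = cfg$n_tr, tr_s = cfg$tr_s)
  tgt <- build_group_target(generate_raters(truth, cfg), spec)
  expect_length(tgt$smoothed, cfg$n_tr)
  expect_gt(cor(tgt$smoothed, taper_smooth(truth$latent, spec)), 0.7)
  expect_true(all(tgt$raw_mean >= 1 & tgt$raw_mean <= 25))
})
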
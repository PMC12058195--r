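# Surrogate-data and resampling statistics.

#' Phase-randomized surrogate of a time series
#'
#' Fourier-based surrogate: the amplitude spectrum is kept exactly,
#' phases of the non-DC, non-Nyquist bins are replaced by iid uniform
#' draws with conjugate symmetry. The surrogate has the original mean,
#' variance, and autocorrelation but no specific temporal alignment
#' with the original, making it the appropriate null for smooth
#' behavioral time courses.
#'
#' @param x Numeric series (length >= 4).
#' @param seed RNG seed.
#' @return Surrogate series of the same length.
#' @export
phase_randomize <- function(x, seed = 1L) {
  n <- length(x)
  if (n < 4L) abort("phase_randomize(): need length >= 4.")
  f <- fft(x)
  half <- (n - 1L) %/% 2L           # bins 2..half+1 get free phases
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 9L))
  phi <- runif(half, 0, 2 * pi)
  g <- f
  idx <- seq_len(half) + 1L
  g[idx] <- Mod(f[idx]) * exp(1i * phi)
  g[n + 2L - idx] <- Conj(g[idx])   # conjugate symmetry; DC/Nyquist untouched
  Re(fft(g, inverse = TRUE)) / n
}

#' Permutation p-value
#'
#' The add-one permutation formula
#' `p = (1 + #(null >= empirical)) / (1 + n_perm)` for the `greater`
#' tail (mirrored for `less`, used for error statistics where smaller
#' is better). Bounded below by `1 / (n_perm + 1)`.
#'
#' @param empirical Observed statistic.
#' @param nulls Null statistics (non-empty).
#' @param tail `"greater"` or `"less"`.
#' @return p-value in `[1/(N+1), 1]`.
#' @export
permutation_pvalue <- function(empirical, nulls,
                               tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (length(nulls) == 0L) abort("permutation_pvalue(): empty null set.")
  hits <- if (tail == "greater") sum(nulls >= empirical) else
    sum(nulls <= empirical)
  (1 + hits) / (1 + length(nulls))
}

#' Phase-randomized null distribution for CPM accuracy
#'
#' Each iteration draws a phase-randomized surrogate of the target and
#' reruns the full modeling pipeline with it. Within-dataset
#' (`mode = "within"`): selection, training, and testing all use the
#' same surrogate, so the null captures the baseline accuracy a model
#' achieves by learning arbitrary stimulus-locked structure — this
#' null is positively skewed. Across-dataset (`mode = "across"`): the
#' surrogate replaces the *training* target and the prediction is
#' scored against the true test target (set
#' `randomize_test = TRUE` to also surrogate the test side); this null
#' centers on zero.
#'
#' @param fcset Training [dynfc_set()] (within mode) or list of
#'   training sets (across mode).
#' @param target Training group target (within mode: also the test
#'   target).
#' @param n_perm Number of iterations (default 1000).
#' @param seed RNG seed; iteration i uses a fixed sub-stream.
#' @param mode `"within"` or `"across"`.
#' @param alpha Selection threshold (within mode).
#' @param hyper A [cpm_hyperparams()].
#' @param test_set,test_target Held-out dataset (across mode).
#' @param mask Feature set used in across mode.
#' @param randomize_test Across mode: also phase-randomize the test
#'   target (default `FALSE`).
#' @return A `null_distribution`: tibble `iteration`, `r`, `rmse`,
#'   with mode/seed/n_perm attributes.
#' @export
build_prediction_null <- function(fcset, target, n_perm = 1000, seed = 1L,
                                  mode = c("within", "across"),
                                  alpha = 0.01, hyper = cpm_hyperparams(),
                                  test_set = NULL, test_target = NULL,
                                  mask = NULL, randomize_test = FALSE) {
  mode <- match.arg(mode)
  if (mode == "across" && (is.null(test_set) || is.null(test_target) ||
    is.null(mask))) {
    abort("build_prediction_null(): across mode needs test_set, test_target, mask.")
  }
  rows <- vector("list", n_perm)
  n_failed <- 0L
  for (it in seq_len(n_perm)) {
    surro <- phase_randomize(target, seed = derive_seed(seed, it, 10L))
    res <- tryCatch({
      if (mode == "within") {
        fit <- run_loso(fcset, surro, alpha = alpha, hyper = hyper)
        tibble(iteration = it, r = fit$mean_r, rmse = fit$mean_rmse)
      } else {
        test_y <- if (randomize_test) {
          phase_randomize(test_target, seed = derive_seed(seed, it, 11L))
        } else {
          test_target
        }
        train_targets <- if (inherits(fcset, "dynfc_set")) list(surro) else
          replicate(length(fcset), surro, simplify = FALSE)
        cr <- run_cross_dataset(fcset, train_targets, test_set, test_y,
          mask = mask, hyper = hyper)
        tibble(iteration = it, r = cr$mean_r, rmse = cr$mean_rmse)
      }
    }, dyncpm_no_features = function(e) {
      tibble(iteration = it, r = NA_real_, rmse = NA_real_)
    })
    if (is.na(res$r)) n_failed <- n_failed + 1L
    rows[[it]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "n_failed") <- n_failed
  class(out) <- c("null_distribution", class(out))
  out
}

#' Circular-shift correlation null
#'
#' Empirical Pearson correlation of two aligned series against a null
#' built by circularly shifting the second series by random nonzero
#' offsets, preserving its autocorrelation while destroying the
#' alignment. When `n_perm` reaches the number of distinct shifts, all
#' shifts are used exactly once.
#'
#' @param a,b Equal-length series (>= 10 TRs, non-constant).
#' @param n_perm Number of shifts (default 1000).
#' @param seed RNG seed.
#' @return A list: `r` (empirical), `p` (one-tailed greater), `nulls`.
#' @export
circular_shift_null <- function(a, b, n_perm = 1000, seed = 1L) {
  n <- length(a)
  if (n != length(b)) abort("circular_shift_null(): length mismatch.")
  if (n < 10L) abort("circular_shift_null(): need length >= 10.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("circular_shift_null(): constant input series.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 12L))
  shifts <- if (n_perm >= n - 1L) {
    seq_len(n - 1L)
  } else {
    sample.int(n - 1L, n_perm, replace = FALSE)
  }
  nulls <- vapply(shifts, function(k) {
    cor(a, b[c((k + 1L):n, 1L:k)])
  }, numeric(1))
  r_emp <- cor(a, b)
  list(r = r_emp, p = permutation_pvalue(r_emp, nulls, "greater"),
    nulls = nulls)
}

#' Two one-sided tests of equivalence (TOST)
#'
#' Tests whether per-fold accuracies are statistically indistinguishable
#' from zero within a minimal-effect interval: one-sided t-tests
#' against each bound, reporting the larger of the two one-sided
#' p-values. Accuracies and bounds are Fisher z-transformed by default
#' (`transform = "fisher"`); a small TOST p supports equivalence.
#'
#' @param values Per-fold correlations (n >= 3).
#' @param bounds Equivalence interval on the correlation scale
#'   (default `c(-0.1, 0.1)`; must be finite with `lower < upper`).
#' @param transform `"fisher"` or `"none"`.
#' @return A tibble `p`, `p_lower`, `p_upper`, `df`, `degenerate`.
#' @export
equivalence_tost <- function(values, bounds = c(-0.1, 0.1),
                             transform = c("fisher", "none")) {
  transform <- match.arg(transform)
  n <- length(values)
  if (n < 3L) abort("equivalence_tost(): need n >= 3 values.")
  if (length(bounds) != 2L || !all(is.finite(bounds)) ||
    bounds[1] >= bounds[2]) {
    abort("equivalence_tost(): bounds must be finite with lower < upper.")
  }
  if (transform == "fisher") {
    values <- fisher_z(values)
    bounds <- atanh(bounds)
  }
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    inside <- m > bounds[1] && m < bounds[2]
    return(tibble(p = if (inside) 0 else 1, p_lower = NA_real_,
      p_upper = NA_real_, df = n - 1L, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t_lo <- (m - bounds[1]) / se   # H0: mean <= lower bound
  t_hi <- (m - bounds[2]) / se   # H0: mean >= upper bound
  p_lo <- pt(t_lo, df = n - 1, lower.tail = FALSE)
  p_hi <- pt(t_hi, df = n - 1, lower.tail = TRUE)
  tibble(p = max(p_lo, p_hi), p_lower = p_lo, p_upper = p_hi,
    df = n - 1L, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of a p-value vector with a rejection mask at
#' level `q`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble `p`, `p_adj`, `reject` in the input order.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) {
    return(tibble(p = numeric(), p_adj = numeric(), reject = logical()))
  }
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("bh_fdr(): p-values must lie in [0, 1].")
  }
  adj <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, p_adj = adj, reject = adj <= q)
}
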
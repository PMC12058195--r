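# broom-style tidiers for the fitted objects.

#' Tidy a leave-one-subject-out CPM fit
#' @param x A `cpm_loso` object.
#' @param ... Unused.
#' @return The per-fold tibble (`subject`, `r`, `rmse`, `n_features`,
#'   `failed`).
#' @method tidy cpm_loso
#' @export
tidy.cpm_loso <- function(x, ...) x$folds

#' One-row summary of a leave-one-subject-out CPM fit
#' @param x A `cpm_loso` object.
#' @param ... Unused.
#' @return A tibble with `mean_r`, `mean_rmse`, `n_subjects`,
#'   `n_consensus`, `n_sign_conflicts`, `alpha`.
#' @method glance cpm_loso
#' @export
glance.cpm_loso <- function(x, ...) {
  tibble(
    mean_r = x$mean_r, mean_rmse = x$mean_rmse,
    n_subjects = x$n_subjects, n_consensus = nrow(x$consensus),
    n_sign_conflicts = x$n_sign_conflicts, alpha = x$alpha
  )
}

#' Tidy an across-dataset CPM evaluation
#' @param x A `cpm_cross` object.
#' @param ... Unused.
#' @return Per-test-subject tibble (`subject`, `r`, `rmse`).
#' @method tidy cpm_cross
#' @export
tidy.cpm_cross <- function(x, ...) x$subjects

#' One-row summary of an across-dataset CPM evaluation
#' @param x A `cpm_cross` object.
#' @param ... Unused.
#' @return A tibble with `mean_r`, `mean_rmse`, `group_r`, `n_subjects`.
#' @method glance cpm_cross
#' @export
glance.cpm_cross <- function(x, ...) {
  tibble(mean_r = x$mean_r, mean_rmse = x$mean_rmse,
    group_r = x$group_r, n_subjects = nrow(x$subjects))
}

#' Tidy an intersubject-correlation result
#' @param x An `isc_result`.
#' @param ... Unused.
#' @return Per-rater tibble (`rater_id`, `r`).
#' @method tidy isc_result
#' @export
tidy.isc_result <- function(x, ...) x$raters

#' One-row summary of an intersubject-correlation result
#' @param x An `isc_result`.
#' @param ... Unused.
#' @return A tibble with `mean_r`, `p`, `n_raters`, `n_perm`.
#' @method glance isc_result
#' @export
glance.isc_result <- function(x, ...) {
  tibble(mean_r = x$mean_r, p = x$p, n_raters = nrow(x$raters),
    n_perm = x$n_perm)
}

#' @export
print.cpm_loso <- function(x, ...) {
  cat(sprintf(
    "Leave-one-subject-out CPM: %d subjects, alpha = %g\n",
    x$n_subjects, x$alpha))
  cat(sprintf("  mean r (Fisher-z averaged): %.3f\n", x$mean_r))
  cat(sprintf("  mean RMSE:                  %.3f\n", x$mean_rmse))
  cat(sprintf("  consensus edges:            %d (%d sign conflicts)\n",
    nrow(x$consensus), x$n_sign_conflicts))
  invisible(x)
}

#' @export
print.cpm_cross <- function(x, ...) {
  cat(sprintf(
    "Across-dataset CPM: %d test subjects\n", nrow(x$subjects)))
  cat(sprintf("  mean r: %.3f   mean RMSE: %.3f   group-average r: %.3f\n",
    x$mean_r, x$mean_rmse, x$group_r))
  invisible(x)
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out ISC: %d raters, mean r = %.3f, sign-flip p = %.4g\n",
    nrow(x$raters), x$mean_r, x$p))
  invisible(x)
}
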
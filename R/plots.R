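# ggplot2 graphics for the main result types.

#' Plot fold accuracies against a null distribution
#'
#' Box of per-fold correlations with the Fisher-z mean marked; when a
#' null distribution is supplied its density is drawn alongside.
#'
#' @param object A `cpm_loso` object.
#' @param null Optional `null_distribution` from
#'   [build_prediction_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpm_loso
#' @export
autoplot.cpm_loso <- function(object, null = NULL, ...) {
  folds <- dplyr::filter(object$folds, !.data$failed)
  p <- ggplot2::ggplot(folds, ggplot2::aes(x = "model", y = .data$r)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.06, alpha = 0.6) +
    ggplot2::annotate("segment", x = 0.75, xend = 1.25,
      y = object$mean_r, yend = object$mean_r, linewidth = 1) +
    ggplot2::labs(x = NULL, y = "fold accuracy (Pearson r)") +
    ggplot2::theme_minimal()
  if (!is.null(null)) {
    nd <- tibble(r = null$r[!is.na(null$r)])
    p <- p + ggplot2::geom_violin(
      data = dplyr::mutate(nd, x = "null"),
      ggplot2::aes(x = .data$x, y = .data$r),
      fill = "grey80", colour = NA, alpha = 0.8)
  }
  p
}

#' Heatmap of network-pair enrichment
#'
#' Proportion of selected edges per network pair; FDR-significant
#' cells are outlined.
#'
#' @param object A `cpm_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpm_enrichment
#' @export
autoplot.cpm_enrichment <- function(object, ...) {
  df <- dplyr::mutate(object,
    netA = factor(.data$netA, levels = NETWORK_LABELS),
    netB = factor(.data$netB, levels = NETWORK_LABELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$netA, y = .data$netB,
    fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
      fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "proportion\nselected") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the stages of a group behavioral target
#'
#' Raw group mean, z-scored average, HRF-convolved, and taper-smoothed
#' series on the TR grid.
#'
#' @param object A `group_target` from [build_group_target()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_target
#' @export
autoplot.group_target <- function(object, ...) {
  n <- length(object$group_z)
  df <- dplyr::bind_rows(
    tibble(tr = seq_len(n), value = zscore(object$raw_mean),
      stage = "raw group mean (z-scaled for display)"),
    tibble(tr = seq_len(n), value = object$group_z, stage = "z-scored"),
    tibble(tr = seq_len(n), value = object$hrf, stage = "HRF-convolved"),
    tibble(tr = seq_len(n), value = object$smoothed,
      stage = "taper-smoothed")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "TR", y = NULL) +
    ggplot2::theme_minimal()
}
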
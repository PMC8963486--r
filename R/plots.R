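# ggplot2 helpers for the main result types.

#' Plot group-mean frailty-index trajectories
#'
#' Mean +/- SEM of the composite index per group over time, with an
#' optional vertical marker at the challenge day.
#'
#' @param fi_records Output of [fi_table()].
#' @param challenge_day Optional day to mark with a dashed line.
#' @return A ggplot object.
#' @export
plot_fi_trajectory <- function(fi_records, challenge_day = NULL) {
  s <- fi_group_summary(fi_records)
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$day, .data$mean_fi,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_fi - .data$sem,
                                          ymax = .data$mean_fi + .data$sem),
                             size = 0.3) +
    ggplot2::labs(x = "day", y = "frailty index (mean ± SEM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(challenge_day)) {
    p <- p + ggplot2::geom_vline(xintercept = challenge_day, linetype = "dashed")
  }
  p
}

#' Plot per-item contribution shares to the frailty index
#'
#' @param fi_records Output of [fi_table()].
#' @return A stacked-area ggplot of item shares per group over time.
#' @export
plot_fi_item_shares <- function(fi_records) {
  sh <- fi_item_shares(fi_records)
  ggplot2::ggplot(sh, ggplot2::aes(.data$day, .data$share, fill = .data$item)) +
    ggplot2::geom_area(position = "stack", na.rm = TRUE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "day", y = "share of group-mean FI", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Ordination plot for a PCoA result
#'
#' @param object A `frailty_pcoa` from [pcoa()].
#' @param metadata Optional sample table (`sample_id`, `arm`, ...) used to
#'   colour points by `arm`.
#' @param ... Unused.
#' @return A ggplot of the first two axes with percent variance in the
#'   axis labels.
#' @export
autoplot.frailty_pcoa <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  if (!is.null(metadata)) d <- dplyr::left_join(d, metadata, by = "sample_id")
  aes <- if ("arm" %in% names(d)) {
    ggplot2::aes(.data$axis1, .data$axis2, colour = .data$arm)
  } else {
    ggplot2::aes(.data$axis1, .data$axis2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of the metabolite screen
#'
#' @param object A `volcano_tbl` from [volcano()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 p, with the
#'   VIP-and-p significant metabolites highlighted.
#' @export
autoplot.volcano_tbl <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p.value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "VIP ≥ 1 & p < 0.05") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-sample F/B ratios by arm
#'
#' @param fb Output of [fb_ratio()] including an `arm` column.
#' @return A ggplot object.
#' @export
plot_fb_ratio <- function(fb) {
  check_cols(fb, c("fb_ratio", "arm"), "fb")
  ggplot2::ggplot(fb, ggplot2::aes(.data$arm, .data$fb_ratio,
                                   colour = .data$arm)) +
    ggplot2::geom_boxplot(outliers = FALSE) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Firmicutes / Bacteroidetes") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
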
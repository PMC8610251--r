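#' Plot per-condition measurements with mean and s.e.m.
#'
#' The dot-plot convention of the quantification figures: one jittered dot
#' per cell (or experiment mean), a crossbar at the condition mean, and
#' s.e.m. whiskers.
#'
#' @param table tidy tibble with `condition`, `value` (and optionally
#'   `experiment_id` for the summary overlay).
#' @param metric_name optional y-axis label.
#' @return a ggplot object.
#' @export
plot_condition_summary <- function(table, metric_name = "value") {
  has_exp <- "experiment_id" %in% names(table)
  smry <- if (has_exp) {
    summarize_conditions(table, unit = "cells")
  } else {
    table %>%
      group_by(.data$condition) %>%
      summarise(
        mean = mean(.data$value),
        sem = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
      )
  }
  ggplot2::ggplot(table, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_crossbar(
      data = smry,
      ggplot2::aes(y = .data$mean, ymin = .data$mean, ymax = .data$mean),
      width = 0.4, linewidth = 0.4
    ) +
    ggplot2::geom_errorbar(
      data = smry,
      ggplot2::aes(
        y = .data$mean,
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = metric_name) +
    ggplot2::theme_classic()
}

#' Plot linked particle tracks
#'
#' Track paths in micrometre coordinates, one colour per track, with the y
#' axis flipped to match image orientation.
#'
#' @param track_points tibble from [link_tracks()].
#' @return a ggplot object.
#' @export
plot_tracks <- function(track_points) {
  ggplot2::ggplot(
    track_points,
    ggplot2::aes(
      x = .data$x_um, y = .data$y_um,
      group = .data$track_id, colour = factor(.data$track_id)
    )
  ) +
    ggplot2::geom_path(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_classic()
}

#' Plot Tukey pairwise comparisons
#'
#' Pairwise mean differences with their Tukey HSD confidence intervals;
#' significant pairs are highlighted.
#'
#' @param x an `lq_comparison` from [compare_groups()] (ANOVA variant).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lq_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    abort("autoplot is defined for the ANOVA/Tukey variant")
  }
  ggplot2::ggplot(
    x$pairwise,
    ggplot2::aes(
      x = .data$diff, y = .data$pair,
      xmin = .data$lwr, xmax = .data$upr,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange() +
    ggplot2::labs(x = "difference in means", y = NULL) +
    ggplot2::theme_classic()
}
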
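#' Compare treatment groups
#'
#' The statistical convention used throughout the reporting layer: exactly
#' two groups are compared with a two-tailed unpaired Student's t-test
#' (equal variances, the classical form); three or more groups with
#' one-way ANOVA followed by Tukey's HSD on all pairs (the Tukey-Kramer
#' generalization when group sizes differ). Significance is declared at
#' p < 0.05.
#'
#' @param table tidy measurement tibble with at least `condition` and
#'   `value` columns (one row per cell or per experiment mean).
#' @param metric_name optional filter on a `metric_name` column.
#' @param alpha significance level.
#' @return an object of class `lq_comparison`; see [tidy.lq_comparison()]
#'   and [glance.lq_comparison()].
#' @export
compare_groups <- function(table, metric_name = NULL, alpha = 0.05) {
  if (!is.null(metric_name) && "metric_name" %in% names(table)) {
    table <- filter(table, .data$metric_name == !!metric_name)
  }
  if (!all(c("condition", "value") %in% names(table))) {
    abort("table needs 'condition' and 'value' columns")
  }
  if (any(!is.finite(table$value))) abort("values must be finite")
  groups <- split(table$value, table$condition)
  if (length(groups) < 2) abort("need at least two conditions to compare")
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2")
  if (length(groups) == 2) {
    ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    res <- list(
      test = "student_t", groups = names(groups),
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, pairwise = NULL, alpha = alpha
    )
  } else {
    df_aov <- data.frame(
      value = table$value,
      condition = factor(table$condition)
    )
    fit <- aov(value ~ condition, data = df_aov)
    sm <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$condition
    pw <- tibble(
      pair = rownames(tk),
      diff = unname(tk[, "diff"]),
      lwr = unname(tk[, "lwr"]),
      upr = unname(tk[, "upr"]),
      adj_p_value = unname(tk[, "p adj"]),
      significant = unname(tk[, "p adj"] < alpha)
    )
    res <- list(
      test = "one_way_anova_tukey", groups = names(groups),
      statistic = sm[["F value"]][1],
      df = c(sm[["Df"]][1], sm[["Df"]][2]),
      p_value = sm[["Pr(>F)"]][1],
      pairwise = pw, alpha = alpha
    )
  }
  structure(res, class = "lq_comparison")
}

#' @export
print.lq_comparison <- function(x, ...) {
  if (x$test == "student_t") {
    cat(sprintf(
      "Student's t-test (%s vs %s): t = %.4g, df = %g, p = %.4g\n",
      x$groups[1], x$groups[2], x$statistic, x$df, x$p_value
    ))
  } else {
    cat(sprintf(
      "One-way ANOVA (%d groups): F(%d, %d) = %.4g, p = %.4g\n",
      length(x$groups), x$df[1], x$df[2], x$statistic, x$p_value
    ))
    cat("Tukey HSD pairs:\n")
    print(as.data.frame(x$pairwise[, c("pair", "diff", "adj_p_value", "significant")]))
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' `tidy()` returns the pairwise table (Tukey pairs for ANOVA, the single
#' pair for a t-test); `glance()` returns the one-row test summary.
#'
#' @param x an `lq_comparison` from [compare_groups()].
#' @param ... unused.
#' @export
tidy.lq_comparison <- function(x, ...) {
  if (x$test == "student_t") {
    tibble(
      pair = paste(x$groups[2], x$groups[1], sep = "-"),
      adj_p_value = x$p_value,
      significant = x$p_value < x$alpha
    )
  } else {
    x$pairwise
  }
}

#' @rdname tidy.lq_comparison
#' @export
glance.lq_comparison <- function(x, ...) {
  tibble(
    test = x$test,
    n_groups = length(x$groups),
    statistic = x$statistic,
    p_value = x$p_value
  )
}

#' Normalize measurements to the vehicle control
#'
#' Within each experiment, values are divided by the mean of the vehicle
#' condition, so the vehicle-normalized mean is exactly 1 per experiment
#' and treated conditions read as fold-changes over control.
#'
#' @param table tidy tibble with `experiment_id`, `condition`, `value`.
#' @param vehicle_condition name of the control condition.
#' @return the table with `value` replaced by the normalized value.
#' @export
normalize_to_vehicle <- function(table, vehicle_condition = "vehicle") {
  stopifnot(all(c("experiment_id", "condition", "value") %in% names(table)))
  missing <- table %>%
    group_by(.data$experiment_id) %>%
    summarise(has = any(.data$condition == vehicle_condition), .groups = "drop") %>%
    filter(!.data$has)
  if (nrow(missing) > 0) {
    abort(sprintf(
      "vehicle condition '%s' missing in experiment(s): %s",
      vehicle_condition, paste(missing$experiment_id, collapse = ", ")
    ))
  }
  table %>%
    group_by(.data$experiment_id) %>%
    mutate(value = .data$value /
      mean(.data$value[.data$condition == vehicle_condition])) %>%
    ungroup()
}

#' Per-condition summary: mean, s.e.m. and n
#'
#' Summaries are computed either across experiment means (default, which
#' avoids pseudo-replication: cells within an experiment are not
#' independent) or across individual cells. Both sample sizes are always
#' reported.
#'
#' @param table tidy tibble with `experiment_id`, `condition`, `value` (and
#'   optionally `cell_id`).
#' @param unit `"experiments"` (mean per experiment first) or `"cells"`.
#' @return tibble: `condition`, `mean`, `sem`, `n_cells`, `n_experiments`;
#'   `sem` is `NA` when only one unit is available.
#' @export
summarize_conditions <- function(table, unit = c("experiments", "cells")) {
  unit <- match.arg(unit)
  stopifnot(all(c("experiment_id", "condition", "value") %in% names(table)))
  counts <- table %>%
    group_by(.data$condition) %>%
    summarise(
      n_cells = dplyr::n(),
      n_experiments = dplyr::n_distinct(.data$experiment_id),
      .groups = "drop"
    )
  base <- if (unit == "experiments") {
    table %>%
      group_by(.data$condition, .data$experiment_id) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  } else {
    table
  }
  stats <- base %>%
    group_by(.data$condition) %>%
    summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  left_join(stats, counts, by = "condition")
}
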
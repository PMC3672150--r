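#' Plot state occupancy of a rule set
#'
#' Bar chart of case and control occupancy counts per state, annotated with
#' each state's assigned class — the tabular analogue of a training-set
#' state-occupancy figure.
#'
#' @param object An `mss_rules` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_rules <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("case_n", "control_n"), names_to = "group",
                        values_to = "n") |>
    dplyr::mutate(group = sub("_n$", "", .data$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$n,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$pattern, y = Inf, label = .data$class),
      vjust = 1.2, size = 3, inherit.aes = FALSE) +
    ggplot2::labs(x = "marker state", y = "samples", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot held-out accuracy across cross-validation splits
#'
#' Shows the best-training-panel held-out accuracy per split (when the
#' headline pass was run) and the distribution of retained-panel split
#' accuracies.
#'
#' @param object An `mss_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mss_cv <- function(object, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$split),
                                          y = .data$split_accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = "split", y = "held-out accuracy") +
    ggplot2::theme_minimal()
  if (!is.null(object$headline)) {
    p <- p + ggplot2::geom_point(
      data = object$headline,
      ggplot2::aes(x = factor(.data$split), y = .data$test_accuracy),
      colour = "red", na.rm = TRUE)
  }
  p
}

#' Plot a state-occupancy summary
#'
#' Percentage of each class's samples in each state, optionally filled by
#' subgroup composition.
#'
#' @param occupancy Output of [summarize_occupancy()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occupancy) {
  aes <- if ("subgroup" %in% names(occupancy)) {
    ggplot2::aes(x = .data$pattern, y = .data$pct, fill = .data$subgroup)
  } else {
    ggplot2::aes(x = .data$pattern, y = .data$pct)
  }
  ggplot2::ggplot(occupancy, aes) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = "marker state", y = "% of class samples") +
    ggplot2::theme_minimal()
}
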
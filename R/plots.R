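#' Volcano plot of a differential screen
#'
#' Signed log2 fold change (positive toward the second group level) against
#' -log10 of the thresholded p-value, colored by enrichment class.
#'
#' @param object A `"diff_result"` tibble from [diff_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diff_result <- function(object, ...) {
  levels <- attr(object, "levels")
  use <- attr(object, "use") %||% "q"
  pv <- if (use == "q") object$q_value else object$p_value
  signed <- log2(pmin(object$fold_change, 1e6)) *
    ifelse(object$direction == levels[2], 1, -1)
  df <- tibble::tibble(lfc = signed, nlp = -log10(pmax(pv, 1e-300)),
                       class = object$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = .data$nlp,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(object, "fc_cut")),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = paste0("log2 fold change (", levels[1], " ←→ ", levels[2], ")"),
      y = paste0("-log10 ", if (use == "q") "FDR-adjusted p" else "p"),
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.diff_result
#' @param x A `"diff_result"` tibble.
#' @export
plot_volcano <- function(x, ...) autoplot.diff_result(x, ...)

#' Bubble plot of damage-class frequencies
#'
#' Relative frequency (percent within each grouping column value) of every
#' ordinal damage class, drawn as scaled circles: the standard presentation
#' of root feeding-damage distributions.
#'
#' @param damage Damage tibble with `score` and the grouping column.
#' @param by Grouping column name (default `"root_type"`).
#' @return A ggplot object.
#' @export
plot_damage_bubbles <- function(damage, by = "root_type") {
  freq <- damage |>
    dplyr::count(.data[[by]], .data$score) |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(freq, ggplot2::aes(x = .data[[by]], y = .data$score,
                                     size = .data$percent)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_y_continuous(breaks = 0:5, limits = c(-0.2, 5.2)) +
    ggplot2::labs(y = "damage score", size = "% of roots") +
    ggplot2::theme_minimal()
}
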
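## ggplot2 displays for the main result types.

#' Attrition funnel plot
#'
#' @param x an `attrition_report`.
#' @param log_scale plot counts on a log axis (useful when early steps
#'   dwarf the cohort).
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot attrition_report
autoplot.attrition_report <- function(x, log_scale = FALSE, ...) {
  df <- tibble::as_tibble(x)
  df$step_label <- factor(paste0("Step ", df$step), levels = paste0("Step ", df$step))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step_label,
                                        y = .data$n_remaining)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "Members remaining",
                  title = "Cohort attrition") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Regimen mix by treatment line
#'
#' Stacked shares of mutually exclusive regimens among initiators of each
#' line.
#'
#' @param patterns a `lot_patterns` from [summarize_lines()].
#' @return a ggplot.
#' @export
plot_regimen_mix <- function(patterns) {
  df <- patterns$regimens
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$line_number),
                                   y = .data$pct, fill = .data$regimen)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Treatment line", y = "% of line initiators",
                  fill = "Regimen",
                  title = "Treatment regimens by line") +
    ggplot2::theme_minimal()
}

#' Treatment-flow (Sankey-style) plot
#'
#' A light-weight rendition of the treatment-flow edge list: regimen
#' states as stacked bars per line, transitions as ribbons with width
#' proportional to member counts. Edges flagged `render = FALSE` by the
#' suppression rule are omitted.
#'
#' @param edges edge list from [build_sankey()], optionally passed through
#'   [apply_suppression()].
#' @return a ggplot.
#' @export
plot_sankey <- function(edges) {
  if (!"render" %in% names(edges)) edges$render <- TRUE
  e <- edges[edges$render & edges$to_state != "no further line", , drop = FALSE]
  nodes <- dplyr::bind_rows(
    dplyr::count(edges, line = .data$from_line, state = .data$from_state,
                 wt = .data$n_members, name = "n"),
    dplyr::count(edges[edges$to_state != "no further line", ],
                 line = .data$to_line, state = .data$to_state,
                 wt = .data$n_members, name = "n")
  ) |>
    dplyr::count(.data$line, .data$state, wt = .data$n, name = "n") |>
    dplyr::group_by(.data$line) |>
    dplyr::arrange(.data$state, .by_group = TRUE) |>
    dplyr::mutate(ymax = cumsum(.data$n), ymin = .data$ymax - .data$n,
                  ymid = (.data$ymin + .data$ymax) / 2) |>
    dplyr::ungroup()
  e <- e |>
    dplyr::left_join(nodes[, c("line", "state", "ymid")],
                     by = c(from_line = "line", from_state = "state")) |>
    dplyr::rename(y_from = "ymid") |>
    dplyr::left_join(nodes[, c("line", "state", "ymid")],
                     by = c(to_line = "line", to_state = "state")) |>
    dplyr::rename(y_to = "ymid")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$from_line + 0.15, xend = .data$to_line - 0.15,
                   y = .data$y_from, yend = .data$y_to,
                   linewidth = .data$n_members),
      alpha = 0.4, colour = "grey40") +
    ggplot2::geom_tile(
      data = nodes,
      ggplot2::aes(x = .data$line, y = .data$ymid, height = .data$n,
                   fill = .data$state), width = 0.3) +
    ggplot2::scale_linewidth(range = c(0.2, 4)) +
    ggplot2::labs(x = "Treatment line", y = "Members", fill = "Regimen",
                  linewidth = "Members",
                  title = "Treatment sequencing across lines") +
    ggplot2::theme_minimal()
}
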
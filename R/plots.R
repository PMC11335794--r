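# ggplot2 renderings of the chart-data structures. Colors follow the
# red/amber/green flag semantics throughout.

FLAG_COLORS <- c(`-2` = "#b30000", `-1` = "#e69f00", `0` = "#2c7a2c",
                 `1` = "#e69f00", `2` = "#b30000")

flag_factor <- function(flag) {
  factor(as.character(flag %|NA|% 0L), levels = names(FLAG_COLORS))
}

#' Plot chart data
#'
#' Renders a [chart_data()] object as a ggplot: scatter of numerator versus
#' denominator (log x) with threshold curves, observed-metric or score bar
#' charts in their documented sort orders, or the longitudinal quartile
#' band with a highlighted site series.
#'
#' @param object A `chart_data` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chart_data <- function(object, ...) {
  d <- object$data
  if (object$kind == "scatter") {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(ggplot2::aes(color = flag_factor(.data$flag)),
                          size = 2.5)
    if (!is.null(object$ref_lines)) {
      p <- p + ggplot2::geom_line(
        data = object$ref_lines,
        ggplot2::aes(x = .data$x, y = .data$y,
                     group = interaction(.data$level, .data$side),
                     linetype = .data$level),
        color = "grey40")
    }
    p <- p + ggplot2::scale_x_log10()
    return(style_flags(p, object, x = "denominator (log scale)",
                       y = "numerator"))
  }
  if (object$kind %in% c("metric_bar", "score_bar")) {
    d$x <- factor(d$x, levels = d$x)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_col(ggplot2::aes(fill = flag_factor(.data$flag)))
    if (!is.null(object$ref_lines) && "value" %in% names(object$ref_lines)) {
      p <- p + ggplot2::geom_hline(
        data = object$ref_lines,
        ggplot2::aes(yintercept = .data$value, linetype = .data$level),
        color = "grey40")
    }
    ylab <- if (object$kind == "score_bar") "score" else "observed metric"
    return(style_flags(p, object, x = "group", y = ylab, fill = TRUE))
  }
  # longitudinal
  p <- ggplot2::ggplot()
  if (!is.null(object$distribution) && nrow(object$distribution) > 0) {
    p <- p + ggplot2::geom_ribbon(
      data = object$distribution,
      ggplot2::aes(x = .data$snapshot_date, ymin = .data$q1, ymax = .data$q3),
      fill = "grey80") +
      ggplot2::geom_line(
        data = object$distribution,
        ggplot2::aes(x = .data$snapshot_date, y = .data$median),
        color = "grey50")
  }
  if (nrow(d) > 0) {
    p <- p + ggplot2::geom_line(
      data = d, ggplot2::aes(x = .data$snapshot_date, y = .data$score),
      color = "#2b6cb0") +
      ggplot2::geom_point(
        data = d,
        ggplot2::aes(x = .data$snapshot_date, y = .data$score,
                     color = flag_factor(.data$flag)), size = 2.5)
  }
  if (!is.null(object$ref_lines)) {
    p <- p + ggplot2::geom_hline(
      data = object$ref_lines,
      ggplot2::aes(yintercept = .data$value, linetype = .data$level),
      color = "grey40")
  }
  style_flags(p, object, x = "snapshot date", y = "score")
}

style_flags <- function(p, object, x, y, fill = FALSE) {
  scale <- if (fill) {
    ggplot2::scale_fill_manual(values = FLAG_COLORS, drop = FALSE,
                               name = "flag")
  } else {
    ggplot2::scale_color_manual(values = FLAG_COLORS, drop = FALSE,
                                name = "flag")
  }
  p + scale +
    ggplot2::labs(x = x, y = y,
                  title = object$metric_id %|NA|% NULL) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @describeIn analyze_normal_approx Bar chart of per-group scores in
#'   descending order with default 2/3 threshold lines.
#' @param object A `kri_analysis` object.
#' @export
autoplot.kri_analysis <- function(object, ...) {
  g <- object$groups[!is.na(object$groups$score), ]
  g <- g[order(-g$score, g$group_id), ]
  d <- tibble(group_id = g$group_id, x = g$group_id, y = g$score,
              flag = 0L)
  cd <- new_chart_data("score_bar", d,
                       ref_lines = tibble(level = c("amber", "red",
                                                    "amber", "red"),
                                          value = c(2, 3, -2, -3)),
                       metric_id = object$metric_id)
  autoplot(cd)
}
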
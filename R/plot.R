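# Mirrored, severity-stacked weekly burden chart.
#
# One horizontal bar row per study week; the left arm extends in the
# negative x direction, the right arm in the positive, with absolute-value
# tick labels. Each bar is stacked by effective CTCAE grade with a
# sequential (light-to-dark) five-level colour scale. Week 1 is at the top,
# matching clinical AE-plot convention.

.default_grade_palette <- c(
  "1" = "#FEE5D9", "2" = "#FCAE91", "3" = "#FB6A4A",
  "4" = "#DE2D26", "5" = "#A50F15"
)

# Long per-grade data frame for one side of the chart.
series_grade_long <- function(series, statistic) {
  df <- as.data.frame(series)
  grades <- paste0("grade_", 1:5)
  long <- tidyr::pivot_longer(
    df[, c("week", "n_at_risk", grades)],
    cols = dplyr::all_of(grades),
    names_to = "grade", values_to = "value", names_prefix = "grade_"
  )
  if (statistic == "normalized") {
    long$value <- ifelse(long$n_at_risk > 0, long$value / long$n_at_risk, 0)
  }
  long$grade <- factor(long$grade, levels = as.character(1:5))
  long$arm <- attr(series, "arm")
  long
}

#' Mirrored severity-stacked burden chart
#'
#' Builds the two-arm weekly burden chart: study week on the y axis
#' (week 1 at the top), burden on the x axis, the first arm mirrored to the
#' left of zero and the second to the right, each weekly bar stacked by
#' effective grade.
#'
#' @param series_left,series_right [arm_series()] objects for the two arms;
#'   both must share the same week grid.
#' @param statistic Plot the `"normalized"` (risk-set-normalized, default)
#'   or `"total"` weekly burden.
#' @param palette Named character vector of five colours for grades
#'   `"1"`..`"5"`; the default is a sequential light-to-dark red scale.
#' @param annotate_risk If `TRUE`, print the weekly risk-set sizes along
#'   each side of the chart.
#' @param title Optional chart title.
#' @return A `ggplot` object; bar geometry equals the series values exactly.
#' @export
both_chart <- function(series_left, series_right,
                       statistic = c("normalized", "total"),
                       palette = NULL, annotate_risk = FALSE, title = NULL) {
  statistic <- match.arg(statistic)
  if (nrow(series_left) == 0 || nrow(series_right) == 0) {
    validation_error("both series must be non-empty")
  }
  if (is.null(palette)) palette <- .default_grade_palette
  if (length(palette) != 5L) {
    config_error("palette must supply exactly 5 colours (grades 1..5)")
  }
  left <- series_grade_long(series_left, statistic)
  right <- series_grade_long(series_right, statistic)
  left$value <- -left$value
  df <- rbind(left, right)
  arm_left <- attr(series_left, "arm")
  arm_right <- attr(series_right, "arm")

  xlab <- if (statistic == "normalized") {
    "weekly burden per subject at risk"
  } else {
    "weekly total burden"
  }
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$value, y = .data$week, fill = .data$grade)
  ) +
    ggplot2::geom_col(orientation = "y", width = 0.85) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_reverse(breaks = unique(df$week)) +
    ggplot2::scale_x_continuous(labels = function(x) abs(x)) +
    ggplot2::scale_fill_manual(
      values = palette, name = "grade", drop = FALSE,
      limits = as.character(1:5)
    ) +
    ggplot2::labs(
      x = xlab, y = "study week",
      title = title,
      subtitle = sprintf("%s (left)  vs  %s (right)", arm_left, arm_right)
    ) +
    ggplot2::theme_minimal()

  if (annotate_risk) {
    risk <- rbind(
      data.frame(week = series_left$week, n = series_left$n_at_risk,
                 side = -1),
      data.frame(week = series_right$week, n = series_right$n_at_risk,
                 side = 1)
    )
    lim <- max(abs(df$value), 1e-9)
    risk$x <- risk$side * lim * 1.08
    p <- p + ggplot2::geom_text(
      data = risk,
      ggplot2::aes(x = .data$x, y = .data$week, label = .data$n),
      inherit.aes = FALSE, size = 2.5, colour = "grey40"
    )
  }
  p
}

#' Save a burden chart to file
#'
#' The format is taken from the file extension: `pdf` (always available),
#' `png`, or `svg` (requires the svglite package).
#'
#' @param plot A `ggplot` object, e.g. from [both_chart()].
#' @param path Output path ending in `.pdf`, `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @param dpi Raster resolution (png only).
#' @return `path`, invisibly.
#' @export
save_chart <- function(plot, path, width = 7, height = 8, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdf", "png", "svg")) {
    config_error(sprintf("unsupported chart format '%s' (use pdf, png or svg)", ext))
  }
  if (ext == "svg" && !requireNamespace("svglite", quietly = TRUE)) {
    io_error("svg output requires the svglite package; use pdf or png")
  }
  tryCatch(
    ggplot2::ggsave(path, plot = plot, width = width, height = height,
                    dpi = dpi),
    error = function(e) {
      io_error(sprintf("failed to write chart to %s: %s", path,
                       conditionMessage(e)))
    }
  )
  invisible(path)
}
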
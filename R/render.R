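#' Render the combined O-E CUSUM chart
#'
#' Draws the cumulative O-E curve across procedures and shades each detected
#' monitoring sequence over its procedure interval — red family for
#' deterioration, green family for improvement — with the rounded event
#' count annotated inside the band. Optionally a second panel shows the
#' underlying CUSUM subscores and control limits (`show_cusum = TRUE`,
#' requires the patchwork package), for users who want to see how close the
#' monitor is to signalling rather than treat it as a black box.
#'
#' SVG output (the default) uses the cairo device and contains no timestamps
#' or random identifiers, so identical inputs produce identical files —
#' convenient for regression-testing charts.
#'
#' @param result an [build_chart()] result.
#' @param path output file; extension is ignored in favour of `format`.
#' @param format `"svg"` or `"png"`.
#' @param deterioration_fill,improvement_fill shading colours.
#' @param annotate draw the rounded per-sequence event counts.
#' @param show_cusum add the CUSUM subscore panel below the O-E panel.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_chart <- function(result, path, format = c("svg", "png"),
                         deterioration_fill = "#d62728",
                         improvement_fill = "#2ca02c",
                         annotate = TRUE, show_cusum = FALSE,
                         width = 9, height = if (show_cusum) 7 else 4.5) {
  stopifnot(inherits(result, "oe_chart_result"))
  format <- match.arg(format)
  p_oe <- oe_panel(result, deterioration_fill, improvement_fill, annotate)
  plot_obj <- p_oe
  if (show_cusum) {
    if (!requireNamespace("patchwork", quietly = TRUE))
      stop("`show_cusum = TRUE` requires the patchwork package")
    plot_obj <- patchwork::wrap_plots(p_oe, cusum_panel(result), ncol = 1,
                                      heights = c(2, 1))
  }
  if (format == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot_obj)
  invisible(path)
}

oe_panel <- function(result, det_fill, imp_fill, annotate) {
  n <- length(result$oe$values)
  # the curve starts at (0, 0): the pre-first-procedure baseline
  curve <- data.frame(index = 0:n, oe = c(0, result$oe$values))
  seqs <- result$sequences
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$index, y = .data$oe))
  if (nrow(seqs)) {
    bands <- data.frame(xmin = seqs$start - 1, xmax = seqs$end,
                        side = seqs$side, count = seqs$display_count)
    p <- p +
      ggplot2::geom_rect(
        data = bands, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf, fill = .data$side),
        alpha = 0.25, show.legend = FALSE) +
      ggplot2::scale_fill_manual(
        values = c(deterioration = det_fill, improvement = imp_fill),
        name = NULL)
    if (annotate) {
      bands$y <- max(curve$oe) + 0.05 * max(1, diff(range(curve$oe)))
      p <- p + ggplot2::geom_text(
        data = bands, inherit.aes = FALSE,
        ggplot2::aes(x = (.data$xmin + .data$xmax) / 2, y = .data$y,
                     label = sprintf("%.1f", .data$count)),
        size = 3)
    }
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Procedure", y = "Cumulative O-E (events)",
                  title = result$label) +
    ggplot2::theme_minimal()
}

cusum_panel <- function(result) {
  tr <- result$trajectory
  n <- length(tr$x_plus)
  df <- data.frame(index = rep(seq_len(n), 2),
                   value = c(tr$x_plus, tr$x_minus),
                   side = rep(c("deterioration", "improvement"), each = n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = c(tr$h_plus, -tr$h_minus),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c(deterioration = "#d62728", improvement = "#2ca02c"),
      name = NULL) +
    ggplot2::labs(x = "Procedure", y = "CUSUM subscore") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
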
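# ggplot2 views of the main result types.

#' Plot a coverage profile
#'
#' Depth is summarized in windows (window medians) for display; the
#' genome-wide median is drawn as a dashed line and anomaly regions, when
#' supplied, are shaded.
#'
#' @param object A [compute_depth()] result.
#' @param anomalies Optional tibble from [detect_anomalies()].
#' @param window Summary window in bases for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, anomalies = NULL, window = 1000L, ...) {
  d <- tidy(object) %>%
    mutate(win = ceiling(.data$position / window)) %>%
    group_by(.data$win) %>%
    summarise(
      position = stats::median(.data$position),
      depth = stats::median(.data$depth), .groups = "drop"
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(
      yintercept = object$median, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Position (bp)", y = "Depth (x)",
      title = sprintf("%s coverage (median %.1fx)", object$scaffold_id, object$median)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(anomalies) && nrow(anomalies)) {
    p <- p + ggplot2::geom_rect(
      data = anomalies,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -Inf, ymax = Inf, fill = .data$kind
      ),
      alpha = 0.2, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(spike = "firebrick", dip = "steelblue"), name = "anomaly"
      )
  }
  p
}

#' Plot a topology model
#'
#' Each inferred molecule is drawn as a horizontal bar over its scaffold
#' interval, height-coded by relative copy number and labelled with its
#' topology and length.
#'
#' @param object A [infer_topology()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topology_model <- function(object, ...) {
  m <- object$molecules
  if (nrow(m) == 0L) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "unresolved topology") +
        ggplot2::theme_void()
    )
  }
  m <- m %>% mutate(
    y = row_number(),
    label = sprintf(
      "%s (%s, %s bp, copy %.2f)", .data$molecule, .data$topology,
      format(.data$length, big.mark = ","), .data$copy_number
    )
  )
  ggplot2::ggplot(m) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$y - 0.3 * .data$copy_number,
      ymax = .data$y + 0.3 * .data$copy_number,
      fill = .data$topology
    )) +
    ggplot2::geom_text(
      ggplot2::aes(
        x = (.data$start + .data$end) / 2, y = .data$y + 0.42,
        label = .data$label
      ),
      size = 3
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(
      x = "Scaffold position (bp)",
      title = sprintf("Inferred topology: %s", object$classification),
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
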
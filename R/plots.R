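#' Plot read coverage along the amplicon
#'
#' Coverage track from a pileup, with called variant positions marked as
#' vertical lines — the classic amplicon coverage view in which a true minor
#' variant appears as a thin vertical stripe against uniform coverage.
#'
#' @param object an `amp_pileup`.
#' @param variants optional `variant_calls` to mark.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.amp_pileup <- function(object, variants = NULL, ...) {
  df <- tibble(position = object$position, coverage = object$coverage)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(x = "amplicon position (bp)", y = "coverage (reads)") +
    ggplot2::theme_minimal()
  if (!is.null(variants) && nrow(variants) > 0) {
    vd <- tibble(position = variants$position,
                 label = variant_labels(variants),
                 frequency = variants$frequency)
    p <- p +
      ggplot2::geom_segment(
        data = vd,
        ggplot2::aes(x = .data$position, xend = .data$position,
                     y = 0, yend = max(df$coverage) * .data$frequency),
        colour = "red", linewidth = 0.8, inherit.aes = FALSE) +
      ggplot2::geom_text(
        data = vd,
        ggplot2::aes(x = .data$position, y = max(df$coverage) * 1.02,
                     label = .data$label),
        angle = 90, hjust = 0, size = 3, inherit.aes = FALSE)
  }
  p
}

#' Plot clonal composition
#'
#' @param object a `clone_table`.
#' @param ... ignored.
#' @return a ggplot bar chart of signature frequencies.
#' @export
autoplot.clone_table <- function(object, ...) {
  df <- tibble(
    signature = factor(ifelse(object$signature == "", "none", object$signature),
                       levels = ifelse(object$signature == "", "none", object$signature)),
    frequency = object$frequency
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$frequency)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "mutation signature (per molecule)",
                  y = "% of evaluable reads") +
    ggplot2::theme_minimal()
}

#' Plot isoform frequencies
#'
#' @param object an `isoform_table`.
#' @param ... ignored.
#' @return a ggplot bar chart of isoform frequencies among full-length reads.
#' @export
autoplot.isoform_table <- function(object, ...) {
  df <- tibble(label = factor(object$label, levels = object$label),
               frequency = object$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$frequency)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "isoform", y = "% of full-length reads") +
    ggplot2::theme_minimal()
}

#' Plot a dilution-series sensitivity experiment
#'
#' Expected versus observed variant frequency per dilution sample on a log
#' scale, with undetected points marked at the bottom of the panel.
#'
#' @param object a `sensitivity_report`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- object$results
  df$shown <- ifelse(df$detected, df$observed_pct, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected_pct, y = .data$shown,
                                   colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_point(data = df[!df$detected, ],
                        ggplot2::aes(y = min(df$expected_pct, na.rm = TRUE) / 2),
                        shape = 4, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "expected frequency (%)", y = "observed frequency (%)",
                  colour = "variant",
                  caption = "crosses: not detected") +
    ggplot2::theme_minimal()
}
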
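#' Plot a calibration result
#'
#' Draws the score-versus-LR curve for one calibrated score column: the
#' median LR on a log scale with its 95% confidence ribbon, reference
#' lines at the evidence-strength likelihood points, and a rug of the
#' labelled truthset scores.
#'
#' @param object An `acmg_calibration` from [calibrate()].
#' @param value Which score column to plot; defaults to the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acmg_calibration <- function(object, value = NULL, ...) {
  md <- object$metadata
  value <- value %||% md$value[1]
  if (!value %in% md$value) {
    abort(paste0("'", value, "' was not calibrated in this result."))
  }
  curve <- object$curves[[value]]
  ts <- object$likelihood_ratios
  lmin <- min(ts[[value]][ts[[md$class_col]] %in% c("P", "B")], na.rm = TRUE)
  lmax <- max(ts[[value]][ts[[md$class_col]] %in% c("P", "B")], na.rm = TRUE)
  cd <- tidy(curve)
  cd$score <- cd$grid * (lmax - lmin) + lmin

  sc <- object$scale
  points <- tidy(sc)
  labelled <- ts[ts[[md$class_col]] %in% c("P", "B"), ]

  ggplot2::ggplot(cd, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_hline(
      data = points,
      ggplot2::aes(yintercept = .data$lr_point),
      linetype = "dashed", colour = "grey70"
    ) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = exp(.data$lower_loglr),
                   ymax = exp(.data$upper_loglr)),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = exp(.data$median_loglr)),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_rug(
      data = labelled,
      ggplot2::aes(x = .data[[value]],
                   colour = .data[[md$class_col]]),
      inherit.aes = FALSE, sides = "b", alpha = 0.6
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(P = "#d55e76", B = "#5e9bd5"),
                                 name = "class") +
    ggplot2::labs(
      x = value, y = "likelihood ratio (log scale)",
      title = paste0("Calibrated ", value, " (prior = ", md$prior, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.acmg_calibration
#' @param x An `acmg_calibration`.
#' @export
plot.acmg_calibration <- function(x, value = NULL, ...) {
  print(autoplot.acmg_calibration(x, value = value, ...))
}
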
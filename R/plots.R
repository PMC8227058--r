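#' Field map of a trial layout
#'
#' Tile map of the field grid coloured by replication, labelled by block,
#' useful for eyeballing the randomization.
#'
#' @param layout A [make_layout()] layout.
#' @return A ggplot object.
#' @export
plot_layout <- function(layout) {
  stopifnot(inherits(layout, "htp_layout"))
  ggplot2::ggplot(
    as_tibble(layout),
    ggplot2::aes(.data$field_col, .data$field_row,
                 fill = factor(.data$rep))
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$block), size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "field column", y = "field row", fill = "rep") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted scatter for an out-of-fold HTP trait
#'
#' @param object An [crossval_predict()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.htp_cv <- function(object, ...) {
  ov <- regression_metrics(object$predictions$y, object$predictions$yhat)
  ggplot2::ggplot(object$predictions, ggplot2::aes(.data$y, .data$yhat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "observed (kg/ha)", y = "out-of-fold prediction (kg/ha)",
      title = sprintf("%s / %s", object$arch, object$target),
      subtitle = sprintf("r = %.2f, RMSE = %.0f", ov$r, ov$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' Overlaid observed/predicted histograms
#'
#' Visual companion to [histogram_intersection()]: both samples binned on
#' shared edges, with the intersection proportion in the title.
#'
#' @param y,yhat Observed and predicted vectors.
#' @param n_bins Number of shared bins.
#' @return A ggplot object.
#' @export
plot_histogram_intersection <- function(y, yhat, n_bins = 20) {
  hi <- histogram_intersection(y, yhat, n_bins)
  df <- dplyr::bind_rows(
    tibble(value = y, which = "observed"),
    tibble(value = yhat, which = "predicted")
  )
  brk <- seq(min(df$value), max(df$value), length.out = n_bins + 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, fill = .data$which)) +
    ggplot2::geom_histogram(breaks = brk, alpha = 0.5,
                            position = "identity") +
    ggplot2::labs(title = sprintf("histogram intersection = %.2f", hi),
                  x = "value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Family BLUPs with prediction-error bars
#'
#' @param object An [reml_fit()] result.
#' @param ... Unused.
#' @return A ggplot object (families ordered by BLUP).
#' @export
autoplot.htp_reml <- function(object, ...) {
  df <- tidy(object)
  df$family <- factor(df$family, levels = df$family[order(df$blup)])
  ggplot2::ggplot(df, ggplot2::aes(.data$blup, .data$family)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$blup - sqrt(.data$pev),
                   xmax = .data$blup + sqrt(.data$pev)),
      height = 0, linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::labs(x = "family BLUP (kg/ha)", y = NULL,
                  title = sprintf("%s: H = %.2f", object$spec$trait, object$H)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
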
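# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted invasiveness model
#'
#' @param x a `ggn_model`.
#' @param ... unused.
#' @return A tibble with `term` and `estimate` (intercept first).
#' @export
tidy.ggn_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$selected_features),
                 estimate = unname(c(x$intercept, x$coefficients)))
}

#' @rdname tidy.ggn_model
#' @export
glance.ggn_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_invasive = x$n_invasive,
                 n_features = length(x$selected_features),
                 cutoff = x$cutoff, flagged = x$flagged,
                 separated = x$separated)
}

#' Tidy an evaluation result
#'
#' @param x a `ggn_eval`.
#' @param ... unused.
#' @return `tidy()`: the ROC points (threshold, fpr, tpr); `glance()`: a
#'   one-row tibble of the summary metrics.
#' @export
tidy.ggn_eval <- function(x, ...) x$roc_points

#' @rdname tidy.ggn_eval
#' @export
glance.ggn_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 youden_J = x$youden_J, cutoff = x$cutoff,
                 n = x$n, n_invasive = x$n_invasive)
}

#' ROC curve plot
#'
#' @param object a `ggn_eval`.
#' @param ... unused.
#' @return A ggplot: the ROC curve with the chance diagonal, the AUC in the
#'   subtitle and the operating point at the chosen cutoff.
#' @export
autoplot.ggn_eval <- function(object, ...) {
  pts <- object$roc_points
  op <- pts[which.min(abs(pts$threshold - object$cutoff)), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_point(data = op, colour = "#b2182b", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "Invasiveness model ROC",
      subtitle = sprintf("AUC %.4f; Youden cutoff %.3f (J = %.3f)",
                         object$auc, object$cutoff, object$youden_J)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume
#'
#' @param volume a `ggn_volume`.
#' @param z slice index (default: middle slice).
#' @param mask optional logical array; its slice contour is overlaid.
#' @return A ggplot raster of the slice in HU.
#' @export
plot_slice <- function(volume, z = NULL, mask = NULL) {
  stopifnot(inherits(volume, "ggn_volume"))
  d <- dim(volume$values)
  z <- z %||% ((d[1] + 1L) %/% 2L)
  sl <- volume$values[z, , ]
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$hu <- as.vector(t(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "HU") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Axial slice z = %d", z)) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    dfm <- df
    dfm$m <- as.vector(t(mask[z, , ]))
    p <- p + ggplot2::geom_tile(
      data = dfm[dfm$m, , drop = FALSE],
      fill = NA, colour = "#b2182b", linewidth = 0.1)
  }
  p
}
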
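# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(m) {
  tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         value = as.vector(m))
}

#' Plot a synthetic sample
#'
#' @param object a `synthetic_sample`.
#' @param what `"image"`, `"leaf_mask"` or `"vein_mask"`.
#' @param ... unused.
#' @export
autoplot.synthetic_sample <- function(object, what = c("image", "leaf_mask",
                                                       "vein_mask"), ...) {
  what <- match.arg(what)
  if (what == "image") {
    img <- object$image
    df <- raster_df(img[, , 1])
    df$fill <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                              as.vector(img[, , 3]))
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::theme_void()
  } else {
    df <- raster_df(object[[what]])
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none") +
      ggplot2::theme_void()
  }
}

#' Bar plot of component-count comparison with Tukey groups
#'
#' @param object a `component_comparison`.
#' @param ... unused.
#' @export
autoplot.component_comparison <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$model, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$group,
                                    y = .data$ci_hi), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "connected components (mean, 95% CI)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of digital vs manual measurements with the fitted line
#'
#' @param object a `linear_validation`.
#' @param ... unused.
#' @export
autoplot.linear_validation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$pred, .data$manual)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "red") +
    ggplot2::labs(x = "digital measurement", y = "manual measurement",
                  subtitle = sprintf("R² = %.3f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Training-history curve of a fitted model
#'
#' @param object any `leaftrace_conv_model`.
#' @param ... unused.
#' @export
autoplot.leaftrace_conv_model <- function(object, ...) {
  h <- object$history
  df <- tibble(epoch = rep(h$epoch, 2),
               loss = c(h$train_loss, h$val_loss),
               set = rep(c("train", "validation"), each = nrow(h)))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::theme_minimal()
}
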
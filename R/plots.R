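# Plot helpers (ggplot2) for training histories and phantom samples.

#' Plot a training history
#'
#' Train/validation loss and validation Dice against the epoch.
#'
#' @param history the tibble returned in `train()$history`.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_history() needs ggplot2", call. = FALSE)
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss, series = "train loss"),
    data.frame(epoch = history$epoch, value = history$val_loss, series = "val loss"),
    data.frame(epoch = history$epoch, value = history$val_dice, series = "val Dice"))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value,
                                     colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phantom image with its mask outline
#'
#' @param sample `list(image = , mask = )` as returned by
#'   [generate_phantom()].
#' @return A ggplot object.
#' @export
plot_phantom <- function(sample) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_phantom() needs ggplot2", call. = FALSE)
  H <- nrow(sample$image); W <- ncol(sample$image)
  df <- data.frame(x = rep(seq_len(W), each = H), y = rep(seq_len(H), W),
                   intensity = as.vector(sample$image),
                   mask = as.vector(sample$mask))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
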
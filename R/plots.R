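# ggplot2 visualisations: training curves for fits and image/mask overlays
# for qualitative inspection of segmentations.

#' Training curves for a fit
#'
#' Loss components and dice trajectories per epoch, faceted by quantity.
#'
#' @param object a `madrnet_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.madrnet_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$loss, series = "hybrid loss",
                   panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$ce, series = "cross-entropy",
                   panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$dice_loss, series = "dice loss",
                   panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$focal_tversky,
                   series = "focal Tversky", panel = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$train_dice, series = "train",
                   panel = "dice"),
    tibble::tibble(epoch = h$epoch, value = h$val_dice, series = "validation",
                   panel = "dice")
  )
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Image with ground-truth / predicted mask overlay
#'
#' @param image matrix or `(H, W, C)` array in `[0, 1]`.
#' @param mask integer label matrix (0 = background).
#' @param pred optional predicted label matrix drawn as contours.
#' @return a ggplot object.
#' @export
plot_segmentation <- function(image, mask = NULL, pred = NULL) {
  img <- if (is.matrix(image)) image else apply(image, c(1, 2), mean)
  h <- nrow(img); w <- ncol(img)
  df <- tibble::tibble(
    y = rep(seq_len(h), times = w),
    x = rep(seq_len(w), each = h),
    intensity = as.vector(img)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask) && any(mask > 0)) {
    mdf <- df
    mdf$label <- as.vector(mask)
    mdf <- mdf[mdf$label > 0, ]
    p <- p + ggplot2::geom_raster(data = mdf,
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  fill = "red", alpha = 0.25)
  }
  if (!is.null(pred)) {
    pdf_ <- df
    pdf_$label <- as.vector(pred)
    p <- p + ggplot2::geom_contour(
      data = pdf_, ggplot2::aes(z = .data$label), breaks = 0.5,
      colour = "cyan", linewidth = 0.4)
  }
  p
}
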
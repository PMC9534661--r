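# ggplot2 helpers for volumes, fits and studies.

#' Plot one slice of a volume with an optional mask overlay
#'
#' @param volume 3-D intensity array.
#' @param mask Optional binary mask of the same shape.
#' @param slice Slice index along `axis`.
#' @param axis Slice axis (default 3).
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, mask = NULL, slice = dim(volume)[axis] %/% 2,
                       axis = 3L) {
  s <- slice_along(volume, axis, slice)
  df <- data.frame(x = rep(seq_len(nrow(s)), ncol(s)),
                   y = rep(seq_len(ncol(s)), each = nrow(s)),
                   intensity = as.vector(s))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "HU")
  if (!is.null(mask)) {
    ms <- slice_along(mask, axis, slice)
    sel <- df[as.vector(ms) != 0, ]
    if (nrow(sel) > 0)
      p <- p + ggplot2::geom_tile(data = sel, fill = "red", alpha = 0.45)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-history curves of a DA-UNet fit
#' @param object A `daunet_fit`.
#' @param ... Unused.
#' @return A ggplot object (loss per epoch, plus validation Dice when
#'   recorded).
#' @export
autoplot.daunet_fit <- function(object, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss")
  if (!all(is.na(h$val_dice)))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_dice),
                                colour = "steelblue", linetype = 2)
  p
}

#' Per-phantom localization errors of a study
#' @param object A `localization_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.localization_study <- function(object, ...) {
  ggplot2::ggplot(object$per_phantom,
                  ggplot2::aes(x = factor(.data$phantom),
                               y = .data$mean_distance_mm)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "phantom", y = "mean matched distance (mm)")
}
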
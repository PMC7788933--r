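#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster facet_wrap
#'   labs scale_fill_viridis_c scale_fill_gradient theme_minimal coord_equal
#'   geom_col
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

raster_df <- function(m, what) {
  tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         value = as.vector(m), what = what)
}

#' Plot training curves
#'
#' Training loss and (when recorded) test MIoU/Dice per epoch.
#'
#' @param object a `train_log` tibble from [train_model()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot train_log
#' @export
autoplot.train_log <- function(object, ...) {
  df <- tibble(epoch = rep(object$epoch, 3),
               metric = rep(c("train loss", "test MIoU", "test Dice"),
                            each = nrow(object)),
               value = c(object$train_loss, object$test_miou,
                         object$test_dice))
  df <- df[is.finite(df$value), , drop = FALSE]
  ggplot(df, aes(x = .data$epoch, y = .data$value,
                 colour = .data$metric)) +
    geom_line() +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a segmentation sample
#'
#' Image and ground-truth mask side by side.
#'
#' @param object a segmentation sample.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot segmentation_sample
#' @export
autoplot.segmentation_sample <- function(object, ...) {
  df <- rbind(raster_df(object$image, "image"),
              raster_df(object$mask, "mask"))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~what) +
    scale_fill_gradient(low = "black", high = "white") +
    coord_equal() +
    labs(x = NULL, y = NULL, title = object$id) +
    theme_minimal()
}

#' Plot a probability map
#'
#' @param object a `probability_map` from [predict.unet_model()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot probability_map
#' @export
autoplot.probability_map <- function(object, ...) {
  df <- raster_df(unclass(object), "p")
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "P(fg)") +
    theme_minimal()
}

#' Plot a cost report
#'
#' Per-layer parameter and MAC counts.
#'
#' @param object a `cost_report` from [count_network()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cost_report
#' @export
autoplot.cost_report <- function(object, ...) {
  df <- tibble(layer = factor(rep(object$layer, 2),
                              levels = unique(object$layer)),
               quantity = rep(c("parameters", "MACs"),
                              each = nrow(object)),
               value = c(object$params, object$macs))
  df <- df[df$value > 0, , drop = FALSE]
  ggplot(df, aes(x = .data$layer, y = .data$value)) +
    geom_col() +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom rlang .data
NULL
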
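#' Predict a probability map for one image
#'
#' Runs the network in evaluation mode (batch norm uses running statistics)
#' on a single-channel image and returns the sigmoid probability map, the
#' same spatial size as the input, every value strictly between 0 and 1.
#'
#' @param object a built `unet_model`.
#' @param image numeric matrix (H x W) with values in \[0, 1\], or an
#'   `(H, W, C)` array matching the topology's input channels.  H and W must
#'   be divisible by `2^n_downsamplings`.
#' @param ... unused.
#' @return a `probability_map`: an H x W matrix of values in (0, 1).
#' @export
predict.unet_model <- function(object, image, ...) {
  topo <- object$topology
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3)
    abort("image must be an H x W matrix or (H, W, C) array")
  if (dim(image)[3] != topo$in_channels)
    abort(sprintf("image has %d channels, topology expects %d",
                  dim(image)[3], topo$in_channels))
  dv <- 2^topo$n_downsamplings
  if (any(dim(image)[1:2] %% dv != 0))
    abort(sprintf(paste0("image size %dx%d is not divisible by %d ",
                         "(= 2^n_downsamplings); resize or pad the input"),
                  dim(image)[1], dim(image)[2], dv))
  x <- array(image, dim = c(dim(image), 1L))
  fw <- net_forward(object, x, training = FALSE)
  out <- fw$prob[, , 1, 1]
  structure(out, class = c("probability_map", "matrix", "array"))
}

#' Threshold a probability map into a binary mask
#'
#' @param map a probability map (numeric matrix in (0, 1)).
#' @param threshold scalar strictly between 0 and 1; pixels with value `>=`
#'   threshold become 1.
#' @return integer 0/1 matrix of the same size.
#' @examples
#' binarize(matrix(c(0.2, 0.8), 1), 0.5)
#' @export
binarize <- function(map, threshold = 0.5) {
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1)
    abort("threshold must lie strictly between 0 and 1")
  out <- matrix(as.integer(map >= threshold), nrow = nrow(map))
  out
}
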
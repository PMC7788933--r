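#' Describe a U-Net-family topology
#'
#' The topology fixes the encoder--decoder skeleton: `n_downsamplings` stages
#' of double 3x3 convolution blocks (each convolution followed by batch
#' normalization and ReLU) with 2x2 stride-2 max pooling between them, a
#' double-conv bottleneck, a decoder of 2x2 stride-2 transposed convolutions
#' that halve the channel count, skip concatenation with the same-resolution
#' encoder feature, double-conv blocks, and a 1x1 output convolution followed
#' by a sigmoid.  Channel width doubles at every down-sampling and halves at
#' every up-sampling.  All convolutions are same-padded, so spatial size is
#' preserved at every stage.
#'
#' With `conv_kind = "pyconv"` every convolution inside the double-conv
#' blocks (encoder, bottleneck and decoder) becomes a pyramidal convolution
#' according to `schedule`; the transposed up-convolutions and the 1x1 head
#' stay standard.
#'
#' @param in_channels input image channels (1 for grayscale).
#' @param out_channels output channels (1 for binary masks).
#' @param base_width channels after the first block.
#' @param n_downsamplings number of pooling steps.
#' @param conv_kind `"standard"` or `"pyconv"`.
#' @param schedule for `conv_kind = "pyconv"`: a named list mapping block
#'   convolution ids (`enc1a`, `enc1b`, ..., `bot_a`, `bot_b`, `dec4a`, ...)
#'   to `list(kernel_sizes =, groups =)` templates, as returned by
#'   [pyconv_default_schedule()] or [pyconv_uniform_schedule()].  `NULL`
#'   selects the package default for the topology.
#' @return An object of class `unet_topology`.
#' @export
unet_topology <- function(in_channels = 1, out_channels = 1, base_width = 32,
                          n_downsamplings = 4,
                          conv_kind = c("standard", "pyconv"),
                          schedule = NULL) {
  conv_kind <- match.arg(conv_kind)
  for (v in c(in_channels, out_channels, base_width, n_downsamplings))
    if (length(v) != 1 || v < 1 || v != round(v))
      abort("topology fields must be positive integers")
  topo <- structure(
    list(in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         base_width = as.integer(base_width),
         n_downsamplings = as.integer(n_downsamplings),
         conv_kind = conv_kind,
         schedule = NULL),
    class = "unet_topology")
  if (conv_kind == "pyconv") {
    topo$schedule <- schedule %||% pyconv_default_schedule(topo)
    ids <- block_conv_ids(n_downsamplings)
    missing <- setdiff(ids, names(topo$schedule))
    if (length(missing))
      abort(paste0("schedule is missing entries for: ",
                   paste(missing, collapse = ", ")))
  }
  topo
}

#' @export
print.unet_topology <- function(x, ...) {
  cat(sprintf("<unet_topology> %s conv, in=%d out=%d base=%d depth=%d\n",
              x$conv_kind, x$in_channels, x$out_channels, x$base_width,
              x$n_downsamplings))
  invisible(x)
}

block_conv_ids <- function(n_down) {
  c(as.vector(t(outer(paste0("enc", seq_len(n_down)), c("a", "b"), paste0))),
    "bot_a", "bot_b",
    as.vector(t(outer(paste0("dec", rev(seq_len(n_down))), c("a", "b"),
                      paste0))))
}

# in/out channels and resolution divisor for every block convolution
block_conv_table <- function(topology) {
  nd <- topology$n_downsamplings
  w <- topology$base_width * 2^(seq_len(nd) - 1)
  wb <- topology$base_width * 2^nd
  rows <- list()
  for (s in seq_len(nd)) {
    cin <- if (s == 1) topology$in_channels else w[s - 1]
    rows[[length(rows) + 1]] <-
      data.frame(id = paste0("enc", s, "a"), cin = cin, cout = w[s],
                 div = 2^(s - 1))
    rows[[length(rows) + 1]] <-
      data.frame(id = paste0("enc", s, "b"), cin = w[s], cout = w[s],
                 div = 2^(s - 1))
  }
  rows[[length(rows) + 1]] <-
    data.frame(id = "bot_a", cin = w[nd], cout = wb, div = 2^nd)
  rows[[length(rows) + 1]] <-
    data.frame(id = "bot_b", cin = wb, cout = wb, div = 2^nd)
  for (s in rev(seq_len(nd))) {
    rows[[length(rows) + 1]] <-
      data.frame(id = paste0("dec", s, "a"), cin = 2 * w[s], cout = w[s],
                 div = 2^(s - 1))
    rows[[length(rows) + 1]] <-
      data.frame(id = paste0("dec", s, "b"), cin = w[s], cout = w[s],
                 div = 2^(s - 1))
  }
  do.call(rbind, rows)
}

# transposed up-convolutions: id, cin, cout, output resolution divisor
upconv_table <- function(topology) {
  nd <- topology$n_downsamplings
  w <- topology$base_width * 2^(seq_len(nd) - 1)
  wb <- topology$base_width * 2^nd
  do.call(rbind, lapply(rev(seq_len(nd)), function(s) {
    data.frame(id = paste0("up", s),
               cin = if (s == nd) wb else w[s + 1],
               cout = w[s], div = 2^(s - 1))
  }))
}

#' The package's default pyramidal-convolution schedule
#'
#' For the canonical topology (base width 32, 4 down-samplings) this returns
#' the calibrated per-layer schedule shipped with the package: kernel-size
#' prefixes of (3, 5, 7, 9) with power-of-two, non-decreasing group counts,
#' chosen by discrete search so that the full network reproduces the published
#' parameter and multiply--accumulate budget of the pyramidal-convolution
#' U-Net (3.7 M parameters; 10.65 GMac at a 512x512 input) while satisfying
#' every pyramid invariant (odd increasing kernels, non-increasing kernel
#' depth, groups dividing both input and level-output channels).  For any
#' other topology it falls back to the uniform 4-level template
#' kernels (3, 5, 7, 9), groups (1, 4, 8, 16).
#'
#' @param topology a [unet_topology()].
#' @return named list of `list(kernel_sizes =, groups =)` templates, one per
#'   block convolution id.
#' @export
pyconv_default_schedule <- function(topology) {
  if (topology$base_width == 32 && topology$n_downsamplings == 4) {
    k2 <- c(3L, 5L); k1 <- 3L; k4 <- c(3L, 5L, 7L, 9L)
    list(
      enc1a = list(kernel_sizes = k1, groups = 1L),
      enc1b = list(kernel_sizes = k1, groups = 32L),
      enc2a = list(kernel_sizes = k2, groups = c(16L, 32L)),
      enc2b = list(kernel_sizes = k2, groups = c(4L, 32L)),
      enc3a = list(kernel_sizes = k2, groups = c(8L, 16L)),
      enc3b = list(kernel_sizes = k2, groups = c(32L, 32L)),
      enc4a = list(kernel_sizes = k2, groups = c(64L, 64L)),
      enc4b = list(kernel_sizes = k2, groups = c(32L, 128L)),
      bot_a = list(kernel_sizes = k2, groups = c(32L, 128L)),
      bot_b = list(kernel_sizes = k4, groups = c(1L, 1L, 16L, 16L)),
      dec4a = list(kernel_sizes = k2, groups = c(32L, 64L)),
      dec4b = list(kernel_sizes = k2, groups = c(32L, 128L)),
      dec3a = list(kernel_sizes = k2, groups = c(4L, 64L)),
      dec3b = list(kernel_sizes = k2, groups = c(32L, 32L)),
      dec2a = list(kernel_sizes = k2, groups = c(16L, 16L)),
      dec2b = list(kernel_sizes = k2, groups = c(4L, 32L)),
      dec1a = list(kernel_sizes = k1, groups = 2L),
      dec1b = list(kernel_sizes = k1, groups = 32L)
    )
  } else {
    pyconv_uniform_schedule(topology)
  }
}

#' Uniform pyramidal-convolution schedule
#'
#' Applies one kernel/group template to every block convolution of a
#' topology.  Group counts are capped per layer to the largest valid divisor
#' of the layer's input and level-output channels (so e.g. the 1-channel stem
#' degrades gracefully), preserving the non-increasing kernel-depth
#' invariant.
#'
#' @param topology a [unet_topology()].
#' @param kernel_sizes,groups the template, by default the 4-level pyramid
#'   kernels (3, 5, 7, 9) with groups (1, 4, 8, 16).
#' @return named list of per-layer templates.
#' @export
pyconv_uniform_schedule <- function(topology, kernel_sizes = c(3, 5, 7, 9),
                                    groups = c(1, 4, 8, 16)) {
  ids <- block_conv_ids(topology$n_downsamplings)
  stats::setNames(lapply(ids, function(id)
    list(kernel_sizes = as.integer(kernel_sizes),
         groups = as.integer(groups))), ids)
}

# resolve the pyconv_spec for one block convolution of a pyconv topology
layer_pyconv_spec <- function(topology, id, cin, cout) {
  tpl <- topology$schedule[[id]]
  if (is.null(tpl)) abort(sprintf("no schedule entry for layer '%s'", id))
  pyconv_spec_from_template(cin, cout, tpl$kernel_sizes, tpl$groups)
}
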
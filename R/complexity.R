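#' Parameter count of a standard (optionally grouped) convolution
#'
#' The closed form `K^2 * (in_channels / groups) * out_channels`, excluding
#' any bias or normalization parameters (those are accounted separately by
#' [count_network()]).
#'
#' @param kernel_size spatial kernel size `K` (square kernel).
#' @param in_channels,out_channels feature-map channel counts.
#' @param groups grouped-convolution group count (1 = dense).
#' @return exact integer-valued count (as a double to avoid overflow).
#' @examples
#' params_standard(3, 64, 64)            # 36864
#' params_standard(3, 64, 64, groups = 4) # 9216
#' @export
params_standard <- function(kernel_size, in_channels, out_channels,
                            groups = 1) {
  check_pos <- function(v, nm)
    if (length(v) != 1 || v < 1 || v != round(v))
      abort(sprintf("%s must be a positive integer", nm))
  check_pos(kernel_size, "kernel_size")
  check_pos(in_channels, "in_channels")
  check_pos(out_channels, "out_channels")
  check_pos(groups, "groups")
  if (in_channels %% groups != 0 || out_channels %% groups != 0)
    abort("groups must divide both in_channels and out_channels")
  kernel_size^2 * (in_channels / groups) * out_channels
}

#' Multiply--accumulate count of a standard convolution
#'
#' `params_standard(...) * width * height` where width and height are the
#' output feature-map size (one multiply--accumulate per weight per output
#' pixel).
#'
#' @inheritParams params_standard
#' @param width,height output feature-map size in pixels.
#' @return exact MAC count.
#' @examples
#' flops_standard(3, 1, 1, 1, 1)  # 9
#' @export
flops_standard <- function(kernel_size, in_channels, out_channels,
                           width, height, groups = 1) {
  if (width < 1 || height < 1) abort("width and height must be positive")
  params_standard(kernel_size, in_channels, out_channels, groups) *
    width * height
}

#' Parameter count of a pyramidal convolution
#'
#' Two accountings are exposed.  `"realizable"` sums, over levels,
#' `K_z^2 * (in_channels / groups_z) * out_channels_z` -- the parameters of
#' the grouped convolutions actually instantiated.  `"idealized"` uses the
#' idealized kernel depth `in_channels / (K_z^2 / K_1^2)` (which is generally
#' not an integer, hence not realizable as a group count), under which every
#' level contributes `K_1^2 * in_channels * out_channels_z` and the total
#' collapses to the standard convolution's `K_1^2 * in_channels *
#' out_channels` regardless of the number of levels -- the cost-equality
#' property of the pyramid.
#'
#' @param spec a [pyconv_spec()].
#' @param mode `"realizable"` (default) or `"idealized"`.
#' @return parameter count (exact for realizable mode; the idealized total is
#'   integral even when per-level terms are fractional).
#' @examples
#' sp <- pyconv_spec(64, 64, c(3, 5, 7, 9), c(1, 4, 8, 16))
#' params_pyconv(sp)               # 27072
#' params_pyconv(sp, "idealized")  # 36864 = params_standard(3, 64, 64)
#' @export
params_pyconv <- function(spec, mode = c("realizable", "idealized")) {
  stopifnot(inherits(spec, "pyconv_spec"))
  mode <- match.arg(mode)
  lv <- spec$levels
  if (mode == "realizable") {
    sum(lv$kernel_size^2 * (spec$in_channels / lv$groups) * lv$out_channels)
  } else {
    k1 <- lv$kernel_size[1]
    depth_ideal <- spec$in_channels / (lv$kernel_size^2 / k1^2)
    sum(lv$kernel_size^2 * depth_ideal * lv$out_channels)
  }
}

#' Multiply--accumulate count of a pyramidal convolution
#'
#' `params_pyconv(spec, mode) * width * height`; in idealized mode this
#' equals the standard convolution's MAC count at kernel size `K_1`.
#'
#' @inheritParams params_pyconv
#' @param width,height output feature-map size in pixels.
#' @return exact MAC count.
#' @export
flops_pyconv <- function(spec, width, height,
                         mode = c("realizable", "idealized")) {
  if (width < 1 || height < 1) abort("width and height must be positive")
  params_pyconv(spec, mode) * width * height
}

#' Multiply--accumulate counting convention
#'
#' Analytic "FLOP" counters disagree about which operation classes they
#' count.  The convention object makes the choice explicit.  The package
#' default counts one MAC per weight per output pixel for convolutions and
#' transposed convolutions only (transposed convolutions counted exactly:
#' `K^2 * Cin * Cout * Hin * Win`, i.e. every weight touches every input
#' pixel once), and counts parameters as every array a checkpoint stores:
#' convolution weights, biases where present, and 4 per batch-norm channel
#' (scale, shift, running mean, running variance).
#'
#' @param count_bn_macs,count_activation_macs,count_pooling_macs,count_bias_macs
#'   logical flags adding 1 MAC (2 for affine batch norm) per element for the
#'   respective op class.
#' @param transposed_conv_output_pixels if `TRUE`, transposed convolutions
#'   are counted per *output* pixel (`K^2 * Cin * Cout * Hout * Wout`, the
#'   convention of some profilers, a 4x overcount for 2x2 stride-2).
#' @param bn_params_per_channel parameters attributed to each normalized
#'   channel (4 = affine + running statistics; 2 = affine only).
#' @return a `counting_convention` list.
#' @export
counting_convention <- function(count_bn_macs = FALSE,
                                count_activation_macs = FALSE,
                                count_pooling_macs = FALSE,
                                count_bias_macs = FALSE,
                                transposed_conv_output_pixels = FALSE,
                                bn_params_per_channel = 4) {
  structure(list(count_bn_macs = count_bn_macs,
                 count_activation_macs = count_activation_macs,
                 count_pooling_macs = count_pooling_macs,
                 count_bias_macs = count_bias_macs,
                 transposed_conv_output_pixels = transposed_conv_output_pixels,
                 bn_params_per_channel = bn_params_per_channel),
            class = "counting_convention")
}

#' Analytic cost report for a whole network
#'
#' Walks every layer of a topology (or of a built model) and reports exact
#' parameter and multiply--accumulate counts per layer plus totals, under an
#' explicit [counting_convention()].  The parameter totals agree exactly with
#' enumerating the weight arrays of the instantiated network.
#'
#' @param x a [unet_topology()] or a built model.
#' @param input_size input image size, a single integer or `c(H, W)`; both
#'   must be divisible by `2^n_downsamplings`.
#' @param convention a [counting_convention()].
#' @return a tibble of class `cost_report` with columns `layer`, `type`,
#'   `params`, `macs`; totals available via [glance()].
#' @examples
#' count_network(unet_topology(base_width = 8, n_downsamplings = 2), 64)
#' @export
count_network <- function(x, input_size = 512,
                          convention = counting_convention()) {
  topology <- if (inherits(x, "unet_model")) x$topology else x
  stopifnot(inherits(topology, "unet_topology"))
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  H <- input_size[1]; W <- input_size[2]
  dv <- 2^topology$n_downsamplings
  if (H %% dv != 0 || W %% dv != 0)
    abort(sprintf("input size must be divisible by %d (2^n_downsamplings)", dv))
  rows <- list()
  add <- function(layer, type, params, macs)
    rows[[length(rows) + 1]] <<- tibble(layer = layer, type = type,
                                        params = params, macs = macs)
  bnp <- convention$bn_params_per_channel
  elementwise <- function(ch, h, w, per_el) per_el * ch * h * w
  bt <- block_conv_table(topology)
  for (i in seq_len(nrow(bt))) {
    id <- bt$id[i]; cin <- bt$cin[i]; cout <- bt$cout[i]
    h <- H / bt$div[i]; w <- W / bt$div[i]
    if (topology$conv_kind == "pyconv") {
      sp <- layer_pyconv_spec(topology, id, cin, cout)
      p <- params_pyconv(sp, "realizable")
      m <- flops_pyconv(sp, w, h, "realizable")
      add(id, "pyconv", p, m)
    } else {
      p <- params_standard(3, cin, cout)
      add(id, "conv3x3", p, flops_standard(3, cin, cout, w, h))
    }
    bn_m <- if (convention$count_bn_macs) elementwise(cout, h, w, 2) else 0
    add(paste0(id, ".bn"), "batchnorm", bnp * cout, bn_m)
    if (convention$count_activation_macs)
      add(paste0(id, ".relu"), "relu", 0, elementwise(cout, h, w, 1))
  }
  if (convention$count_pooling_macs) {
    nd <- topology$n_downsamplings
    wdt <- topology$base_width * 2^(seq_len(nd) - 1)
    for (s in seq_len(nd))
      add(paste0("pool", s), "maxpool2x2", 0,
          elementwise(wdt[s], H / 2^(s - 1), W / 2^(s - 1), 1))
  }
  ut <- upconv_table(topology)
  for (i in seq_len(nrow(ut))) {
    hin <- H / (2 * ut$div[i]); win <- W / (2 * ut$div[i])
    p <- 4 * ut$cin[i] * ut$cout[i] + ut$cout[i] # weights + bias
    m <- if (convention$transposed_conv_output_pixels)
      4 * ut$cin[i] * ut$cout[i] * (2 * hin) * (2 * win)
    else
      4 * ut$cin[i] * ut$cout[i] * hin * win
    if (convention$count_bias_macs)
      m <- m + elementwise(ut$cout[i], 2 * hin, 2 * win, 1)
    add(ut$id[i], "convtr2x2", p, m)
  }
  hp <- topology$base_width * topology$out_channels + topology$out_channels
  hm <- flops_standard(1, topology$base_width, topology$out_channels, W, H)
  if (convention$count_bias_macs)
    hm <- hm + elementwise(topology$out_channels, H, W, 1)
  add("head", "conv1x1", hp, hm)
  if (convention$count_activation_macs)
    add("sigmoid", "sigmoid", 0, elementwise(topology$out_channels, H, W, 1))
  out <- dplyr::bind_rows(rows)
  attr(out, "convention") <- convention
  attr(out, "input_size") <- c(H, W)
  class(out) <- c("cost_report", class(out))
  out
}

#' @method glance cost_report
#' @export
glance.cost_report <- function(x, ...) {
  tibble(params = sum(x$params),
         macs = sum(x$macs),
         params_millions = sum(x$params) / 1e6,
         gmac = sum(x$macs) / 1e9)
}

#' @method tidy cost_report
#' @export
tidy.cost_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
print.cost_report <- function(x, ...) {
  NextMethod()
  g <- glance.cost_report(x)
  cat(sprintf("# total: %.0f params (%.2f M), %.0f MACs (%.2f GMac)\n",
              g$params, g$params_millions, g$macs, g$gmac))
  invisible(x)
}
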
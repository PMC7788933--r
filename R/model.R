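#' Build the baseline U-Net
#'
#' Instantiates weights for a standard-convolution topology: Kaiming fan-in
#' Gaussian initialisation for convolution kernels, batch-norm scale 1 /
#' shift 0, zero biases.  Convolutions inside double-conv blocks carry no
#' bias (they are followed by batch normalization); the transposed
#' up-convolutions and the 1x1 head carry biases.
#'
#' @param topology a [unet_topology()] with `conv_kind = "standard"`;
#'   alternatively arguments to construct one.
#' @param seed integer seed controlling the initialisation.
#' @return an object of class `unet_model`.
#' @examples
#' m <- build_unet(unet_topology(base_width = 4, n_downsamplings = 1), seed = 1)
#' n_parameters(m)
#' @export
build_unet <- function(topology = unet_topology(), seed = NULL) {
  stopifnot(inherits(topology, "unet_topology"))
  if (topology$conv_kind != "standard")
    abort("build_unet() expects conv_kind = 'standard'; see build_pyconvunet()")
  build_network(topology, seed)
}

#' Build the pyramidal-convolution U-Net
#'
#' Identical skeleton to [build_unet()], but every convolution inside the
#' double-conv blocks (encoder, bottleneck and decoder) is a pyramidal
#' convolution following the topology's schedule; up-convolutions and the
#' 1x1 head remain standard.  With the default calibrated schedule at base
#' width 32 the parameter total is strictly less than half the baseline
#' U-Net's.
#'
#' @param topology a [unet_topology()] with `conv_kind = "pyconv"`, or `NULL`
#'   for the canonical one (base width 32, 4 down-samplings, default
#'   schedule).
#' @param seed integer seed controlling the initialisation.
#' @return an object of class `unet_model`.
#' @export
build_pyconvunet <- function(topology = NULL, seed = NULL) {
  if (is.null(topology)) topology <- unet_topology(conv_kind = "pyconv")
  stopifnot(inherits(topology, "unet_topology"))
  if (topology$conv_kind != "pyconv")
    abort("build_pyconvunet() expects conv_kind = 'pyconv'")
  build_network(topology, seed)
}

kaiming <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

build_network <- function(topology, seed = NULL) {
  with_seed(seed, {
    params <- list()
    buffers <- list()
    specs <- list()
    bt <- block_conv_table(topology)
    for (i in seq_len(nrow(bt))) {
      id <- bt$id[i]; cin <- bt$cin[i]; cout <- bt$cout[i]
      if (topology$conv_kind == "pyconv") {
        sp <- layer_pyconv_spec(topology, id, cin, cout)
        specs[[id]] <- sp
        for (z in seq_len(nrow(sp$levels))) {
          lv <- sp$levels[z, ]
          params[[paste0(id, ".L", z, ".w")]] <-
            kaiming(c(lv$kernel_size, lv$kernel_size, lv$depth,
                      lv$out_channels), lv$kernel_size^2 * lv$depth)
        }
      } else {
        params[[paste0(id, ".w")]] <- kaiming(c(3, 3, cin, cout), 9 * cin)
      }
      params[[paste0(id, ".bn.gamma")]] <- rep(1, cout)
      params[[paste0(id, ".bn.beta")]] <- rep(0, cout)
      buffers[[paste0(id, ".bn.mean")]] <- rep(0, cout)
      buffers[[paste0(id, ".bn.var")]] <- rep(1, cout)
    }
    ut <- upconv_table(topology)
    for (i in seq_len(nrow(ut))) {
      id <- ut$id[i]
      params[[paste0(id, ".w")]] <- kaiming(c(2, 2, ut$cin[i], ut$cout[i]),
                                            4 * ut$cin[i])
      params[[paste0(id, ".b")]] <- rep(0, ut$cout[i])
    }
    params[["head.w"]] <- kaiming(c(1, 1, topology$base_width,
                                    topology$out_channels),
                                  topology$base_width)
    params[["head.b"]] <- rep(0, topology$out_channels)
    structure(list(topology = topology, params = params, buffers = buffers,
                   specs = specs, bn_eps = 1e-5, bn_momentum = 0.1),
              class = "unet_model")
  })
}

#' Count the parameters of a built model
#'
#' Enumerates the instantiated arrays: convolution weights, biases, batch
#' norm affine parameters and (by default, matching the package's cost
#' accounting) the batch-norm running statistics a checkpoint stores.
#'
#' @param model a built `unet_model`.
#' @param include_buffers count batch-norm running mean/variance too.
#' @return total number of stored values.
#' @export
n_parameters <- function(model, include_buffers = TRUE) {
  stopifnot(inherits(model, "unet_model"))
  n <- sum(vapply(model$params, length, numeric(1)))
  if (include_buffers)
    n <- n + sum(vapply(model$buffers, length, numeric(1)))
  n
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s convolutions, base=%d depth=%d: %s parameters\n",
              x$topology$conv_kind, x$topology$base_width,
              x$topology$n_downsamplings,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Broom-style one-row model summary
#'
#' @param x a built `unet_model`.
#' @param ... unused.
#' @return a one-row tibble with topology fields, parameter count and the
#'   analytic GMac total at a 512x512 input (when the size is admissible).
#' @method glance unet_model
#' @export
glance.unet_model <- function(x, ...) {
  gm <- tryCatch(sum(count_network(x$topology, 512)$macs) / 1e9,
                 error = function(e) NA_real_)
  tibble(conv_kind = x$topology$conv_kind,
         base_width = x$topology$base_width,
         n_downsamplings = x$topology$n_downsamplings,
         params = n_parameters(x),
         params_millions = n_parameters(x) / 1e6,
         gmac_512 = gm)
}

#' Per-layer parameter table of a built model
#'
#' @param x a built `unet_model`.
#' @param ... unused.
#' @return tibble with one row per stored array (`name`, `n`).
#' @method tidy unet_model
#' @export
tidy.unet_model <- function(x, ...) {
  all <- c(x$params, x$buffers)
  tibble(name = names(all),
         n = vapply(all, length, numeric(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the topology description and every weight and buffer
#' array; a save/load round trip is bit-exact.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) abort("not a unet_model checkpoint")
  model
}
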
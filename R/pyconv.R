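#' Pyramidal convolution layer specification
#'
#' A pyramidal convolution (PyConv) runs `n` parallel convolution levels over
#' the same input: the spatial kernel size grows from the first level to the
#' last while the kernel depth (the number of input channels each kernel
#' spans, `in_channels / groups`) shrinks, and the per-level outputs are
#' concatenated along the channel axis.  A single level with `groups = 1`
#' degenerates to a standard convolution.
#'
#' `pyconv_spec()` validates the configuration:
#' kernel sizes must be odd and strictly increasing, each level's group count
#' must divide both `in_channels` and the level's output channels, and the
#' kernel depth must be non-increasing from level 1 to level `n`.  Output
#' channels are split equally across levels unless `level_out_channels` is
#' given; a non-divisible remainder is assigned to level 1 (the cheapest,
#' detail-oriented kernel).
#'
#' @param in_channels number of input feature channels.
#' @param out_channels total output channels (sum over levels).
#' @param kernel_sizes odd integers, strictly increasing, one per level.
#' @param groups positive integers, one per level; each must divide
#'   `in_channels` and the level's output channels.
#' @param level_out_channels optional explicit per-level output channels
#'   (overrides the equal split).
#' @return An object of class `pyconv_spec`: a list with `in_channels`,
#'   `out_channels` and a `levels` data frame (`kernel_size`, `out_channels`,
#'   `groups`, `depth`).
#' @examples
#' pyconv_spec(64, 64, kernel_sizes = c(3, 5, 7, 9), groups = c(1, 4, 8, 16))
#' @export
pyconv_spec <- function(in_channels, out_channels, kernel_sizes,
                        groups = rep(1L, length(kernel_sizes)),
                        level_out_channels = NULL) {
  stopifnot(length(in_channels) == 1, length(out_channels) == 1)
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  if (in_channels < 1 || out_channels < 1)
    abort("in_channels and out_channels must be positive integers")
  n <- length(kernel_sizes)
  if (n < 1) abort("at least one pyramid level is required")
  if (length(groups) != n)
    abort("kernel_sizes and groups must have the same length")
  kernel_sizes <- as.integer(kernel_sizes)
  groups <- as.integer(groups)
  if (any(kernel_sizes < 1) || any(kernel_sizes %% 2 == 0))
    abort(paste0("kernel sizes must be odd and >= 1, got: ",
                 paste(kernel_sizes, collapse = ", ")))
  if (n > 1 && any(diff(kernel_sizes) <= 0))
    abort("kernel sizes must strictly increase from level 1 to level n")
  if (any(groups < 1) || any(in_channels %% groups != 0))
    abort(sprintf("each group count must divide in_channels = %d (got: %s)",
                  in_channels, paste(groups, collapse = ", ")))
  if (is.null(level_out_channels)) {
    base <- out_channels %/% n
    rem <- out_channels %% n
    level_out_channels <- rep(base, n)
    level_out_channels[1] <- level_out_channels[1] + rem
  } else {
    level_out_channels <- as.integer(level_out_channels)
    if (length(level_out_channels) != n)
      abort("level_out_channels must have one entry per level")
  }
  if (any(level_out_channels < 1))
    abort("every level must output at least one channel")
  if (sum(level_out_channels) != out_channels)
    abort("level output channels must sum to out_channels")
  if (any(level_out_channels %% groups != 0))
    abort("each level's output channels must be divisible by its group count")
  depth <- in_channels %/% groups
  if (n > 1 && any(diff(depth) > 0))
    abort(paste0("kernel depth (in_channels/groups) must be non-increasing ",
                 "from level 1 to level n, got depths: ",
                 paste(depth, collapse = ", ")))
  structure(
    list(in_channels = in_channels,
         out_channels = out_channels,
         levels = data.frame(kernel_size = kernel_sizes,
                             out_channels = level_out_channels,
                             groups = groups,
                             depth = depth)),
    class = "pyconv_spec")
}

#' @export
print.pyconv_spec <- function(x, ...) {
  cat(sprintf("<pyconv_spec> %d -> %d channels, %d level(s)\n",
              x$in_channels, x$out_channels, nrow(x$levels)))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' @export
format.pyconv_spec <- function(x, ...) {
  sprintf("pyconv(%d->%d; k=%s; g=%s)", x$in_channels, x$out_channels,
          paste(x$levels$kernel_size, collapse = ","),
          paste(x$levels$groups, collapse = ","))
}

# largest group <= requested that divides both in_channels and level_out;
# used when a schedule template meets a layer too narrow for it (e.g. the
# 1-channel stem)
pyconv_cap_groups <- function(requested, in_channels, level_out) {
  vapply(requested, function(g) {
    g <- min(g, in_channels, level_out)
    while (g > 1 && (in_channels %% g != 0 || level_out %% g != 0)) g <- g - 1
    as.integer(max(g, 1))
  }, integer(1))
}

# build a pyconv_spec from a schedule template (kernels + requested groups),
# applying the group fallback and keeping the depth monotone
pyconv_spec_from_template <- function(in_channels, out_channels, kernel_sizes,
                                      groups) {
  n <- length(kernel_sizes)
  base <- out_channels %/% n
  rem <- out_channels %% n
  louts <- rep(base, n)
  louts[1] <- louts[1] + rem
  g <- mapply(function(gg, lo) pyconv_cap_groups(gg, in_channels, lo),
              groups, louts)
  g <- as.integer(cummax(g)) # preserve non-increasing depth after fallback
  pyconv_spec(in_channels, out_channels, kernel_sizes, g,
              level_out_channels = louts)
}

#' Initialise weights for a pyramidal convolution
#'
#' Kaiming (He) fan-in scaled Gaussian initialisation, one weight array per
#' level with shape `(K, K, in_channels/groups, level_out_channels)`.
#'
#' @param spec a [pyconv_spec()].
#' @param seed optional integer seed (leaves the caller's RNG untouched).
#' @return list of numeric arrays, one per level.
#' @export
pyconv_init_weights <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pyconv_spec"))
  with_seed(seed, {
    lapply(seq_len(nrow(spec$levels)), function(z) {
      lv <- spec$levels[z, ]
      fan_in <- lv$kernel_size^2 * lv$depth
      array(rnorm(lv$kernel_size^2 * lv$depth * lv$out_channels,
                  sd = sqrt(2 / fan_in)),
            dim = c(lv$kernel_size, lv$kernel_size, lv$depth, lv$out_channels))
    })
  })
}

#' Apply a pyramidal convolution
#'
#' Runs every pyramid level as a same-padded grouped convolution over the
#' input and concatenates the level outputs along the channel axis, so the
#' output spatial size always equals the input's.  Levels are independent;
#' computing them separately and concatenating gives the identical result.
#'
#' @param x input feature map, an `(H, W, C)` or `(H, W, C, N)` numeric array
#'   with `C == spec$in_channels`.
#' @param spec a [pyconv_spec()].
#' @param weights list of per-level weight arrays as produced by
#'   [pyconv_init_weights()].
#' @return feature map of shape `(H, W, out_channels[, N])`.
#' @examples
#' sp <- pyconv_spec(4, 8, kernel_sizes = c(3, 5), groups = c(1, 2))
#' w <- pyconv_init_weights(sp, seed = 1)
#' y <- pyconv_forward(array(rnorm(8 * 8 * 4), c(8, 8, 4)), sp, w)
#' dim(y)
#' @export
pyconv_forward <- function(x, spec, weights) {
  stopifnot(inherits(spec, "pyconv_spec"))
  drop3 <- FALSE
  if (length(dim(x)) == 3) {
    dim(x) <- c(dim(x), 1L)
    drop3 <- TRUE
  }
  if (length(dim(x)) != 4)
    abort("x must be an (H, W, C) or (H, W, C, N) array")
  if (dim(x)[3] != spec$in_channels)
    abort(sprintf("input has %d channels but the spec expects %d",
                  dim(x)[3], spec$in_channels))
  if (length(weights) != nrow(spec$levels))
    abort("one weight array per pyramid level is required")
  outs <- lapply(seq_len(nrow(spec$levels)), function(z) {
    lv <- spec$levels[z, ]
    w <- weights[[z]]
    expected <- c(lv$kernel_size, lv$kernel_size, lv$depth, lv$out_channels)
    if (!identical(as.integer(dim(w)), as.integer(expected)))
      abort(sprintf("level %d weight must have shape (%s), got (%s)",
                    z, paste(expected, collapse = ", "),
                    paste(dim(w), collapse = ", ")))
    cpp_conv2d_forward(x, w, lv$groups)
  })
  y <- array(0, dim = c(dim(x)[1], dim(x)[2], spec$out_channels, dim(x)[4]))
  c0 <- 0
  for (z in seq_along(outs)) {
    co <- spec$levels$out_channels[z]
    y[, , c0 + seq_len(co), ] <- outs[[z]]
    c0 <- c0 + co
  }
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}
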
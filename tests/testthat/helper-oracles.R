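`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles and small fixtures used across the suite.

# Direct nested-loop same-padded grouped convolution (definition-level,
# independent of the package's im2col/GEMM path).
oracle_conv <- function(x, w, groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  K <- dim(w)[1]; Cg <- dim(w)[3]; Co <- dim(w)[4]
  stopifnot(Cg == C / groups)
  pad <- (K - 1) / 2
  Cog <- Co / groups
  y <- array(0, dim = c(H, W, Co))
  for (o in seq_len(Co)) {
    g <- ceiling(o / Cog)       # group of this output channel
    cin0 <- (g - 1) * Cg
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- 0
      for (ci in seq_len(Cg)) for (kh in seq_len(K)) for (kw in seq_len(K)) {
        ii <- i + kh - 1 - pad
        jj <- j + kw - 1 - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          acc <- acc + x[ii, jj, cin0 + ci] * w[kh, kw, ci, o]
      }
      y[i, j, o] <- acc
    }
  }
  y
}

# pyconv oracle: per-level direct convolution, then channel concatenation
oracle_pyconv <- function(x, spec, weights) {
  outs <- lapply(seq_len(nrow(spec$levels)), function(z)
    oracle_conv(x, weights[[z]], spec$levels$groups[z]))
  arr <- array(0, dim = c(dim(x)[1], dim(x)[2], spec$out_channels))
  c0 <- 0
  for (z in seq_along(outs)) {
    co <- spec$levels$out_channels[z]
    arr[, , c0 + seq_len(co)] <- outs[[z]]
    c0 <- c0 + co
  }
  arr
}

tiny_topology <- function(conv_kind = "standard", base_width = 4,
                          n_downsamplings = 1, ...) {
  if (conv_kind == "pyconv") {
    base <- unet_topology(base_width = base_width,
                          n_downsamplings = n_downsamplings)
    unet_topology(base_width = base_width,
                  n_downsamplings = n_downsamplings, conv_kind = "pyconv",
                  schedule = pyconv_uniform_schedule(base,
                                                     kernel_sizes = c(3, 5),
                                                     groups = c(1, 2)), ...)
  } else {
    unet_topology(base_width = base_width,
                  n_downsamplings = n_downsamplings, ...)
  }
}

tiny_dataset <- function(n = 4, size = 16, seed = 1) {
  # blob-free quick samples: bright square on dark background
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    img <- matrix(0.15 + 0.02 * rnorm(size * size), size)
    r0 <- sample(2:(size / 2), 1)
    rows <- r0:(r0 + size / 4)
    cols <- sample(2:(size / 2), 1) + 0:(size / 4)
    msk <- matrix(0L, size, size)
    msk[rows, cols] <- 1L
    img[rows, cols] <- img[rows, cols] + 0.6
    structure(list(image = pmin(pmax(img, 0), 1), mask = msk,
                   id = sprintf("t%02d", i)),
              class = "segmentation_sample")
  }))
}

# random binary mask pair of a given size
random_mask_pair <- function(size = 8, p = 0.4) {
  list(pred = matrix(rbinom(size * size, 1, p), size),
       truth = matrix(rbinom(size * size, 1, p), size))
}
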
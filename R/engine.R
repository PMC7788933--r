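# Forward and backward passes through the encoder--decoder.
#
# Feature maps are (H, W, C, N) arrays.  The forward pass records the caches
# needed for exact backpropagation; the backward pass returns a named list of
# gradients matching model$params.

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
    abort("skip connection shape mismatch (spatial dims or batch differ)")
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

conv_unit_forward <- function(model, id, x, training) {
  p <- model$params
  sp <- model$specs[[id]]
  if (!is.null(sp)) { # pyramidal convolution
    nlev <- nrow(sp$levels)
    z <- array(0, dim = c(dim(x)[1], dim(x)[2], sp$out_channels, dim(x)[4]))
    c0 <- 0
    for (zl in seq_len(nlev)) {
      lv <- sp$levels[zl, ]
      yz <- cpp_conv2d_forward(x, p[[paste0(id, ".L", zl, ".w")]], lv$groups)
      z[, , c0 + seq_len(lv$out_channels), ] <- yz
      c0 <- c0 + lv$out_channels
    }
  } else {
    z <- cpp_conv2d_forward(x, p[[paste0(id, ".w")]], 1L)
  }
  bn <- cpp_bn_forward(z, p[[paste0(id, ".bn.gamma")]],
                       p[[paste0(id, ".bn.beta")]],
                       model$buffers[[paste0(id, ".bn.mean")]],
                       model$buffers[[paste0(id, ".bn.var")]],
                       model$bn_eps, training)
  a <- bn$y
  a[a < 0] <- 0
  list(a = a, cache = list(x = x, z = z, mean = bn$mean, var = bn$var, a = a))
}

conv_unit_backward <- function(model, id, cache, da, training) {
  p <- model$params
  dz_bn <- da * (cache$a > 0)
  bnb <- cpp_bn_backward(cache$z, dz_bn, p[[paste0(id, ".bn.gamma")]],
                         cache$mean, cache$var, model$bn_eps, training)
  grads <- list()
  grads[[paste0(id, ".bn.gamma")]] <- bnb$dgamma
  grads[[paste0(id, ".bn.beta")]] <- bnb$dbeta
  dz <- bnb$dx
  sp <- model$specs[[id]]
  if (!is.null(sp)) {
    dx <- NULL
    c0 <- 0
    for (zl in seq_len(nrow(sp$levels))) {
      lv <- sp$levels[zl, ]
      dyz <- dz[, , c0 + seq_len(lv$out_channels), , drop = FALSE]
      c0 <- c0 + lv$out_channels
      cb <- cpp_conv2d_backward(cache$x, p[[paste0(id, ".L", zl, ".w")]],
                                dyz, lv$groups)
      grads[[paste0(id, ".L", zl, ".w")]] <- cb$dw
      dx <- if (is.null(dx)) cb$dx else dx + cb$dx
    }
  } else {
    cb <- cpp_conv2d_backward(cache$x, p[[paste0(id, ".w")]], dz, 1L)
    grads[[paste0(id, ".w")]] <- cb$dw
    dx <- cb$dx
  }
  list(dx = dx, grads = grads)
}

block_forward <- function(model, ida, idb, x, training) {
  u1 <- conv_unit_forward(model, ida, x, training)
  u2 <- conv_unit_forward(model, idb, u1$a, training)
  list(a = u2$a, cache = list(a = u1$cache, b = u2$cache))
}

block_backward <- function(model, ida, idb, cache, da, training) {
  ub <- conv_unit_backward(model, idb, cache$b, da, training)
  ua <- conv_unit_backward(model, ida, cache$a, ub$dx, training)
  list(dx = ua$dx, grads = c(ub$grads, ua$grads))
}

net_forward <- function(model, x, training = FALSE) {
  topo <- model$topology
  nd <- topo$n_downsamplings
  stopifnot(length(dim(x)) == 4, dim(x)[3] == topo$in_channels)
  caches <- list(blocks = list(), pools = list(), ups = list())
  skips <- list()
  h <- x
  for (s in seq_len(nd)) {
    blk <- block_forward(model, paste0("enc", s, "a"), paste0("enc", s, "b"),
                         h, training)
    caches$blocks[[paste0("enc", s)]] <- blk$cache
    skips[[s]] <- blk$a
    pl <- cpp_maxpool2_forward(blk$a)
    caches$pools[[s]] <- list(idx = pl$idx, dims = dim(blk$a))
    h <- pl$y
  }
  blk <- block_forward(model, "bot_a", "bot_b", h, training)
  caches$blocks[["bot"]] <- blk$cache
  d <- blk$a
  for (s in rev(seq_len(nd))) {
    caches$ups[[paste0("up", s)]] <- d
    u <- cpp_convtr2_forward(d, model$params[[paste0("up", s, ".w")]],
                             model$params[[paste0("up", s, ".b")]])
    cc <- concat_channels(skips[[s]], u)
    blk <- block_forward(model, paste0("dec", s, "a"), paste0("dec", s, "b"),
                         cc, training)
    caches$blocks[[paste0("dec", s)]] <- blk$cache
    d <- blk$a
  }
  caches$dec_out <- d
  logits <- cpp_conv2d_forward(d, model$params[["head.w"]], 1L)
  for (ch in seq_len(topo$out_channels))
    logits[, , ch, ] <- logits[, , ch, ] + model$params[["head.b"]][ch]
  prob <- array(stats::plogis(logits), dim = dim(logits))
  list(prob = prob, logits = logits, caches = caches, skips = skips)
}

net_backward <- function(model, fw, dlogits, training = TRUE) {
  topo <- model$topology
  nd <- topo$n_downsamplings
  grads <- list()
  cb <- cpp_conv2d_backward(fw$caches$dec_out, model$params[["head.w"]],
                            dlogits, 1L)
  grads[["head.w"]] <- cb$dw
  grads[["head.b"]] <- apply(dlogits, 3, sum)
  dd <- cb$dx
  dskips <- list()
  for (s in seq_len(nd)) {
    bb <- block_backward(model, paste0("dec", s, "a"), paste0("dec", s, "b"),
                         fw$caches$blocks[[paste0("dec", s)]], dd, training)
    grads <- c(grads, bb$grads)
    nskip <- dim(fw$skips[[s]])[3]
    dskips[[s]] <- bb$dx[, , seq_len(nskip), , drop = FALSE]
    du <- bb$dx[, , nskip + seq_len(dim(bb$dx)[3] - nskip), , drop = FALSE]
    tb <- cpp_convtr2_backward(fw$caches$ups[[paste0("up", s)]],
                               model$params[[paste0("up", s, ".w")]], du)
    grads[[paste0("up", s, ".w")]] <- tb$dw
    grads[[paste0("up", s, ".b")]] <- tb$db
    dd <- tb$dx
  }
  bb <- block_backward(model, "bot_a", "bot_b", fw$caches$blocks[["bot"]],
                       dd, training)
  grads <- c(grads, bb$grads)
  dpool <- bb$dx
  for (s in rev(seq_len(nd))) {
    pl <- fw$caches$pools[[s]]
    denc <- cpp_maxpool2_backward(dpool, pl$idx, pl$dims) + dskips[[s]]
    bb <- block_backward(model, paste0("enc", s, "a"), paste0("enc", s, "b"),
                         fw$caches$blocks[[paste0("enc", s)]], denc, training)
    grads <- c(grads, bb$grads)
    dpool <- bb$dx
  }
  grads
}

# exponential-moving-average update of batch-norm running statistics from the
# caches of one training-mode forward pass
update_bn_buffers <- function(model, fw) {
  mom <- model$bn_momentum
  for (nm in names(fw$caches$blocks)) {
    blk <- fw$caches$blocks[[nm]]
    ids <- if (nm == "bot") c("bot_a", "bot_b")
           else paste0(nm, c("a", "b"))
    for (k in 1:2) {
      cache <- blk[[c("a", "b")[k]]]
      id <- ids[k]
      mkey <- paste0(id, ".bn.mean"); vkey <- paste0(id, ".bn.var")
      model$buffers[[mkey]] <- (1 - mom) * model$buffers[[mkey]] +
        mom * cache$mean
      model$buffers[[vkey]] <- (1 - mom) * model$buffers[[vkey]] +
        mom * cache$var
    }
  }
  model
}
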
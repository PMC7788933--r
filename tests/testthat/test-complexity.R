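test_that("standard convolution closed forms evaluate exactly", {
  expect_equal(params_standard(1, 1, 1), 1)
  expect_equal(params_standard(3, 64, 64), 36864)
  expect_equal(params_standard(3, 64, 64, groups = 4), 9216)
  # enumeration oracle for the grouped case: instantiate and count
  sp <- pyconv_spec(64, 64, kernel_sizes = 3, groups = 4)
  w <- pyconv_init_weights(sp, seed = 1)
  expect_equal(sum(lengths(w)), 9216)

  expect_equal(flops_standard(3, 1, 1, 1, 1), 9)
  expect_equal(flops_standard(3, 64, 64, 1, 1), params_standard(3, 64, 64))
  expect_equal(flops_standard(3, 64, 64, 128, 128), 603979776)
  expect_error(params_standard(0, 1, 1), "positive")
  expect_error(params_standard(3, 64, 64, groups = 5), "divide")
})

test_that("pyconv parameter accounting matches enumerated weights", {
  sp <- pyconv_spec(64, 64, c(3, 5, 7, 9), c(1, 4, 8, 16))
  expect_equal(params_pyconv(sp, "realizable"),
               9 * 64 * 16 + 25 * 16 * 16 + 49 * 8 * 16 + 81 * 4 * 16)
  expect_equal(params_pyconv(sp, "realizable"), 27072) # enumeration oracle
  w <- pyconv_init_weights(sp, seed = 1)
  expect_equal(sum(lengths(w)), params_pyconv(sp, "realizable"))
  # degenerate single level equals the standard count
  sp1 <- pyconv_spec(64, 64, kernel_sizes = 3, groups = 1)
  expect_equal(params_pyconv(sp1), params_standard(3, 64, 64))
  expect_equal(flops_pyconv(sp, 32, 32), 27072 * 1024)
  expect_equal(flops_pyconv(sp, 1, 1), params_pyconv(sp))
})

test_that("idealized pyconv cost equals the standard convolution on a grid", {
  # the cost-equality property, exhaustively over >= 50 specs
  kernel_lists <- list(c(3), c(3, 5), c(3, 5, 7), c(3, 5, 7, 9),
                       c(5, 7), c(3, 7, 11))
  widths <- list(c(16, 16), c(32, 64), c(64, 64), c(64, 32), c(128, 128),
                 c(48, 96), c(256, 64), c(8, 8), c(96, 48), c(64, 128),
                 c(32, 32), c(16, 48))
  n_checked <- 0
  for (kl in kernel_lists) for (wd in widths) {
    if (wd[2] %% length(kl) != 0) next
    sp <- pyconv_spec(wd[1], wd[2], kl, rep(1, length(kl)))
    expect_equal(params_pyconv(sp, "idealized"),
                 params_standard(kl[1], wd[1], wd[2]))
    expect_equal(flops_pyconv(sp, 24, 24, "idealized"),
                 flops_standard(kl[1], wd[1], wd[2], 24, 24))
    # FLOPs factorize as params x W x H in both modes
    expect_equal(flops_pyconv(sp, 7, 13, "realizable"),
                 params_pyconv(sp, "realizable") * 7 * 13)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("increasing groups never increases the realizable count", {
  for (g2 in c(1, 2, 4, 8)) {
    a <- params_pyconv(pyconv_spec(64, 64, c(3, 5), c(1, g2)))
    b <- params_pyconv(pyconv_spec(64, 64, c(3, 5), c(1, min(2 * g2, 16))))
    expect_gte(a, b)
  }
})

test_that("count_network totals equal enumerated weights for every layer kind", {
  topos <- list(
    tiny_topology("standard", base_width = 8, n_downsamplings = 2),
    tiny_topology("pyconv", base_width = 8, n_downsamplings = 2),
    unet_topology(),                       # canonical baseline
    unet_topology(conv_kind = "pyconv")    # canonical pyconv
  )
  for (topo in topos) {
    rep <- count_network(topo, 64)
    m <- pyconvunet:::build_network(topo, seed = 1)
    expect_equal(sum(rep$params), n_parameters(m))
    # totals equal the sum of per-layer entries by construction of glance
    expect_equal(glance(rep)$params, sum(rep$params))
  }
})

test_that("counting convention flags add the documented op classes", {
  topo <- tiny_topology("standard", base_width = 8, n_downsamplings = 2)
  base <- glance(count_network(topo, 64))$macs
  with_bn <- glance(count_network(topo, 64,
    counting_convention(count_bn_macs = TRUE)))$macs
  with_all <- glance(count_network(topo, 64,
    counting_convention(count_bn_macs = TRUE, count_activation_macs = TRUE,
                        count_pooling_macs = TRUE,
                        count_bias_macs = TRUE)))$macs
  expect_gt(with_bn, base)
  expect_gt(with_all, with_bn)
  # output-pixel transposed accounting quadruples the up-conv MACs
  rep0 <- count_network(topo, 64)
  rep1 <- count_network(topo, 64,
    counting_convention(transposed_conv_output_pixels = TRUE))
  up0 <- rep0$macs[grepl("^up", rep0$layer)]
  up1 <- rep1$macs[grepl("^up", rep1$layer)]
  expect_equal(up1, 4 * up0)
  # bn params per channel flag
  repbn2 <- count_network(topo, 64,
    counting_convention(bn_params_per_channel = 2))
  m <- pyconvunet:::build_network(topo, seed = 1)
  expect_equal(sum(repbn2$params), n_parameters(m, include_buffers = FALSE))
  expect_error(count_network(topo, 50), "divisible")
})
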
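test_that("pyconv_spec validates the pyramid invariants", {
  # degenerate single level is a standard convolution description
  sp1 <- pyconv_spec(64, 64, kernel_sizes = 3, groups = 1)
  expect_equal(nrow(sp1$levels), 1)
  expect_equal(sp1$levels$depth, 64)

  # default 4-level schedule arithmetic
  sp4 <- pyconv_spec(64, 64, c(3, 5, 7, 9), c(1, 4, 8, 16))
  expect_equal(sp4$levels$out_channels, rep(16, 4))
  expect_equal(sp4$levels$depth, c(64, 16, 8, 4))

  # distinct diagnostics for each violated invariant
  expect_error(pyconv_spec(64, 64, c(4), c(1)), "odd")
  expect_error(pyconv_spec(64, 64, c(3, 3), c(1, 1)), "strictly increase")
  expect_error(pyconv_spec(64, 64, c(3, 5), c(1, 3)), "divide in_channels")
  expect_error(pyconv_spec(64, 64, c(3, 5), c(4, 1)), "non-increasing")
  expect_error(pyconv_spec(64, 64, c(3, 5), c(1, 2),
                           level_out_channels = c(10, 10)),
               "sum to out_channels")
})

test_that("non-divisible output split assigns the remainder to level 1", {
  sp <- pyconv_spec(32, 31, c(3, 5, 7), c(1, 1, 1))
  expect_equal(sp$levels$out_channels, c(11, 10, 10))
  expect_equal(sum(sp$levels$out_channels), 31)
})

test_that("group fallback caps templates at narrow layers", {
  # 1-channel stem: every group falls back to 1
  sp <- pyconvunet:::pyconv_spec_from_template(1, 32, c(3, 5, 7, 9),
                                               c(1, 4, 8, 16))
  expect_equal(sp$levels$groups, rep(1L, 4))
  # depth non-increasing preserved after capping
  sp2 <- pyconvunet:::pyconv_spec_from_template(8, 32, c(3, 5, 7, 9),
                                                c(1, 4, 8, 16))
  expect_true(all(diff(sp2$levels$depth) <= 0))
  expect_true(all(8 %% sp2$levels$groups == 0))
})

test_that("single-level pyconv reproduces a standard convolution exactly", {
  set.seed(11)
  sp <- pyconv_spec(4, 6, kernel_sizes = 3, groups = 1)
  w <- pyconv_init_weights(sp, seed = 2)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y <- pyconv_forward(x, sp, w)
  expect_identical(dim(y), c(8L, 8L, 6L))
  expect_equal(y, oracle_conv(x, w[[1]], 1), tolerance = 1e-12)
})

test_that("pyconv_forward matches the nested-loop oracle on seeded inputs", {
  configs <- list(
    list(cin = 4, cout = 8, k = c(3, 5), g = c(1, 2), size = 8),
    list(cin = 8, cout = 24, k = c(3, 5, 7), g = c(2, 4, 8), size = 9),
    list(cin = 8, cout = 32, k = c(3, 5, 7, 9), g = c(1, 2, 4, 8), size = 16),
    list(cin = 6, cout = 12, k = c(3, 5), g = c(3, 6), size = 12)
  )
  for (cf in configs) {
    for (seed in 1:3) {
      set.seed(seed)
      sp <- pyconv_spec(cf$cin, cf$cout, cf$k, cf$g)
      w <- pyconv_init_weights(sp, seed = seed + 100)
      x <- array(rnorm(cf$size^2 * cf$cin), c(cf$size, cf$size, cf$cin))
      expect_lt(max(abs(pyconv_forward(x, sp, w) - oracle_pyconv(x, sp, w))),
                1e-5)
    }
  }
})

test_that("spatial size is preserved for every level and input size", {
  sp <- pyconv_spec(4, 16, c(3, 5, 7, 9), c(1, 2, 4, 4))
  w <- pyconv_init_weights(sp, seed = 1)
  for (size in c(9, 12, 16, 21)) {
    x <- array(rnorm(size * size * 4), c(size, size, 4))
    expect_identical(dim(pyconv_forward(x, sp, w))[1:2],
                     as.integer(c(size, size)))
  }
})

test_that("levels computed independently concatenate to the layer output", {
  set.seed(3)
  sp <- pyconv_spec(8, 8, c(3, 5), c(2, 4))
  w <- pyconv_init_weights(sp, seed = 5)
  x <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  whole <- pyconv_forward(x, sp, w)
  lv1 <- pyconv_forward(x, pyconv_spec(8, 4, 3, 2), w[1])
  lv2 <- pyconv_forward(x, pyconv_spec(8, 4, 5, 4), w[2])
  # bit-for-bit: the layer is exactly the concatenation of its levels
  expect_identical(whole[, , 1:4], lv1)
  expect_identical(whole[, , 5:8], lv2)
})

test_that("zero weights give zero output and mismatches are rejected", {
  sp <- pyconv_spec(4, 8, c(3, 5), c(1, 2))
  w <- lapply(pyconv_init_weights(sp, seed = 1), function(a) a * 0)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_true(all(pyconv_forward(x, sp, w) == 0))
  bad <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_error(pyconv_forward(bad, sp, pyconv_init_weights(sp, 1)),
               "channels")
  wbad <- pyconv_init_weights(sp, 1)
  dim(wbad[[2]]) <- rev(dim(wbad[[2]]))
  expect_error(pyconv_forward(x, sp, wbad), "shape")
})
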
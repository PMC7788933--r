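test_that("topology validation and channel doubling follow the U-Net rule", {
  topo <- unet_topology()
  bt <- pyconvunet:::block_conv_table(topo)
  enc_out <- bt$cout[grepl("^enc", bt$id) & grepl("b$", bt$id)]
  expect_equal(enc_out, c(32, 64, 128, 256))
  expect_equal(bt$cout[bt$id == "bot_b"], 512)
  # decoder halves: up-conv output channels mirror the encoder
  ut <- pyconvunet:::upconv_table(topo)
  expect_equal(sort(ut$cout), c(32, 64, 128, 256))
  expect_error(unet_topology(base_width = 0), "positive")
})

test_that("baseline U-Net reproduces the published parameter budget", {
  m <- build_unet(unet_topology(), seed = 1)
  # conv weights alone (excluding BN and biases)
  wsum <- sum(vapply(m$params[grepl("\\.w$", names(m$params))], length,
                     numeric(1)))
  expect_equal(wsum, 7756096)
  expect_equal(round(n_parameters(m) / 1e6, 2), 7.77)
})

test_that("pyconv U-Net undercuts half the baseline parameter total", {
  mp <- build_pyconvunet(seed = 1)
  mu <- build_unet(seed = 1)
  expect_lt(n_parameters(mp), 0.5 * n_parameters(mu))
  expect_equal(round(n_parameters(mp) / 1e6, 1), 3.7)
})

test_that("prediction preserves spatial size and the sigmoid range", {
  m <- pyconvunet:::build_network(tiny_topology(base_width = 4,
                                                n_downsamplings = 2), seed = 2)
  img <- matrix(runif(64 * 64), 64)
  pm <- predict(m, img)
  expect_identical(dim(pm), c(64L, 64L))
  expect_true(all(pm > 0 & pm < 1))
  # rectangular inputs work too (same padding everywhere)
  img2 <- matrix(runif(32 * 48), 32)
  expect_identical(dim(predict(m, img2)), c(32L, 48L))
  # determinism in evaluation mode
  expect_identical(predict(m, img), predict(m, img))
})

test_that("inadmissible sizes are rejected with the required multiple named", {
  m <- pyconvunet:::build_network(unet_topology(base_width = 4), seed = 1)
  expect_error(predict(m, matrix(0.5, 50, 50)), "divisible by 16")
})

test_that("all-zero weights yield a constant 0.5 probability map", {
  m <- pyconvunet:::build_network(tiny_topology(base_width = 4,
                                                n_downsamplings = 1), seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  # zero BN scale and shift => zero logits => sigmoid = 0.5
  pm <- predict(m, matrix(runif(16 * 16), 16))
  expect_true(all(pm == 0.5))
})

test_that("binarize follows the >= convention and is monotone", {
  const <- matrix(0.5, 4, 4)
  expect_true(all(binarize(const, 0.5) == 1))
  expect_equal(binarize(matrix(c(0.2, 0.8), 1), 0.5),
               matrix(c(0L, 1L), 1))
  pm <- matrix(runif(100), 10)
  m1 <- binarize(pm, 0.3); m2 <- binarize(pm, 0.7)
  expect_true(all(m2 <= m1)) # higher threshold => subset mask
  expect_error(binarize(pm, 0), "between 0 and 1")
  expect_error(binarize(pm, 1.2), "between 0 and 1")
})

test_that("checkpoints round-trip bit-exactly", {
  m <- pyconvunet:::build_network(tiny_topology("pyconv", base_width = 8,
                                                n_downsamplings = 1), seed = 7)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m, m2)
  img <- matrix(runif(16 * 16), 16)
  expect_identical(predict(m, img), predict(m2, img))
})

test_that("analytic accounting equals enumeration for built pyconv nets", {
  topo <- unet_topology(conv_kind = "pyconv")
  m <- build_pyconvunet(topo, seed = 1)
  expect_equal(sum(count_network(topo, 64)$params), n_parameters(m))
})

test_that("pyconv schedules that are unrealizable at a stage are rejected", {
  base <- unet_topology(base_width = 8, n_downsamplings = 1)
  sched <- pyconv_uniform_schedule(base, kernel_sizes = c(3, 5),
                                   groups = c(1, 2))
  sched$enc1b <- NULL
  expect_error(unet_topology(base_width = 8, n_downsamplings = 1,
                             conv_kind = "pyconv", schedule = sched),
               "missing entries")
})
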
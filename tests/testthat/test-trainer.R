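test_that("constant-0.5 predictions cost exactly log(2) regardless of target", {
  for (q in c(0, 0.2, 0.5, 1)) {
    y <- array(rbinom(100, 1, q), c(10, 10))
    expect_equal(bce_loss(array(0.5, c(10, 10)), y), log(2))
  }
})

# a stub "network" whose prediction is fixed; exercises the evaluation path
# through the generic predict()
predict.stub_model <- function(object, image, ...) object$map
registerS3method("predict", "stub_model", predict.stub_model)

test_that("evaluation of a perfect predictor returns MIoU = Dice = 1", {
  ds <- tiny_dataset(n = 3, size = 16)
  for (s in ds) {
    stub <- structure(list(map = s$mask * 0.98 + 0.01),
                      class = "stub_model")
    ev <- evaluate_model(stub, list(s))
    expect_equal(ev$miou, 1)
    expect_equal(ev$dice, 1)
  }
})

test_that("an all-0.5 predictor at threshold 0.5 predicts all foreground", {
  ds <- tiny_dataset(n = 2, size = 16)
  stub <- structure(list(map = matrix(0.5, 16, 16)), class = "stub_model")
  ev <- evaluate_model(stub, ds, threshold = 0.5)
  ny <- sum(vapply(ds, function(s) sum(s$mask), numeric(1)))
  npix <- 2 * 16 * 16
  expect_equal(ev$dice, 2 * ny / (npix + ny)) # closed form of Dice
  ev2 <- evaluate_model(stub, ds, threshold = 0.5)
  expect_identical(ev, ev2)
  expect_error(evaluate_model(stub, list()), "no samples")
})

test_that("training is reproducible and logs one row per epoch", {
  ds <- tiny_dataset(n = 4, size = 16)
  topo <- tiny_topology(base_width = 4, n_downsamplings = 1)
  run <- function() {
    m <- pyconvunet:::build_network(topo, seed = 1)
    train_model(m, ds[1:3], ds[4], train_config(epochs = 2, batch_size = 2,
                                                seed = 11))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 2)
  expect_true(all(is.finite(f1$log$train_loss)))
  expect_true(all(c("epoch", "train_loss", "test_miou", "test_dice") %in%
                  names(f1$log)))
})

test_that("best-Dice weights are checkpointed during training", {
  ds <- tiny_dataset(n = 3, size = 16)
  topo <- tiny_topology(base_width = 4, n_downsamplings = 1)
  m <- pyconvunet:::build_network(topo, seed = 2)
  path <- withr::local_tempfile(fileext = ".ckpt")
  fit <- train_model(m, ds[1:2], ds[3],
                     train_config(epochs = 2, batch_size = 2, seed = 3,
                                  checkpoint_path = path))
  expect_true(file.exists(path))
  best <- load_checkpoint(path)
  expect_s3_class(best, "unet_model")
  expect_identical(best$params, fit$best_model$params)
})

test_that("training rejects inadmissible inputs", {
  topo <- tiny_topology(base_width = 4, n_downsamplings = 2)
  m <- pyconvunet:::build_network(topo, seed = 1)
  expect_error(train_model(m, list(), config = train_config(epochs = 1)),
               "empty")
  bad <- list(structure(list(image = matrix(0.5, 10, 10),
                             mask = matrix(0L, 10, 10), id = "bad"),
                        class = "segmentation_sample"))
  expect_error(train_model(m, bad, config = train_config(epochs = 1)),
               "divisible")
  expect_error(train_config(optimizer = "sgd"), "unknown optimizer")
  expect_error(train_config(loss = "hinge"))
})

test_that("the dice loss option also trains", {
  ds <- tiny_dataset(n = 2, size = 16)
  topo <- tiny_topology(base_width = 4, n_downsamplings = 1)
  m <- pyconvunet:::build_network(topo, seed = 5)
  fit <- train_model(m, ds, config = train_config(epochs = 2, batch_size = 2,
                                                  loss = "dice", seed = 1))
  expect_true(all(is.finite(fit$log$train_loss)))
  expect_lt(fit$log$train_loss[2], fit$log$train_loss[1])
})
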
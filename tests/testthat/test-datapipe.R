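test_that("write/load round trip preserves masks exactly, images to 8 bits", {
  ds <- generate_synth_dataset(synth_config(n_images = 3, size = 32,
                                            seed = 4))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_length(list.files(file.path(dir, "images")), 3)
  expect_length(list.files(file.path(dir, "masks")), 3)
  back <- load_dataset(dir)
  expect_equal(vapply(back, `[[`, "", "id"),
               sort(vapply(ds, `[[`, "", "id")))
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$mask, ds[[i]]$mask)
    expect_lte(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 255)
  }
})

test_that("masks stored as {0, 255} PNGs load as strictly binary", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images")); dir.create(file.path(dir, "masks"))
  img <- matrix(runif(32 * 32), 32)
  msk <- matrix(sample(c(0, 1), 32 * 32, TRUE), 32) # becomes 0/255 on disk
  png::writePNG(img, file.path(dir, "images", "a.png"))
  png::writePNG(msk, file.path(dir, "masks", "a.png"))
  s <- load_dataset(dir)[[1]]
  expect_true(all(s$mask %in% c(0L, 1L)))
  expect_equal(s$mask, matrix(as.integer(msk), 32))
})

test_that("orphan files and shape mismatches are reported by id", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images")); dir.create(file.path(dir, "masks"))
  png::writePNG(matrix(0.5, 16, 16), file.path(dir, "images", "lonely.png"))
  expect_error(load_dataset(dir), "lonely")
  png::writePNG(matrix(0, 8, 8), file.path(dir, "masks", "lonely.png"))
  expect_error(load_dataset(dir), "shape mismatch")
})

test_that("augmentation is a 5-fold exact pixel permutation", {
  ds <- tiny_dataset(n = 1, size = 16)
  aug <- augment_sample(ds[[1]])
  expect_length(aug, 5)
  expect_equal(vapply(aug, `[[`, "", "id")[-1],
               paste0(ds[[1]]$id, "_", c("hflip", "vflip", "rot90",
                                         "rot180")))
  for (a in aug) {
    # per-class pixel counts preserved (pure permutation)
    expect_equal(sum(a$mask), sum(ds[[1]]$mask))
    expect_equal(sort(as.vector(a$image)), sort(as.vector(ds[[1]]$image)))
  }
  hf <- pyconvunet:::apply_aug
  m <- ds[[1]]$image
  expect_identical(hf(hf(m, "hflip"), "hflip"), m)       # involution
  expect_identical(hf(hf(m, "vflip"), "vflip"), m)
  r1 <- hf(m, "rot90")
  expect_identical(hf(hf(hf(r1, "rot90"), "rot90"), "rot90"), m) # 4-cycle
  expect_identical(hf(r1, "rot90"), hf(m, "rot180"))     # group structure
})

test_that("the split is seed-deterministic, disjoint and exhaustive", {
  ds <- tiny_dataset(n = 10, size = 16)
  sp <- split_dataset(ds, 0.8, seed = 42)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  sp2 <- split_dataset(ds, 0.8, seed = 42)
  expect_identical(ids(sp$train), ids(sp2$train))
  # floor rule at awkward sizes (checked without building 267 images)
  fake <- lapply(1:267, function(i) list(id = sprintf("s%03d", i)))
  spf <- split_dataset(fake, 0.8, seed = 1)
  expect_length(spf$train, 213)
  expect_length(spf$test, 54)
  expect_error(split_dataset(ds[1], 0.8, 1), "at least 2")
})

test_that("augmenting after splitting cannot leak test content", {
  ds <- tiny_dataset(n = 10, size = 16)
  sp <- split_dataset(ds, 0.8, seed = 7)
  aug_train <- augment_dataset(sp$train)
  expect_length(aug_train, 40)
  stems <- unique(sub("_(hflip|vflip|rot90|rot180)$", "",
                      vapply(aug_train, `[[`, "", "id")))
  expect_length(intersect(stems, vapply(sp$test, `[[`, "", "id")), 0)
})

test_that("reflection padding reaches the next multiple and crops back", {
  img <- matrix(runif(50 * 70), 50)
  pd <- pad_to_multiple(img, 16)
  expect_equal(dim(pd$image), c(64, 80))
  expect_equal(pd$image[pd$crop$rows, pd$crop$cols], img)
})
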
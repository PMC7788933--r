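#' Load a paired image/mask dataset from disk
#'
#' Expects the layout `dir/images/` and `dir/masks/` with files pairable by
#' filename stem (PNG or TIFF).  Images whose values fall outside \[0, 1\]
#' (e.g. raw-intensity TIFFs) are min--max scaled into it; images already in
#' \[0, 1\] are left untouched so that a write/load round trip only incurs
#' 8-bit quantization.  Multi-channel files are averaged to one channel;
#' masks are binarized at mid-intensity.  Samples are returned in
#' lexicographic id order.
#'
#' @param dir dataset directory.
#' @return list of segmentation samples (`image`, `mask`, `id`).
#' @export
load_dataset <- function(dir) {
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    abort(sprintf("expected '%s' and '%s' to exist", img_dir, msk_dir))
  pat <- "\\.(png|tif|tiff)$"
  imgs <- list.files(img_dir, pattern = pat, ignore.case = TRUE)
  msks <- list.files(msk_dir, pattern = pat, ignore.case = TRUE)
  stem <- function(f) sub(pat, "", f, ignore.case = TRUE)
  ist <- stem(imgs); mst <- stem(msks)
  orphans <- c(setdiff(ist, mst), setdiff(mst, ist))
  if (length(orphans))
    abort(paste0("unpaired image/mask stem(s): ",
                 paste(sort(orphans), collapse = ", ")))
  ord <- order(ist)
  imgs <- imgs[ord]; ist <- ist[ord]
  msks <- msks[match(ist, mst)]
  read_gray <- function(path) {
    a <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
    if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                          drop = FALSE], c(1, 2), mean)
    a
  }
  lapply(seq_along(imgs), function(i) {
    im <- read_gray(file.path(img_dir, imgs[i]))
    mk <- read_gray(file.path(msk_dir, msks[i]))
    if (!all(dim(im) == dim(mk)))
      abort(sprintf("image/mask shape mismatch for '%s': %s vs %s", ist[i],
                    paste(dim(im), collapse = "x"),
                    paste(dim(mk), collapse = "x")))
    rng <- range(im)
    if ((rng[1] < 0 || rng[2] > 1) && rng[2] > rng[1])
      im <- (im - rng[1]) / (rng[2] - rng[1])
    structure(list(image = im,
                   mask = matrix(as.integer(mk >= 0.5), nrow(mk)),
                   id = ist[i]),
              class = "segmentation_sample")
  })
}

rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_aug <- function(m, op) {
  switch(op,
         identity = m,
         hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
         vflip = m[rev(seq_len(nrow(m))), , drop = FALSE],
         rot90 = rot90_ccw(m),
         rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))),
                    drop = FALSE],
         abort(sprintf("unknown augmentation '%s'", op)))
}

#' Augment one sample with the flip/rotation protocol
#'
#' Expands a sample into five: the original plus horizontal flip, vertical
#' flip, 90 degree (counter-clockwise) rotation and 180 degree rotation,
#' each applied identically to image and mask.  All four operations are
#' exact pixel permutations (no interpolation), so per-class pixel counts
#' are preserved.
#'
#' @param sample a segmentation sample.
#' @return list of 5 samples; augmented ids carry the op-name suffix.
#' @export
augment_sample <- function(sample) {
  ops <- c("hflip", "vflip", "rot90", "rot180")
  out <- c(list(sample), lapply(ops, function(op) {
    structure(list(image = apply_aug(sample$image, op),
                   mask = apply_aug(sample$mask, op),
                   id = paste0(sample$id, "_", op)),
              class = "segmentation_sample")
  }))
  out
}

#' @rdname augment_sample
#' @param samples list of samples; each is expanded 5-fold.
#' @export
augment_dataset <- function(samples) {
  unlist(lapply(samples, augment_sample), recursive = FALSE)
}

#' Seeded train/test split
#'
#' Shuffles the *original* samples with a fixed seed and splits them into a
#' training part of `floor(train_fraction * n)` samples and a disjoint,
#' exhaustive test remainder.  Augmentation is intended to be applied to the
#' training split only, after splitting, so no transformed copy of a test
#' image can leak into training.
#'
#' @param samples list of segmentation samples (at least 2).
#' @param train_fraction fraction of samples used for training.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with `train` and `test` sample lists.
#' @examples
#' ds <- generate_synth_dataset(synth_config(n_images = 5, size = 32))
#' sp <- split_dataset(ds, 0.8, seed = 1)
#' length(sp$train); length(sp$test)
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 0) {
  n <- length(samples)
  if (n < 2) abort("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("train_fraction must lie strictly between 0 and 1")
  perm <- with_seed(seed, sample(n))
  ntr <- floor(train_fraction * n)
  list(train = samples[perm[seq_len(ntr)]],
       test = samples[perm[setdiff(seq_len(n), seq_len(ntr))]])
}

#' Write predicted masks as PNG files
#'
#' @param masks named list of 0/1 matrices (names become file stems).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_predictions <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(masks))
    png::writePNG(masks[[nm]] * 1.0, file.path(dir, paste0(nm, ".png")))
  invisible(dir)
}

#' Reflection-pad an image to the next admissible size
#'
#' [predict.unet_model()] requires spatial sizes divisible by
#' `2^n_downsamplings` and refuses others.  This helper center-pads an
#' arbitrary image by edge reflection to the next multiple and returns the
#' padded image together with the crop window to map a prediction back.
#'
#' @param image numeric matrix.
#' @param multiple required divisor of both dimensions.
#' @return list with `image` (padded) and `crop` (`list(rows =, cols =)`).
#' @export
pad_to_multiple <- function(image, multiple = 16) {
  H <- nrow(image); W <- ncol(image)
  Ht <- ceiling(H / multiple) * multiple
  Wt <- ceiling(W / multiple) * multiple
  top <- (Ht - H) %/% 2; bot <- Ht - H - top
  lft <- (Wt - W) %/% 2; rgt <- Wt - W - lft
  ri <- c(rev(seq_len(top) + 1), seq_len(H), H - seq_len(bot))
  ci <- c(rev(seq_len(lft) + 1), seq_len(W), W - seq_len(rgt))
  list(image = image[ri, ci, drop = FALSE],
       crop = list(rows = top + seq_len(H), cols = lft + seq_len(W)))
}
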
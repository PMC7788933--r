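#' Pixel confusion counts between a prediction and the ground truth
#'
#' Builds the `(k+1) x (k+1)` confusion matrix over class labels `0..k`
#' (0 = background): entry `(i, j)` counts pixels whose true class is `i` and
#' predicted class is `j` (truth indexes rows, prediction indexes columns).
#' Per-class TP/FP/FN follow from the matrix: `TP_i` is the diagonal entry,
#' `FP_i` the column sum minus it, `FN_i` the row sum minus it.
#'
#' Counts from several images can be pooled with `+` before computing
#' metrics (micro-averaging).
#'
#' @param pred,truth integer matrices of equal shape with labels in `0..k`.
#' @param k number of foreground categories (1 for binary masks).
#' @return an object of class `confusion_counts`.
#' @examples
#' cc <- confusion_counts(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' cc$p
#' @export
confusion_counts <- function(pred, truth, k = 1) {
  if (!all(dim(pred) == dim(truth)))
    abort("pred and truth must have identical shapes")
  pv <- as.integer(pred); tv <- as.integer(truth)
  if (anyNA(pv) || anyNA(tv) || any(pv < 0) || any(pv > k) ||
      any(tv < 0) || any(tv > k))
    abort(sprintf("labels must lie in 0..%d", k))
  kk <- k + 1L
  p <- matrix(tabulate(tv * kk + pv + 1L, nbins = kk * kk),
              nrow = kk, byrow = TRUE,
              dimnames = list(truth = 0:k, pred = 0:k))
  structure(list(k = as.integer(k), p = p), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %d foreground class(es), %d pixels\n",
              x$k, sum(x$p)))
  print(x$p)
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  stopifnot(inherits(e1, "confusion_counts"), inherits(e2, "confusion_counts"),
            e1$k == e2$k)
  structure(list(k = e1$k, p = e1$p + e2$p), class = "confusion_counts")
}

#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  kk <- x$k + 1L
  tibble(truth = rep(0:x$k, each = kk),
         pred = rep(0:x$k, times = kk),
         n = as.vector(t(x$p)))
}

per_class_tfpn <- function(cc) {
  tp <- unname(diag(cc$p))
  fp <- unname(colSums(cc$p)) - tp
  fn <- unname(rowSums(cc$p)) - tp
  list(tp = tp, fp = fp, fn = fn)
}

#' Mean intersection-over-union
#'
#' The mean over the `k+1` classes (background included) of
#' `TP / (TP + FP + FN)`.  A class absent from both prediction and truth has
#' an empty union; by default it contributes `empty_union` = 1 (perfect
#' agreement on absence) rather than an undefined 0/0.
#'
#' @param cc a [confusion_counts()] object.
#' @param empty_union IoU attributed to a class with empty union.
#' @return a value in \[0, 1\].
#' @examples
#' miou(confusion_counts(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 1, 0, 0), 2)))
#' @export
miou <- function(cc, empty_union = 1) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (sum(cc$p) == 0) abort("confusion counts are empty")
  t <- per_class_tfpn(cc)
  denom <- t$tp + t$fp + t$fn
  iou <- ifelse(denom == 0, empty_union, t$tp / denom)
  mean(iou)
}

#' Dice coefficient of the foreground class
#'
#' `2 TP / (2 TP + FP + FN)` on the foreground of a binary task, identical
#' to the set form `2 |X intersect Y| / (|X| + |Y|)` with X the predicted and Y the
#' true foreground.  If both masks are empty the score is defined as 1.
#' Algebraically `Dice = 2 IoU / (1 + IoU)`, so Dice never falls below the
#' foreground IoU.
#'
#' @param cc a [confusion_counts()] with `k = 1`.
#' @return a value in \[0, 1\].
#' @export
dice_score <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$k != 1) abort("dice_score() is defined for binary tasks (k = 1)")
  t <- per_class_tfpn(cc)
  denom <- 2 * t$tp[2] + t$fp[2] + t$fn[2]
  if (denom == 0) return(1)
  2 * t$tp[2] / denom
}

#' Evaluate a model on labelled samples
#'
#' Predicts every sample in evaluation mode, thresholds at `threshold`,
#' pools the confusion counts over the whole set and reports micro-averaged
#' MIoU and Dice (the metric of the pooled counts) together with a per-image
#' table, whose column means give the macro-average.
#'
#' @param model a built `unet_model`.
#' @param samples list of segmentation samples (each with `$image`, `$mask`,
#'   `$id`), e.g. from [generate_synth_dataset()] or [load_dataset()].
#' @param threshold binarization threshold.
#' @return list with `miou`, `dice` (pooled) and `per_image` (a tibble with
#'   one row per sample).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  if (!length(samples)) abort("no samples to evaluate")
  pooled <- NULL
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pr <- predict(model, s$image)
    cc <- confusion_counts(binarize(pr, threshold), s$mask, k = 1)
    pooled <- if (is.null(pooled)) cc else pooled + cc
    rows[[i]] <- tibble(id = s$id, miou = miou(cc), dice = dice_score(cc))
  }
  list(miou = miou(pooled), dice = dice_score(pooled),
       per_image = dplyr::bind_rows(rows))
}
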
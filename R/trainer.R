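#' Training configuration
#'
#' Defaults follow the package's training protocol: 50 epochs with
#' mini-batches of 5, Adam at learning rate 1e-3, per-pixel binary
#' cross-entropy between the sigmoid output and the binary mask (a soft Dice
#' loss is available as an alternative), evaluation on the test set after
#' every epoch, and best-weights selection by pooled test Dice.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param optimizer only `"adam"` is implemented.
#' @param loss `"bce"` (default) or `"dice"`.
#' @param seed seed for shuffling (training is deterministic given the seed
#'   and a fixed thread count).
#' @param eval_every_epoch evaluate test MIoU/Dice after each epoch.
#' @param eval_train also evaluate metrics on the training split (slower;
#'   used by overfitting diagnostics).
#' @param threshold binarization threshold used during evaluation.
#' @param checkpoint_path optional path; best-Dice weights are saved there.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 5, lr = 1e-3,
                         optimizer = "adam", loss = c("bce", "dice"),
                         seed = 0, eval_every_epoch = TRUE,
                         eval_train = FALSE, threshold = 0.5,
                         checkpoint_path = NULL) {
  loss <- match.arg(loss)
  if (!identical(optimizer, "adam"))
    abort(sprintf("unknown optimizer '%s'", optimizer))
  if (epochs < 1 || batch_size < 1 || lr <= 0)
    abort("epochs, batch_size must be positive; lr must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, loss = loss, seed = seed,
                 eval_every_epoch = eval_every_epoch,
                 eval_train = eval_train, threshold = threshold,
                 checkpoint_path = checkpoint_path),
            class = "train_config")
}

#' Per-pixel binary cross-entropy
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`.  At a constant
#' prediction of 0.5 the loss equals `log(2)` for any target.
#'
#' @param prob predicted probabilities in (0, 1).
#' @param target binary targets of the same shape.
#' @return scalar loss (>= 0).
#' @export
bce_loss <- function(prob, target) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

soft_dice_loss <- function(prob, target, smooth = 1) {
  num <- 2 * sum(prob * target) + smooth
  den <- sum(prob) + sum(target) + smooth
  1 - num / den
}

stack_batch <- function(samples, idx) {
  H <- nrow(samples[[idx[1]]]$image); W <- ncol(samples[[idx[1]]]$image)
  x <- array(0, dim = c(H, W, 1, length(idx)))
  y <- array(0, dim = c(H, W, 1, length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1, j] <- samples[[idx[j]]]$image
    y[, , 1, j] <- samples[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) abort(sprintf("missing gradient for '%s'", nm))
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a segmentation network
#'
#' Mini-batch optimization of the per-pixel loss with Adam, seeded shuffling
#' every epoch, per-epoch evaluation (pooled MIoU and Dice on the test set),
#' and best-Dice weight tracking.  Two calls with identical seeds, data and
#' configuration produce identical logs under single-threaded execution.
#'
#' @param model a built `unet_model` (see [build_unet()],
#'   [build_pyconvunet()]).
#' @param train_samples non-empty list of segmentation samples whose sizes
#'   are divisible by `2^n_downsamplings`.
#' @param test_samples optional held-out samples for per-epoch evaluation.
#' @param config a [train_config()].
#' @return a `train_result`: list with `model` (final weights), `best_model`
#'   (best pooled test Dice, or final if no test set), `log` (a `train_log`
#'   tibble with one row per epoch) and `config`.
#' @export
train_model <- function(model, train_samples, test_samples = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (!length(train_samples)) abort("empty training set")
  dv <- 2^model$topology$n_downsamplings
  for (s in train_samples)
    if (any(dim(s$image) %% dv != 0))
      abort(sprintf("sample '%s' size not divisible by %d", s$id, dv))
  n <- length(train_samples)
  state <- adam_init(model$params)
  rows <- vector("list", config$epochs)
  best_dice <- -Inf
  best_model <- NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1, n)]
        bt <- stack_batch(train_samples, idx)
        fw <- net_forward(model, bt$x, training = TRUE)
        loss <- if (config$loss == "bce") bce_loss(fw$prob, bt$y)
                else soft_dice_loss(fw$prob, bt$y)
        if (!is.finite(loss))
          abort(sprintf("non-finite loss at epoch %d (batch starting %d)",
                        epoch, b0))
        dlogits <- if (config$loss == "bce") {
          (fw$prob - bt$y) / length(bt$y)
        } else {
          num <- 2 * sum(fw$prob * bt$y) + 1
          den <- sum(fw$prob) + sum(bt$y) + 1
          dp <- -(2 * bt$y * den - num) / den^2
          dp * fw$prob * (1 - fw$prob)
        }
        grads <- net_backward(model, fw, dlogits, training = TRUE)
        upd <- adam_step(model$params, grads, state, config$lr)
        model$params <- upd$params
        state <- upd$state
        model <- update_bn_buffers(model, fw)
        losses <- c(losses, loss)
      }
      row <- tibble(epoch = epoch, train_loss = mean(losses),
                    test_miou = NA_real_, test_dice = NA_real_)
      if (config$eval_train) {
        ev <- evaluate_model(model, train_samples, config$threshold)
        row$train_miou <- ev$miou
        row$train_dice <- ev$dice
      }
      if (!is.null(test_samples) && config$eval_every_epoch) {
        ev <- evaluate_model(model, test_samples, config$threshold)
        row$test_miou <- ev$miou
        row$test_dice <- ev$dice
        if (ev$dice > best_dice) {
          best_dice <- ev$dice
          best_model <- model
          if (!is.null(config$checkpoint_path))
            save_checkpoint(model, config$checkpoint_path)
        }
      }
      rows[[epoch]] <- row
    }
  })
  log <- dplyr::bind_rows(rows)
  class(log) <- c("train_log", class(log))
  structure(list(model = model, best_model = best_model %||% model,
                 log = log, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epoch(s), final loss %.4f\n",
              nrow(x$log), x$log$train_loss[nrow(x$log)]))
  invisible(x)
}

#' @method glance train_result
#' @export
glance.train_result <- function(x, ...) {
  lg <- x$log
  tibble(epochs = nrow(lg),
         final_loss = lg$train_loss[nrow(lg)],
         best_test_dice = if (all(is.na(lg$test_dice))) NA_real_
                          else max(lg$test_dice, na.rm = TRUE),
         final_test_miou = lg$test_miou[nrow(lg)],
         final_test_dice = lg$test_dice[nrow(lg)])
}

#' @method tidy train_result
#' @export
tidy.train_result <- function(x, ...) as_tibble(x$log)
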
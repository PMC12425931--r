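# Training protocol: cross-entropy loss, SGD with momentum, step learning-rate
# schedule, epoch loop with validation Dice tracking.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 8, 100 epochs, SGD with
#' initial learning rate 0.001 reduced by a factor of 10 every 20 epochs,
#' cross-entropy loss, random horizontal flip augmentation on the training
#' split. Momentum 0.9 is the de-facto default for segmentation training;
#' weight decay is 0 for fidelity to the stated recipe.
#'
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs.
#' @param lr0 initial learning rate.
#' @param lr_step epochs between learning-rate drops.
#' @param lr_gamma multiplicative learning-rate decay factor.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param hflip_prob probability of horizontal flip augmentation (training
#'   split only).
#' @param seed RNG seed governing shuffling and augmentation.
#' @return An object of class `mdwc_train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 100L, lr0 = 0.001,
                         lr_step = 20L, lr_gamma = 0.1, momentum = 0.9,
                         weight_decay = 0, hflip_prob = 0.5, seed = 42L) {
  stopifnot(lr0 > 0, lr_gamma > 0, lr_gamma <= 1, batch_size >= 1, epochs >= 1,
            lr_step >= 1, hflip_prob >= 0, hflip_prob <= 1)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr0 = lr0, lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 momentum = momentum, weight_decay = weight_decay,
                 hflip_prob = hflip_prob, seed = as.integer(seed)),
            class = "mdwc_train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lr0 * lr_gamma ^ floor(epoch / lr_step)` with 0-based
#' epochs, i.e. with the defaults the rate drops tenfold at epochs 20, 40,
#' 60 and 80.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg a [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_at_epoch(0, train_config())   # 0.001
#' lr_at_epoch(20, train_config())  # 0.0001
lr_at_epoch <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("invalid input: epoch must be non-negative", call. = FALSE)
  if (any(epoch >= cfg$epochs)) stop("invalid input: epoch beyond schedule", call. = FALSE)
  cfg$lr0 * cfg$lr_gamma^floor(epoch / cfg$lr_step)
}

fold_labels <- function(mask) {
  # mask: H x W matrix or N x H x W array -> folded integer vector (h, w, n)
  if (is.matrix(mask)) return(as.integer(mask))
  stopifnot(length(dim(mask)) == 3L)
  as.integer(aperm(mask, c(2L, 3L, 1L)))
}

ce_loss_ft <- function(logits, y) {
  n <- nrow(logits$m)
  if (length(y) != n) stop("invalid input: label/logit size mismatch", call. = FALSE)
  if (any(y < 0L | y >= ncol(logits$m)))
    stop("invalid input: labels outside the class range", call. = FALSE)
  p <- cpp_row_softmax(logits$m)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = ft(g / n, logits$sp))
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over pixels of the negative log-softmax probability of the true
#' class.
#'
#' @param logits `N x C x H x W` array of class scores.
#' @param mask integer labels in `0..C-1`, as an `H x W` matrix (N = 1) or
#'   `N x H x W` array.
#' @return Scalar loss.
#' @export
#' @examples
#' logits <- array(0, c(1, 2, 2, 2))  # uniform scores
#' ce_loss(logits, matrix(0L, 2, 2))  # log(2)
ce_loss <- function(logits, mask) {
  ce_loss_ft(ft_from_array(logits), fold_labels(mask))$loss
}

# ---- SGD -------------------------------------------------------------------

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

sgd_update <- function(params, lr, momentum, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    p$mom <- momentum * p$mom + g
    p$value <- p$value - lr * p$mom
  }
  invisible(NULL)
}

stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  m <- matrix(unlist(lapply(samples, function(s) as.vector(s$image)), use.names = FALSE),
              ncol = 1L)
  y <- as.integer(unlist(lapply(samples, function(s) as.vector(s$mask)), use.names = FALSE))
  list(x = ft(m, c(H, W, length(samples))), y = y)
}

#' One SGD step on a batch of image/mask pairs
#'
#' Runs a training-mode forward pass, cross-entropy backward pass and an SGD
#' parameter update.
#'
#' @param net an `mdwc_net`.
#' @param samples list of samples, each `list(image = , mask = )` with equal
#'   spatial dims.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @return The batch loss (invisibly usable for logging).
#' @export
train_step <- function(net, samples, lr, momentum = 0.9, weight_decay = 0) {
  b <- stack_batch(samples)
  params <- net_params(net)
  zero_grads(params)
  logits <- net_forward_ft(net, b$x, train = TRUE)
  l <- ce_loss_ft(logits, b$y)
  net_backward_ft(net, l$grad)
  sgd_update(params, lr, momentum, weight_decay)
  l$loss
}

eval_split <- function(net, samples, batch_size = 8L) {
  losses <- numeric(0)
  dices <- numeric(0)
  for (start in seq(1L, length(samples), by = batch_size)) {
    chunk <- samples[start:min(start + batch_size - 1L, length(samples))]
    b <- stack_batch(chunk)
    logits <- net_forward_ft(net, b$x, train = FALSE)
    pred <- max.col(logits$m, ties.method = "first") - 1L
    HW <- prod(dim(chunk[[1]]$mask))
    for (i in seq_along(chunk)) {
      rows <- (i - 1L) * HW + seq_len(HW)
      losses <- c(losses, ce_loss_ft(ft(logits$m[rows, , drop = FALSE], c(logits$sp[1:2], 1L)),
                                     b$y[rows])$loss)
      cc <- confusion_counts(matrix(pred[rows], nrow(chunk[[i]]$mask)), chunk[[i]]$mask)
      dices <- c(dices, dice(cc))
    }
  }
  list(loss = mean(losses), dice = mean(dices))
}

hflip_sample <- function(s) {
  s$image <- s$image[, ncol(s$image):1, drop = FALSE]
  s$mask <- s$mask[, ncol(s$mask):1, drop = FALSE]
  s
}

#' Train a network
#'
#' Mini-batch SGD with momentum and the step learning-rate schedule of
#' [lr_at_epoch()]. Each epoch shuffles the training split, applies a fresh
#' horizontal-flip draw per sample, runs the SGD steps, then records train
#' loss, validation loss and validation Dice (evaluation mode). The weights
#' with the best validation Dice are kept and restored into the returned
#' network; all randomness is governed by `cfg$seed`.
#'
#' @param net an `mdwc_net`.
#' @param data `list(train = , val = )`, each a list of samples
#'   (`list(image = , mask = , id = )`).
#' @param cfg a [train_config()].
#' @param checkpoint_path optional file stem; the best-validation checkpoint
#'   is written there via [save_checkpoint()].
#' @param verbose log per-epoch progress to stderr.
#' @return `list(net, history, best_epoch, best_val_dice)`; `history` is a
#'   tibble with columns epoch, lr, train_loss, val_loss, val_dice.
#' @export
train <- function(net, data, cfg = train_config(), checkpoint_path = NULL,
                  verbose = FALSE) {
  if (is.null(data$train) || length(data$train) == 0L)
    stop("invalid input: empty training split", call. = FALSE)
  if (is.null(data$val) || length(data$val) == 0L)
    stop("invalid input: empty validation split", call. = FALSE)
  set.seed(cfg$seed)
  params <- net_params(net)
  history <- vector("list", cfg$epochs)
  best <- list(dice = -Inf, epoch = NA_integer_, values = NULL, running = NULL)
  for (epoch in 0:(cfg$epochs - 1L)) {
    lr <- lr_at_epoch(epoch, cfg)
    ord <- sample.int(length(data$train))
    batch_losses <- c()
    batch_sizes <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      samples <- lapply(data$train[take], function(s)
        if (stats::runif(1) < cfg$hflip_prob) hflip_sample(s) else s)
      b <- stack_batch(samples)
      zero_grads(params)
      logits <- net_forward_ft(net, b$x, train = TRUE)
      l <- ce_loss_ft(logits, b$y)
      net_backward_ft(net, l$grad)
      sgd_update(params, lr, cfg$momentum, cfg$weight_decay)
      batch_losses <- c(batch_losses, l$loss)
      batch_sizes <- c(batch_sizes, length(take))
    }
    train_loss <- sum(batch_losses * batch_sizes) / sum(batch_sizes)
    ev <- eval_split(net, data$val)
    if (ev$dice > best$dice) {
      best$dice <- ev$dice
      best$epoch <- epoch
      best$values <- lapply(params, function(p) p$value)
      best$running <- snapshot_bn(net)
    }
    history[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = train_loss,
      val_loss = ev$loss, val_dice = ev$dice)
    if (verbose)
      message(sprintf("[%s] epoch %3d lr %.2g train %.4f val %.4f dice %.4f",
                      format(Sys.time(), "%H:%M:%S"), epoch, lr, train_loss,
                      ev$loss, ev$dice))
  }
  for (i in seq_along(params)) params[[i]]$value <- best$values[[i]]
  restore_bn(net, best$running)
  if (!is.null(checkpoint_path)) save_checkpoint(net, checkpoint_path)
  list(net = net, history = do.call(rbind, history),
       best_epoch = best$epoch, best_val_dice = best$dice)
}
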
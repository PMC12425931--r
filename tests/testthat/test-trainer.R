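# Training protocol: schedule, loss, determinism, checkpointing, prediction.

ns <- asNamespace("mdwcnet")

test_that("the step learning-rate schedule drops tenfold every 20 epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(19, cfg), 0.001)
  expect_equal(lr_at_epoch(20, cfg), 0.0001)
  expect_equal(lr_at_epoch(99, cfg), 0.001 * 1e-4)
  lrs <- vapply(0:99, lr_at_epoch, 0, cfg = cfg)
  expect_equal(length(unique(lrs)), 5L)
  expect_equal(which(diff(lrs) != 0), c(20L, 40L, 60L, 80L))  # 0-based epochs 20/40/60/80
  expect_error(lr_at_epoch(-1, cfg), "invalid input")
  expect_error(lr_at_epoch(100, cfg), "invalid input")
})

test_that("cross-entropy matches a per-pixel softmax/NLL oracle", {
  # probability ~1 on the true class -> loss ~0
  lg <- array(0, c(1, 2, 2, 2)); lg[1, 2, , ] <- 50
  expect_lt(ce_loss(lg, matrix(1L, 2, 2)), 1e-12)
  # uniform logits -> log(2)
  expect_equal(ce_loss(array(0.7, c(1, 2, 3, 3)), matrix(0L, 3, 3)), log(2))
  # random case against an explicit loop
  set.seed(1)
  lg <- array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  mask <- array(sample(0:1, 32, TRUE), c(2, 4, 4))
  ref <- 0
  for (n in 1:2) for (i in 1:4) for (j in 1:4) {
    z <- lg[n, , i, j]
    p <- exp(z) / sum(exp(z))
    ref <- ref - log(p[mask[n, i, j] + 1])
  }
  expect_equal(ce_loss(lg, mask), ref / 32, tolerance = 1e-12)
  expect_error(ce_loss(lg, array(2L, c(2, 4, 4))), "labels")
})

test_that("training logs one history row per epoch and is seed-deterministic", {
  set.seed(1)
  data <- list(train = lapply(1:8, toy_sample, side = 32),
               val = lapply(9:10, toy_sample, side = 32))
  cfg <- train_config(epochs = 2, batch_size = 4, lr0 = 0.01, seed = 7)
  fit1 <- train(build_network(tiny_cfg(), init_seed = 5), data, cfg)
  expect_equal(nrow(fit1$history), 2L)
  expect_named(fit1$history, c("epoch", "lr", "train_loss", "val_loss", "val_dice"))
  fit2 <- train(build_network(tiny_cfg(), init_seed = 5), data, cfg)
  expect_identical(fit1$history$train_loss[1], fit2$history$train_loss[1])
  expect_identical(fit1$history, fit2$history)
  expect_error(train(build_network(tiny_cfg()), list(train = list(), val = data$val), cfg),
               "empty training split")
})

test_that("a single SGD step strictly decreases the loss for a small learning rate", {
  for (seed in 1:3) {
    net <- build_network(tiny_cfg(), init_seed = seed)
    set.seed(seed)
    samples <- lapply(seq_len(4) + 10 * seed, toy_sample, side = 32)
    b <- ns$stack_batch(samples)
    l0 <- ns$ce_loss_ft(ns$net_forward_ft(net, b$x, train = TRUE), b$y)$loss
    train_step(net, samples, lr = 1e-3)
    l1 <- ns$ce_loss_ft(ns$net_forward_ft(net, b$x, train = TRUE), b$y)$loss
    expect_lt(l1, l0)
  }
})

test_that("sustained single-batch training overfits to near-zero loss", {
  net <- build_network(tiny_cfg(), init_seed = 2)
  samples <- lapply(1:2, toy_sample, side = 32)
  losses <- vapply(1:200, function(i) train_step(net, samples, lr = 0.05), 0)
  expect_lt(losses[200], 0.05)
  # smoothed loss is non-increasing overall (window 10)
  sm <- stats::filter(losses, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("checkpoints round-trip bit-exactly, config sidecar included", {
  data <- list(train = lapply(1:4, toy_sample, side = 32),
               val = lapply(5:6, toy_sample, side = 32))
  net <- build_network(tiny_cfg(), init_seed = 3)
  fit <- train(net, data, train_config(epochs = 1, batch_size = 4, seed = 1))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$net, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$cfg, fit$net$cfg)
  ev1 <- ns$eval_split(fit$net, data$val)
  ev2 <- ns$eval_split(back, data$val)
  expect_identical(ev1$dice, ev2$dice)
  expect_identical(ev1$loss, ev2$loss)
  # predictions are identical too
  expect_identical(net_predict(fit$net, data$val[[1]]$image),
                   net_predict(back, data$val[[1]]$image))
})

test_that("prediction takes the per-pixel argmax with ties to class 0", {
  net <- build_network(tiny_cfg(), init_seed = 4)
  # force known logits through the classifier bias on zero weights
  for (p in ns$net_params(net)) p$value[] <- 0
  cls_b <- net$cls$params$b
  cls_b$value <- c(0, 1)
  expect_true(all(net_predict(net, matrix(0.5, 32, 32)) == 1L))
  cls_b$value <- c(0, 0)  # exact tie everywhere
  expect_true(all(net_predict(net, matrix(0.5, 32, 32)) == 0L))
})
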
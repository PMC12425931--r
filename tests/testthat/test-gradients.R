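# Analytic gradients against central finite differences.

ns <- asNamespace("mdwcnet")

# loss = sum(target * output); returns worst relative error over sampled
# coordinates of every parameter of `mod`
gradcheck_module <- function(mod, x, eps = 1e-6, n_coords = 10) {
  target <- NULL
  loss_of <- function() {
    y <- ns$m_fwd(mod, x, train = TRUE)
    if (is.null(target)) target <<- matrix(seq_len(length(y$m)) %% 7 - 3, nrow(y$m))
    sum(y$m * target)
  }
  params <- ns$module_params(mod)
  ns$zero_grads(params)
  invisible(loss_of())
  y <- ns$m_fwd(mod, x, train = TRUE)
  ns$m_bwd(mod, ns$ft(target, y$sp))
  worst <- 0
  for (p in params) {
    for (ei in sample(length(p$value), min(n_coords, length(p$value)))) {
      v0 <- p$value[ei]
      p$value[ei] <- v0 + eps; lp <- loss_of()
      p$value[ei] <- v0 - eps; lm <- loss_of()
      p$value[ei] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - p$grad[ei]) / max(abs(num), abs(p$grad[ei]), 1e-6))
    }
  }
  worst
}

test_that("adaptive weighting layer obeys its analytic gradient (dL/dw_n = sum x_n dL/dy_n)", {
  # closed form: single channel summing to S with L = sum(output) gives dL/dw = S
  set.seed(1)
  x <- ns$ft(matrix(rnorm(36), 36, 1), c(6L, 6L, 1L))
  mod <- ns$nn_chscale(1L)
  ns$zero_grads(mod$params)
  y <- ns$m_fwd(mod, x, train = TRUE)
  ns$m_bwd(mod, ns$ft(matrix(1, 36, 1), y$sp))
  expect_equal(mod$params$w$grad, sum(x$m), tolerance = 1e-12, ignore_attr = TRUE)
  # finite differences over random 1 x 4 x 6 x 6 inputs, several seeds
  for (seed in 1:5) {
    set.seed(seed)
    xt <- ns$ft_from_array(array(rnorm(4 * 36), c(1, 4, 6, 6)))
    mod <- ns$nn_chscale(4L)
    mod$params$w$value <- runif(4, 0.5, 1.5)
    expect_lt(gradcheck_module(mod, xt, eps = 1e-4), 1e-3)
  }
})

test_that("every block type passes a finite-difference gradient check", {
  set.seed(2)
  checks <- list(
    list(mod = ns$nn_mscaw(3L, 8L), C = 3L),
    list(mod = ns$nn_bieb_upper(8L, 2L), C = 8L),
    list(mod = ns$nn_bieb_lower(6L), C = 6L),
    list(mod = ns$nn_cbam(8L, 2L), C = 8L),
    list(mod = ns$nn_aspp(3L, 8L), C = 3L),
    list(mod = ns$nn_plain_conv(3L, 5L), C = 3L),
    list(mod = ns$nn_bn(4L), C = 4L),
    list(mod = ns$nn_conv(3L, 4L, 3L, dilation = 2L), C = 3L))
  for (ch in checks) {
    x <- ns$ft(matrix(rnorm(48 * ch$C), 48, ch$C), c(6L, 4L, 2L))
    expect_lt(gradcheck_module(ch$mod, x), 5e-5)
  }
})

test_that("DFCB propagates exact gradients to both encoder and decoder inputs", {
  set.seed(3)
  mod <- ns$nn_dfcb(4L)
  enc <- ns$ft(matrix(rnorm(32 * 4), 32, 4), c(4L, 4L, 2L))
  dec <- ns$ft(matrix(rnorm(32 * 8), 32, 8), c(4L, 4L, 2L))
  target <- matrix(rnorm(32 * 4), 32, 4)
  loss_of <- function() sum(ns$m_fwd(mod, list(enc = enc, dec = dec), TRUE)$m * target)
  ns$zero_grads(ns$module_params(mod))
  y <- ns$m_fwd(mod, list(enc = enc, dec = dec), TRUE)
  g <- ns$m_bwd(mod, ns$ft(target, y$sp))
  eps <- 1e-6
  for (ei in sample(length(enc$m), 10)) {
    v0 <- enc$m[ei]
    enc$m[ei] <- v0 + eps; lp <- loss_of()
    enc$m[ei] <- v0 - eps; lm <- loss_of()
    enc$m[ei] <- v0
    expect_equal(g$enc$m[ei], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  for (ei in sample(length(dec$m), 10)) {
    v0 <- dec$m[ei]
    dec$m[ei] <- v0 + eps; lp <- loss_of()
    dec$m[ei] <- v0 - eps; lm <- loss_of()
    dec$m[ei] <- v0
    expect_equal(g$dec$m[ei], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("the assembled network's parameter gradients match finite differences", {
  set.seed(4)
  net <- build_network(tiny_cfg(), init_seed = 4)
  x <- ns$ft_from_array(array(rnorm(2 * 16 * 16), c(2, 1, 16, 16)))
  yl <- sample(0:1, 16 * 16 * 2, replace = TRUE)
  params <- ns$net_params(net)
  ns$zero_grads(params)
  l <- ns$ce_loss_ft(ns$net_forward_ft(net, x, TRUE), yl)
  ns$net_backward_ft(net, l$grad)
  eps <- 1e-6
  worst <- 0
  for (rep in 1:40) {
    p <- params[[sample(length(params), 1)]]
    ei <- sample(length(p$value), 1)
    v0 <- p$value[ei]
    f <- function(v) {
      p$value[ei] <- v
      out <- ns$ce_loss_ft(ns$net_forward_ft(net, x, TRUE), yl)$loss
      p$value[ei] <- v0
      out
    }
    num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
    worst <- max(worst, abs(num - p$grad[ei]) / max(abs(num), abs(p$grad[ei]), 1e-6))
  }
  expect_lt(worst, 1e-3)
})
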
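# Block-level contracts of the three MDWC-Net building blocks and the
# assembled network.

ns <- asNamespace("mdwcnet")

test_that("depthwise separable conv honours shape, linearity and identity kernels", {
  # zero input -> zero output (linear operator, no bias)
  z <- depthwise_separable_conv(array(0, c(1, 4, 8, 8)),
                                array(rnorm(3 * 3 * 4), c(3, 3, 4)),
                                matrix(rnorm(4 * 8), 4, 8))
  expect_equal(dim(z), c(1L, 8L, 8L, 8L))
  expect_true(all(z == 0))
  # identity depthwise kernel + unit pointwise reproduces the input
  set.seed(1)
  x <- array(rnorm(25), c(1, 1, 5, 5))
  dw <- array(0, c(3, 3, 1)); dw[2, 2, 1] <- 1
  expect_equal(depthwise_separable_conv(x, dw, matrix(1, 1, 1)), x, tolerance = 1e-14)
  # even kernels are rejected
  expect_error(depthwise_separable_conv(x, array(0, c(2, 2, 1)), matrix(1, 1, 1)),
               "invalid configuration")
})

test_that("adaptive channel weighting scales channels and validates lengths", {
  set.seed(2)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  expect_equal(adaptive_weight_apply(x, c(1, 1, 1)), x)
  expect_true(all(adaptive_weight_apply(x, c(0, 0, 0)) == 0))
  w <- c(0.5, -2, 3)
  y <- adaptive_weight_apply(x, w)
  for (c in 1:3) expect_equal(y[, c, , ], w[c] * x[, c, , ])
  expect_error(adaptive_weight_apply(x, c(1, 2)), "invalid configuration")
})

test_that("channel softmax is a per-pixel distribution with the exact 2-channel values", {
  # constant input, 4 channels -> uniform 0.25
  expect_equal(as.vector(channel_softmax(array(5, c(1, 4, 3, 3)))),
               rep(0.25, 36), tolerance = 1e-14)
  # single channel -> exactly 1
  expect_equal(as.vector(channel_softmax(array(rnorm(9), c(1, 1, 3, 3)))),
               rep(1, 9))
  # channels (0, ln 3) -> (0.25, 0.75)
  x <- array(0, c(1, 2, 1, 1)); x[1, 2, 1, 1] <- log(3)
  expect_equal(as.vector(channel_softmax(x)), c(0.25, 0.75), tolerance = 1e-14)
  # sums to one at every pixel for random input, even with huge logits
  set.seed(3)
  big <- array(rnorm(2 * 6 * 4 * 4, sd = 30), c(2, 6, 4, 4))
  s <- channel_softmax(big)
  expect_true(all(s > 0))
  expect_equal(as.vector(apply(s, c(1, 3, 4), sum)), rep(1, 2 * 16), tolerance = 1e-6)
})

test_that("MSCAW concatenates four weighted branches and collapses to the plain variant", {
  set.seed(4)
  mod <- ns$nn_mscaw(16L, 64L)
  x <- ns$ft_from_array(array(rnorm(1 * 16 * 32 * 32), c(1, 16, 32, 32)))
  y <- ns$m_fwd(mod, x, train = TRUE)
  expect_equal(ns$ft_shape(y), c(1L, 64L, 32L, 32L))
  # zero input -> zero output (ReLU(0) = 0 after BN with zero shift)
  z <- ns$m_fwd(mod, ns$ft(matrix(0, 32 * 32, 16), c(32L, 32L, 1L)), train = TRUE)
  expect_true(all(z$m == 0))
  # with adaptive weights at their initial value 1, the weighted block equals
  # the weighting-free variant built from identical conv weights, bit for bit
  set.seed(7); m1 <- ns$nn_mscaw(8L, 16L, weighting = TRUE)
  set.seed(7); m2 <- ns$nn_mscaw(8L, 16L, weighting = FALSE)
  xt <- ns$ft_from_array(array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8)))
  expect_identical(ns$m_fwd(m1, xt, TRUE)$m, ns$m_fwd(m2, xt, TRUE)$m)
  expect_error(ns$nn_mscaw(8L, 30L), "invalid configuration")
})

test_that("DFCB maps (C, 2C) channels to C with softmax-gated fusion", {
  set.seed(5)
  mod <- ns$nn_dfcb(64L)
  enc <- ns$ft_from_array(array(rnorm(1 * 64 * 32 * 32), c(1, 64, 32, 32)))
  dec <- ns$ft_from_array(array(rnorm(1 * 128 * 32 * 32), c(1, 128, 32, 32)))
  y <- ns$m_fwd(mod, list(enc = enc, dec = dec), train = TRUE)
  expect_equal(ns$ft_shape(y), c(1L, 64L, 32L, 32L))
  # zero encoder input: the first C/2 output channels vanish
  y0 <- ns$m_fwd(mod, list(enc = ns$ft(matrix(0, 1024, 64), c(32L, 32L, 1L)), dec = dec),
                 train = TRUE)
  expect_true(all(y0$m[, 1:32] == 0))
  expect_false(all(y0$m[, 33:64] == 0))
  # channel mismatch / spatial mismatch are rejected
  expect_error(ns$m_fwd(mod, list(enc = enc, dec = enc), TRUE), "invalid configuration")
  small <- ns$ft_from_array(array(0, c(1, 128, 16, 16)))
  expect_error(ns$m_fwd(mod, list(enc = enc, dec = small), TRUE), "invalid configuration")
  # degenerate case C = 2: the softmax gate over one channel is exactly 1, so
  # the outputs are the reduced maps themselves
  mod2 <- ns$nn_dfcb(2L)
  e2 <- ns$ft_from_array(array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4)))
  d2 <- ns$ft_from_array(array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4)))
  y2 <- ns$m_fwd(mod2, list(enc = e2, dec = d2), train = TRUE)
  fn1 <- mod2$cache$fn1; fi1 <- mod2$cache$fi1
  expect_equal(mod2$cache$fi2, matrix(1, 32, 1))
  expect_equal(y2$m, ns$cpp_cbind_all(list(fn1, fi1)))
})

test_that("BIEB channel attention produces sigmoid weights with shared pooling paths", {
  set.seed(6)
  mod <- ns$nn_bieb_upper(8L, 2L)
  x <- ns$ft_from_array(array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4)))
  y <- ns$m_fwd(mod, x, train = TRUE)
  z <- mod$cache$z
  expect_true(all(z > 0 & z < 1))                      # strict sigmoid range
  expect_equal(y$m, ns$cpp_nc_scale(x$m, z, 16L, 2L))  # output is z * x
  # zero-initialised perceptron: z = sigmoid(0) = 0.5 -> output x/2
  for (p in mod$params) p$value[] <- 0
  y5 <- ns$m_fwd(mod, x, train = TRUE)
  expect_equal(y5$m, x$m / 2, tolerance = 1e-14)
  # constant channel: avg-pool and max-pool agree, so both MLP outputs coincide
  set.seed(7)
  mod2 <- ns$nn_bieb_upper(4L, 2L)
  xc <- ns$ft(matrix(rep(c(1.5, -2, 0.25, 4), each = 16), 16, 4), c(4L, 4L, 1L))
  ns$m_fwd(mod2, xc, train = TRUE)
  expect_equal(mod2$cache$fa$o, mod2$cache$fm$o, tolerance = 1e-12)
  expect_error(ns$nn_bieb_upper(8L, 8L), "invalid configuration")
})

test_that("BIEB residual branch keeps shape and its residual bookkeeping identity", {
  set.seed(8)
  mod <- ns$nn_bieb_lower(16L)
  x <- ns$ft_from_array(array(rnorm(1 * 16 * 8 * 8), c(1, 16, 8, 8)))
  y <- ns$m_fwd(mod, x, train = TRUE)
  expect_equal(ns$ft_shape(y), c(1L, 16L, 8L, 8L))
  # output minus delta(F5-2) equals F~5-1 = F~5 + x exactly
  f5t <- ns$m_fwd(mod$children[[1]], x, train = FALSE)  # eval: frozen stats
  y_eval <- ns$m_fwd(mod, x, train = FALSE)
  f51 <- f5t$m + x$m
  f52 <- ns$m_fwd(mod$children[[2]], ns$ft(f51, x$sp), train = FALSE)
  delta <- ns$m_fwd(mod$children[[3]], f52, train = FALSE)
  expect_equal(y_eval$m - delta$m, f51, tolerance = 1e-12)
})

test_that("BIEB ablation rows: full branch sum equals upper plus lower; single-branch configs match", {
  set.seed(9)
  x <- ns$ft_from_array(array(rnorm(1 * 16 * 8 * 8), c(1, 16, 8, 8)))
  set.seed(11); full <- ns$nn_bieb(16L, 2L, upper = TRUE, lower = TRUE)
  set.seed(11); up <- ns$nn_bieb(16L, 2L, upper = TRUE, lower = FALSE)
  yu <- ns$m_fwd(up, x, TRUE)
  yl <- ns$m_fwd(full$children[[2]], x, TRUE)
  expect_equal(ns$m_fwd(full, x, TRUE)$m,
               ns$m_fwd(full$children[[1]], x, TRUE)$m + yl$m, tolerance = 1e-12)
  # upper-only output equals the channel-attention branch alone
  expect_equal(yu$m, ns$m_fwd(up$children[[1]], x, TRUE)$m)
  expect_error(ns$nn_bieb(16L, 2L, upper = FALSE, lower = FALSE), "invalid configuration")
})

test_that("assembled network meets the logits shape contract at multiple sizes", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, init_seed = 1)
  for (side in c(32L, 48L)) {
    lg <- net_forward(net, array(runif(side * side), c(1, 1, side, side)))
    expect_equal(dim(lg), c(1L, 2L, side, side))
  }
  expect_error(net_forward(net, array(0, c(1, 1, 30, 30))), "divisible by 16")
  expect_error(net_forward(net, array(0, c(1, 2, 32, 32))), "input channels")
})

test_that("network configuration invariants are enforced", {
  expect_error(network_config(encoder_widths = c(64, 32, 128, 256)), "increasing")
  expect_error(network_config(encoder_widths = c(6, 12, 24, 48)), "divisible")
  expect_error(network_config(kernel_set = c(2, 4, 6, 8)), "odd")
  expect_error(network_config(encoder_widths = c(8, 16, 32, 48)), "double")
  expect_error(network_config(use_bieb_upper = FALSE, use_bieb_lower = FALSE),
               "at least one branch")
  expect_error(ablation_config("nope"), "unknown ablation")
})

test_that("parameter counting is exact on hand-countable modules and deterministic", {
  expect_equal(ns$n_param_scalars(ns$module_params(ns$nn_pwconv(4L, 8L))), 32)
  expect_equal(ns$n_param_scalars(ns$module_params(ns$nn_ds_conv(4L, 8L, 3L))),
               4 * 9 + 4 * 8)
  n1 <- count_parameters(build_network(tiny_cfg(), init_seed = 1))
  n2 <- count_parameters(build_network(tiny_cfg(), init_seed = 99))
  expect_identical(n1, n2)  # count depends on config only, not on init
})

test_that("the U-Net-shaped baseline is reachable and heavier than the default design", {
  base <- build_network(tiny_ablation("baseline"), init_seed = 1)
  full <- build_network(tiny_cfg(), init_seed = 1)
  expect_gt(count_parameters(base), count_parameters(full))
  lg <- net_forward(base, array(runif(32 * 32), c(1, 1, 32, 32)))
  expect_equal(dim(lg), c(1L, 2L, 32L, 32L))
})

test_that("every ablation variant builds, runs and differs where it should", {
  x <- array(runif(32 * 32), c(1, 1, 32, 32))
  counts <- integer(0)
  for (nm in ablation_names()) {
    net <- build_network(tiny_ablation(nm, mlp_reduction = 4), init_seed = 3)
    lg <- net_forward(net, x)
    expect_equal(dim(lg), c(1L, 2L, 32L, 32L))
    counts[nm] <- count_parameters(net)
  }
  # disabling the adaptive weighting removes exactly the per-channel weights
  ws <- c(8, 16, 32, 64)
  expect_equal(counts[["mscaw_only"]] - counts[["multiscale_conv_only"]],
               sum(ws) + 2 * 64 + sum(rev(ws)))  # one weight per channel per block
})
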
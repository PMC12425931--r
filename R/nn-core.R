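# Minimal neural-network core: folded tensors, parameter slots, and layer
# modules with hand-written forward/backward passes.
#
# A feature map of shape (batch N, channels C, height H, width W) is stored
# "folded" as a (H*W*N) x C matrix plus its spatial dims, so channel-wise
# operations are plain matrix algebra and BLAS does the heavy lifting.

#' Create a folded feature map
#'
#' @param m numeric matrix of dim `(H*W*N) x C`; row order is height fastest,
#'   then width, then image index.
#' @param sp integer vector `c(H, W, N)`.
#' @return A folded tensor (list with elements `m` and `sp`).
#' @keywords internal
ft <- function(m, sp) list(m = m, sp = as.integer(sp))

ft_channels <- function(x) ncol(x$m)

ft_shape <- function(x) c(x$sp[3L], ncol(x$m), x$sp[1L], x$sp[2L])

#' Convert between 4-D arrays (N x C x H x W) and folded tensors
#'
#' @param a numeric array with dim `c(N, C, H, W)`.
#' @return `ft_from_array()` returns a folded tensor; `ft_as_array()` the
#'   corresponding `N x C x H x W` array.
#' @keywords internal
ft_from_array <- function(a) {
  stopifnot(length(dim(a)) == 4L)
  d <- dim(a)  # N C H W
  m <- matrix(aperm(a, c(3L, 4L, 1L, 2L)), d[3L] * d[4L] * d[1L], d[2L])
  ft(m, c(d[3L], d[4L], d[1L]))
}

#' @rdname ft_from_array
#' @param x a folded tensor.
#' @keywords internal
ft_as_array <- function(x) {
  H <- x$sp[1L]; W <- x$sp[2L]; N <- x$sp[3L]; C <- ncol(x$m)
  aperm(array(x$m, c(H, W, N, C)), c(3L, 4L, 1L, 2L))
}

# ---- parameters ------------------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = dim(value) %||% length(value))
  p$mom <- p$grad
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

param_add_grad <- function(p, g) p$grad <- p$grad + g

#' Number of trainable scalars held by a module tree
#' @keywords internal
n_param_scalars <- function(params) sum(vapply(params, function(p) length(p$value), 0))

# Kaiming-uniform initialisation with the leaky-relu slope a = sqrt(5)
# convention used by the reference deep-learning frameworks' conv layers:
# U(-b, b) with b = 1/sqrt(fan_in). Keeping the reference convention matters
# for reproducing the published training dynamics (initial logits stay
# small, so the class prior calibrates within the first few steps).
he_init <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

# ---- module framework ------------------------------------------------------

new_module <- function(type, fwd, bwd, params = list(), children = list(), extra = list()) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$fwd <- fwd
  self$bwd <- bwd
  self$params <- params
  self$children <- children
  self$cache <- new.env(parent = emptyenv())
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = self)
  class(self) <- c(paste0("nn_", type), "nn_module")
  self
}

m_fwd <- function(self, x, train = TRUE) self$fwd(self, x, train)
m_bwd <- function(self, gy) self$bwd(self, gy)

#' Collect every parameter slot in a module tree (depth-first, stable order)
#' @keywords internal
module_params <- function(m) {
  out <- unname(m$params)
  for (ch in m$children) out <- c(out, module_params(ch))
  out
}

# ---- primitive layers ------------------------------------------------------

nn_identity <- function() {
  new_module("identity",
    fwd = function(self, x, train) x,
    bwd = function(self, gy) gy)
}

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  new_module("sequential",
    fwd = function(self, x, train) {
      for (mod in self$children) x <- m_fwd(mod, x, train)
      x
    },
    bwd = function(self, gy) {
      for (mod in rev(self$children)) gy <- m_bwd(mod, gy)
      gy
    },
    children = mods)
}

#' Depthwise k x k convolution (per-channel spatial filter, no bias)
#' @keywords internal
nn_dwconv <- function(channels, k) {
  if (k %% 2L == 0L) stop("invalid configuration: kernel size must be odd", call. = FALSE)
  w <- new_param(matrix(he_init(c(k * k, channels), fan_in = k * k), k * k, channels))
  new_module("dwconv",
    fwd = function(self, x, train) {
      self$cache$x <- x
      ft(cpp_dwconv_fwd(x$m, self$params$w$value, x$sp[1L], x$sp[2L], x$sp[3L], self$k), x$sp)
    },
    bwd = function(self, gy) {
      x <- self$cache$x
      r <- cpp_dwconv_bwd2(x$m, self$params$w$value, gy$m,
                          x$sp[1L], x$sp[2L], x$sp[3L], self$k)
      param_add_grad(self$params$w, r$gw)
      ft(r$gx, x$sp)
    },
    params = list(w = w), extra = list(k = as.integer(k)))
}

#' Pointwise (1 x 1) convolution, i.e. per-pixel channel mixing
#' @keywords internal
nn_pwconv <- function(in_ch, out_ch, bias = FALSE) {
  w <- new_param(matrix(he_init(c(in_ch, out_ch), fan_in = in_ch), in_ch, out_ch))
  params <- list(w = w)
  if (bias) params$b <- new_param(numeric(out_ch))
  new_module("pwconv",
    fwd = function(self, x, train) {
      self$cache$x <- x
      y <- x$m %*% self$params$w$value
      if (!is.null(self$params$b)) y <- cpp_col_add(y, self$params$b$value)
      ft(y, x$sp)
    },
    bwd = function(self, gy) {
      x <- self$cache$x
      param_add_grad(self$params$w, crossprod(x$m, gy$m))
      if (!is.null(self$params$b)) param_add_grad(self$params$b, colSums(gy$m))
      ft(tcrossprod(gy$m, self$params$w$value), x$sp)
    },
    params = params)
}

#' Standard k x k convolution via im2col + GEMM (optional dilation, no bias)
#' @keywords internal
nn_conv <- function(in_ch, out_ch, k, dilation = 1L) {
  if (k %% 2L == 0L) stop("invalid configuration: kernel size must be odd", call. = FALSE)
  w <- new_param(matrix(he_init(c(k * k * in_ch, out_ch), fan_in = k * k * in_ch),
                        k * k * in_ch, out_ch))
  new_module("conv",
    fwd = function(self, x, train) {
      cols <- cpp_im2col(x$m, x$sp[1L], x$sp[2L], x$sp[3L], self$k, self$dilation)
      self$cache$cols <- cols
      self$cache$sp <- x$sp
      self$cache$in_ch <- ncol(x$m)
      ft(cols %*% self$params$w$value, x$sp)
    },
    bwd = function(self, gy) {
      param_add_grad(self$params$w, crossprod(self$cache$cols, gy$m))
      gcols <- tcrossprod(gy$m, self$params$w$value)
      sp <- self$cache$sp
      ft(cpp_col2im(gcols, sp[1L], sp[2L], sp[3L], self$cache$in_ch, self$k, self$dilation), sp)
    },
    params = list(w = w),
    extra = list(k = as.integer(k), dilation = as.integer(dilation)))
}

#' Batch normalisation over (pixels, images) per channel
#' @keywords internal
nn_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_module("bn",
    fwd = function(self, x, train) {
      if (train) {
        n <- nrow(x$m)
        mu <- colMeans(x$m)
        v <- pmax(cpp_colsums_prod(x$m, x$m) / n - mu * mu, 0)
        invstd <- 1 / sqrt(v + self$eps)
        r <- cpp_bn_fwd(x$m, mu, invstd, self$params$gamma$value, self$params$beta$value)
        self$cache$xhat <- r$xhat
        self$cache$invstd <- invstd
        self$cache$sp <- x$sp
        unbias <- if (n > 1) n / (n - 1) else 1
        self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
        self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * v * unbias
        return(ft(r$y, x$sp))
      }
      invstd <- 1 / sqrt(self$running_var + self$eps)
      a <- self$params$gamma$value * invstd
      b <- self$params$beta$value - self$running_mean * a
      ft(cpp_col_affine(x$m, a, b), x$sp)
    },
    bwd = function(self, gy) {
      xhat <- self$cache$xhat
      if (is.null(xhat)) stop("batch-norm backward requires a training-mode forward", call. = FALSE)
      r <- cpp_bn_bwd(gy$m, xhat, self$params$gamma$value, self$cache$invstd)
      param_add_grad(self$params$gamma, r$sgx)
      param_add_grad(self$params$beta, r$sg)
      ft(r$gx, self$cache$sp)
    },
    params = list(gamma = new_param(rep(1, channels)), beta = new_param(numeric(channels))),
    extra = list(eps = eps, momentum = momentum,
                 running_mean = numeric(channels), running_var = rep(1, channels)))
}

nn_relu <- function() {
  new_module("relu",
    fwd = function(self, x, train) {
      y <- cpp_relu_fwd(x$m)
      self$cache$y <- y
      ft(y, x$sp)
    },
    bwd = function(self, gy) ft(cpp_relu_bwd(gy$m, self$cache$y), gy$sp))
}

#' Adaptive per-channel weighting: one learnable scalar per channel
#'
#' Forward: output channel n is `w_n` times input channel n. The analytic
#' gradient w.r.t. `w_n` is the sum over pixels of `x_n * dL/dY_n`.
#' @keywords internal
nn_chscale <- function(channels) {
  new_module("chscale",
    fwd = function(self, x, train) {
      if (length(self$params$w$value) != ncol(x$m))
        stop("invalid configuration: adaptive weight length must equal channel count",
             call. = FALSE)
      self$cache$x <- x
      ft(cpp_col_scale_r(x$m, self$params$w$value), x$sp)
    },
    bwd = function(self, gy) {
      param_add_grad(self$params$w, cpp_colsums_prod(self$cache$x$m, gy$m))
      ft(cpp_col_scale_r(gy$m, self$params$w$value), gy$sp)
    },
    params = list(w = new_param(rep(1, channels))))
}

# column scaling without building a diag matrix
cpp_col_scale_r <- function(m, v) cpp_col_scale(m, v)

#' Channel softmax: per pixel, softmax across the channel dimension
#' @keywords internal
nn_chsoftmax <- function() {
  new_module("chsoftmax",
    fwd = function(self, x, train) {
      s <- cpp_row_softmax(x$m)
      self$cache$s <- s
      ft(s, x$sp)
    },
    bwd = function(self, gy) ft(cpp_softmax_bwd(self$cache$s, gy$m), gy$sp))
}

# standalone softmax gradient given cached probabilities (used inside DFCB)
chsoftmax_bwd <- function(s, g) cpp_softmax_bwd(s, g)

nn_maxpool2 <- function() {
  new_module("maxpool2",
    fwd = function(self, x, train) {
      if (x$sp[1L] %% 2L != 0L || x$sp[2L] %% 2L != 0L)
        stop("invalid input: max-pooling requires even spatial dims", call. = FALSE)
      r <- cpp_maxpool2_fwd(x$m, x$sp[1L], x$sp[2L], x$sp[3L])
      self$cache$idx <- r$idx
      self$cache$nrow_in <- nrow(x$m)
      self$cache$sp_in <- x$sp
      ft(r$y, c(x$sp[1L] %/% 2L, x$sp[2L] %/% 2L, x$sp[3L]))
    },
    bwd = function(self, gy) {
      ft(cpp_maxpool2_bwd(gy$m, self$cache$idx, self$cache$nrow_in), self$cache$sp_in)
    })
}

nn_upsample2 <- function() {
  new_module("upsample2",
    fwd = function(self, x, train) {
      self$cache$sp_in <- x$sp
      ft(cpp_upsample2_fwd(x$m, x$sp[1L], x$sp[2L], x$sp[3L]),
         c(2L * x$sp[1L], 2L * x$sp[2L], x$sp[3L]))
    },
    bwd = function(self, gy) {
      sp <- self$cache$sp_in
      ft(cpp_upsample2_bwd(gy$m, sp[1L], sp[2L], sp[3L]), sp)
    })
}

#' Fused batch normalisation + ReLU (single memory pass)
#' @keywords internal
nn_bn_relu <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_module("bn",
    fwd = function(self, x, train) {
      if (train) {
        n <- nrow(x$m)
        mu <- colMeans(x$m)
        v <- pmax(cpp_colsums_prod(x$m, x$m) / n - mu * mu, 0)
        invstd <- 1 / sqrt(v + self$eps)
        r <- cpp_bnrelu_fwd(x$m, mu, invstd, self$params$gamma$value, self$params$beta$value)
        self$cache$xhat <- r$xhat
        self$cache$invstd <- invstd
        self$cache$sp <- x$sp
        unbias <- if (n > 1) n / (n - 1) else 1
        self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
        self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * v * unbias
        return(ft(r$y, x$sp))
      }
      invstd <- 1 / sqrt(self$running_var + self$eps)
      a <- self$params$gamma$value * invstd
      b <- self$params$beta$value - self$running_mean * a
      ft(cpp_col_affine_relu(x$m, a, b), x$sp)
    },
    bwd = function(self, gy) {
      if (is.null(self$cache$xhat))
        stop("batch-norm backward requires a training-mode forward", call. = FALSE)
      r <- cpp_bnrelu_bwd(gy$m, self$cache$xhat, self$params$gamma$value,
                          self$params$beta$value, self$cache$invstd)
      param_add_grad(self$params$gamma, r$sgx)
      param_add_grad(self$params$beta, r$sg)
      ft(r$gx, self$cache$sp)
    },
    params = list(gamma = new_param(rep(1, channels)), beta = new_param(numeric(channels))),
    extra = list(eps = eps, momentum = momentum,
                 running_mean = numeric(channels), running_var = rep(1, channels)))
}
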
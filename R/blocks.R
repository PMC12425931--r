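# The three MDWC-Net building blocks (MSCAW, DFCB, BIEB) plus the plain-conv,
# ASPP and CBAM drop-ins used by the ablation variants.

# ---- generic parallel-branch container (concatenates along channels) -------

nn_parallel_concat <- function(branches) {
  new_module("parallel_concat",
    fwd = function(self, x, train) {
      ys <- lapply(self$children, m_fwd, x = x, train = train)
      self$cache$widths <- vapply(ys, function(y) ncol(y$m), 0L)
      ft(cpp_cbind_all(lapply(ys, `[[`, "m")), x$sp)
    },
    bwd = function(self, gy) {
      widths <- self$cache$widths
      stops <- cumsum(widths)
      starts <- stops - widths + 1L
      gx <- NULL
      for (i in seq_along(self$children)) {
        g <- ft(gy$m[, starts[i]:stops[i], drop = FALSE], gy$sp)
        gxi <- m_bwd(self$children[[i]], g)
        gx <- if (is.null(gx)) gxi$m else gx + gxi$m
      }
      ft(gx, gy$sp)
    },
    children = branches)
}

#' Depthwise-separable convolution module
#'
#' A per-channel `k x k` spatial filter followed by a pointwise (1 x 1)
#' cross-channel convolution; no bias terms (each conv is normally followed by
#' batch normalisation).
#'
#' @param in_ch,out_ch input / output channel counts.
#' @param k odd kernel size.
#' @return An internal network module.
#' @keywords internal
nn_ds_conv <- function(in_ch, out_ch, k) {
  nn_sequential(nn_dwconv(in_ch, k), nn_pwconv(in_ch, out_ch))
}

# ---- MSCAW ----------------------------------------------------------------

#' Multi-scale convolution adaptive weighting (MSCAW) block
#'
#' Four parallel depthwise-separable branches (kernel sizes 1/3/5/7 by
#' default), each mapping to `out_ch / n_branches` channels followed by batch
#' normalisation, ReLU and - when `weighting` is `TRUE` - a learnable
#' per-channel adaptive weight; branch outputs are concatenated along the
#' channel axis. With `weighting = FALSE` this is the "multi-scale conv only"
#' ablation variant.
#'
#' @param in_ch,out_ch channel counts; `out_ch` must be divisible by the
#'   number of kernel sizes.
#' @param kernels integer vector of odd kernel sizes.
#' @param weighting logical; apply the adaptive weighting layer per branch.
#' @return An internal network module.
#' @keywords internal
nn_mscaw <- function(in_ch, out_ch, kernels = c(1L, 3L, 5L, 7L), weighting = TRUE) {
  nb <- length(kernels)
  if (out_ch %% nb != 0L)
    stop("invalid configuration: out_ch must be divisible by the number of branches",
         call. = FALSE)
  bw <- out_ch %/% nb
  branches <- lapply(kernels, function(k) {
    mods <- list(nn_dwconv(in_ch, k), nn_pwconv(in_ch, bw), nn_bn_relu(bw))
    if (weighting) mods <- c(mods, list(nn_chscale(bw)))
    nn_sequential(mods)
  })
  nn_parallel_concat(branches)
}

# ---- plain double conv (U-Net baseline level) ------------------------------

nn_plain_conv <- function(in_ch, out_ch) {
  nn_sequential(nn_conv(in_ch, out_ch, 3L), nn_bn_relu(out_ch),
                nn_conv(out_ch, out_ch, 3L), nn_bn_relu(out_ch))
}

# ---- ASPP drop-in ----------------------------------------------------------

# Minimal atrous spatial pyramid: 1x1 branch plus three 3x3 branches with
# dilation rates 1/2/4, each to out_ch/4, BN + ReLU, concatenated.
nn_aspp <- function(in_ch, out_ch, rates = c(1L, 2L, 4L)) {
  if (out_ch %% (length(rates) + 1L) != 0L)
    stop("invalid configuration: out_ch must be divisible by the ASPP branch count",
         call. = FALSE)
  bw <- out_ch %/% (length(rates) + 1L)
  branches <- c(
    list(nn_sequential(nn_pwconv(in_ch, bw), nn_bn_relu(bw))),
    lapply(rates, function(r)
      nn_sequential(nn_conv(in_ch, bw, 3L, dilation = r), nn_bn_relu(bw)))
  )
  nn_parallel_concat(branches)
}

# ---- DFCB ------------------------------------------------------------------

#' Dual feature complementary block (DFCB) for skip fusion
#'
#' The encoder map (C channels) is reduced to C/2 by a 1x1 conv + BN + ReLU;
#' the upsampled decoder map (2C channels) is reduced to C/2 by a 1x1 conv and
#' passed through a channel softmax, which gates both reduced maps by
#' pixel-wise multiplication; the two gated maps are concatenated back to C
#' channels.
#'
#' @param channels the encoder-side channel count C (must be even).
#' @return An internal two-input network module whose `fwd` takes
#'   `list(enc = , dec = )` and whose `bwd` returns the same structure.
#' @keywords internal
nn_dfcb <- function(channels) {
  if (channels %% 2L != 0L)
    stop("invalid configuration: DFCB channel count must be even", call. = FALSE)
  half <- channels %/% 2L
  enc_path <- nn_sequential(nn_pwconv(channels, half), nn_bn_relu(half))
  dec_conv <- nn_pwconv(2L * channels, half)
  new_module("dfcb",
    fwd = function(self, x, train) {
      enc <- x$enc; dec <- x$dec
      if (!identical(enc$sp, dec$sp))
        stop("invalid configuration: DFCB inputs must share spatial dims", call. = FALSE)
      if (ncol(dec$m) != 2L * ncol(enc$m) || ncol(enc$m) != self$channels)
        stop("invalid configuration: DFCB expects encoder C and decoder 2C channels",
             call. = FALSE)
      fn1 <- m_fwd(self$children[[1]], enc, train)       # encoder path, C/2
      fi1 <- m_fwd(self$children[[2]], dec, train)       # decoder path, C/2
      fi2 <- cpp_row_softmax(fi1$m)                      # channel softmax gate
      self$cache$fn1 <- fn1$m
      self$cache$fi1 <- fi1$m
      self$cache$fi2 <- fi2
      ft(cpp_cbind_all(list(fn1$m * fi2, fi1$m * fi2)), enc$sp)
    },
    bwd = function(self, gy) {
      half <- ncol(gy$m) %/% 2L
      g1 <- gy$m[, seq_len(half), drop = FALSE]
      g2 <- gy$m[, half + seq_len(half), drop = FALSE]
      fn1 <- self$cache$fn1; fi1 <- self$cache$fi1; fi2 <- self$cache$fi2
      g_fn1 <- g1 * fi2
      g_fi2 <- g1 * fn1 + g2 * fi1
      g_fi1 <- chsoftmax_bwd(fi2, g_fi2) + g2 * fi2
      genc <- m_bwd(self$children[[1]], ft(g_fn1, gy$sp))
      gdec <- m_bwd(self$children[[2]], ft(g_fi1, gy$sp))
      list(enc = genc, dec = gdec)
    },
    children = list(enc_path, dec_conv),
    extra = list(channels = as.integer(channels)))
}

# ---- BIEB ------------------------------------------------------------------

# shared two-layer perceptron used by the channel-attention branch
mlp_fwd <- function(p, pars) {
  hpre <- p %*% pars$w1$value + rep(pars$b1$value, each = nrow(p))
  h <- pmax(hpre, 0)
  o <- h %*% pars$w2$value + rep(pars$b2$value, each = nrow(p))
  list(o = o, h = h, p = p)
}

mlp_bwd <- function(go, cache, pars) {
  param_add_grad(pars$w2, crossprod(cache$h, go))
  param_add_grad(pars$b2, colSums(go))
  gh <- tcrossprod(go, pars$w2$value) * (cache$h > 0)
  param_add_grad(pars$w1, crossprod(cache$p, gh))
  param_add_grad(pars$b1, colSums(gh))
  tcrossprod(gh, pars$w1$value)
}

#' BIEB channel-attention (upper) branch
#'
#' Global average and global max pooling compress the map to per-channel
#' scalars; a shared two-layer perceptron (channels -> channels/r -> channels,
#' ReLU between, biases on both layers) processes both, the outputs are summed
#' and squashed by a sigmoid into channel weights in (0, 1) which rescale the
#' input map.
#'
#' @param channels channel count of the bottleneck map.
#' @param reduction perceptron bottleneck ratio r (must be < `channels`).
#' @return An internal network module.
#' @keywords internal
nn_bieb_upper <- function(channels, reduction = 16L) {
  if (reduction >= channels)
    stop("invalid configuration: mlp_reduction must be smaller than the channel count",
         call. = FALSE)
  hidden <- max(1L, channels %/% reduction)
  params <- list(
    w1 = new_param(matrix(he_init(c(channels, hidden), fan_in = channels), channels, hidden)),
    b1 = new_param(numeric(hidden)),
    w2 = new_param(matrix(he_init(c(hidden, channels), fan_in = hidden), hidden, channels)),
    b2 = new_param(numeric(channels)))
  new_module("bieb_upper",
    fwd = function(self, x, train) {
      H <- x$sp[1L]; W <- x$sp[2L]; N <- x$sp[3L]; C <- ncol(x$m)
      HW <- H * W
      a3 <- array(x$m, c(HW, N, C))
      avg <- colMeans(a3)                     # N x C
      mx <- apply(a3, c(2L, 3L), max)
      widx <- apply(a3, c(2L, 3L), which.max) # hw index of the max, N x C
      fa <- mlp_fwd(avg, self$params)
      fm <- mlp_fwd(mx, self$params)
      z <- 1 / (1 + exp(-(fa$o + fm$o)))
      self$cache$x <- x
      self$cache$z <- z
      self$cache$fa <- fa
      self$cache$fm <- fm
      self$cache$widx <- widx
      ft(cpp_nc_scale(x$m, z, HW, N), x$sp)
    },
    bwd = function(self, gy) {
      x <- self$cache$x
      H <- x$sp[1L]; W <- x$sp[2L]; N <- x$sp[3L]; C <- ncol(x$m)
      HW <- H * W
      z <- self$cache$z
      gz <- cpp_nc_dot(x$m, gy$m, HW, N)
      gx <- cpp_nc_scale(gy$m, z, HW, N)
      gzpre <- gz * z * (1 - z)
      ga <- mlp_bwd(gzpre, self$cache$fa, self$params)
      gm <- mlp_bwd(gzpre, self$cache$fm, self$params)
      gx <- cpp_nc_add(gx, ga / HW, HW, N)
      widx <- self$cache$widx
      rows <- as.vector(widx) + HW * (as.vector(row(widx)) - 1L)
      ij <- cbind(rows, as.vector(col(widx)))
      gx[ij] <- gx[ij] + as.vector(gm)
      ft(gx, x$sp)
    },
    params = params)
}

#' BIEB residual (lower) branch
#'
#' Two depthwise-separable 3x3 convolutions with BN + ReLU, wired with
#' residual additions: `F~5 = ReLU(BN(conv(x)))`, `F~5-1 = F~5 + x`,
#' `F5-2 = ReLU(BN(conv(F~5-1)))`, output `= delta(F5-2) + F~5-1` where
#' `delta` is the adaptive per-channel weighting layer.
#'
#' @param channels channel count (preserved throughout).
#' @return An internal network module.
#' @keywords internal
nn_bieb_lower <- function(channels) {
  conv1 <- nn_sequential(nn_ds_conv(channels, channels, 3L), nn_bn_relu(channels))
  conv2 <- nn_sequential(nn_ds_conv(channels, channels, 3L), nn_bn_relu(channels))
  delta <- nn_chscale(channels)
  new_module("bieb_lower",
    fwd = function(self, x, train) {
      f5t <- m_fwd(self$children[[1]], x, train)
      f51 <- ft(f5t$m + x$m, x$sp)
      f52 <- m_fwd(self$children[[2]], f51, train)
      out <- ft(m_fwd(self$children[[3]], f52, train)$m + f51$m, x$sp)
      out
    },
    bwd = function(self, gy) {
      g_f52 <- m_bwd(self$children[[3]], gy)
      g_f51 <- ft(gy$m + m_bwd(self$children[[2]], g_f52)$m, gy$sp)
      gx <- m_bwd(self$children[[1]], g_f51)
      ft(gx$m + g_f51$m, gy$sp)
    },
    children = list(conv1, conv2, delta))
}

#' Bottleneck information enhancement block (BIEB)
#'
#' Pixel-wise sum of the channel-attention (upper) branch and the residual
#' double-conv (lower) branch. Either branch can be disabled for the ablation
#' variants, in which case the output is the enabled branch alone.
#' @keywords internal
nn_bieb <- function(channels, reduction = 16L, upper = TRUE, lower = TRUE) {
  if (!upper && !lower)
    stop("invalid configuration: BIEB requires at least one branch enabled", call. = FALSE)
  branches <- list()
  if (upper) branches <- c(branches, list(nn_bieb_upper(channels, reduction)))
  if (lower) branches <- c(branches, list(nn_bieb_lower(channels)))
  new_module("bieb",
    fwd = function(self, x, train) {
      ys <- lapply(self$children, m_fwd, x = x, train = train)
      out <- ys[[1]]$m
      if (length(ys) > 1L) for (i in 2:length(ys)) out <- out + ys[[i]]$m
      ft(out, x$sp)
    },
    bwd = function(self, gy) {
      gx <- NULL
      for (mod in self$children) {
        g <- m_bwd(mod, gy)
        gx <- if (is.null(gx)) g$m else gx + g$m
      }
      ft(gx, gy$sp)
    },
    children = branches)
}

# ---- CBAM drop-in ----------------------------------------------------------

# Minimal convolutional block attention: channel attention (same layout as the
# BIEB upper branch) followed by spatial attention (per-pixel channel mean and
# max -> 7x7 conv -> sigmoid gate).
nn_cbam <- function(channels, reduction = 16L) {
  chatt <- nn_bieb_upper(channels, reduction)
  sconv <- nn_conv(2L, 1L, 7L)
  new_module("cbam",
    fwd = function(self, x, train) {
      u <- m_fwd(self$children[[1]], x, train)
      rmax <- cpp_row_max(u$m)
      s2 <- ft(cbind(rowMeans(u$m), rmax$value), x$sp)
      spre <- m_fwd(self$children[[2]], s2, train)
      s <- 1 / (1 + exp(-spre$m))
      self$cache$u <- u
      self$cache$s <- as.vector(s)
      self$cache$maxidx <- rmax$idx
      ft(u$m * as.vector(s), x$sp)
    },
    bwd = function(self, gy) {
      u <- self$cache$u
      s <- self$cache$s
      C <- ncol(u$m)
      gs <- rowSums(u$m * gy$m)
      gu <- gy$m * s
      gspre <- gs * s * (1 - s)
      gs2 <- m_bwd(self$children[[2]], ft(matrix(gspre, ncol = 1L), gy$sp))
      gu <- gu + gs2$m[, 1L] / C
      ij <- cbind(seq_len(nrow(u$m)), self$cache$maxidx)
      gu[ij] <- gu[ij] + gs2$m[, 2L]
      m_bwd(self$children[[1]], ft(gu, gy$sp))
    },
    children = list(chatt, sconv))
}
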
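# Network configuration, assembly, forward/backward passes, prediction and
# parameter counting.

#' Network configuration for MDWC-Net and its ablation variants
#'
#' The default configuration is the full MDWC-Net: a five-level
#' encoder-decoder with one MSCAW block per level, encoder widths
#' 64/128/256/512 and a 1024-channel bottleneck, DFCB skip fusion, and the
#' full BIEB bottleneck block. Every ablation variant is reachable by
#' switching `multiscale_block`, `skip_fusion`, `bottleneck` and the block
#' flags (see [ablation_config()]).
#'
#' The dual feature complementary block consumes an encoder map with C
#' channels together with a decoder map with 2C channels, which forces the
#' encoder widths to double exactly at every level and the bottleneck to be
#' twice the deepest encoder width; `encoder_widths` is validated accordingly
#' when `skip_fusion = "dfcb"`.
#'
#' @param in_channels input image channels (1 for grayscale radiographs).
#' @param num_classes output classes (2: background / foreground).
#' @param encoder_widths channel widths of the four encoder levels; strictly
#'   increasing, each divisible by `length(kernel_set)` and by 2.
#' @param kernel_set odd kernel sizes of the multi-scale branches.
#' @param mlp_reduction channel-attention perceptron bottleneck ratio.
#' @param use_mscaw_weighting apply the adaptive weighting layer inside MSCAW.
#' @param use_bieb_upper,use_bieb_lower enable the BIEB branches.
#' @param skip_fusion `"dfcb"` or `"concat"` (plain U-Net style skip).
#' @param bottleneck `"bieb"`, `"plain"` (identity) or `"cbam"`.
#' @param multiscale_block `"mscaw"`, `"plain_conv"` (U-Net double conv) or
#'   `"aspp"`.
#' @param bn_eps,bn_momentum batch-normalisation epsilon and running-stat
#'   momentum (recorded in the config for reproducibility).
#' @return An object of class `mdwc_config` (a validated list).
#' @export
#' @examples
#' cfg <- network_config(encoder_widths = c(8, 16, 32, 64))
#' cfg$bottleneck_width
network_config <- function(in_channels = 1L,
                           num_classes = 2L,
                           encoder_widths = c(64L, 128L, 256L, 512L),
                           kernel_set = c(1L, 3L, 5L, 7L),
                           mlp_reduction = 16L,
                           use_mscaw_weighting = TRUE,
                           use_bieb_upper = TRUE,
                           use_bieb_lower = TRUE,
                           skip_fusion = c("dfcb", "concat"),
                           bottleneck = c("bieb", "plain", "cbam"),
                           multiscale_block = c("mscaw", "plain_conv", "aspp"),
                           bn_eps = 1e-5,
                           bn_momentum = 0.1) {
  skip_fusion <- match.arg(skip_fusion)
  bottleneck <- match.arg(bottleneck)
  multiscale_block <- match.arg(multiscale_block)
  encoder_widths <- as.integer(encoder_widths)
  kernel_set <- as.integer(kernel_set)
  stop_cfg <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (length(encoder_widths) != 4L) stop_cfg("encoder_widths must have 4 levels")
  if (any(diff(encoder_widths) <= 0L)) stop_cfg("encoder_widths must be strictly increasing")
  if (any(encoder_widths %% length(kernel_set) != 0L) || any(encoder_widths %% 2L != 0L))
    stop_cfg("encoder widths must be divisible by the branch count and by 2")
  if (any(kernel_set %% 2L == 0L)) stop_cfg("kernel sizes must be odd")
  if (skip_fusion == "dfcb" && any(diff(log2(encoder_widths)) != 1))
    stop_cfg("DFCB skip fusion requires encoder widths that double at every level")
  bottleneck_width <- 2L * encoder_widths[4L]
  if (bottleneck %in% c("bieb", "cbam") && mlp_reduction >= bottleneck_width)
    stop_cfg("mlp_reduction must be smaller than the bottleneck width")
  if (bottleneck == "bieb" && !use_bieb_upper && !use_bieb_lower)
    stop_cfg("BIEB bottleneck requires at least one branch enabled")
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              encoder_widths = encoder_widths,
              bottleneck_width = bottleneck_width,
              kernel_set = kernel_set,
              mlp_reduction = as.integer(mlp_reduction),
              use_mscaw_weighting = isTRUE(use_mscaw_weighting),
              use_bieb_upper = isTRUE(use_bieb_upper),
              use_bieb_lower = isTRUE(use_bieb_lower),
              use_dfcb = skip_fusion == "dfcb",
              skip_fusion = skip_fusion,
              bottleneck = bottleneck,
              multiscale_block = multiscale_block,
              bn_eps = bn_eps,
              bn_momentum = bn_momentum)
  class(cfg) <- "mdwc_config"
  cfg
}

#' @export
print.mdwc_config <- function(x, ...) {
  cat("MDWC-Net configuration\n")
  cat("  widths:", paste(c(x$encoder_widths, x$bottleneck_width), collapse = "-"),
      " kernels:", paste(x$kernel_set, collapse = "/"), "\n")
  cat("  multiscale:", x$multiscale_block,
      if (x$multiscale_block == "mscaw" && !x$use_mscaw_weighting) "(no weighting)" else "",
      " skip:", x$skip_fusion, " bottleneck:", x$bottleneck, "\n")
  invisible(x)
}

ms_block_factory <- function(cfg) {
  switch(cfg$multiscale_block,
    mscaw = function(in_ch, out_ch)
      nn_mscaw(in_ch, out_ch, cfg$kernel_set, weighting = cfg$use_mscaw_weighting),
    plain_conv = nn_plain_conv,
    aspp = nn_aspp)
}

#' Build an MDWC-Net from a configuration
#'
#' Assembles the five-level encoder-decoder: four encoder levels (one
#' multiscale block + 2x2 max-pool each), a bottleneck stage (multiscale
#' block expanding to the bottleneck width, then the configured bottleneck
#' enhancement block), four decoder levels (bilinear 2x upsampling, skip
#' fusion, one multiscale block) and a final 1x1 classifier convolution.
#'
#' @param cfg an [network_config()] object.
#' @param init_seed optional integer; when given, `set.seed(init_seed)` is
#'   called before weight initialisation so two builds are identical.
#' @return An object of class `mdwc_net`.
#' @export
#' @examples
#' net <- build_network(network_config(encoder_widths = c(8, 16, 32, 64)),
#'                      init_seed = 1)
#' count_parameters(net)
build_network <- function(cfg = network_config(), init_seed = NULL) {
  stopifnot(inherits(cfg, "mdwc_config"))
  if (!is.null(init_seed)) set.seed(init_seed)
  make_block <- ms_block_factory(cfg)
  w <- cfg$encoder_widths
  bw <- cfg$bottleneck_width
  in_chs <- c(cfg$in_channels, w[-4L])

  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$enc <- lapply(1:4, function(i) make_block(in_chs[i], w[i]))
  net$pools <- lapply(1:4, function(i) nn_maxpool2())
  net$bot_in <- make_block(w[4L], bw)
  net$bot <- switch(cfg$bottleneck,
    bieb = nn_bieb(bw, cfg$mlp_reduction, cfg$use_bieb_upper, cfg$use_bieb_lower),
    cbam = nn_cbam(bw, cfg$mlp_reduction),
    plain = nn_identity())
  net$ups <- lapply(1:4, function(i) nn_upsample2())
  if (cfg$skip_fusion == "dfcb") {
    net$fus <- lapply(1:4, function(i) nn_dfcb(w[i]))
    net$dec <- lapply(1:4, function(i) make_block(w[i], w[i]))
  } else {
    net$fus <- lapply(1:4, function(i) nn_pwconv(2L * w[i], w[i]))  # halving conv
    net$dec <- lapply(1:4, function(i) make_block(2L * w[i], w[i]))
  }
  net$cls <- nn_pwconv(w[1L], cfg$num_classes, bias = TRUE)
  class(net) <- "mdwc_net"
  net
}

net_modules <- function(net) {
  c(net$enc, net$pools, list(net$bot_in, net$bot), net$ups, net$fus, net$dec,
    list(net$cls))
}

#' Collect all trainable parameter slots of a network
#' @param net an `mdwc_net`.
#' @return List of parameter environments (value/grad/momentum).
#' @keywords internal
net_params <- function(net) {
  out <- list()
  for (m in net_modules(net)) out <- c(out, module_params(m))
  out
}

#' Count trainable parameters
#'
#' Exact enumeration of every learnable scalar: convolution filters, batch
#' normalisation affine terms, perceptron weights and biases, adaptive
#' weights, and the classifier bias. Invariant to input size.
#'
#' @param net an `mdwc_net`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "mdwc_net"))
  n_param_scalars(net_params(net))
}

#' @export
print.mdwc_net <- function(x, ...) {
  cat("<mdwc_net> ", format(count_parameters(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  print(x$cfg)
  invisible(x)
}

as_ftens <- function(x, in_channels = NULL) {
  if (is.list(x) && !is.null(x$m)) return(x)
  if (is.matrix(x)) x <- array(x, c(1L, 1L, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 4L)
  ft_from_array(x)
}

#' Run the network forward
#'
#' @param net an `mdwc_net`.
#' @param x input: an `N x C x H x W` array (or an `H x W` matrix, treated as
#'   a single grayscale image). H and W must be divisible by 16.
#' @param train logical; training mode (batch statistics) vs evaluation mode
#'   (running statistics) for batch normalisation.
#' @return Logits as an `N x num_classes x H x W` array.
#' @export
net_forward <- function(net, x, train = FALSE) {
  ft_as_array(net_forward_ft(net, as_ftens(x), train))
}

net_forward_ft <- function(net, x, train = TRUE) {
  cfg <- net$cfg
  if (ncol(x$m) != cfg$in_channels)
    stop("invalid input: expected ", cfg$in_channels, " input channels", call. = FALSE)
  if (x$sp[1L] %% 16L != 0L || x$sp[2L] %% 16L != 0L)
    stop("invalid input: spatial dims must be divisible by 16", call. = FALSE)
  skips <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    e <- m_fwd(net$enc[[i]], h, train)
    skips[[i]] <- e
    h <- m_fwd(net$pools[[i]], e, train)
  }
  h <- m_fwd(net$bot_in, h, train)
  h <- m_fwd(net$bot, h, train)
  for (i in 4:1) {
    u <- m_fwd(net$ups[[i]], h, train)
    if (cfg$skip_fusion == "dfcb") {
      h <- m_fwd(net$fus[[i]], list(enc = skips[[i]], dec = u), train)
    } else {
      uh <- m_fwd(net$fus[[i]], u, train)
      h <- ft(cpp_cbind_all(list(skips[[i]]$m, uh$m)), uh$sp)
    }
    h <- m_fwd(net$dec[[i]], h, train)
  }
  m_fwd(net$cls, h, train)
}

net_backward_ft <- function(net, glogits) {
  cfg <- net$cfg
  g <- m_bwd(net$cls, glogits)
  gskips <- vector("list", 4L)
  for (i in 1:4) {
    g <- m_bwd(net$dec[[i]], g)
    if (cfg$skip_fusion == "dfcb") {
      r <- m_bwd(net$fus[[i]], g)
      gskips[[i]] <- r$enc
      gu <- r$dec
    } else {
      C <- ncol(g$m) %/% 2L
      gskips[[i]] <- ft(g$m[, seq_len(C), drop = FALSE], g$sp)
      gu <- m_bwd(net$fus[[i]], ft(g$m[, C + seq_len(C), drop = FALSE], g$sp))
    }
    g <- m_bwd(net$ups[[i]], gu)
  }
  g <- m_bwd(net$bot, g)
  g <- m_bwd(net$bot_in, g)
  for (i in 4:1) {
    g <- m_bwd(net$pools[[i]], g)
    g <- ft(g$m + gskips[[i]]$m, g$sp)
    g <- m_bwd(net$enc[[i]], g)
  }
  g
}

#' Predict a segmentation mask
#'
#' Runs the network in evaluation mode and takes the per-pixel argmax over
#' the class logits; ties are broken toward the lowest class index.
#'
#' @param net a trained `mdwc_net`.
#' @param image an `H x W` matrix in `[0, 1]` (or an `N x C x H x W` array).
#' @return An integer `H x W` mask (or `N x H x W` array for batched input).
#' @export
net_predict <- function(net, image) {
  single <- is.matrix(image)
  x <- as_ftens(image)
  logits <- net_forward_ft(net, x, train = FALSE)
  cls <- max.col(logits$m, ties.method = "first") - 1L
  H <- logits$sp[1L]; W <- logits$sp[2L]; N <- logits$sp[3L]
  a <- array(cls, c(H, W, N))
  if (single) matrix(a[, , 1L], H, W) else aperm(a, c(3L, 1L, 2L))
}

# ---- functional forms of the primitive ops (array in / array out) ----------

#' Depthwise separable convolution (functional form)
#'
#' Channel-wise `k x k` convolution followed by a pointwise 1x1 cross-channel
#' convolution, both bias-free, with "same" zero padding.
#'
#' @param x `N x C x H x W` array.
#' @param depthwise `k x k x C` array of per-channel filters.
#' @param pointwise `C x out_channels` matrix.
#' @return `N x out_channels x H x W` array.
#' @export
#' @examples
#' x <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
#' dw <- array(0, c(3, 3, 2)); dw[2, 2, ] <- 1  # identity depthwise filter
#' y <- depthwise_separable_conv(x, dw, diag(2))
#' all.equal(y, x)
depthwise_separable_conv <- function(x, depthwise, pointwise) {
  k <- dim(depthwise)[1L]
  if (k %% 2L == 0L) stop("invalid configuration: kernel size must be odd", call. = FALSE)
  stopifnot(dim(depthwise)[2L] == k, dim(depthwise)[3L] == dim(x)[2L],
            nrow(pointwise) == dim(x)[2L])
  xt <- ft_from_array(x)
  h <- cpp_dwconv_fwd(xt$m, matrix(depthwise, k * k, dim(x)[2L]),
                      xt$sp[1L], xt$sp[2L], xt$sp[3L], k)
  ft_as_array(ft(h %*% pointwise, xt$sp))
}

#' Apply adaptive per-channel weights (functional form)
#'
#' Output channel n equals `w[n]` times input channel n.
#'
#' @param x `N x C x H x W` array.
#' @param w numeric vector of length C.
#' @return Array of the same shape as `x`.
#' @export
adaptive_weight_apply <- function(x, w) {
  if (length(w) != dim(x)[2L])
    stop("invalid configuration: weight length must equal channel count", call. = FALSE)
  xt <- ft_from_array(x)
  ft_as_array(ft(cpp_col_scale_r(xt$m, w), xt$sp))
}

#' Channel softmax (functional form)
#'
#' At every pixel, softmax across the channel dimension (numerically
#' stabilised by max subtraction): outputs are positive and sum to 1 over
#' channels.
#'
#' @param x `N x C x H x W` array.
#' @return Array of the same shape.
#' @export
channel_softmax <- function(x) {
  xt <- ft_from_array(x)
  ft_as_array(ft(cpp_row_softmax(xt$m), xt$sp))
}
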
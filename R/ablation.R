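# Ablation variants: every row of the component-ablation study is reachable
# through a named configuration.

ablation_table <- list(
  baseline            = list(multiscale_block = "plain_conv", skip_fusion = "concat",
                             bottleneck = "plain"),
  multiscale_conv_only = list(multiscale_block = "mscaw", use_mscaw_weighting = FALSE,
                             skip_fusion = "concat", bottleneck = "plain"),
  mscaw_only          = list(multiscale_block = "mscaw", skip_fusion = "concat",
                             bottleneck = "plain"),
  mscaw_bieb_upper    = list(multiscale_block = "mscaw", skip_fusion = "concat",
                             bottleneck = "bieb", use_bieb_lower = FALSE),
  mscaw_bieb_lower    = list(multiscale_block = "mscaw", skip_fusion = "concat",
                             bottleneck = "bieb", use_bieb_upper = FALSE),
  mscaw_bieb_full     = list(multiscale_block = "mscaw", skip_fusion = "concat",
                             bottleneck = "bieb"),
  mscaw_dfcb          = list(multiscale_block = "mscaw", skip_fusion = "dfcb",
                             bottleneck = "plain"),
  full                = list(multiscale_block = "mscaw", skip_fusion = "dfcb",
                             bottleneck = "bieb"),
  w_aspp              = list(multiscale_block = "aspp", skip_fusion = "dfcb",
                             bottleneck = "bieb"),
  w_cbam              = list(multiscale_block = "mscaw", skip_fusion = "dfcb",
                             bottleneck = "cbam"))

#' Named ablation variants of the network
#'
#' `ablation_names()` lists the available variants; `ablation_config()`
#' returns the corresponding [network_config()]. `"baseline"` is the
#' U-Net-shaped reference (plain double convs, concatenation skips, plain
#' bottleneck); `"full"` is the complete MDWC-Net; `"w_aspp"` / `"w_cbam"`
#' swap the multiscale block for ASPP and the bottleneck block for CBAM.
#'
#' @param name one of `ablation_names()`.
#' @param ... further arguments passed to [network_config()] (e.g. smaller
#'   `encoder_widths` for quick experiments).
#' @return A `mdwc_config`.
#' @export
#' @examples
#' ablation_names()
#' ablation_config("mscaw_only", encoder_widths = c(8, 16, 32, 64))
ablation_config <- function(name, ...) {
  if (!name %in% names(ablation_table))
    stop("invalid configuration: unknown ablation variant '", name, "'", call. = FALSE)
  do.call(network_config, utils::modifyList(ablation_table[[name]], list(...)))
}

#' @rdname ablation_config
#' @export
ablation_names <- function() names(ablation_table)
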
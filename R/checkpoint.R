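# Checkpointing: a single serialized state file plus a sidecar JSON with the
# network configuration, so a checkpoint can be loaded without re-stating the
# config.

module_walk <- function(m, fn, acc = list()) {
  acc <- fn(m, acc)
  for (ch in m$children) acc <- module_walk(ch, fn, acc)
  acc
}

# batch-norm running statistics in stable (module-tree) order
snapshot_bn <- function(net) {
  out <- list()
  for (m in net_modules(net)) {
    out <- c(out, module_walk(m, function(mod, acc) {
      if (inherits(mod, "nn_bn"))
        acc <- c(acc, list(list(mean = mod$running_mean, var = mod$running_var)))
      acc
    }))
  }
  out
}

restore_bn <- function(net, snaps) {
  i <- 0L
  for (m in net_modules(net)) {
    module_walk(m, function(mod, acc) {
      if (inherits(mod, "nn_bn")) {
        i <<- i + 1L
        mod$running_mean <- snaps[[i]]$mean
        mod$running_var <- snaps[[i]]$var
      }
      acc
    })
  }
  invisible(NULL)
}

cfg_as_plain_list <- function(cfg) {
  keep <- c("in_channels", "num_classes", "encoder_widths", "kernel_set",
            "mlp_reduction", "use_mscaw_weighting", "use_bieb_upper",
            "use_bieb_lower", "skip_fusion", "bottleneck", "multiscale_block",
            "bn_eps", "bn_momentum")
  unclass(cfg)[keep]
}

cfg_from_plain_list <- function(l) do.call(network_config, l)

#' Save / load a network checkpoint
#'
#' `save_checkpoint()` writes the parameter values and batch-norm running
#' statistics to `<path>` (RDS) and the producing configuration to
#' `<path>.json`; `load_checkpoint()` rebuilds the network from the sidecar
#' config and restores the state exactly.
#'
#' @param net an `mdwc_net`.
#' @param path checkpoint file path (the JSON sidecar gets a `.json` suffix).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored `mdwc_net`.
#' @export
save_checkpoint <- function(net, path) {
  state <- list(config = cfg_as_plain_list(net$cfg),
                params = lapply(net_params(net), function(p) p$value),
                bn = snapshot_bn(net))
  saveRDS(state, path)
  jsonlite::write_json(state$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  net <- build_network(cfg_from_plain_list(state$config))
  params <- net_params(net)
  if (length(params) != length(state$params))
    stop("invalid input: checkpoint does not match the rebuilt network", call. = FALSE)
  for (i in seq_along(params)) params[[i]]$value <- state$params[[i]]
  restore_bn(net, state$bn)
  net
}
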
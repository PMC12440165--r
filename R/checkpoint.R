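# Checkpointing: a single serialized weight dictionary with a version tag,
# plus a YAML sidecar holding the configuration in readable form.

ckpt_version <- "asgbc-checkpoint-1"

# order-stable polynomial hash of a config list serialized to YAML
config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save a training checkpoint
#'
#' Writes the weight dictionary (backbone, expander, prototypes, optimizer
#' state, iteration counter, config hash, seed) to `path` and the
#' configuration as YAML next to it (`<path>.yaml`).
#'
#' @param ckpt A checkpoint list as returned by [pretrain_extractor()].
#' @param path Output file (conventionally `.rds`).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(identical(ckpt$version, ckpt_version))
  saveRDS(ckpt, path)
  yaml::write_yaml(ckpt$config, paste0(path, ".yaml"))
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The checkpoint list; forward passes through the rebuilt extractor
#'   reproduce the saved model bit for bit.
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!identical(ckpt$version, ckpt_version))
    stop("unrecognized checkpoint version: ", ckpt$version)
  ckpt
}

# overwrite the values of a parameter tree with stored plain arrays;
# traversal is positional so unnamed list levels (e.g. stage/block lists)
# are covered too
assign_weights <- function(params, weights) {
  if (is.list(params) && !is_ad(params)) {
    stopifnot(length(params) == length(weights))
    for (i in seq_along(params)) assign_weights(params[[i]], weights[[i]])
    return(invisible(NULL))
  }
  params$val <- weights
  invisible(NULL)
}

#' Rebuild a feature extractor from checkpoint weights
#'
#' @param ckpt A checkpoint list.
#' @return An `asgbc_extractor` with the stored weights.
#' @export
extractor_from_checkpoint <- function(ckpt) {
  fx <- withr::with_seed(0L, build_feature_extractor(do.call(backbone_config,
                                                             ckpt$config$backbone)))
  assign_weights(fx$params, ckpt$backbone_weights)
  fx
}
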
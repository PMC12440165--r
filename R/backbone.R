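# Residual convolutional feature extractors with optional MsHop blocks.
#
# Three profiles are provided. `micro` is a four-stage residual network sized
# for 64x64 grayscale inputs and a single CPU core; `resnet18` and `resnet50`
# follow the standard basic-block / bottleneck layouts. MsHop blocks are
# inserted after the residual stages listed in `mshop_stages` (default: after
# stages 2 and 3, where covariance pooling sees mid-level texture). Random
# initialization is the default; ImageNet-pretrained weights are not bundled
# and requesting them raises an explicit error.

#' Backbone configuration
#'
#' @param architecture One of `"micro"`, `"resnet18"`, `"resnet50"`.
#' @param mshop_stages Integer vector of residual-stage indices after which an
#'   MsHop block is inserted; `integer(0)` disables MsHop (the ablation
#'   baseline).
#' @param input_size Input image side length in pixels.
#' @param in_channels Number of input channels (1 for B-mode ultrasound;
#'   single-channel input is replicated if a 3-channel stem is configured).
#' @param pretrained_init Must be `FALSE` in this package: no weight download
#'   is ever required. `TRUE` raises an error instructing offline mode.
#' @param embed_dim Output embedding dimension of the extractor.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(architecture = c("micro", "resnet18", "resnet50"),
                            mshop_stages = c(2L, 3L), input_size = 64L,
                            in_channels = 1L, pretrained_init = FALSE,
                            embed_dim = 64L) {
  architecture <- match.arg(architecture)
  structure(list(architecture = architecture,
                 mshop_stages = as.integer(mshop_stages),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 pretrained_init = isTRUE(pretrained_init),
                 embed_dim = as.integer(embed_dim)),
            class = "backbone_config")
}

arch_plan <- function(architecture) {
  switch(architecture,
    micro = list(stem = list(ch = 8L, k = 3L, stride = 2L),
                 gap_stages = c(2L, 3L),   # pooled features: mid + high level
                 stages = list(
                   list(ch = 16L, stride = 2L, blocks = 1L, type = "basic"),
                   list(ch = 32L, stride = 2L, blocks = 1L, type = "basic"),
                   list(ch = 32L, stride = 2L, blocks = 1L, type = "basic"))),
    resnet18 = list(stem = list(ch = 64L, k = 7L, stride = 4L),
                    stages = list(
                      list(ch = 64L,  stride = 1L, blocks = 2L, type = "basic"),
                      list(ch = 128L, stride = 2L, blocks = 2L, type = "basic"),
                      list(ch = 256L, stride = 2L, blocks = 2L, type = "basic"),
                      list(ch = 512L, stride = 2L, blocks = 2L, type = "basic"))),
    resnet50 = list(stem = list(ch = 64L, k = 7L, stride = 4L),
                    stages = list(
                      list(ch = 256L,  stride = 1L, blocks = 3L, type = "bottleneck"),
                      list(ch = 512L,  stride = 2L, blocks = 4L, type = "bottleneck"),
                      list(ch = 1024L, stride = 2L, blocks = 6L, type = "bottleneck"),
                      list(ch = 2048L, stride = 2L, blocks = 3L, type = "bottleneck"))),
    stop("unknown architecture"))
}

init_block <- function(cin, cout, stride, type) {
  # the last convolution of each residual branch starts near zero so every
  # block is approximately the identity at initialization (keeps activation
  # scale bounded without normalization layers)
  if (type == "basic") {
    w <- list(w1 = init_conv(3, 3, cin, cout), b1 = numeric(cout),
              w2 = 0.1 * init_conv(3, 3, cout, cout), b2 = numeric(cout))
  } else {
    mid <- cout %/% 4L
    w <- list(w1 = init_conv(1, 1, cin, mid), b1 = numeric(mid),
              w2 = init_conv(3, 3, mid, mid), b2 = numeric(mid),
              w3 = 0.1 * init_conv(1, 1, mid, cout), b3 = numeric(cout))
  }
  if (stride != 1L || cin != cout) {
    w$skip_w <- init_conv(1, 1, cin, cout)
    w$skip_b <- numeric(cout)
  }
  w
}

g_block <- function(x, w, stride, type) {
  if (type == "basic") {
    h <- ad_relu(ad_conv2d(x, w$w1, w$b1, stride = stride, pad = 1L))
    h <- ad_conv2d(h, w$w2, w$b2, stride = 1L, pad = 1L)
  } else {
    h <- ad_relu(ad_conv2d(x, w$w1, w$b1, stride = 1L, pad = 0L))
    h <- ad_relu(ad_conv2d(h, w$w2, w$b2, stride = stride, pad = 1L))
    h <- ad_conv2d(h, w$w3, w$b3, stride = 1L, pad = 0L)
  }
  skip <- if (!is.null(w$skip_w))
    ad_conv2d(x, w$skip_w, w$skip_b, stride = stride, pad = 0L) else x
  ad_relu(ad_add(h, skip))
}

#' Build a feature extractor
#'
#' Constructs the residual backbone described by `cfg`, with MsHop blocks
#' inserted after the configured stages, and a global-average-pool plus linear
#' projection head mapping to `embed_dim`. Weights are drawn from the current
#' RNG state; call inside a seeded context for reproducibility.
#'
#' @param cfg A [backbone_config()].
#' @return An object of class `asgbc_extractor` holding the configuration,
#'   the per-stage shapes and the parameter tree.
#' @export
build_feature_extractor <- function(cfg) {
  if (cfg$pretrained_init)
    stop("pretrained weights are not bundled; run with pretrained_init = FALSE ",
         "(offline random initialization)")
  plan <- arch_plan(cfg$architecture)
  size <- cfg$input_size
  stem_pad <- (plan$stem$k - 1L) %/% 2L
  size <- (size + 2L * stem_pad - plan$stem$k) %/% plan$stem$stride + 1L
  params <- list(stem = list(w = init_conv(plan$stem$k, plan$stem$k,
                                           cfg$in_channels, plan$stem$ch),
                             b = numeric(plan$stem$ch)),
                 stages = list(), mshop = list())
  mshop_cfgs <- list()
  cin <- plan$stem$ch
  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    blocks <- list()
    for (b in seq_len(st$blocks)) {
      stride <- if (b == 1L) st$stride else 1L
      blocks[[b]] <- init_block(cin, st$ch, stride, st$type)
      cin <- st$ch
    }
    size <- (size + 2L - 3L) %/% st$stride + 1L  # the same-padded strided 3x3 sets the size
    params$stages[[i]] <- blocks
    if (i %in% cfg$mshop_stages) {
      mcfg <- mshop_config(H = size, W = size, D = st$ch)
      mshop_cfgs[[as.character(i)]] <- mcfg
      params$mshop[[as.character(i)]] <- mshop_init(mcfg)
    }
  }
  gap_stages <- plan$gap_stages
  if (is.null(gap_stages)) gap_stages <- length(plan$stages)
  gap_dim <- sum(vapply(gap_stages,
                        function(i) plan$stages[[i]]$ch, integer(1)))
  params$proj <- list(W = init_linear(gap_dim, cfg$embed_dim),
                      b = numeric(cfg$embed_dim))
  structure(list(cfg = cfg, plan = plan, mshop_cfgs = mshop_cfgs,
                 params = params_from_weights(params), frozen = FALSE),
            class = "asgbc_extractor")
}

#' @export
print.asgbc_extractor <- function(x, ...) {
  np <- length(param_vector(x$params))
  cat(sprintf("<asgbc_extractor> %s, input %dpx, embed_dim %d, MsHop after stages {%s}, %d parameters%s\n",
              x$cfg$architecture, x$cfg$input_size, x$cfg$embed_dim,
              paste(x$cfg$mshop_stages, collapse = ","), np,
              if (x$frozen) " (frozen)" else ""))
  invisible(x)
}

# forward graph; x is an (H, W, C, N) node
g_extractor <- function(fx, x) {
  plan <- fx$plan
  p <- fx$params
  stem_pad <- (plan$stem$k - 1L) %/% 2L
  h <- ad_relu(ad_conv2d(x, p$stem$w, p$stem$b,
                         stride = plan$stem$stride, pad = stem_pad))
  gap_stages <- plan$gap_stages
  if (is.null(gap_stages)) gap_stages <- length(plan$stages)
  gaps <- list()
  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    for (b in seq_along(p$stages[[i]])) {
      stride <- if (b == 1L) st$stride else 1L
      h <- g_block(h, p$stages[[i]][[b]], stride, st$type)
    }
    mk <- as.character(i)
    if (!is.null(p$mshop[[mk]])) h <- g_mshop_block(h, p$mshop[[mk]])
    if (i %in% gap_stages) gaps[[length(gaps) + 1L]] <- ad_gap(h)
  }
  pooled <- if (length(gaps) == 1L) gaps[[1L]] else ad_cbind(gaps)
  ad_add_rowvec(ad_matmul(pooled, p$proj$W), p$proj$b)
}

# images: (H, W, N) or (H, W, C, N) plain array -> (H, W, C, N) with channel
# replication if the stem expects more channels than provided
prep_images <- function(images, in_channels) {
  d <- dim(images)
  if (length(d) == 3L) {
    dim(images) <- c(d[1], d[2], 1L, d[3])
    d <- dim(images)
  }
  if (d[3] == 1L && in_channels > 1L)
    images <- images[, , rep(1L, in_channels), , drop = FALSE]
  images
}

#' Embed a batch of images
#'
#' Runs the extractor forward (no gradients) and returns the embedding matrix.
#' Large batches are processed in chunks to bound memory.
#'
#' @param fx An `asgbc_extractor`.
#' @param images Array `(H, W, N)` or `(H, W, C, N)` of images in `[0, 1]`.
#' @param chunk Samples per forward chunk.
#' @return Numeric matrix `N x embed_dim`.
#' @export
extractor_forward <- function(fx, images, chunk = 64L) {
  images <- prep_images(images, fx$cfg$in_channels)
  N <- dim(images)[4]
  out <- matrix(0, N, fx$cfg$embed_dim)
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(N, s + chunk - 1L)
    xb <- images[, , , idx, drop = FALSE]
    out[idx, ] <- ad_value(g_extractor(fx, ad_const(xb)))
  }
  out
}

#' Freeze the extractor
#'
#' Marks the backbone as frozen; downstream training (the linear probe) will
#' not touch its parameters.
#'
#' @param fx An `asgbc_extractor`.
#' @return The extractor with the frozen flag set.
#' @export
extractor_freeze <- function(fx) {
  fx$frozen <- TRUE
  fx
}
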
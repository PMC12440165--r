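# The multi-scale high-order pooling (MsHop) block.
#
# A feature map F of size H x W x D (axis 1 = height, axis 2 = width,
# axis 3 = channels) is first passed through a hierarchical multi-scale
# stage: the channels are split into four groups, each group goes through its
# own 3x3 convolution, and from the second group onward the previous group's
# output is added to the input before convolving. The four outputs are
# concatenated and fused by a 1x1 convolution into F'. Three 1x1 reductions
# then shrink one axis each (channels to D', width to W', height to H'); the
# covariance matrix of the reduced features is computed along each axis, a
# row-wise convolution plus an affine map plus a sigmoid turns each covariance
# matrix into a statistical weight vector, and the three rescaled copies of F'
# are summed, fused by a final 1x1 convolution and added back to F as a
# residual.
#
# Public functions operate on a single H x W x D array; training uses the same
# graph builders on batched (H, W, D, N) tensors, so per-sample and batched
# paths cannot drift apart. Covariances are always per-sample: batch
# statistics are never mixed inside the block.

#' MsHop block configuration
#'
#' Reduction sizes and kernel settings for a multi-scale high-order pooling
#' block attached to feature maps of size `H x W x D`. Defaults follow the
#' package convention `W' = ceiling(W/2)`, `H' = ceiling(H/2)`,
#' `D' = ceiling(D/4)`; the only hard requirement is that each reduced size is
#' strictly smaller than the original and at least 2 (a covariance over fewer
#' than two variables is not meaningful).
#'
#' @param H,W,D Feature-map height, width and channel count the block is
#'   attached to.
#' @param H_red,W_red,D_red Reduced sizes; defaults as above.
#' @param rowconv_kernel Odd length of the 1-D kernel convolved along each row
#'   of a covariance matrix when forming the attention vectors.
#' @param groups Number of channel groups in the multi-scale split (fixed 4).
#' @return A list of class `mshop_config`.
#' @export
mshop_config <- function(H, W, D,
                         H_red = ceiling(H / 2), W_red = ceiling(W / 2),
                         D_red = max(2L, ceiling(D / 4)),
                         rowconv_kernel = 3L, groups = 4L) {
  if (groups != 4L) stop("mshop_config: the multi-scale split uses exactly 4 groups")
  if (D %% 4L != 0L) stop("mshop_config: channel count must be divisible by 4")
  if (!(W_red < W && H_red < H && D_red < D))
    stop("mshop_config: reduced sizes must be strictly smaller than the original")
  if (min(W_red, H_red, D_red) < 2L)
    stop("mshop_config: reduced sizes below 2 leave the covariance undefined")
  if (rowconv_kernel %% 2L != 1L) stop("mshop_config: rowconv_kernel must be odd")
  structure(list(H = as.integer(H), W = as.integer(W), D = as.integer(D),
                 H_red = as.integer(H_red), W_red = as.integer(W_red),
                 D_red = as.integer(D_red),
                 rowconv_kernel = as.integer(rowconv_kernel), groups = 4L),
            class = "mshop_config")
}

#' Initialize MsHop weights
#'
#' Draws a fresh weight set for one MsHop block. Uses the RNG; seed outside
#' for reproducibility.
#'
#' @param cfg An [mshop_config()].
#' @return Nested list of plain arrays (the checkpoint form).
#' @export
mshop_init <- function(cfg) {
  g <- cfg$D / 4L
  k <- cfg$rowconv_kernel
  att_init <- function(side, target) {
    list(kern = stats::rnorm(k, sd = 1 / sqrt(k)),
         A = matrix(stats::rnorm(side * target, sd = 1 / sqrt(side)), target, side),
         b = numeric(target))
  }
  list(
    ms = list(k1 = init_conv(3, 3, g, g), b1 = numeric(g),
              k2 = init_conv(3, 3, g, g), b2 = numeric(g),
              k3 = init_conv(3, 3, g, g), b3 = numeric(g),
              k4 = init_conv(3, 3, g, g), b4 = numeric(g),
              fuse = init_conv(1, 1, cfg$D, cfg$D), fuse_b = numeric(cfg$D)),
    red = list(W = init_conv(1, 1, cfg$W, cfg$W_red), W_b = numeric(cfg$W_red),
               H = init_conv(1, 1, cfg$H, cfg$H_red), H_b = numeric(cfg$H_red),
               D = init_conv(1, 1, cfg$D, cfg$D_red), D_b = numeric(cfg$D_red)),
    att = list(W = att_init(cfg$W_red, cfg$W),
               H = att_init(cfg$H_red, cfg$H),
               D = att_init(cfg$D_red, cfg$D)),
    # near-zero fusion start: the block opens as an identity residual
    out = list(fuse = 0.1 * init_conv(1, 1, cfg$D, cfg$D), fuse_b = numeric(cfg$D))
  )
}

# ---- custom op: same-padded 1-D convolution along each row -----------------

# R[i, ] = sum_t kern[t] * C[i, j + t - off], off = (r+1)/2, zero padded.
# Equivalent to C %*% T with banded Toeplitz T[c, j] = kern[c - j + off].
rowconv_toeplitz <- function(kern, kside) {
  r <- length(kern)
  off <- (r + 1L) / 2L
  Tm <- matrix(0, kside, kside)
  for (j in seq_len(kside)) {
    for (t in seq_len(r)) {
      c <- j + t - off
      if (c >= 1 && c <= kside) Tm[c, j] <- kern[t]
    }
  }
  Tm
}

ad_rowconv <- function(C, kern) {
  C <- as_ad(C); kern <- as_ad(kern)
  kside <- ncol(C$val)
  r <- length(kern$val)
  off <- (r + 1L) / 2L
  Tm <- rowconv_toeplitz(as.numeric(kern$val), kside)
  Cv <- C$val
  ad_node(Cv %*% Tm, list(C, kern), function(g) {
    dC <- g %*% t(Tm)
    dT <- t(Cv) %*% g
    dk <- numeric(r)
    for (j in seq_len(kside)) {
      for (t in seq_len(r)) {
        c <- j + t - off
        if (c >= 1 && c <= kside) dk[t] <- dk[t] + dT[c, j]
      }
    }
    list(dC, dk)
  })
}

# ---- graph builders (batched; x is an (H, W, D, N) node) -------------------

g_hierarchical_multiscale <- function(x, w) {
  D <- dim(ad_value(x))[3]
  g <- D / 4L
  s_prev <- NULL
  outs <- vector("list", 4L)
  for (i in 1:4) {
    Fi <- ad_slice_c(x, ((i - 1L) * g + 1L):(i * g))
    inp <- if (i == 1L) Fi else ad_add(Fi, s_prev)
    s_prev <- ad_conv2d(inp, w$ms[[paste0("k", i)]], w$ms[[paste0("b", i)]],
                        stride = 1L, pad = 1L)
    outs[[i]] <- s_prev
  }
  ad_conv2d(ad_concat_c(outs), w$ms$fuse, w$ms$fuse_b, stride = 1L, pad = 0L)
}

# sample covariance of an m x k observation-matrix node, divisor m - 1
g_cov <- function(X) {
  m <- nrow(ad_value(X))
  mu <- ad_smul(ad_matmul(ad_const(matrix(1, 1, m)), X), 1 / m)
  Xc <- ad_sub(X, ad_matmul(ad_const(matrix(1, m, 1)), mu))
  ad_smul(ad_matmul(ad_aperm(Xc, c(2, 1)), Xc), 1 / (m - 1))
}

# attention vector from one covariance-matrix node
g_cov_attention <- function(C, att) {
  k <- ncol(ad_value(C))
  R <- ad_rowconv(C, att$kern)
  v <- ad_smul(ad_matmul(R, ad_const(matrix(1, k, 1))), 1 / k)   # row means
  ad_sigmoid(ad_add(ad_matmul(att$A, v), ad_reshape(att$b, c(length(ad_value(att$b)), 1))))
}

# reduced tensor for one direction; axis_perm moves the reduced axis into the
# channel slot of the conv
g_reduce <- function(x, perm, wred, bred) {
  xp <- if (is.null(perm)) x else ad_aperm(x, perm)
  ad_conv2d(xp, wred, bred, stride = 1L, pad = 0L)
}

# ---- fused batched ops (training fast path) --------------------------------
# Per-sample covariance over the third axis: (a, b, k, N) -> (k, k, N).
ad_batch_cov <- function(x) {
  x <- as_ad(x)
  d <- dim(x$val)
  m <- d[1] * d[2]; k <- d[3]; N <- d[4]
  xv <- x$val
  dim(xv) <- c(m, k, N)
  out <- array(0, c(k, k, N))
  xc <- xv
  for (n in seq_len(N)) {
    X <- xv[, , n]
    Xc <- X - rep(colMeans(X), each = m)
    xc[, , n] <- Xc
    out[, , n] <- crossprod(Xc) / (m - 1)
  }
  ad_node(out, list(x), function(g) {
    dim(g) <- c(k, k, N)
    dx <- xc
    for (n in seq_len(N)) {
      S <- (g[, , n] + t(g[, , n])) / (m - 1)
      dXc <- xc[, , n] %*% S
      dx[, , n] <- dXc - rep(colMeans(dXc), each = m)
    }
    dim(dx) <- d
    list(dx)
  })
}

# Batched covariance attention: row-conv + row-mean collapses to a single
# matrix-vector product C_n %*% (T %*% 1 / k); then affine + sigmoid.
# C3: (k, k, N) node -> (target, N).
ad_batch_att <- function(C3, kern, A, b) {
  C3 <- as_ad(C3); kern <- as_ad(kern); A <- as_ad(A); b <- as_ad(b)
  d <- dim(C3$val)
  k <- d[1]; N <- d[3]
  r <- length(kern$val)
  # w = T(kern) %*% 1/k is linear in kern: w = Mk %*% kern
  Mk <- matrix(0, k, r)
  off <- (r + 1L) / 2L
  for (j in seq_len(k)) for (t in seq_len(r)) {
    c <- j + t - off
    if (c >= 1 && c <= k) Mk[c, t] <- Mk[c, t] + 1 / k
  }
  wv <- as.vector(Mk %*% as.numeric(kern$val))
  Cm <- C3$val
  dim(Cm) <- c(k, k * N)                      # columns grouped by sample
  V <- matrix(crossprod_cols(Cm, wv, k, N), k, N)
  pre <- A$val %*% V + as.numeric(b$val)
  lam <- 1 / (1 + exp(-pre))
  ad_node(lam, list(C3, kern, A, b), function(g) {
    dpre <- g * lam * (1 - lam)
    dV <- t(A$val) %*% dpre                   # k x N
    dC <- array(0, d)
    dw <- numeric(k)
    for (n in seq_len(N)) {
      dC[, , n] <- outer(dV[, n], wv)
      dw <- dw + t(C3$val[, , n]) %*% dV[, n]
    }
    list(dC, as.numeric(t(Mk) %*% dw), dpre %*% t(V), rowSums(dpre))
  })
}

# V[, n] = C_n %*% w for stacked square matrices
crossprod_cols <- function(Cm, w, k, N) {
  out <- matrix(0, k, N)
  for (n in seq_len(N)) out[, n] <- Cm[, ((n - 1) * k + 1):(n * k)] %*% w
  out
}

# batched per-direction attention vectors, (len x N)
g_direction_lambda <- function(xred, att) {
  ad_batch_att(ad_batch_cov(xred), att$kern, att$A, att$b)
}

g_mshop_block <- function(x, w) {
  Fp <- g_hierarchical_multiscale(x, w)                          # F'
  xd <- g_reduce(Fp, NULL, w$red$D, w$red$D_b)                   # H,W,D',N
  xw <- g_reduce(Fp, c(1, 3, 2, 4), w$red$W, w$red$W_b)          # H,D,W',N
  xh <- g_reduce(Fp, c(2, 3, 1, 4), w$red$H, w$red$H_b)          # W,D,H',N
  lam_D <- g_direction_lambda(xd, w$att$D)                       # D x N
  lam_W <- g_direction_lambda(xw, w$att$W)                       # W x N
  lam_H <- g_direction_lambda(xh, w$att$H)                       # H x N
  scaled <- ad_add(ad_add(ad_scale_axis(Fp, lam_W, 2L),
                          ad_scale_axis(Fp, lam_D, 3L)),
                   ad_scale_axis(Fp, lam_H, 1L))
  ad_add(ad_conv2d(scaled, w$out$fuse, w$out$fuse_b, stride = 1L, pad = 0L), x)
}

# ---- public per-sample API -------------------------------------------------

check_feature_map <- function(F) {
  if (length(dim(F)) != 3L) stop("feature map must be a 3-d array (H x W x D)")
  if (any(!is.finite(F))) stop("feature map contains non-finite values")
  invisible(F)
}

as_batch1 <- function(F) array(F, dim = c(dim(F), 1L))

#' Hierarchical multi-scale stage of the MsHop block
#'
#' Splits the channels of `F` into four groups, applies a 3x3 convolution per
#' group with the previous group's output added from the second group onward,
#' concatenates the four outputs and fuses them with a 1x1 convolution.
#' Spatial size is preserved (3x3 convolutions are same-padded).
#'
#' @param F Feature map, array `H x W x D` with `D` divisible by 4.
#' @param weights An MsHop weight set from [mshop_init()] (the `ms` part is
#'   used), or a list with the same fields.
#' @return The fused feature map `F'`, same shape as `F`.
#' @export
hierarchical_multiscale <- function(F, weights) {
  check_feature_map(F)
  if (dim(F)[3] %% 4L != 0L) stop("channel count must be divisible by 4")
  w <- if (!is.null(weights$ms)) weights else list(ms = weights)
  out <- ad_value(g_hierarchical_multiscale(ad_const(as_batch1(F)), w))
  array(out, dim = dim(F))
}

#' Directional covariance matrices of a feature map
#'
#' Reduces `F'` along each of the three axes with a 1x1 convolution (channels
#' to `D'`, width to `W'`, height to `H'`) and returns the per-axis sample
#' covariance matrices. For the channel direction every spatial position is
#' one observation over the `D'` reduced variables; for the width (height)
#' direction every height-channel (width-channel) coordinate is one
#' observation over the `W'` (`H'`) reduced variables. Observations are
#' mean-centered and the divisor is the number of observations minus one, so
#' the matrices are symmetric positive semi-definite by construction.
#'
#' @param F Feature map `H x W x D` (typically the multi-scale output `F'`).
#' @param cfg An [mshop_config()] matching `dim(F)`.
#' @param weights MsHop weight set (the `red` part is used).
#' @return `list(C_W, C_H, C_D)` of sizes `W'xW'`, `H'xH'`, `D'xD'`.
#' @export
directional_covariances <- function(F, cfg, weights) {
  check_feature_map(F)
  d <- dim(F)
  if (!(cfg$W_red < d[2] && cfg$H_red < d[1] && cfg$D_red < d[3]))
    stop("reduced sizes must be strictly smaller than the feature-map sizes")
  if (min(cfg$W_red, cfg$H_red, cfg$D_red) < 2L)
    stop("covariance undefined for reduced size < 2")
  x <- ad_const(as_batch1(F))
  w <- weights
  covs <- list(
    C_W = g_cov(ad_sample_obs(g_reduce(x, c(1, 3, 2, 4), w$red$W, w$red$W_b), 1L)),
    C_H = g_cov(ad_sample_obs(g_reduce(x, c(2, 3, 1, 4), w$red$H, w$red$H_b), 1L)),
    C_D = g_cov(ad_sample_obs(g_reduce(x, NULL, w$red$D, w$red$D_b), 1L))
  )
  lapply(covs, ad_value)
}

#' Covariance attention vector
#'
#' Turns a square covariance matrix into a statistical weight vector: a 1-D
#' kernel is convolved along each row (same padding), rows are averaged, a
#' learned affine map takes the result from the covariance side length to
#' `target_len`, and a sigmoid squashes the output into (0, 1).
#'
#' @param C Square matrix (`k x k`).
#' @param target_len Length of the returned weight vector (the size of the
#'   feature-map axis the vector will rescale).
#' @param weights `list(kern, A, b)` with `kern` the 1-D kernel, `A` a
#'   `target_len x k` matrix and `b` a length-`target_len` bias.
#' @return Numeric vector in (0, 1) of length `target_len`.
#' @export
covariance_attention <- function(C, target_len, weights) {
  if (target_len < 1L) stop("target_len must be at least 1")
  if (nrow(C) != ncol(C)) stop("C must be square")
  stopifnot(nrow(weights$A) == target_len, ncol(weights$A) == ncol(C))
  as.vector(ad_value(g_cov_attention(ad_const(C), weights)))
}

#' Apply a full MsHop block
#'
#' Composes the hierarchical multi-scale stage, the three directional
#' covariance attentions and the residual fusion:
#' `out = Conv1x1(lam_W (x) F' + lam_D (x) F' + lam_H (x) F') + F`,
#' where each weight vector broadcasts along its own axis. Output shape equals
#' input shape; setting the final fusion weights and bias to zero makes the
#' block an exact identity.
#'
#' @param F Feature map `H x W x D`.
#' @param cfg An [mshop_config()] matching `dim(F)`.
#' @param weights Weight set from [mshop_init()].
#' @return Array of the same shape as `F`.
#' @export
mshop_block <- function(F, cfg, weights) {
  check_feature_map(F)
  d <- dim(F)
  if (d[1] != cfg$H || d[2] != cfg$W || d[3] != cfg$D)
    stop("feature-map shape does not match the block configuration")
  out <- ad_value(g_mshop_block(ad_const(as_batch1(F)), weights))
  array(out, dim = d)
}
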
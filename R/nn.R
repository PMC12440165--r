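# Small neural-network toolkit on top of the autodiff tape: weight
# initializers, fully connected stacks, the Adam optimizer and the cosine
# learning-rate schedule used by the training pipeline.

# He/Kaiming-style fan-in initializer for conv kernels (kh, kw, Cin, Cout)
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin, cout))
}

# (d_in x d_out) weight matrix, fan-in scaled
init_linear <- function(d_in, d_out) {
  matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
}

# Convert a (possibly nested) list of plain arrays into ad_param nodes with the
# same structure, and back. Checkpoints store the plain-array form.
params_from_weights <- function(w) {
  if (is.list(w)) return(lapply(w, params_from_weights))
  ad_param(w)
}

weights_from_params <- function(p) {
  if (is.list(p) && !is_ad(p)) return(lapply(p, weights_from_params))
  p$val
}

flatten_params <- function(p) {
  if (is.list(p) && !is_ad(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  list(p)
}

# Every parameter value concatenated into one numeric vector (freeze checks).
param_vector <- function(p) {
  unlist(lapply(flatten_params(p), function(n) as.numeric(n$val)), use.names = FALSE)
}

# ---- optimizer -------------------------------------------------------------

adam_new <- function(params, lr = 0.003, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  ps <- flatten_params(params)
  list(params = ps,
       m = lapply(ps, function(p) array(0, dim = c(length(p$val)))),
       v = lapply(ps, function(p) array(0, dim = c(length(p$val)))),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- as.numeric(p$grad)
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * as.numeric(p$val)
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$val <- p$val - lr * keep_dim(upd, p$val)
  }
  opt
}

#' Cosine learning-rate schedule
#'
#' Learning rate at step `t` (1-based) of `total` steps, decaying from
#' `lr0` to (numerically) zero along a half cosine, as used for the
#' self-supervised pretraining phase.
#'
#' @param t Current step, 1-based.
#' @param total Total number of steps.
#' @param lr0 Initial learning rate.
#' @return The learning rate for step `t`.
#' @export
cosine_lr <- function(t, total, lr0) {
  lr0 * 0.5 * (1 + cos(pi * (t - 1) / max(1, total - 1)))
}

# ---- fully connected stacks ------------------------------------------------

# Column-wise batch standardization as a differentiable subgraph:
# (x - colmean) / sqrt(colvar + eps), biased variance. Used inside the
# expander during pretraining; it is what keeps the variance hinge away from
# the constant-embedding fixed point.
g_batch_standardize <- function(x, eps = 1e-5) {
  n <- nrow(ad_value(x)); d <- ncol(ad_value(x))
  ones_col <- ad_const(matrix(1, n, 1))
  mu <- ad_smul(ad_matmul(ad_const(matrix(1, 1, n)), x), 1 / n)
  xc <- ad_sub(x, ad_matmul(ones_col, mu))
  v <- ad_smul(ad_matmul(ad_const(matrix(1, 1, n)), ad_square(xc)), 1 / n)
  sd_row <- ad_sqrt(ad_sadd(v, eps))
  ad_div(xc, ad_matmul(ones_col, sd_row))
}

# weights: list of list(W = d_in x d_out, b = d_out); applies an activation
# between layers (not after the last). `standardize` inserts batch
# standardization between the affine map and the activation of hidden layers
# (requires >= 2 rows).
mlp_forward <- function(x, weights, activation = ad_relu, standardize = FALSE) {
  h <- as_ad(x)
  L <- length(weights)
  for (i in seq_len(L)) {
    h <- ad_add_rowvec(ad_matmul(h, weights[[i]]$W), weights[[i]]$b)
    if (i < L) {
      if (standardize) h <- g_batch_standardize(h)
      h <- activation(h)
    }
  }
  h
}

mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = init_linear(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
  })
}
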
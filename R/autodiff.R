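# Minimal tape-based reverse-mode automatic differentiation over R arrays.
#
# Every value in a computation is an `ad_node`: an environment holding the
# forward value, an accumulated gradient, references to parent nodes and a
# backward closure mapping the node's gradient to gradients for its parents.
# Node ids increase monotonically, so reverse-id order is a valid topological
# order for backpropagation. Parameters are ordinary nodes created once and
# reused across freshly built graphs; children hold references to parents
# (never the reverse), so discarded graphs are garbage-collected while the
# parameter environments persist.
#
# The op set is intentionally small: exactly what the backbones, the MsHop
# block, the dual-branch loss and the VAAL game need. All ops are
# deterministic; gradient correctness is checked against central finite
# differences in the test suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_next_id <- function() {
  .ad_env$counter <- .ad_env$counter + 1L
  .ad_env$counter
}

ad_node <- function(val, parents = list(), bw = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$param <- param
  e$id <- ad_next_id()
  class(e) <- "ad_node"
  e
}

ad_const <- function(x) ad_node(x)

ad_param <- function(x) ad_node(x, param = TRUE)

is_ad <- function(x) inherits(x, "ad_node")

as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad(x)) x$val else x

# Accumulate gradient g into node n.
ad_acc <- function(n, g) {
  if (is.null(n$grad)) n$grad <- g else n$grad <- n$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar root. Gradients accumulate on every reachable
# node; callers read them off parameter nodes.
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$val) == 1L)
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 256L)
  k <- 0L
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    k <- k + 1L
    if (k > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[k]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(k)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  root$grad <- 1
  for (n in nodes[ord]) {
    if (is.null(n$bw) || is.null(n$grad)) next
    gs <- n$bw(n$grad)
    for (i in seq_along(n$parents)) {
      if (!is.null(gs[[i]])) ad_acc(n$parents[[i]], gs[[i]])
    }
  }
  invisible(root)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

keep_dim <- function(g, template) {
  if (!is.null(dim(template))) dim(g) <- dim(template)
  g
}

# ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av * bv, list(a, b),
          function(g) list(keep_dim(g * bv, av), keep_dim(g * av, bv)))
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av / bv, list(a, b),
          function(g) list(keep_dim(g / bv, av), keep_dim(-g * av / (bv * bv), bv)))
}

# scalar (plain numeric) multiply / add
ad_smul <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$val * s, list(a), function(g) list(g * s))
}

ad_sadd <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$val + s, list(a), function(g) list(g))
}

ad_neg <- function(a) ad_smul(a, -1)

ad_square <- function(a) {
  a <- as_ad(a)
  av <- a$val
  ad_node(av * av, list(a), function(g) list(2 * g * av))
}

ad_sqrt <- function(a) {
  a <- as_ad(a)
  sv <- sqrt(a$val)
  ad_node(sv, list(a), function(g) list(g / (2 * sv)))
}

ad_exp <- function(a) {
  a <- as_ad(a)
  ev <- exp(a$val)
  ad_node(ev, list(a), function(g) list(g * ev))
}

ad_log <- function(a) {
  a <- as_ad(a)
  av <- a$val
  ad_node(log(av), list(a), function(g) list(g / av))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  av <- a$val
  mask <- av > 0
  ad_node(av * mask, list(a), function(g) list(keep_dim(g * mask, av)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  sv <- 1 / (1 + exp(-a$val))
  ad_node(sv, list(a), function(g) list(g * sv * (1 - sv)))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  tv <- tanh(a$val)
  ad_node(tv, list(a), function(g) list(g * (1 - tv * tv)))
}

# max(a, 0) is ad_relu; generic hinge max(c - a, 0) composes from those.

# numerically stable log(1 + exp(a)); gradient is sigmoid(a)
ad_softplus <- function(a) {
  a <- as_ad(a)
  av <- a$val
  sv <- pmax(av, 0) + log1p(exp(-abs(av)))
  sg <- 1 / (1 + exp(-av))
  ad_node(keep_dim(sv, av), list(a), function(g) list(keep_dim(g * sg, av)))
}

# ---- reductions ------------------------------------------------------------

ad_sum <- function(a) {
  a <- as_ad(a)
  av <- a$val
  ad_node(sum(av), list(a), function(g) list(keep_dim(array(g, dim = c(length(av))), av)))
}

ad_mean <- function(a) {
  a <- as_ad(a)
  av <- a$val
  m <- length(av)
  ad_node(sum(av) / m, list(a),
          function(g) list(keep_dim(array(g / m, dim = c(length(av))), av)))
}

# ---- shape ops -------------------------------------------------------------

ad_reshape <- function(a, dims) {
  a <- as_ad(a)
  od <- dim(a$val)
  v <- a$val
  dim(v) <- dims
  ad_node(v, list(a), function(g) { dim(g) <- od; list(g) })
}

ad_aperm <- function(a, perm) {
  a <- as_ad(a)
  inv <- order(perm)
  ad_node(aperm(a$val, perm), list(a), function(g) list(aperm(g, inv)))
}

# ---- matrix ops ------------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

# column-bind matrix nodes
ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$val)
  cs <- vapply(vals, ncol, integer(1))
  ends <- cumsum(cs)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# add a row vector (length = ncol) to every row of a matrix
ad_add_rowvec <- function(a, v) {
  a <- as_ad(a); v <- as_ad(v)
  av <- a$val
  ad_node(sweep(av, 2, as.vector(v$val), "+"), list(a, v),
          function(g) list(g, colSums(g)))
}

# ---- convolution and pooling ----------------------------------------------

# x: (H, W, C, N) node; w: (kh, kw, Cin, Cout) node; b: (Cout) node or NULL.
ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  x <- as_ad(x); w <- as_ad(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_ad(b)
  bias <- if (has_b) as.numeric(b$val) else numeric(0)
  y <- conv2d_fw(x$val, w$val, bias, as.integer(stride), as.integer(pad))
  parents <- if (has_b) list(x, w, b) else list(x, w)
  xv <- x$val; wv <- w$val
  need_dx <- !is.null(x$bw) || isTRUE(x$param)   # constant leaves skip col2im
  ad_node(y, parents, function(g) {
    dim(g) <- dim(y)
    bwd <- conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad), has_b,
                     need_dx)
    if (has_b) list(bwd$dx, bwd$dw, as.numeric(bwd$db)) else list(bwd$dx, bwd$dw)
  })
}

# global average pool: (H, W, C, N) -> (N, C) matrix of per-channel means
ad_gap <- function(x) {
  x <- as_ad(x)
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  v <- x$val
  dim(v) <- c(H * W, C * N)
  cm <- colMeans(v)                        # channel-by-sample means
  out <- matrix(cm, C, N)
  ad_node(t(out), list(x), function(g) {
    gfull <- matrix(rep(as.vector(t(g)) / (H * W), each = H * W), H * W)
    dim(gfull) <- d
    list(gfull)
  })
}

# slice a channel range from (H, W, C, N)
ad_slice_c <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$val)
  ad_node(x$val[, , idx, , drop = FALSE], list(x), function(g) {
    full <- array(0, dim = d)
    full[, , idx, ] <- g
    list(full)
  })
}

# concatenate 4-d nodes along the channel axis
ad_concat_c <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$val)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ends <- cumsum(cs)
  starts <- c(1, head(ends, -1) + 1)
  ad_node(out, nodes, function(g) {
    dim(g) <- dim(out)
    lapply(seq_along(nodes), function(i) g[, , starts[i]:ends[i], , drop = FALSE])
  })
}

# extract sample n of a 4-d node as an (a*b) x k observation matrix, where the
# third array axis supplies the k variables
ad_sample_obs <- function(x, n) {
  x <- as_ad(x)
  d <- dim(x$val)
  m <- d[1] * d[2]
  v <- x$val[, , , n, drop = FALSE]
  dim(v) <- c(m, d[3])
  ad_node(v, list(x), function(g) {
    full <- array(0, dim = d)
    gi <- g
    dim(gi) <- c(d[1], d[2], d[3], 1)
    full[, , , n] <- gi
    list(full)
  })
}

# stack column-vector nodes (len x 1) into a (len x N) matrix
ad_stack_cols <- function(cols) {
  cols <- lapply(cols, as_ad)
  vals <- vapply(cols, function(c) as.vector(c$val), numeric(length(cols[[1]]$val)))
  vals <- matrix(vals, ncol = length(cols))
  ad_node(vals, cols, function(g) {
    g <- matrix(g, ncol = length(cols))
    lapply(seq_along(cols), function(i) matrix(g[, i], ncol = 1))
  })
}

# multiply a (H, W, C, N) node by a per-sample weight vector along one axis:
# lam is (dim_len x N); axis in 1:3
ad_scale_axis <- function(x, lam, axis) {
  x <- as_ad(x); lam <- as_ad(lam)
  d <- dim(x$val)
  N <- d[4]
  perm <- c(axis, setdiff(1:3, axis), 4)
  inv <- order(perm)
  rest <- prod(d[setdiff(1:3, axis)])
  xp <- aperm(x$val, perm)
  dim(xp) <- c(d[axis], rest * N)
  lv <- lam$val
  lam_big <- lv[, rep(seq_len(N), each = rest), drop = FALSE]
  yp <- xp * lam_big
  dim(yp) <- c(d[axis], d[setdiff(1:3, axis)], N)
  y <- aperm(yp, inv)
  ad_node(y, list(x, lam), function(g) {
    gp <- aperm(keep_dim(g, y), perm)
    dim(gp) <- c(d[axis], rest * N)
    dxp <- gp * lam_big
    dim(dxp) <- c(d[axis], d[setdiff(1:3, axis)], N)
    prod_mat <- gp * xp
    dl <- vapply(seq_len(N),
                 function(n) rowSums(prod_mat[, ((n - 1) * rest + 1):(n * rest),
                                              drop = FALSE]),
                 numeric(d[axis]))
    list(aperm(dxp, inv), matrix(dl, nrow = d[axis]))
  })
}

# fused, numerically stable softmax cross-entropy against constant targets:
# logits (n x K) node, targets (n x K) fixed weights; returns mean over rows of
# -sum_k targets[i,k] * log softmax(logits)[i,k], each row of targets summing
# to its own mass (callers normalize as needed).
ad_softmax_xent <- function(logits, targets) {
  logits <- as_ad(logits)
  lv <- logits$val
  mx <- apply(lv, 1, max)
  sh <- lv - mx
  es <- exp(sh)
  Z <- rowSums(es)
  logp <- sh - log(Z)
  p <- es / Z
  n <- nrow(lv)
  loss <- -sum(targets * logp) / n
  rowmass <- rowSums(targets)
  ad_node(loss, list(logits), function(g) {
    list(g * (p * rowmass - targets) / n)
  })
}
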
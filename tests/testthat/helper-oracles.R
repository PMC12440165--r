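# Straight-line reference implementations used as independent oracles.
# Everything here is written with explicit loops and no layer abstractions,
# deliberately ignorant of the package's autodiff/graph machinery.

# literal same-padded convolution of a (H, W, Cin) array with (kh, kw, Cin,
# Cout) kernels, stride 1
oracle_conv <- function(x, k, b = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]
  kh <- dim(k)[1]; kw <- dim(k)[2]; cin <- dim(k)[3]; cout <- dim(k)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  out <- array(0, c(H, W, cout))
  for (o in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (c in seq_len(cin)) for (a in seq_len(kh)) for (bb in seq_len(kw)) {
      ii <- i + a - 1 - ph; jj <- j + bb - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * k[a, bb, c, o]
    }
    out[i, j, o] <- acc + if (is.null(b)) 0 else b[o]
  }
  out
}

# hierarchical multi-scale stage, literal recursion + concatenation + fusion
oracle_hierarchical <- function(F, w) {
  D <- dim(F)[3]; g <- D / 4
  S <- vector("list", 4)
  for (i in 1:4) {
    Fi <- F[, , ((i - 1) * g + 1):(i * g), drop = FALSE]
    inp <- if (i == 1) Fi else Fi + S[[i - 1]]
    S[[i]] <- oracle_conv(inp, w$ms[[paste0("k", i)]], w$ms[[paste0("b", i)]])
  }
  cat4 <- array(0, dim(F))
  for (i in 1:4) cat4[, , ((i - 1) * g + 1):(i * g)] <- S[[i]]
  oracle_conv(cat4, w$ms$fuse, w$ms$fuse_b)
}

# sample covariance of an m x k observation matrix, explicit loop
oracle_cov <- function(X) {
  m <- nrow(X); k <- ncol(X)
  xbar <- colMeans(X)
  C <- matrix(0, k, k)
  for (i in seq_len(m)) {
    d <- X[i, ] - xbar
    C <- C + outer(d, d)
  }
  C / (m - 1)
}

# axis reductions via explicit permutation + 1x1 conv, then covariance
oracle_directional_covs <- function(F, w) {
  red1x1 <- function(x, k, b) {  # x: (a, b, cin); k: (1,1,cin,cout)
    a <- dim(x)[1]; bb <- dim(x)[2]; cout <- dim(k)[4]
    out <- array(0, c(a, bb, cout))
    for (o in seq_len(cout)) for (i in seq_len(a)) for (j in seq_len(bb))
      out[i, j, o] <- sum(x[i, j, ] * k[1, 1, , o]) + b[o]
    out
  }
  obs <- function(x) matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
  xd <- red1x1(F, w$red$D, w$red$D_b)
  xw <- red1x1(aperm(F, c(1, 3, 2)), w$red$W, w$red$W_b)
  xh <- red1x1(aperm(F, c(2, 3, 1)), w$red$H, w$red$H_b)
  list(C_W = oracle_cov(obs(xw)), C_H = oracle_cov(obs(xh)),
       C_D = oracle_cov(obs(xd)))
}

# row-wise 1-D convolution (same padding) + row means + affine + sigmoid
oracle_attention <- function(C, att) {
  k <- ncol(C); r <- length(att$kern); off <- (r + 1) / 2
  R <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    acc <- 0
    for (t in seq_len(r)) {
      jj <- j + t - off
      if (jj >= 1 && jj <= k) acc <- acc + att$kern[t] * C[i, jj]
    }
    R[i, j] <- acc
  }
  v <- rowMeans(R)
  1 / (1 + exp(-(as.vector(att$A %*% v) + att$b)))
}

# the whole MsHop block, composed literally
oracle_mshop <- function(F, w) {
  Fp <- oracle_hierarchical(F, w)
  covs <- oracle_directional_covs(Fp, w)
  lw <- oracle_attention(covs$C_W, w$att$W)
  lh <- oracle_attention(covs$C_H, w$att$H)
  ld <- oracle_attention(covs$C_D, w$att$D)
  H <- dim(F)[1]; W <- dim(F)[2]; D <- dim(F)[3]
  scaled <- array(0, dim(F))
  for (i in seq_len(H)) for (j in seq_len(W)) for (d in seq_len(D))
    scaled[i, j, d] <- Fp[i, j, d] * (lw[j] + ld[d] + lh[i])
  red1x1 <- function(x, k, b) {
    out <- array(0, dim(x))
    for (o in seq_len(dim(k)[4])) for (i in seq_len(H)) for (j in seq_len(W))
      out[i, j, o] <- sum(x[i, j, ] * k[1, 1, , o]) + b[o]
    out
  }
  red1x1(scaled, w$out$fuse, w$out$fuse_b) + F
}

# long-run Sinkhorn toward uniform marginals (rows 1/n, cols 1/K)
oracle_sinkhorn <- function(scores, eps, iters) {
  n <- nrow(scores); K <- ncol(scores)
  L <- scores / eps
  L <- L - apply(L, 1, max)
  Q <- exp(L)
  for (i in seq_len(iters)) {
    Q <- sweep(Q, 2, colSums(Q) * K, "/")
    Q <- sweep(Q, 1, rowSums(Q) * n, "/")
  }
  Q
}

# classification metrics from first principles (per-class loops)
oracle_metrics <- function(y_true, y_pred) {
  cls <- c("normal", "benign", "malignant")
  n <- length(y_true)
  acc <- sum(y_true == y_pred) / n
  f1s <- numeric(3)
  for (i in 1:3) {
    tp <- sum(y_true == cls[i] & y_pred == cls[i])
    fp <- sum(y_true != cls[i] & y_pred == cls[i])
    fn <- sum(y_true == cls[i] & y_pred != cls[i])
    f1s[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  sens <- {
    pos <- y_true == "malignant"
    sum(pos & y_pred == "malignant") / sum(pos)
  }
  spec <- {
    neg <- y_true != "malignant"
    sum(neg & y_pred != "malignant") / sum(neg)
  }
  c(accuracy = acc, specificity = spec, sensitivity = sens,
    f1_malignant = f1s[3], macro_f1 = mean(f1s))
}

# kappa bounds by brute-force grid over the within-class joint-agreement
# free parameters (probability both raters are correct in each true class)
oracle_kappa_grid <- function(sa, sb, pa_spec, pb_spec, prev, grid = 400) {
  ks <- c()
  ra <- prev * sa + (1 - prev) * (1 - pa_spec)
  rb <- prev * sb + (1 - prev) * (1 - pb_spec)
  pe <- ra * rb + (1 - ra) * (1 - rb)
  cpos <- seq(max(0, sa + sb - 1), min(sa, sb), length.out = grid)
  cneg <- seq(max(0, pa_spec + pb_spec - 1), min(pa_spec, pb_spec),
              length.out = grid)
  apos <- 1 - sa - sb + 2 * cpos
  aneg <- 1 - pa_spec - pb_spec + 2 * cneg
  po <- outer(prev * apos, (1 - prev) * aneg, "+")
  k <- (po - pe) / (1 - pe)
  c(min(k), max(k))
}

expect_batched_matches_oracle <- function(F, cfg, w, tol = 1e-5) {
  expect_equal(mshop_block(F, cfg, w), oracle_mshop(F, w), tolerance = tol)
}

# tiny synthetic two-cluster image set for the active-learning coverage test
make_cluster_images <- function(n_big, n_small, size = 32, seed = 1) {
  withr::with_seed(seed, {
    imgs <- array(0, c(size, size, n_big + n_small))
    for (i in seq_len(n_big)) {       # cluster A: bright top-left blob
      img <- matrix(0.2 + 0.05 * stats::rnorm(size * size), size, size)
      img[5:14, 5:14] <- img[5:14, 5:14] + 0.6
      imgs[, , i] <- pmin(pmax(img, 0), 1)
    }
    for (i in seq_len(n_small)) {     # cluster B: dark band bottom-right
      img <- matrix(0.7 + 0.05 * stats::rnorm(size * size), size, size)
      img[(size - 12):(size - 3), (size - 12):(size - 3)] <- 0.05
      imgs[, , n_big + i] <- pmin(pmax(img, 0), 1)
    }
    imgs
  })
}
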
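# The dual-branch self-supervised objective.
#
# Branch 1 (contrastive): a variance-invariance-covariance loss on expander
# embeddings Z1, Z2 of two views — invariance pulls paired embeddings
# together, a hinge on the per-dimension standard deviation keeps every
# dimension spread out, and the squared off-diagonal covariance decorrelates
# dimensions.
#
# Branch 2 (clustering): extractor features Y1, Y2 are softly assigned to a
# bank of prototype vectors via entropically regularized optimal transport
# (Sinkhorn-Knopp on the transport polytope: row marginals 1/n, column
# marginals 1/K), and each view must predict the other view's codes through a
# temperature softmax over cosine similarities (swapped prediction).
#
# Total: L_total = L_con(Z1, Z2) + alpha * L_clu(Y1, Y2).
#
# Public functions here are plain-arithmetic implementations used for
# analysis and testing; the training pipeline rebuilds the same quantities as
# autodiff graphs (g_* builders below), and the suite asserts the two paths
# agree to near machine precision.

#' Hyperparameters of the dual-branch loss
#'
#' Defaults follow the published configuration wherever a value is printed:
#' `lambda = mu = 25`, `gamma = 1`, `alpha = 0.1` and the transport
#' regularizer `eps_ot = 1e-4`. The covariance weight `nu = 1`, the variance
#' stabilizer `eps_var = 1e-4`, the assignment temperature `tau = 0.1`, the
#' number of prototypes `K = 30` and `sinkhorn_iters = 3` are package
#' defaults for quantities the source configuration leaves open.
#'
#' @param lambda,mu,nu Weights of the invariance, variance and covariance
#'   terms.
#' @param gamma Target standard deviation of the variance hinge.
#' @param eps_var Stabilizer inside the square root of the variance term.
#' @param eps_ot Entropic regularizer of the transport assignment; the printed
#'   value 1e-4 yields near-hard assignments.
#' @param alpha Weight of the clustering branch in the total loss.
#' @param sinkhorn_iters Alternating normalization sweeps when computing codes.
#' @param tau Softmax temperature of the swapped-prediction probability.
#' @param K Number of prototypes.
#' @param sqrt_variance If `TRUE` (default) the variance term penalizes the
#'   regularized standard deviation `sqrt(Var + eps_var)`; `FALSE` restores
#'   the literal variance reading `Var + eps_var`.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda = 25, mu = 25, nu = 1, gamma = 1,
                         eps_var = 1e-4, eps_ot = 1e-4, alpha = 0.1,
                         sinkhorn_iters = 3L, tau = 0.1, K = 30L,
                         sqrt_variance = TRUE) {
  stopifnot(lambda > 0, mu > 0, nu > 0, gamma > 0, eps_var > 0, eps_ot > 0,
            alpha >= 0, sinkhorn_iters >= 1, tau > 0, K >= 2)
  structure(list(lambda = lambda, mu = mu, nu = nu, gamma = gamma,
                 eps_var = eps_var, eps_ot = eps_ot, alpha = alpha,
                 sinkhorn_iters = as.integer(sinkhorn_iters), tau = tau,
                 K = as.integer(K), sqrt_variance = isTRUE(sqrt_variance)),
            class = "loss_weights")
}

#' Prototype bank
#'
#' `K` learnable cluster centers in embedding space. Rows are unit-normalized
#' at creation when `normalize = TRUE` (the default), matching the cosine
#' similarity used by the swapped-prediction probability.
#'
#' @param K Number of prototypes.
#' @param d Embedding dimension.
#' @param tau Softmax temperature.
#' @param normalize Keep prototype rows at unit Euclidean norm.
#' @return A list of class `prototype_bank` with element `data` (`K x d`).
#' @export
prototype_bank <- function(K, d, tau = 0.1, normalize = TRUE) {
  data <- matrix(stats::rnorm(K * d), K, d)
  if (normalize) data <- data / sqrt(rowSums(data^2))
  structure(list(data = data, tau = tau, normalize = normalize),
            class = "prototype_bank")
}

#' Three-layer expander weights
#'
#' @param d_in Extractor embedding dimension.
#' @param d_hidden Hidden width of the first two layers.
#' @param d_out Output embedding dimension fed to the contrastive loss.
#' @return Weight list consumable by [expand()].
#' @export
expander_init <- function(d_in, d_hidden = 128L, d_out = 128L) {
  mlp_init(c(d_in, d_hidden, d_hidden, d_out))
}

#' Apply the expander
#'
#' Three fully connected layers with ReLU nonlinearities between layers 1-2
#' and 2-3 (none after the last). During pretraining the hidden layers are
#' additionally batch-standardized before the ReLU (`standardize = TRUE`,
#' parameter-free); this keeps the variance hinge of the contrastive loss
#' away from its constant-embedding fixed point and requires `n >= 2`.
#'
#' @param Y `n x d_in` matrix of extractor features.
#' @param weights From [expander_init()].
#' @param standardize Insert batch standardization in the hidden layers.
#' @return `n x d_out` matrix.
#' @export
expand <- function(Y, weights, standardize = FALSE) {
  stopifnot(all(is.finite(Y)))
  h <- Y
  L <- length(weights)
  for (i in seq_len(L)) {
    h <- sweep(h %*% weights[[i]]$W, 2, weights[[i]]$b, "+")
    if (i < L) {
      if (standardize) {
        v <- colMeans(sweep(h, 2, colMeans(h))^2)
        h <- sweep(sweep(h, 2, colMeans(h)), 2, sqrt(v + 1e-5), "/")
      }
      h <- pmax(h, 0)
    }
  }
  h
}

#' Invariance term
#'
#' Mean squared Euclidean distance between paired rows of the two embedding
#' batches: `(1/n) * sum_i ||z1_i - z2_i||^2`.
#'
#' @param Z1,Z2 Equal-shape `n x d` matrices.
#' @return Nonnegative scalar, symmetric in its arguments.
#' @export
invariance_term <- function(Z1, Z2) {
  if (!identical(dim(Z1), dim(Z2))) stop("invariance_term: shape mismatch")
  sum((Z1 - Z2)^2) / nrow(Z1)
}

#' Variance term
#'
#' Hinge on the regularized standard deviation of each embedding dimension:
#' `(1/d) * sum_j max(0, gamma - sqrt(Var(z_j) + eps_var))` with the unbiased
#' column variance. Bounded in `[0, gamma]`.
#'
#' @param Z `n x d` matrix, `n >= 2`.
#' @param w A [loss_weights()].
#' @return Scalar in `[0, gamma]`.
#' @export
variance_term <- function(Z, w = loss_weights()) {
  if (nrow(Z) < 2) stop("variance_term: needs at least 2 samples")
  v <- apply(Z, 2, stats::var)
  s <- if (w$sqrt_variance) sqrt(v + w$eps_var) else v + w$eps_var
  mean(pmax(0, w$gamma - s))
}

#' Covariance term
#'
#' Mean squared off-diagonal entry of the `d x d` sample covariance of `Z`
#' (divisor `n - 1`), scaled by `1/d`.
#'
#' @param Z `n x d` matrix, `n >= 2`.
#' @return Nonnegative scalar.
#' @export
covariance_term <- function(Z) {
  if (nrow(Z) < 2) stop("covariance_term: needs at least 2 samples")
  C <- stats::cov(Z)
  (sum(C^2) - sum(diag(C)^2)) / ncol(Z)
}

#' Contrastive (variance-invariance-covariance) loss
#'
#' `lambda * s(Z1,Z2) + mu * [v(Z1) + v(Z2)] + nu * [c(Z1) + c(Z2)]`.
#'
#' @param Z1,Z2 Equal-shape `n x d` embedding matrices, `n >= 2`.
#' @param w A [loss_weights()].
#' @return Scalar loss.
#' @export
contrastive_loss <- function(Z1, Z2, w = loss_weights()) {
  w$lambda * invariance_term(Z1, Z2) +
    w$mu * (variance_term(Z1, w) + variance_term(Z2, w)) +
    w$nu * (covariance_term(Z1) + covariance_term(Z2))
}

#' Entropic optimal-transport codes (Sinkhorn-Knopp)
#'
#' Maps a score matrix to the transport polytope: starting from
#' `exp(scores / eps_ot)` (row-max subtracted for overflow safety), columns
#' are normalized to sum `1/K` and rows to sum `1/n`, alternating for
#' `sinkhorn_iters` sweeps and finishing with the row normalization, so row
#' sums are exact to machine precision and column sums approach `1/K` as the
#' iteration count grows.
#'
#' @param scores `n x K` matrix of feature-prototype similarities.
#' @param w A [loss_weights()] (uses `eps_ot`, `sinkhorn_iters`).
#' @return `n x K` nonnegative code matrix `Q`.
#' @export
compute_codes <- function(scores, w = loss_weights()) {
  if (any(!is.finite(scores))) stop("compute_codes: non-finite scores")
  n <- nrow(scores); K <- ncol(scores)
  L <- scores / w$eps_ot
  L <- L - apply(L, 1, max)
  Q <- exp(L)
  for (it in seq_len(w$sinkhorn_iters)) {
    cs <- pmax(colSums(Q), 1e-300)
    Q <- Q / (K * matrix(cs, n, K, byrow = TRUE))
    rs <- pmax(rowSums(Q), 1e-300)
    Q <- Q / (n * matrix(rs, n, K))
  }
  Q
}

row_normalize <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("zero-norm row encountered where a direction is required")
  M / nrm
}

#' Clustering (swapped-prediction) loss
#'
#' Assigns each view's features to the prototype bank with [compute_codes()]
#' and scores how well the other view predicts those codes:
#' `L_clu = l(Y1, Q2) + l(Y2, Q1)` with
#' `l(Y, Q) = -(1/n) sum_i sum_k n*Q_ik * log p_i(k)` and
#' `p_i(k) = softmax_k(cos(y_i, c_k) / tau)` on unit-normalized features and
#' prototypes. Codes are treated as constants (no gradient flows through the
#' Sinkhorn assignment).
#'
#' @param Y1,Y2 `n x d` feature matrices.
#' @param P A [prototype_bank()] with `d` columns.
#' @param w A [loss_weights()].
#' @return Scalar loss (nonnegative).
#' @export
clustering_loss <- function(Y1, Y2, P, w = loss_weights()) {
  if (!identical(dim(Y1), dim(Y2))) stop("clustering_loss: shape mismatch")
  if (ncol(Y1) != ncol(P$data)) stop("clustering_loss: prototype dimension mismatch")
  C <- if (P$normalize) row_normalize(P$data) else P$data
  Y1h <- row_normalize(Y1)
  Y2h <- row_normalize(Y2)
  s1 <- Y1h %*% t(C)
  s2 <- Y2h %*% t(C)
  Q1 <- compute_codes(s1, w)
  Q2 <- compute_codes(s2, w)
  swapped_xent(s1, Q2, P$tau) + swapped_xent(s2, Q1, P$tau)
}

# -(1/n) sum_i sum_k (n Q_ik) log softmax(scores/tau)_ik, numerically stable
swapped_xent <- function(scores, Q, tau) {
  n <- nrow(scores)
  L <- scores / tau
  L <- L - apply(L, 1, max)
  logp <- L - log(rowSums(exp(L)))
  -sum((n * Q) * logp) / n
}

#' Total dual-branch loss
#'
#' `L_total = L_con(Z1, Z2) + alpha * L_clu(Y1, Y2)`.
#'
#' @param Y1,Y2 Extractor features (clustering branch).
#' @param Z1,Z2 Expander embeddings (contrastive branch).
#' @param P A [prototype_bank()].
#' @param w A [loss_weights()].
#' @return Scalar loss.
#' @export
total_loss <- function(Y1, Y2, Z1, Z2, P, w = loss_weights()) {
  contrastive_loss(Z1, Z2, w) +
    if (w$alpha > 0) w$alpha * clustering_loss(Y1, Y2, P, w) else 0
}

# ---- graph builders used by the training pipeline --------------------------

g_colvar_stats <- function(z) {
  n <- nrow(ad_value(z))
  ones_col <- ad_const(matrix(1, n, 1))
  mu <- ad_smul(ad_matmul(ad_const(matrix(1, 1, n)), z), 1 / n)
  zc <- ad_sub(z, ad_matmul(ones_col, mu))
  list(zc = zc, n = n)
}

g_invariance <- function(z1, z2) {
  n <- nrow(ad_value(z1))
  ad_smul(ad_sum(ad_square(ad_sub(z1, z2))), 1 / n)
}

g_variance <- function(z, w) {
  st <- g_colvar_stats(z)
  d <- ncol(ad_value(z))
  v <- ad_smul(ad_matmul(ad_const(matrix(1, 1, st$n)), ad_square(st$zc)), 1 / (st$n - 1))
  s <- if (w$sqrt_variance) ad_sqrt(ad_sadd(v, w$eps_var)) else ad_sadd(v, w$eps_var)
  ad_smul(ad_sum(ad_relu(ad_sub(ad_const(matrix(w$gamma, 1, d)), s))), 1 / d)
}

g_covariance <- function(z) {
  st <- g_colvar_stats(z)
  d <- ncol(ad_value(z))
  C <- ad_smul(ad_matmul(ad_aperm(st$zc, c(2, 1)), st$zc), 1 / (st$n - 1))
  sq <- ad_square(C)
  offdiag <- ad_sub(ad_sum(sq), ad_sum(ad_mul(sq, ad_const(diag(d)))))
  ad_smul(offdiag, 1 / d)
}

g_contrastive <- function(z1, z2, w) {
  ad_add(ad_smul(g_invariance(z1, z2), w$lambda),
         ad_add(ad_smul(ad_add(g_variance(z1, w), g_variance(z2, w)), w$mu),
                ad_smul(ad_add(g_covariance(z1), g_covariance(z2)), w$nu)))
}

# unit-normalize rows of a matrix node
g_row_normalize <- function(y) {
  d <- ncol(ad_value(y))
  nrm <- ad_sqrt(ad_matmul(ad_square(y), ad_const(matrix(1, d, 1))))  # n x 1
  inv <- ad_div(ad_const(matrix(1, nrow(ad_value(y)), 1)), nrm)
  ad_mul(y, ad_matmul(inv, ad_const(matrix(1, 1, d))))
}

# swapped-prediction cross-entropy; Q fixed (plain matrix)
g_swapped_xent <- function(y, protos, Q, tau) {
  yh <- g_row_normalize(y)
  ch <- g_row_normalize(protos)
  logits <- ad_smul(ad_matmul(yh, ad_aperm(ch, c(2, 1))), 1 / tau)
  n <- nrow(Q)
  ad_softmax_xent(logits, n * Q)
}
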
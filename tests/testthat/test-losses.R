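# Dual-branch loss: closed-form instances, loop oracles, transport-polytope
# codes and the gradient-flow contract.

test_that("expander follows the affine-ReLU-affine chain and parameter count", {
  w <- expander_init(2, d_hidden = 3, d_out = 2)
  n_par <- sum(vapply(w, function(l) length(l$W) + length(l$b), numeric(1)))
  expect_identical(n_par, (2 * 3 + 3) + (3 * 3 + 3) + (3 * 2 + 2))
  # zero input with bias-free weights stays zero
  w0 <- lapply(w, function(l) list(W = l$W, b = 0 * l$b))
  expect_equal(expand(matrix(0, 4, 2), w0), matrix(0, 4, 2))
  # hand-computed chain on a 1x2 input
  wt <- list(list(W = matrix(c(1, -1, 0.5, 2), 2, 2), b = c(0.1, -0.1)),
             list(W = matrix(c(1, 0, 0, 1), 2, 2), b = c(0, 0)),
             list(W = matrix(c(2, 1, -1, 1), 2, 2), b = c(0.5, 0)))
  y <- matrix(c(1, 2), 1, 2)
  h1 <- pmax(y %*% wt[[1]]$W + rep(wt[[1]]$b, each = 1), 0)
  h2 <- pmax(h1 %*% wt[[2]]$W, 0)
  expect_equal(expand(y, wt), h2 %*% wt[[3]]$W + rep(wt[[3]]$b, each = 1),
               tolerance = 1e-12)
})

test_that("invariance term: identity, pythagorean instance, loop oracle", {
  Z <- matrix(stats::rnorm(20), 5, 4)
  expect_identical(invariance_term(Z, Z), 0)
  expect_equal(invariance_term(matrix(c(3, 4), 1), matrix(c(0, 0), 1)), 25)
  withr::with_seed(5, {
    Z1 <- matrix(stats::rnorm(20), 5, 4); Z2 <- matrix(stats::rnorm(20), 5, 4)
    ref <- mean(vapply(1:5, function(i) sum((Z1[i, ] - Z2[i, ])^2), numeric(1)))
    expect_equal(invariance_term(Z1, Z2), ref, tolerance = 1e-9)
    expect_identical(invariance_term(Z1, Z2), invariance_term(Z2, Z1))
  })
  expect_error(invariance_term(Z, Z[1:3, ]), "shape")
})

test_that("variance term: hinge saturation and closed forms", {
  w <- loss_weights()
  # column (0, 2): sd = sqrt(2) > gamma -> hinge inactive
  expect_equal(variance_term(matrix(c(0, 2), 2, 1), w), 0)
  # constant column: max(0, 1 - sqrt(1e-4)) = 0.99
  expect_equal(variance_term(matrix(c(1, 1), 2, 1), w), 0.99)
  # two columns {(0,2), (1,1)}: (0 + 0.99) / 2
  expect_equal(variance_term(cbind(c(0, 2), c(1, 1)), w), 0.495)
  expect_error(variance_term(matrix(1, 1, 2), w), "at least 2")
  # literal (no square root) reading restores Var + eps
  wl <- loss_weights(sqrt_variance = FALSE)
  expect_equal(variance_term(matrix(c(1, 1), 2, 1), wl), 1 - 1e-4)
})

test_that("covariance term: orthogonal columns, hand instance, loop oracle", {
  # centered orthogonal columns are uncorrelated
  Z <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(covariance_term(Z), 0)
  expect_equal(covariance_term(matrix(c(1, -1, 1, -1), 2, 2)), 4)
  withr::with_seed(8, {
    Z <- matrix(stats::rnorm(18), 6, 3)
    C <- oracle_cov(Z)
    ref <- 0
    for (i in 1:3) for (j in 1:3) if (i != j) ref <- ref + C[i, j]^2
    expect_equal(covariance_term(Z), ref / 3, tolerance = 1e-9)
  })
})

test_that("contrastive loss composes its three terms", {
  w <- loss_weights()
  Z <- matrix(c(1, -1, 1, -1), 2, 2)
  expect_equal(contrastive_loss(Z, Z, w), 8)   # 25*0 + 25*0 + 1*(4+4)
  withr::with_seed(13, {
    Z1 <- matrix(stats::rnorm(40), 8, 5); Z2 <- matrix(stats::rnorm(40), 8, 5)
    ref <- w$lambda * invariance_term(Z1, Z2) +
      w$mu * (variance_term(Z1, w) + variance_term(Z2, w)) +
      w$nu * (covariance_term(Z1) + covariance_term(Z2))
    expect_equal(contrastive_loss(Z1, Z2, w), ref, tolerance = 1e-9)
  })
  # decorrelated high-spread embeddings: exact zero on identical views
  Zs <- sqrt(2) * cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(contrastive_loss(Zs, Zs, w), 0)
})

test_that("transport codes: symmetry, exact marginals, long-run oracle", {
  w <- loss_weights()
  expect_equal(compute_codes(matrix(1, 2, 2), w), matrix(0.25, 2, 2))
  withr::with_seed(21, {
    s <- matrix(stats::rnorm(40), 8, 5)
    Q <- compute_codes(s, w)
    expect_true(all(Q >= 0))
    expect_equal(rowSums(Q), rep(1 / 8, 8), tolerance = 1e-9)
    # column marginals approach 1/K at an entropic regularization strong
    # enough for Sinkhorn's support premises (the printed default 1e-4
    # yields near-one-hot codes whose dead columns cannot be rebalanced)
    ws <- loss_weights(eps_ot = 0.05, sinkhorn_iters = 300)
    Qs <- compute_codes(s, ws)
    expect_equal(rowSums(Qs), rep(1 / 8, 8), tolerance = 1e-9)
    expect_lt(max(abs(colSums(Qs) - 1 / 5)), 1e-3)
    # the non-final marginal tightens as iterations grow
    err3 <- max(abs(colSums(compute_codes(s, loss_weights(eps_ot = 0.05, sinkhorn_iters = 3))) - 1 / 5))
    err50 <- max(abs(colSums(compute_codes(s, loss_weights(eps_ot = 0.05, sinkhorn_iters = 50))) - 1 / 5))
    expect_lt(err50, err3)
    # moderate-entropy instance against an independent long-run oracle
    s3 <- matrix(stats::rnorm(9), 3, 3)
    w3 <- loss_weights(eps_ot = 0.05, sinkhorn_iters = 50)
    expect_equal(compute_codes(s3, w3), oracle_sinkhorn(s3, 0.05, 50),
                 tolerance = 1e-6)
  })
  expect_error(compute_codes(matrix(c(1, NA), 1)), "finite")
})

test_that("clustering loss: symmetry, uniform instance, loop oracle, bound", {
  w <- loss_weights()
  withr::with_seed(31, {
    P <- prototype_bank(4, 6)
    Y1 <- matrix(stats::rnorm(30), 5, 6)
    Y2 <- matrix(stats::rnorm(30), 5, 6)
    # identical views: both swapped sides coincide
    both <- clustering_loss(Y1, Y1, P, w)
    Ch <- P$data / sqrt(rowSums(P$data^2))
    Y1h <- Y1 / sqrt(rowSums(Y1^2))
    Q1 <- compute_codes(Y1h %*% t(Ch), w)
    side <- -sum((5 * Q1) * {
      L <- (Y1h %*% t(Ch)) / P$tau
      L <- L - apply(L, 1, max)
      L - log(rowSums(exp(L)))
    }) / 5
    expect_equal(both, 2 * side, tolerance = 1e-9)
    expect_gte(clustering_loss(Y1, Y2, P, w), 0)
    # cross-entropy attains the entropy of the codes when p matches Q-tilde:
    # a single sample with symmetric prototypes gives p = (0.5, 0.5)
    P2 <- prototype_bank(2, 2)
    P2$data <- rbind(c(1, 0), c(0, 1))
    y <- matrix(c(1, 1) / sqrt(2), 1, 2)
    expect_equal(clustering_loss(y, y, P2, w), 2 * log(2), tolerance = 1e-9)
    expect_error(clustering_loss(matrix(0, 2, 2), matrix(1, 2, 2), P2, w),
                 "zero-norm")
  })
})

test_that("total loss combines branches with alpha", {
  w <- loss_weights()
  withr::with_seed(41, {
    P <- prototype_bank(5, 4)
    Y1 <- matrix(stats::rnorm(24), 6, 4); Y2 <- matrix(stats::rnorm(24), 6, 4)
    Z1 <- matrix(stats::rnorm(24), 6, 4); Z2 <- matrix(stats::rnorm(24), 6, 4)
    ref <- contrastive_loss(Z1, Z2, w) + 0.1 * clustering_loss(Y1, Y2, P, w)
    expect_equal(total_loss(Y1, Y2, Z1, Z2, P, w), ref, tolerance = 1e-9)
    w0 <- loss_weights(alpha = 0)
    expect_equal(total_loss(Y1, Y2, Z1, Z2, P, w0),
                 contrastive_loss(Z1, Z2, w0))
  })
})

test_that("graph-built losses equal the plain-arithmetic implementations", {
  withr::with_seed(51, {
    w <- loss_weights()
    Z1 <- matrix(stats::rnorm(40), 8, 5); Z2 <- matrix(stats::rnorm(40), 8, 5)
    g <- asgbc:::g_contrastive(asgbc:::ad_const(Z1), asgbc:::ad_const(Z2), w)
    expect_equal(asgbc:::ad_value(g), contrastive_loss(Z1, Z2, w),
                 tolerance = 1e-10)
    P <- prototype_bank(4, 5)
    Y <- matrix(stats::rnorm(40), 8, 5)
    Ch <- P$data / sqrt(rowSums(P$data^2))
    Yh <- Y / sqrt(rowSums(Y^2))
    Q <- compute_codes(Yh %*% t(Ch), w)
    gx <- asgbc:::g_swapped_xent(asgbc:::ad_const(Y), asgbc:::ad_const(P$data),
                                 Q, P$tau)
    expect_equal(asgbc:::ad_value(gx), asgbc:::swapped_xent(Yh %*% t(Ch), Q, P$tau),
                 tolerance = 1e-10)
  })
})

test_that("a gradient step on fixed codes decreases the clustering loss", {
  withr::with_seed(61, {
    w <- loss_weights()
    Y <- matrix(stats::rnorm(40), 8, 5)
    protos <- asgbc:::ad_param(prototype_bank(4, 5)$data)
    Ch <- asgbc:::safe_row_normalize(protos$val)
    Yh <- asgbc:::safe_row_normalize(Y)
    Q <- compute_codes(Yh %*% t(Ch), w)
    loss_at <- function() {
      asgbc:::ad_value(asgbc:::g_swapped_xent(asgbc:::ad_const(Y), protos, Q, w$tau))
    }
    l0 <- loss_at()
    node <- asgbc:::g_swapped_xent(asgbc:::ad_const(Y), protos, Q, w$tau)
    asgbc:::ad_zero_grad(list(protos))
    asgbc:::ad_backward(node)
    protos$val <- protos$val - 0.05 * protos$grad
    expect_lt(loss_at(), l0)
  })
})

test_that("variance term is monotone non-increasing in column spread", {
  w <- loss_weights()
  vals <- vapply(seq(0.1, 2, by = 0.1), function(s)
    variance_term(matrix(c(-s, s), 2, 1), w), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 0 & vals <= w$gamma))
})

test_that("covariance term is invariant to constant column shifts", {
  withr::with_seed(71, {
    Z <- matrix(stats::rnorm(30), 10, 3)
    Zs <- sweep(Z, 2, c(5, -3, 100), "+")
    expect_equal(covariance_term(Z), covariance_term(Zs), tolerance = 1e-9)
  })
})
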
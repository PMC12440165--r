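# The reverse-mode tape against central finite differences, on the ops whose
# gradients are hand-derived.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_grad_ok <- function(build, x0, tol = 1e-5) {
  p <- asgbc:::ad_param(x0)
  asgbc:::ad_backward(build(p))
  ga <- as.numeric(p$grad)
  gn <- as.numeric(num_grad(function(x) {
    asgbc:::ad_value(build(asgbc:::ad_param(asgbc:::keep_dim(x, x0))))
  }, x0))
  expect_lt(max(abs(ga - gn)), tol)
}

test_that("convolution gradients match finite differences", {
  withr::with_seed(1, {
    x0 <- array(stats::rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
    w0 <- 0.3 * array(stats::rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
    b0 <- 0.1 * stats::rnorm(4)
    sq_sum <- function(n) asgbc:::ad_sum(asgbc:::ad_square(n))
    expect_grad_ok(function(p)
      sq_sum(asgbc:::ad_conv2d(p, asgbc:::ad_const(w0), asgbc:::ad_const(b0),
                               stride = 2, pad = 1)), x0)
    expect_grad_ok(function(p)
      sq_sum(asgbc:::ad_conv2d(asgbc:::ad_const(x0), p, asgbc:::ad_const(b0),
                               stride = 1, pad = 1)), w0)
    expect_grad_ok(function(p)
      sq_sum(asgbc:::ad_conv2d(asgbc:::ad_const(x0), asgbc:::ad_const(w0), p,
                               stride = 1, pad = 0)), b0)
  })
})

test_that("fused batched covariance/attention ops match finite differences", {
  withr::with_seed(2, {
    x0 <- array(stats::rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
    kern0 <- stats::rnorm(3)
    A0 <- matrix(stats::rnorm(12), 4, 3)
    b0 <- stats::rnorm(4)
    sq_sum <- function(n) asgbc:::ad_sum(asgbc:::ad_square(n))
    expect_grad_ok(function(p) sq_sum(asgbc:::ad_batch_cov(p)), x0)
    att_loss <- function(C3, kern, A, b)
      sq_sum(asgbc:::ad_batch_att(C3, kern, A, b))
    C0 <- asgbc:::ad_value(asgbc:::ad_batch_cov(asgbc:::ad_const(x0)))
    expect_grad_ok(function(p) att_loss(p, asgbc:::ad_const(kern0),
                                        asgbc:::ad_const(A0), asgbc:::ad_const(b0)), C0)
    expect_grad_ok(function(p) att_loss(asgbc:::ad_const(C0), p,
                                        asgbc:::ad_const(A0), asgbc:::ad_const(b0)), kern0)
    expect_grad_ok(function(p) att_loss(asgbc:::ad_const(C0), asgbc:::ad_const(kern0),
                                        p, asgbc:::ad_const(b0)), A0)
  })
})

test_that("axis scaling, pooling and softmax cross-entropy gradients hold", {
  withr::with_seed(3, {
    x0 <- array(stats::rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
    sq_sum <- function(n) asgbc:::ad_sum(asgbc:::ad_square(n))
    for (ax in 1:3) {
      lam0 <- matrix(stats::rnorm(dim(x0)[ax] * 2), dim(x0)[ax], 2)
      expect_grad_ok(function(p)
        sq_sum(asgbc:::ad_scale_axis(p, asgbc:::ad_const(lam0), ax)), x0)
      expect_grad_ok(function(p)
        sq_sum(asgbc:::ad_scale_axis(asgbc:::ad_const(x0), p, ax)), lam0)
    }
    expect_grad_ok(function(p) sq_sum(asgbc:::ad_gap(p)), x0)
    l0 <- matrix(stats::rnorm(12), 3, 4)
    tg <- matrix(stats::runif(12), 3, 4); tg <- tg / rowSums(tg)
    expect_grad_ok(function(p) asgbc:::ad_softmax_xent(p, tg), l0)
    m0 <- matrix(stats::rnorm(10), 5, 2)
    expect_grad_ok(function(p)
      sq_sum(asgbc:::g_batch_standardize(p)), m0, tol = 1e-4)
  })
})

test_that("a full micro-extractor gradient step matches finite differences", {
  # end-to-end check through conv stages, MsHop, GAP and the projection on a
  # tiny input; perturb the projection weights (cheap but exercises the
  # whole backward sweep)
  withr::with_seed(4, {
    cfg <- backbone_config("micro", input_size = 64L, mshop_stages = 2L,
                           embed_dim = 4L)
    fx <- build_feature_extractor(cfg)
    x <- array(stats::runif(64 * 64 * 2), c(64, 64, 1, 2))
    W0 <- fx$params$proj$W$val
    loss_for <- function(Wv) {
      fx$params$proj$W$val <- Wv
      asgbc:::ad_value(asgbc:::ad_sum(asgbc:::ad_square(
        asgbc:::g_extractor(fx, asgbc:::ad_const(x)))))
    }
    node <- asgbc:::ad_sum(asgbc:::ad_square(
      asgbc:::g_extractor(fx, asgbc:::ad_const(x))))
    asgbc:::ad_zero_grad(asgbc:::flatten_params(fx$params))
    asgbc:::ad_backward(node)
    ga <- as.numeric(fx$params$proj$W$grad)
    gn <- as.numeric(num_grad(function(v) loss_for(asgbc:::keep_dim(v, W0)), W0,
                              eps = 1e-5))
    fx$params$proj$W$val <- W0
    expect_lt(max(abs(ga - gn)) / max(1, max(abs(ga))), 1e-5)
  })
})
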
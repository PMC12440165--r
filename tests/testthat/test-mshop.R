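# The MsHop block against literal straight-line oracles and its contractual
# degeneracies.

mk_cfg <- function(H = 8, W = 8, D = 8) mshop_config(H, W, D)

test_that("hierarchical multi-scale stage matches the literal recursion", {
  withr::with_seed(42, {
    cfg <- mk_cfg()
    w <- mshop_init(cfg)
    F <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
    expect_equal(hierarchical_multiscale(F, w), oracle_hierarchical(F, w),
                 tolerance = 1e-6)
    # zero input through bias-free weights stays zero (linearity)
    expect_equal(hierarchical_multiscale(array(0, c(8, 8, 8)), w),
                 array(0, c(8, 8, 8)), tolerance = 1e-12)
  })
})

test_that("Dirac kernels with identity fusion yield cumulative group sums", {
  # 4x4x4: one channel per group; each 3x3 kernel passes its input through,
  # so S_i accumulates F_1 + ... + F_i; identity 1x1 fusion exposes them.
  F <- array(stats::rnorm(4 * 4 * 4), c(4, 4, 4))
  dirac <- array(0, c(3, 3, 1, 1)); dirac[2, 2, 1, 1] <- 1
  w <- list(ms = list(k1 = dirac, b1 = 0, k2 = dirac, b2 = 0,
                      k3 = dirac, b3 = 0, k4 = dirac, b4 = 0,
                      fuse = array(diag(4), c(1, 1, 4, 4)), fuse_b = numeric(4)))
  out <- hierarchical_multiscale(F, w)
  for (i in 1:4)
    expect_equal(out[, , i], apply(F[, , 1:i, drop = FALSE], c(1, 2), sum),
                 tolerance = 1e-12)
})

test_that("directional covariances are exact, symmetric and PSD", {
  withr::with_seed(7, {
    cfg <- mshop_config(4, 4, 8, H_red = 2, W_red = 2, D_red = 2)
    w <- mshop_init(cfg)
    F <- array(stats::rnorm(4 * 4 * 8), c(4, 4, 8))
    got <- directional_covariances(F, cfg, w)
    ref <- oracle_directional_covs(F, w)
    for (nm in names(ref)) {
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-6)
      expect_lt(max(abs(got[[nm]] - t(got[[nm]]))), 1e-9)
      expect_gt(min(eigen(got[[nm]], symmetric = TRUE)$values), -1e-8)
    }
    # spatially constant input: all covariances vanish
    got0 <- directional_covariances(array(0.3, c(4, 4, 8)), cfg, w)
    for (C in got0) expect_equal(max(abs(C)), 0, tolerance = 1e-12)
  })
})

test_that("covariance attention is a sigmoid of row-conv + affine", {
  att <- list(kern = c(0.5, 1, -0.25), A = matrix(seq(-0.4, 0.7, length.out = 12), 4, 3),
              b = c(0.1, -0.2, 0, 0.3))
  C <- matrix(c(1, 0.2, -0.1, 0.2, 2, 0.5, -0.1, 0.5, 1.5), 3, 3)
  got <- covariance_attention(C, 4L, att)
  expect_equal(got, oracle_attention(C, att), tolerance = 1e-9)
  expect_true(all(got > 0 & got < 1))
  # zero matrix with bias-free weights: exactly sigmoid(0) = 0.5
  att0 <- list(kern = c(0.3, -0.7, 0.2), A = matrix(stats::rnorm(12), 4, 3),
               b = numeric(4))
  expect_equal(covariance_attention(matrix(0, 3, 3), 4L, att0), rep(0.5, 4))
})

test_that("mshop block: shape, residual degeneracy and oracle equivalence", {
  withr::with_seed(11, {
    cfg <- mshop_config(16, 16, 8)
    w <- mshop_init(cfg)
    F <- array(stats::rnorm(16 * 16 * 8), c(16, 16, 8))
    out <- mshop_block(F, cfg, w)
    expect_identical(dim(out), dim(F))
    # zeroed final fusion: pure residual identity
    w0 <- w
    w0$out$fuse[] <- 0; w0$out$fuse_b[] <- 0
    expect_equal(mshop_block(F, cfg, w0), F, tolerance = 1e-12)
    # full composition against the literal oracle
    cfg8 <- mk_cfg()
    w8 <- mshop_init(cfg8)
    F8 <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
    expect_batched_matches_oracle(F8, cfg8, w8)
  })
})

test_that("oracle equivalence holds across random shapes and weights", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      H <- sample(5:8, 1); W <- sample(5:8, 1); D <- 4 * sample(1:2, 1)
      cfg <- mshop_config(H, W, D, D_red = 2)
      w <- mshop_init(cfg)
      F <- array(stats::rnorm(H * W * D), c(H, W, D))
      expect_batched_matches_oracle(F, cfg, w)
    }
  })
})

test_that("two forward passes agree bit for bit", {
  withr::with_seed(3, {
    cfg <- mk_cfg()
    w <- mshop_init(cfg)
    F <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
    expect_identical(mshop_block(F, cfg, w), mshop_block(F, cfg, w))
  })
})

test_that("configuration errors are raised", {
  expect_error(mshop_config(8, 8, 6), "divisible by 4")
  expect_error(mshop_config(8, 8, 8, W_red = 8), "strictly smaller")
  expect_error(mshop_config(3, 8, 8, H_red = 1), "strictly smaller|below 2")
  withr::with_seed(1, {
    cfg <- mk_cfg()
    w <- mshop_init(cfg)
    bad <- array(NA_real_, c(8, 8, 8))
    expect_error(mshop_block(bad, cfg, w), "finite")
    expect_error(covariance_attention(matrix(0, 3, 3), 0L, w$att$W), "target_len")
  })
})
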
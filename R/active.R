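# Phase 1: variational-adversarial active data selection.
#
# A beta-VAE learns a latent representation of all images while a
# discriminator is trained to tell latents of already-selected ("labeled
# pool") images from the rest. The VAE simultaneously tries to fool the
# discriminator into calling everything selected, so the discriminator's
# score becomes a learned measure of how well a sample is covered by the
# current selection: unselected-looking samples (lowest scores) are the most
# informative and are acquired first. The whole phase never reads labels.

#' Active-learning configuration
#'
#' @param latent_dim VAE latent dimension.
#' @param beta Weight of the KL term in the VAE objective.
#' @param lambda1,lambda2 Weights of the transductive and adversarial parts of
#'   the combined VAE objective.
#' @param init_fraction Fraction of the pool selected uniformly at random
#'   before the game starts.
#' @param budget_schedule Increasing label-budget fractions; acquisition tops
#'   the selected pool up to each in turn.
#' @param epochs Training epochs of the VAE/discriminator game.
#' @param lr_vae,lr_disc Adam learning rates for the VAE and discriminator.
#' @param batch_size Minibatch size per pool.
#' @param hidden Hidden width of the encoder/decoder/discriminator MLPs.
#' @param vae_image_size Images are resized to this side length and flattened
#'   before entering the VAE.
#' @param seed RNG seed governing initialization, minibatching and the random
#'   initial selection.
#' @return A list of class `al_config`.
#' @export
al_config <- function(latent_dim = 32L, beta = 1, lambda1 = 1, lambda2 = 1,
                      init_fraction = 0.05,
                      budget_schedule = c(0.15, 0.25, 0.35),
                      epochs = 10L, lr_vae = 1e-3, lr_disc = 1e-3,
                      batch_size = 64L, hidden = 256L, vae_image_size = 32L,
                      seed = 1L) {
  if (!(init_fraction > 0 && init_fraction < min(budget_schedule)))
    stop("al_config: need 0 < init_fraction < min(budget_schedule)")
  if (any(diff(budget_schedule) <= 0) || max(budget_schedule) > 1)
    stop("al_config: budget_schedule must be strictly increasing and <= 1")
  structure(list(latent_dim = as.integer(latent_dim), beta = beta,
                 lambda1 = lambda1, lambda2 = lambda2,
                 init_fraction = init_fraction,
                 budget_schedule = budget_schedule,
                 epochs = as.integer(epochs), lr_vae = lr_vae,
                 lr_disc = lr_disc, batch_size = as.integer(batch_size),
                 hidden = as.integer(hidden),
                 vae_image_size = as.integer(vae_image_size),
                 seed = as.integer(seed)),
            class = "al_config")
}

vae_init <- function(p, hidden, latent_dim) {
  list(enc = list(W = init_linear(p, hidden), b = numeric(hidden)),
       mu = list(W = init_linear(hidden, latent_dim), b = numeric(latent_dim)),
       lv = list(W = 0.1 * init_linear(hidden, latent_dim), b = numeric(latent_dim)),
       dec1 = list(W = init_linear(latent_dim, hidden), b = numeric(hidden)),
       dec2 = list(W = init_linear(hidden, p), b = numeric(p)))
}

disc_init <- function(latent_dim, hidden = 64L) {
  mlp_init(c(latent_dim, hidden, hidden, 1L))
}

# encoder graph: x node (n x p) -> list(mu, lv) nodes
g_vae_encode <- function(x, vp) {
  h <- ad_relu(ad_add_rowvec(ad_matmul(x, vp$enc$W), vp$enc$b))
  list(mu = ad_add_rowvec(ad_matmul(h, vp$mu$W), vp$mu$b),
       lv = ad_add_rowvec(ad_matmul(h, vp$lv$W), vp$lv$b))
}

g_vae_decode <- function(z, vp) {
  h <- ad_relu(ad_add_rowvec(ad_matmul(z, vp$dec1$W), vp$dec1$b))
  ad_sigmoid(ad_add_rowvec(ad_matmul(h, vp$dec2$W), vp$dec2$b))
}

# per-pool VAE term: squared reconstruction error (summed over pixels,
# averaged over the batch — the balance that keeps the posterior informative
# against the summed KL) + beta * batch-mean KL
g_vae_pool_loss <- function(x, vp, beta, noise) {
  enc <- g_vae_encode(x, vp)
  z <- ad_add(enc$mu, ad_mul(ad_exp(ad_smul(enc$lv, 0.5)), ad_const(noise)))
  xhat <- g_vae_decode(z, vp)
  recon <- ad_smul(ad_sum(ad_square(ad_sub(xhat, x))), 1 / nrow(noise))
  n <- nrow(noise)
  kl <- ad_smul(ad_sum(ad_sub(ad_smul(ad_add(ad_square(enc$mu),
                                             ad_exp(enc$lv)), 0.5),
                              ad_smul(ad_sadd(enc$lv, 1), 0.5))), 1 / n)
  list(loss = ad_add(recon, ad_smul(kl, beta)), z = z, mu = enc$mu)
}

# discriminator logits for a latent matrix node
g_disc_logits <- function(z, dp) mlp_forward(z, dp)

#' Transductive VAE loss
#'
#' Reconstruction error plus `beta` times the Gaussian KL to the unit prior,
#' summed over the selected-pool and unselected-pool batches. Reconstruction
#' is the mean squared pixel error of the decoded latent; the KL of a
#' diagonal posterior `N(mu, exp(lv))` against `N(0, I)` is
#' `0.5 * sum(mu^2 + exp(lv) - 1 - lv)` per sample, averaged over the batch.
#' With `noise = NULL` the posterior mean is decoded (deterministic); pass
#' standard-normal draws to reproduce a reparameterized training step.
#'
#' @param batch_S,batch_U `n x p` matrices of flattened images from the
#'   selected and unselected pools.
#' @param vae_weights Weight list from `vae_init` (plain arrays).
#' @param cfg An [al_config()] (uses `beta`).
#' @param noise_S,noise_U Optional `n x latent_dim` standard-normal draws.
#' @return Scalar loss; signals an error naming the offending term if it is
#'   non-finite.
#' @export
vae_transductive_loss <- function(batch_S, batch_U, vae_weights, cfg,
                                  noise_S = NULL, noise_U = NULL) {
  if (nrow(batch_S) < 1 || nrow(batch_U) < 1)
    stop("vae_transductive_loss: both batches must be non-empty")
  ld <- ncol(vae_weights$mu$W)
  if (is.null(noise_S)) noise_S <- matrix(0, nrow(batch_S), ld)
  if (is.null(noise_U)) noise_U <- matrix(0, nrow(batch_U), ld)
  ls <- g_vae_pool_loss(ad_const(batch_S), vae_weights, cfg$beta, noise_S)
  lu <- g_vae_pool_loss(ad_const(batch_U), vae_weights, cfg$beta, noise_U)
  val <- ad_value(ls$loss) + ad_value(lu$loss)
  if (!is.finite(val))
    stop("vae_transductive_loss diverged (",
         if (!is.finite(ad_value(ls$loss))) "selected-pool term" else "unselected-pool term",
         " is non-finite)")
  val
}

clip_probs <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    if (any(p <= 0)) warning("discriminator scores at 0 clipped to 1e-12")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  p
}

#' Adversarial VAE loss
#'
#' The VAE side of the minimax game: `-mean(log dS) - mean(log dU)` — the VAE
#' wants the discriminator to call every latent "selected".
#'
#' @param d_scores_S,d_scores_U Discriminator probabilities in (0, 1).
#' @return Nonnegative scalar.
#' @export
vae_adversarial_loss <- function(d_scores_S, d_scores_U) {
  -mean(log(clip_probs(d_scores_S))) - mean(log(clip_probs(d_scores_U)))
}

#' Discriminator loss
#'
#' `-mean(log dS) - mean(log(1 - dU))`: the discriminator labels
#' selected-pool latents 1 and unselected-pool latents 0.
#'
#' @param d_scores_S,d_scores_U Discriminator probabilities in (0, 1).
#' @return Nonnegative scalar.
#' @export
discriminator_loss <- function(d_scores_S, d_scores_U) {
  -mean(log(clip_probs(d_scores_S))) - mean(log(1 - clip_probs(d_scores_U)))
}

#' Combined VAE objective
#'
#' `lambda1 * L_trd + lambda2 * L_adv`.
#'
#' @param L_trd,L_adv Scalar transductive and adversarial losses.
#' @param cfg An [al_config()].
#' @return Scalar.
#' @export
combined_vae_loss <- function(L_trd, L_adv, cfg) {
  cfg$lambda1 * L_trd + cfg$lambda2 * L_adv
}

#' Pick the most informative unselected samples
#'
#' Returns exactly `budget` positions with the smallest discriminator scores
#' (lowest predicted probability of already belonging to the selected pool).
#' Ties break by ascending original index; the result is ordered by score,
#' then index.
#'
#' @param d_scores_U Numeric scores over the unselected pool.
#' @param budget Number of samples to acquire; must not exceed the pool.
#' @return Integer positions into `d_scores_U`.
#' @export
select_informative <- function(d_scores_U, budget) {
  if (budget > length(d_scores_U))
    stop("select_informative: budget exceeds the unselected pool")
  if (budget == 0) return(integer(0))
  ord <- order(d_scores_U, seq_along(d_scores_U))
  ord[seq_len(budget)]
}

new_data_pool <- function(selected, unselected, universe_size, log = list(),
                          seed = NA_integer_) {
  structure(list(selected = sort(as.integer(selected)),
                 unselected = sort(as.integer(unselected)),
                 universe_size = as.integer(universe_size), log = log,
                 seed = seed),
            class = "data_pool")
}

validate_data_pool <- function(pool) {
  stopifnot(length(intersect(pool$selected, pool$unselected)) == 0,
            setequal(c(pool$selected, pool$unselected),
                     seq_len(pool$universe_size)))
  invisible(pool)
}

#' @export
print.data_pool <- function(x, ...) {
  cat(sprintf("<data_pool> %d/%d selected (%.1f%%), %d acquisition round(s)\n",
              length(x$selected), x$universe_size,
              100 * length(x$selected) / x$universe_size, length(x$log)))
  invisible(x)
}

#' Run active data selection (Phase 1)
#'
#' Initializes the selected pool with `ceiling(init_fraction * N)` uniformly
#' random samples, plays the VAE/discriminator game for `cfg$epochs` epochs,
#' then acquires the lowest-scoring unselected samples round by round until
#' each budget fraction is met. Selection scores are discriminator outputs on
#' latent posterior means, so acquisition is deterministic given the trained
#' weights. The label column of the manifest is never consulted.
#'
#' @param manifest Data frame with at least `image_path` (labels are ignored).
#' @param cfg An [al_config()].
#' @param images Optional preloaded image array `(H, W, N)` in `[0, 1]`,
#'   ordered as the manifest; loaded from `image_path` when omitted.
#' @param initial Optional integer indices of an already-annotated seed set;
#'   when omitted, `ceiling(init_fraction * N)` samples are drawn uniformly.
#' @return A `data_pool` with per-round logs (`budget`, acquired indices,
#'   score summaries) and the seed.
#' @export
run_active_selection <- function(manifest, cfg, images = NULL, initial = NULL) {
  if (is.null(images)) images <- load_images(manifest$image_path)
  N <- dim(images)[3]
  stopifnot(N == nrow(manifest))
  sz <- cfg$vae_image_size
  X <- t(vapply(seq_len(N),
                function(i) as.numeric(resize_image(images[, , i], sz)),
                numeric(sz * sz)))
  withr::with_seed(cfg$seed, {
    selected <- if (is.null(initial))
      sort(sample.int(N, ceiling(cfg$init_fraction * N)))
    else sort(as.integer(initial))
    unselected <- setdiff(seq_len(N), selected)
    p <- sz * sz
    vp <- params_from_weights(vae_init(p, cfg$hidden, cfg$latent_dim))
    dp <- params_from_weights(disc_init(cfg$latent_dim))
    opt_v <- adam_new(vp, lr = cfg$lr_vae)
    opt_d <- adam_new(dp, lr = cfg$lr_disc)
    steps <- max(1L, ceiling(N / cfg$batch_size))
    train_game <- function() {
    for (ep in seq_len(cfg$epochs)) {
      for (st in seq_len(steps)) {
        bs <- sample(selected, min(cfg$batch_size, length(selected)),
                     replace = length(selected) < cfg$batch_size)
        bu <- sample(unselected, min(cfg$batch_size, length(unselected)))
        nS <- matrix(stats::rnorm(length(bs) * cfg$latent_dim), length(bs))
        nU <- matrix(stats::rnorm(length(bu) * cfg$latent_dim), length(bu))
        # --- VAE update: transductive + adversarial ---
        ls <- g_vae_pool_loss(ad_const(X[bs, , drop = FALSE]), vp, cfg$beta, nS)
        lu <- g_vae_pool_loss(ad_const(X[bu, , drop = FALSE]), vp, cfg$beta, nU)
        adv <- ad_add(ad_mean(ad_softplus(ad_neg(g_disc_logits(ls$z, dp)))),
                      ad_mean(ad_softplus(ad_neg(g_disc_logits(lu$z, dp)))))
        lvae <- ad_add(ad_smul(ad_add(ls$loss, lu$loss), cfg$lambda1),
                       ad_smul(adv, cfg$lambda2))
        ad_zero_grad(c(flatten_params(vp), flatten_params(dp)))
        ad_backward(lvae)
        opt_v <- adam_step(opt_v)
        # --- discriminator update on detached latents ---
        zS <- ad_const(ad_value(ls$z)); zU <- ad_const(ad_value(lu$z))
        ld <- ad_add(ad_mean(ad_softplus(ad_neg(g_disc_logits(zS, dp)))),
                     ad_mean(ad_softplus(g_disc_logits(zU, dp))))
        ad_zero_grad(flatten_params(dp))
        ad_backward(ld)
        opt_d <- adam_step(opt_d)
      }
    }
    }
    # --- per-round game training + acquisition on latent means ---
    # the game is (re)trained before every acquisition round so later rounds
    # score against the grown labeled pool instead of re-ranking a single
    # frozen score list (which would acquire redundant neighbors)
    score_all <- function(idx) {
      mu <- ad_value(g_vae_encode(ad_const(X[idx, , drop = FALSE]), vp)$mu)
      as.numeric(1 / (1 + exp(-ad_value(g_disc_logits(ad_const(mu), dp)))))
    }
    log <- list()
    for (b in cfg$budget_schedule) {
      target <- ceiling(b * N)
      need <- target - length(selected)
      if (need <= 0) next
      train_game()
      scores <- score_all(unselected)
      pick <- select_informative(scores, min(need, length(unselected)))
      acquired <- unselected[pick]
      selected <- sort(c(selected, acquired))
      unselected <- setdiff(unselected, acquired)
      log[[length(log) + 1L]] <- list(budget = b, n_selected = length(selected),
                                      acquired = acquired,
                                      score_range = range(scores))
    }
    validate_data_pool(new_data_pool(selected, unselected, N, log, cfg$seed))
  })
}
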
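# Phases 2 and 3: self-supervised pretraining of the feature extractor on the
# selected pool, and the frozen-backbone linear probe — plus the end-to-end
# orchestration (select -> pretrain -> probe -> evaluate).

#' Training configuration
#'
#' Defaults are the published settings: Adam with `beta1 = 0.9`, batch size
#' 64, initial learning rate 0.003, weight decay 1e-6, a cosine schedule and
#' 800 optimizer steps ("iterations" count optimizer steps, not epochs;
#' batches are drawn as shuffled epochs without replacement). Desk-scale runs
#' pass smaller `iterations`/`batch_size`.
#'
#' @param iterations Number of optimizer steps of Phase 2.
#' @param batch_size Samples per step (>= 2; the variance and covariance
#'   terms are undefined for a single sample).
#' @param lr Initial learning rate.
#' @param beta1 Adam first-moment decay (the "momentum" of the optimizer).
#' @param weight_decay L2 weight decay.
#' @param schedule `"cosine"` or `"constant"`.
#' @param probe_steps,probe_lr,probe_wd Linear-probe optimizer steps,
#'   learning rate and ridge (weight-decay) strength; the ridge keeps the
#'   probe sample-efficient at small label budgets.
#' @param seed RNG seed for initialization, batching and augmentation.
#' @param deterministic Kept for the configuration contract; all compute here
#'   is single-threaded and deterministic given the seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(iterations = 800L, batch_size = 64L, lr = 0.003,
                         beta1 = 0.9, weight_decay = 1e-6,
                         schedule = c("cosine", "constant"),
                         probe_steps = 300L, probe_lr = 0.05, probe_wd = 0.01,
                         seed = 1L, deterministic = TRUE) {
  schedule <- match.arg(schedule)
  stopifnot(iterations >= 1, batch_size >= 2, lr > 0, probe_steps >= 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 weight_decay = weight_decay, schedule = schedule,
                 probe_steps = as.integer(probe_steps), probe_lr = probe_lr,
                 probe_wd = probe_wd,
                 seed = as.integer(seed), deterministic = isTRUE(deterministic)),
            class = "train_config")
}

safe_row_normalize <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)

#' Self-supervised pretraining of the feature extractor (Phase 2)
#'
#' Runs the dual-branch training loop on the selected pool: two augmented
#' views per batch, extractor and expander forward passes, transport codes
#' from the current prototypes (no gradient through the assignment), the
#' contrastive + clustering loss, and an Adam step with the configured
#' schedule. Labels are never consulted. A non-finite loss aborts the run and
#' returns the last good weight snapshot.
#'
#' @param pool A `data_pool`; only `pool$selected` images are used.
#' @param manifest Manifest data frame aligned with `images` (used for
#'   bookkeeping only; the label column may be absent).
#' @param images Image array `(H, W, N)` aligned with the manifest.
#' @param backbone_cfg A [backbone_config()].
#' @param loss_w A [loss_weights()]; `alpha = 0` disables the clustering
#'   branch (the contrastive-only baseline configuration).
#' @param train_cfg A [train_config()].
#' @param policy An [augmentation_policy()].
#' @return A checkpoint list (weights, prototypes, optimizer state, iteration
#'   counter, config hash, seed) with the per-iteration loss log attached.
#' @export
pretrain_extractor <- function(pool, manifest, images,
                               backbone_cfg = backbone_config(),
                               loss_w = loss_weights(),
                               train_cfg = train_config(),
                               policy = augmentation_policy()) {
  sel <- pool$selected
  if (length(sel) < 2) stop("pretrain_extractor: selected pool too small")
  imgs <- images[, , sel, drop = FALSE]
  n <- length(sel)
  bs <- min(train_cfg$batch_size, n)
  withr::with_seed(train_cfg$seed, {
    fx <- build_feature_extractor(backbone_cfg)
    exp_p <- params_from_weights(expander_init(backbone_cfg$embed_dim))
    protos <- ad_param(prototype_bank(loss_w$K, backbone_cfg$embed_dim)$data)
    all_p <- list(backbone = fx$params, expander = exp_p, protos = protos)
    opt <- adam_new(all_p, lr = train_cfg$lr, beta1 = train_cfg$beta1,
                    weight_decay = train_cfg$weight_decay)
    perm <- sample(n); pos <- 1L
    log <- matrix(NA_real_, train_cfg$iterations, 3,
                  dimnames = list(NULL, c("L_con", "L_clu", "L_total")))
    snapshot <- weights_from_params(all_p)
    aborted <- FALSE
    it <- 0L
    while (it < train_cfg$iterations) {
      it <- it + 1L
      if (pos + bs - 1L > n) { perm <- sample(n); pos <- 1L }
      idx <- perm[pos:(pos + bs - 1L)]
      pos <- pos + bs
      views <- make_views(imgs[, , idx, drop = FALSE], policy,
                          seed = as.integer((as.numeric(train_cfg$seed) * 1009 +
                            it) %% 2147483629))
      x1 <- ad_const(prep_images(views$X1, backbone_cfg$in_channels))
      x2 <- ad_const(prep_images(views$X2, backbone_cfg$in_channels))
      y1 <- g_extractor(fx, x1); y2 <- g_extractor(fx, x2)
      z1 <- mlp_forward(y1, exp_p, standardize = TRUE)
      z2 <- mlp_forward(y2, exp_p, standardize = TRUE)
      loss <- g_contrastive(z1, z2, loss_w)
      l_clu_val <- 0
      if (loss_w$alpha > 0) {
        Cv <- safe_row_normalize(protos$val)
        Q1 <- compute_codes(safe_row_normalize(ad_value(y1)) %*% t(Cv), loss_w)
        Q2 <- compute_codes(safe_row_normalize(ad_value(y2)) %*% t(Cv), loss_w)
        l_clu <- ad_add(g_swapped_xent(y1, protos, Q2, loss_w$tau),
                        g_swapped_xent(y2, protos, Q1, loss_w$tau))
        l_clu_val <- ad_value(l_clu)
        loss <- ad_add(loss, ad_smul(l_clu, loss_w$alpha))
      }
      ltot <- ad_value(loss)
      log[it, ] <- c(ltot - loss_w$alpha * l_clu_val, l_clu_val, ltot)
      if (!is.finite(ltot)) {
        warning("non-finite loss at iteration ", it,
                "; aborting with the last good checkpoint", call. = FALSE)
        assign_weights(all_p, snapshot)
        aborted <- TRUE
        break
      }
      ad_zero_grad(flatten_params(all_p))
      ad_backward(loss)
      lr <- if (train_cfg$schedule == "cosine")
        cosine_lr(it, train_cfg$iterations, train_cfg$lr) else train_cfg$lr
      opt <- adam_step(opt, lr = lr)
      protos$val <- safe_row_normalize(protos$val)
      if (it %% 10L == 0L) snapshot <- weights_from_params(all_p)
    }
    config <- list(backbone = unclass(backbone_cfg), loss = unclass(loss_w),
                   train = unclass(train_cfg), policy = unclass(policy))
    list(version = ckpt_version,
         config = config,
         config_hash = config_hash(config),
         backbone_weights = weights_from_params(fx$params),
         expander_weights = weights_from_params(exp_p),
         prototypes = protos$val,
         optimizer = list(t = opt$t, m = opt$m, v = opt$v),
         iteration = it, aborted = aborted,
         seed = train_cfg$seed,
         log = as.data.frame(cbind(iter = seq_len(nrow(log)), log)))
  })
}

#' Linear probe on the frozen backbone (Phase 3)
#'
#' Embeds the selected images with the frozen extractor, standardizes the
#' embedding dimensions, and fits one affine layer (embed_dim -> 3) by
#' softmax cross-entropy with Adam. Backbone parameters are untouched.
#'
#' @param ckpt Checkpoint from [pretrain_extractor()].
#' @param pool A `data_pool`; every selected sample must carry a label.
#' @param manifest Manifest with labels, aligned with `images`.
#' @param images Image array `(H, W, N)`.
#' @param train_cfg A [train_config()] (uses `probe_steps`, `probe_lr`,
#'   `seed`).
#' @return An `asgbc_model`: frozen extractor + probe, usable with
#'   [predict.asgbc_model()].
#' @export
linear_probe <- function(ckpt, pool, manifest, images,
                         train_cfg = train_config()) {
  sel <- pool$selected
  labs <- manifest$label[sel]
  if (any(is.na(labs) | labs == ""))
    stop("linear_probe: every selected sample needs a label")
  fx <- extractor_freeze(extractor_from_checkpoint(ckpt))
  emb <- extractor_forward(fx, images[, , sel, drop = FALSE])
  mu <- colMeans(emb)
  sdv <- pmax(apply(emb, 2, stats::sd), 1e-8)
  embs <- sweep(sweep(emb, 2, mu), 2, sdv, "/")
  y <- factor(labs, levels = phantom_classes)
  onehot <- diag(3)[as.integer(y), , drop = FALSE]
  withr::with_seed(train_cfg$seed, {
    W <- ad_param(matrix(0, ncol(embs), 3L))
    b <- ad_param(numeric(3L))
    wd <- if (is.null(train_cfg$probe_wd)) 0 else train_cfg$probe_wd
    opt <- adam_new(list(W, b), lr = train_cfg$probe_lr, weight_decay = wd)
    for (st in seq_len(train_cfg$probe_steps)) {
      logits <- ad_add_rowvec(ad_matmul(ad_const(embs), W), b)
      loss <- ad_softmax_xent(logits, onehot)
      ad_zero_grad(list(W, b))
      ad_backward(loss)
      opt <- adam_step(opt)
    }
    structure(list(extractor = fx, probe = list(W = W$val, b = b$val),
                   feature_center = mu, feature_scale = sdv,
                   classes = phantom_classes),
              class = "asgbc_model")
  })
}

#' Predict classes for new images
#'
#' @param object An `asgbc_model`.
#' @param images Image array `(H, W, N)`.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Character labels or an `N x 3` probability matrix.
#' @export
predict.asgbc_model <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  emb <- extractor_forward(object$extractor, images)
  embs <- sweep(sweep(emb, 2, object$feature_center), 2, object$feature_scale, "/")
  logits <- sweep(embs %*% object$probe$W, 2, object$probe$b, "+")
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits) / rowSums(exp(logits))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' @export
print.asgbc_model <- function(x, ...) {
  cat("<asgbc_model> frozen", x$extractor$cfg$architecture,
      "extractor + linear probe over", paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

# Patient-grouped holdout, stratified by class when labels are available so
# every class is represented on both sides.
split_patients <- function(manifest, test_fraction, seed) {
  test_p <- withr::with_seed(as.integer(seed), {
    if (!is.null(manifest$label)) {
      cls_of <- tapply(manifest$label, manifest$patient_id,
                       function(x) x[1])
      unlist(lapply(split(names(cls_of), unname(cls_of)), function(ps) {
        sample(ps, max(1L, round(test_fraction * length(ps))))
      }), use.names = FALSE)
    } else {
      patients <- unique(manifest$patient_id)
      sample(patients, max(1L, round(test_fraction * length(patients))))
    }
  })
  list(train = which(!manifest$patient_id %in% test_p),
       test = which(manifest$patient_id %in% test_p))
}

#' Run the full three-phase pipeline
#'
#' Holds out a patient-grouped test split, runs active (or uniform random)
#' selection on the training pool to the label budget, pretrains the
#' extractor on the selected images, fits the linear probe on their labels,
#' and evaluates on the held-out patients. With `dir` set, writes
#' `pool.json`, `checkpoint.rds` (+ YAML sidecar), `metrics.json` and
#' `run_log.csv`.
#'
#' @param manifest Manifest with labels.
#' @param images Image array `(H, W, N)` aligned with the manifest; loaded
#'   from `image_path` when `NULL`.
#' @param budget Label-budget fraction of the training pool; `1` uses every
#'   training sample (selection is skipped).
#' @param selection `"active"` or `"random"` (the ablation arm).
#' @param test_fraction Fraction of patients held out for evaluation.
#' @param al_cfg,backbone_cfg,loss_w,train_cfg,policy Phase configurations.
#' @param pretrain_epochs If set, overrides `train_cfg$iterations` with
#'   `ceiling(pretrain_epochs * n_selected / batch_size)` (at least 10), so
#'   every budget sees the same number of passes over its selected pool.
#' @param seed Master seed; overrides the seeds inside `al_cfg`/`train_cfg`
#'   and drives the patient split.
#' @param dir Optional artifact directory.
#' @return List with `metrics` (five headline metrics + confusion matrix),
#'   `model`, `pool`, `checkpoint`, `split` and the loss `log`.
#' @export
run_asgbc <- function(manifest, images = NULL, budget = 0.35,
                      selection = c("active", "random"), test_fraction = 0.2,
                      al_cfg = al_config(), backbone_cfg = backbone_config(),
                      loss_w = loss_weights(), train_cfg = train_config(),
                      policy = augmentation_policy(), pretrain_epochs = NULL,
                      seed = 1L, dir = NULL) {
  selection <- match.arg(selection)
  if (is.null(images)) images <- load_images(manifest$image_path)
  al_cfg$seed <- as.integer(seed)
  train_cfg$seed <- as.integer(seed) + 1L
  split <- split_patients(manifest, test_fraction, seed)
  tr_manifest <- manifest[split$train, , drop = FALSE]
  tr_images <- images[, , split$train, drop = FALSE]
  n_tr <- length(split$train)
  if (budget >= 1) {
    pool <- new_data_pool(seq_len(n_tr), integer(0), n_tr, seed = seed)
  } else if (selection == "active") {
    # keep the configured intermediate rounds below the requested budget
    al_cfg$budget_schedule <- sort(unique(c(
      al_cfg$budget_schedule[al_cfg$budget_schedule < budget], budget)))
    pool <- run_active_selection(tr_manifest[, c("image_path", "patient_id")],
                                 al_cfg, tr_images)
  } else {
    k <- ceiling(budget * n_tr)
    sel <- withr::with_seed(as.integer(seed), sort(sample.int(n_tr, k)))
    pool <- new_data_pool(sel, setdiff(seq_len(n_tr), sel), n_tr, seed = seed)
  }
  if (!is.null(pretrain_epochs))
    train_cfg$iterations <- max(10L, as.integer(ceiling(
      pretrain_epochs * length(pool$selected) / train_cfg$batch_size)))
  ckpt <- pretrain_extractor(pool, tr_manifest, tr_images, backbone_cfg,
                             loss_w, train_cfg, policy)
  model <- linear_probe(ckpt, pool, tr_manifest, tr_images, train_cfg)
  pred <- predict(model, images[, , split$test, drop = FALSE])
  metrics <- confusion_and_metrics(manifest$label[split$test], pred)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(list(selected = pool$selected,
                              unselected = pool$unselected,
                              budgets = budget, seed = seed),
                         file.path(dir, "pool.json"), auto_unbox = TRUE)
    save_checkpoint(ckpt, file.path(dir, "checkpoint.rds"))
    jsonlite::write_json(metrics[metric_names],
                         file.path(dir, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(ckpt$log, file.path(dir, "run_log.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics, model = model, pool = pool, checkpoint = ckpt,
       split = split, log = ckpt$log)
}
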
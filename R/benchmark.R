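# Desk-scale benchmark harnesses on the synthetic phantom cohort: the
# label-efficiency comparison (active vs random selection vs full data), the
# component ablation, and the noise-robustness sweep. Problem sizes are the
# package's desk-scale study conditions; each harness is deterministic given
# its seed vector.

desk_backbone_config <- function(mshop = TRUE) {
  backbone_config("micro",
                  mshop_stages = if (mshop) c(2L, 3L) else integer(0),
                  input_size = 64L, in_channels = 1L, embed_dim = 64L)
}

# Desk-scale schedule: published optimizer settings (Adam, lr 0.003, cosine)
# with iterations scaled to equal passes over the selected pool.
desk_train_config <- function(seed, iterations = 100L, batch_size = 64L,
                              lr = 0.003) {
  train_config(iterations = iterations, batch_size = batch_size, lr = lr,
               seed = seed)
}

desk_al_config <- function(seed, budget) {
  # single-budget schedule: each budget is its own experiment in the
  # label-efficiency protocol
  al_config(epochs = 6L, budget_schedule = budget, seed = seed)
}

#' Label-efficiency benchmark (active vs random vs full data)
#'
#' For each seed, generates a fresh phantom cohort, holds out a
#' patient-grouped test split, and runs the pipeline three times on the same
#' data: actively selected budget, uniformly random budget of the same size,
#' and the full training pool. Reports test metrics per arm and seed.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_patients,images_per_patient Cohort size (default roughly 600
#'   images).
#' @param budget Label-budget fraction for the selection arms.
#' @param pretrain_epochs Passes over the selected pool during Phase 2
#'   (iterations scale with the pool so every arm gets equal optimization
#'   pressure).
#' @param batch_size Phase 2 batch size.
#' @param al_latent_dim Latent dimension of the selection VAE. The desk
#'   default is deliberately small: a low-capacity latent encodes coarse
#'   class-relevant appearance rather than patient identity, so acquisition
#'   diversifies across appearance instead of hoarding every image of a few
#'   unusual patients.
#' @param loss_w A [loss_weights()].
#' @param arms Subset of `c("active", "random", "full")`.
#' @return Data frame: seed, arm, and the five test metrics.
#' @export
label_efficiency_benchmark <- function(seeds = 1:5, n_patients = 150L,
                                       images_per_patient = c(3L, 5L),
                                       budget = 0.35, pretrain_epochs = 7,
                                       batch_size = 64L, al_latent_dim = 8L,
                                       loss_w = loss_weights(),
                                       arms = c("active", "random", "full")) {
  rows <- list()
  for (s in seeds) {
    ds <- generate_dataset(phantom_config(n_patients = n_patients,
                                          images_per_patient = images_per_patient,
                                          seed = 20000L + s))
    for (arm in arms) {
      res <- run_asgbc(ds$manifest, ds$images,
                       budget = if (arm == "full") 1 else budget,
                       selection = if (arm == "random") "random" else "active",
                       al_cfg = {ac <- desk_al_config(s, budget)
                                 ac$latent_dim <- as.integer(al_latent_dim); ac},
                       backbone_cfg = desk_backbone_config(TRUE),
                       loss_w = loss_w,
                       train_cfg = desk_train_config(s, batch_size = batch_size),
                       pretrain_epochs = pretrain_epochs,
                       seed = s)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, arm = arm, t(unlist(res$metrics[metric_names])))
    }
  }
  do.call(rbind, rows)
}

ablation_arm_settings <- list(
  baseline = list(mshop = FALSE, alpha = 0),
  mshop    = list(mshop = TRUE,  alpha = 0),
  loss     = list(mshop = FALSE, alpha = 0.1),
  full     = list(mshop = TRUE,  alpha = 0.1)
)

#' Component ablation benchmark
#'
#' Compares the contrastive-only baseline against enabling the MsHop block,
#' the clustering branch, or both, on identical phantom cohorts with the full
#' training pool labeled (no selection, isolating the architectural and loss
#' effects).
#'
#' @param seeds Replicate seeds.
#' @param arms Subset of `c("baseline", "mshop", "loss", "full")`.
#' @param n_patients,images_per_patient Cohort size (default roughly 240
#'   images).
#' @param pretrain_epochs,batch_size Phase 2 schedule per run.
#' @return Data frame: seed, arm, and the five test metrics.
#' @export
ablation_benchmark <- function(seeds = 1:5,
                               arms = c("baseline", "mshop", "loss"),
                               n_patients = 80L,
                               images_per_patient = c(2L, 4L),
                               pretrain_epochs = 7, batch_size = 64L) {
  rows <- list()
  for (s in seeds) {
    ds <- generate_dataset(phantom_config(n_patients = n_patients,
                                          images_per_patient = images_per_patient,
                                          seed = 30000L + s))
    for (arm in arms) {
      st <- ablation_arm_settings[[arm]]
      lw <- loss_weights(alpha = st$alpha)
      res <- run_asgbc(ds$manifest, ds$images, budget = 1,
                       backbone_cfg = desk_backbone_config(st$mshop),
                       loss_w = lw,
                       train_cfg = desk_train_config(s, batch_size = batch_size),
                       pretrain_epochs = pretrain_epochs,
                       seed = s)
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, arm = arm, t(unlist(res$metrics[metric_names])))
    }
  }
  do.call(rbind, rows)
}

#' Noise-robustness benchmark
#'
#' Trains the full configuration once per seed and re-evaluates the model on
#' test images corrupted at each noise level (spatially correlated Gaussian
#' noise, kernel sigma 5 px).
#'
#' @param seeds Replicate seeds.
#' @param levels Noise levels as fractions of the dynamic range.
#' @param n_patients,images_per_patient Cohort size.
#' @param pretrain_epochs,batch_size Phase 2 schedule per run.
#' @return Data frame: seed, level, metric values and `<metric>_drop`
#'   percentages relative to the clean run.
#' @export
noise_benchmark <- function(seeds = 1:5, levels = c(0.01, 0.05, 0.10),
                            n_patients = 100L, images_per_patient = c(3L, 3L),
                            pretrain_epochs = 7, batch_size = 64L) {
  rows <- list()
  for (s in seeds) {
    ds <- generate_dataset(phantom_config(n_patients = n_patients,
                                          images_per_patient = images_per_patient,
                                          seed = 40000L + s))
    res <- run_asgbc(ds$manifest, ds$images, budget = 1,
                     backbone_cfg = desk_backbone_config(TRUE),
                     loss_w = loss_weights(),
                     train_cfg = desk_train_config(s, batch_size = batch_size),
                     pretrain_epochs = pretrain_epochs,
                     seed = s)
    nr <- noise_robustness(res$model,
                           ds$images[, , res$split$test, drop = FALSE],
                           ds$manifest$label[res$split$test],
                           levels = levels, seed = s)
    rows[[length(rows) + 1L]] <- cbind(seed = s, nr)
  }
  do.call(rbind, rows)
}
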
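# Evaluation protocol: 3-class confusion metrics with the malignant-vs-rest
# binarization for sensitivity/specificity, patient-grouped k-fold
# cross-validation, paired t-tests with normal-approximation confidence
# intervals, relative-change arithmetic, the noise-robustness table, and
# Fréchet-style agreement (kappa) bounds between raters known only through
# marginal summaries.

metric_names <- c("accuracy", "specificity", "sensitivity", "f1_malignant",
                  "macro_f1")

f1_binary <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(0)   # no instances and no predictions
  2 * tp / (2 * tp + fp + fn)
}

#' Confusion matrix and headline metrics
#'
#' Accuracy is 3-class (trace over total). Sensitivity is the malignant
#' recall and specificity the fraction of truly non-malignant (normal and
#' benign pooled) samples predicted non-malignant. `f1_malignant` is the F1
#' of the malignant-vs-rest binarization and `macro_f1` the unweighted mean
#' of the three per-class F1 scores (a per-class F1 with neither predictions
#' nor instances is defined as 0).
#'
#' @param y_true,y_pred Label vectors over
#'   `c("normal", "benign", "malignant")`.
#' @return List with `confusion` (3x3 integer matrix, rows = truth) and the
#'   five metrics.
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  bad <- setdiff(unique(c(y_true, y_pred)), phantom_classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  ft <- factor(y_true, levels = phantom_classes)
  fp <- factor(y_pred, levels = phantom_classes)
  cm <- table(truth = ft, prediction = fp)
  total <- sum(cm)
  per_class_f1 <- vapply(phantom_classes, function(cl) {
    tp <- cm[cl, cl]
    f1_binary(tp, sum(cm[, cl]) - tp, sum(cm[cl, ]) - tp)
  }, numeric(1))
  mal <- "malignant"
  tp <- cm[mal, mal]
  list(confusion = unclass(cm),
       accuracy = sum(diag(cm)) / total,
       sensitivity = tp / sum(cm[mal, ]),
       specificity = sum(cm[phantom_classes != mal, phantom_classes != mal]) /
         sum(cm[phantom_classes != mal, ]),
       f1_malignant = unname(per_class_f1[mal]),
       macro_f1 = mean(per_class_f1))
}

metrics_vector <- function(y_true, y_pred) {
  m <- confusion_and_metrics(y_true, y_pred)
  unlist(m[metric_names])
}

#' Aggregate per-fold metrics
#'
#' @param fold_metrics Matrix (folds x metrics) or data frame of per-fold
#'   metric values.
#' @return Data frame with mean, sd and normal-approximation 95% confidence
#'   interval (`mean +- 1.96 * sd / sqrt(k)`) per metric.
#' @export
summarize_folds <- function(fold_metrics) {
  fm <- as.matrix(fold_metrics)
  k <- nrow(fm)
  mn <- colMeans(fm)
  sd <- apply(fm, 2, stats::sd)
  half <- 1.96 * sd / sqrt(k)
  data.frame(metric = colnames(fm), mean = mn, sd = sd,
             ci_lo = mn - half, ci_hi = mn + half, row.names = NULL)
}

#' Patient-grouped fold assignment
#'
#' Shuffles the distinct patients and deals them round-robin into `folds`
#' groups, so fold sizes differ by at most one patient and no patient can
#' appear on both sides of any split.
#'
#' @param patient_ids Per-sample patient identifiers.
#' @param folds Number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Integer fold id per sample.
#' @export
patient_folds <- function(patient_ids, folds = 10L, seed = 1L) {
  patients <- unique(patient_ids)
  if (length(patients) < folds)
    stop("fewer distinct patients (", length(patients), ") than folds (", folds, ")")
  shuffled <- withr::with_seed(as.integer(seed), sample(patients))
  pf <- stats::setNames(rep_len(seq_len(folds), length(shuffled)), shuffled)
  unname(pf[as.character(patient_ids)])
}

#' Patient-grouped cross-validation
#'
#' Partitions patients (never single images) into `folds` groups, calls
#' `fit_predict` once per fold with the training and validation manifest
#' rows, and aggregates the five metrics across folds.
#'
#' @param manifest Data frame with `patient_id` and `label` columns.
#' @param fit_predict `function(train_idx, test_idx)` returning predicted
#'   labels for `test_idx` (row indices into the manifest).
#' @param folds Number of folds.
#' @param seed Shuffle seed for the patient assignment.
#' @return List with `per_fold` (folds x 5 metric matrix), `summary` (from
#'   [summarize_folds()]) and `fold_of` (per-sample fold id).
#' @export
grouped_cross_validation <- function(manifest, fit_predict, folds = 10L,
                                     seed = 1L) {
  fold_of <- patient_folds(manifest$patient_id, folds, seed)
  per_fold <- matrix(NA_real_, folds, length(metric_names),
                     dimnames = list(NULL, metric_names))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    pred <- fit_predict(train_idx, test_idx)
    per_fold[f, ] <- metrics_vector(manifest$label[test_idx], pred)
  }
  list(per_fold = per_fold, summary = summarize_folds(per_fold),
       fold_of = fold_of)
}

#' Paired t-test between per-fold metric vectors
#'
#' Two-sided paired t-test at the 0.05 level. Zero-variance differences are
#' degenerate: `p` is reported as exactly 1 with `degenerate = TRUE`.
#'
#' @param metric_vec_a,metric_vec_b Equal-length per-fold metric vectors.
#' @return List with `t`, `p`, `significant`, `degenerate`.
#' @export
paired_comparison <- function(metric_vec_a, metric_vec_b) {
  stopifnot(length(metric_vec_a) == length(metric_vec_b),
            length(metric_vec_a) >= 2)
  d <- metric_vec_a - metric_vec_b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d))))
    return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE))
  tt <- tryCatch(stats::t.test(metric_vec_a, metric_vec_b, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, degenerate = FALSE)
}

#' Relative change in percent
#'
#' `100 * |new - old| / old`, rounded to `digits`; the direction is reported
#' separately so "accuracy increased by 1.7%" and "accuracy decreased by
#' 1.02%" both come out as positive percentages.
#'
#' @param old_value Reference value (> 0).
#' @param new_value New value.
#' @param digits Decimal places (1 or 2 in the usual reporting).
#' @return List with `percent` and `direction`
#'   (`"improvement"`, `"degradation"` or `"none"`).
#' @export
relative_change <- function(old_value, new_value, digits = 1) {
  if (old_value <= 0) stop("relative_change: old_value must be positive")
  pct <- round(100 * abs(new_value - old_value) / old_value, digits)
  dir <- if (new_value > old_value) "improvement"
         else if (new_value < old_value) "degradation" else "none"
  list(percent = pct, direction = dir)
}

#' Noise-robustness table
#'
#' Re-evaluates a trained model on copies of the test images corrupted by
#' [corrupt_noise()] at each level and reports, per metric, the value and the
#' relative degradation versus the clean run (two decimals).
#'
#' @param model An `asgbc_model` (see [linear_probe()]).
#' @param images Test images `(H, W, N)`.
#' @param labels True labels.
#' @param levels Noise levels (fractions of the dynamic range); 0 is always
#'   evaluated as the reference row.
#' @param kernel_sigma Spatial sigma of the noise field, pixels.
#' @param seed Base seed for the noise draws.
#' @return Data frame: one row per level, metric values and `<metric>_drop`
#'   percent columns.
#' @export
noise_robustness <- function(model, images, labels,
                             levels = c(0.01, 0.05, 0.10), kernel_sigma = 5,
                             seed = 1L) {
  levels <- sort(unique(c(0, levels)))
  rows <- list()
  clean <- NULL
  for (li in seq_along(levels)) {
    lv <- levels[li]
    imgs <- images
    if (lv > 0) {
      # one noise realization per image, shared across levels and scaled:
      # corruption severity is then nested in the level (dose-response)
      for (i in seq_len(dim(images)[3]))
        imgs[, , i] <- corrupt_noise(images[, , i], lv, kernel_sigma,
                                     seed = as.integer((as.numeric(seed) * 7919 +
                                       i) %% 2147483629))
    }
    m <- metrics_vector(labels, predict(model, imgs))
    if (lv == 0) clean <- m
    drop <- vapply(metric_names, function(nm) {
      if (lv == 0) return(0)
      if (!is.finite(clean[nm]) || clean[nm] <= 0) return(NA_real_)
      relative_change(clean[nm], m[nm], digits = 2)$percent
    }, numeric(1))
    rows[[li]] <- c(level = lv, m, stats::setNames(drop, paste0(metric_names, "_drop")))
  }
  as.data.frame(do.call(rbind, rows))
}

#' Rater summary
#'
#' Marginal performance of one rater on a binary (malignant vs non-malignant)
#' task, as printed in comparison tables.
#'
#' @param sensitivity,specificity Per-class correctness rates in `[0, 1]`.
#' @param prevalence Malignant prevalence in `(0, 1)` (shared by the raters
#'   being compared).
#' @param accuracy Optional printed accuracy (not used by the bounds).
#' @param n Optional sample size.
#' @return List of class `rater_summary`.
#' @export
rater_summary <- function(sensitivity, specificity, prevalence,
                          accuracy = NA_real_, n = NA_integer_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must lie strictly inside (0, 1)")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence, accuracy = accuracy, n = n),
            class = "rater_summary")
}

#' Agreement (kappa) bounds from marginal summaries
#'
#' When only each rater's sensitivity and specificity are known, the joint
#' rating table is not identified: within each true class the probability
#' that both raters are correct is free inside its Fréchet interval. The
#' observed agreement `P_o` is therefore an interval, while the chance
#' agreement `P_e` is fixed by the marginal positive rates, giving sharp
#' bounds on Cohen's kappa `(P_o - P_e) / (1 - P_e)`.
#'
#' @param rater_a,rater_b [rater_summary()] objects with a common prevalence.
#' @return Named vector `c(kappa_min, kappa_max)`, both in `[-1, 1]`.
#' @export
kappa_bounds <- function(rater_a, rater_b) {
  if (abs(rater_a$prevalence - rater_b$prevalence) > 1e-12)
    stop("raters must share a prevalence")
  pi1 <- rater_a$prevalence
  sa <- rater_a$sensitivity; sb <- rater_b$sensitivity
  pa_spec <- rater_a$specificity; pb_spec <- rater_b$specificity
  agree_range <- function(ca, cb) {
    both_lo <- max(0, ca + cb - 1)
    both_hi <- min(ca, cb)
    c(1 - ca - cb + 2 * both_lo, 1 - ca - cb + 2 * both_hi)
  }
  pos <- agree_range(sa, sb)
  neg <- agree_range(pa_spec, pb_spec)
  po <- pi1 * pos + (1 - pi1) * neg          # elementwise (lo, hi)
  ra <- pi1 * sa + (1 - pi1) * (1 - pa_spec) # marginal positive rates
  rb <- pi1 * sb + (1 - pi1) * (1 - pb_spec)
  pe <- ra * rb + (1 - ra) * (1 - rb)
  if (1 - pe < 1e-12)
    stop("chance agreement is 1; kappa undefined for these marginals")
  k <- sort((po - pe) / (1 - pe))
  c(kappa_min = max(-1, k[1]), kappa_max = min(1, k[2]))
}
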
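# Evaluation protocol: metric definitions against independent oracles,
# patient-grouped folds, paired tests, relative change, kappa bounds.

test_that("confusion metrics: perfect and hand-computed instances", {
  y <- rep(c("normal", "benign", "malignant"), each = 10)
  m <- confusion_and_metrics(y, y)
  expect_equal(unlist(m[asgbc:::metric_names]),
               c(accuracy = 1, specificity = 1, sensitivity = 1,
                 f1_malignant = 1, macro_f1 = 1))
  # rows (true -> pred): normal [8,2,0], benign [1,9,0], malignant [0,2,8]
  y_true <- rep(c("normal", "benign", "malignant"), times = c(10, 10, 10))
  y_pred <- c(rep("normal", 8), rep("benign", 2),
              "normal", rep("benign", 9),
              rep("benign", 2), rep("malignant", 8))
  m <- confusion_and_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 25 / 30)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$f1_malignant, 16 / 18)
  expect_equal(m$macro_f1, (16 / 19 + 18 / 23 + 16 / 18) / 3)
  expect_error(confusion_and_metrics(character(0), character(0)), "empty")
  expect_error(confusion_and_metrics("normal", "weird"), "unknown")
})

test_that("metrics agree with a first-principles oracle on random vectors", {
  withr::with_seed(17, {
    cls <- c("normal", "benign", "malignant")
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      y_true <- sample(cls, n, replace = TRUE, prob = c(0.35, 0.45, 0.2))
      if (!"malignant" %in% y_true) y_true[1] <- "malignant"
      y_pred <- sample(cls, n, replace = TRUE)
      got <- asgbc:::metrics_vector(y_true, y_pred)
      expect_equal(got, oracle_metrics(y_true, y_pred), tolerance = 1e-12)
    }
  })
})

test_that("patient folds partition patients without leakage", {
  ids <- rep(sprintf("P%02d", 1:10), each = 3)
  f <- patient_folds(ids, folds = 10, seed = 1)
  # 10 patients in 10 folds: every validation fold is one patient
  expect_identical(sort(unique(f)), 1:10)
  for (k in 1:10)
    expect_length(unique(ids[f == k]), 1L)
  # 30 patients, 3 images each, 10 folds: sizes differ by at most one patient
  ids30 <- rep(sprintf("Q%02d", 1:30), each = 3)
  f30 <- patient_folds(ids30, folds = 10, seed = 2)
  per_fold_patients <- vapply(1:10, function(k) length(unique(ids30[f30 == k])),
                              numeric(1))
  expect_lte(diff(range(per_fold_patients)), 1)
  for (k in 1:10)
    expect_length(intersect(unique(ids30[f30 == k]), unique(ids30[f30 != k])), 0)
  expect_error(patient_folds(ids, folds = 11), "fewer")
})

test_that("grouped cross-validation aggregates per-fold metrics", {
  withr::with_seed(23, {
    man <- data.frame(patient_id = rep(sprintf("P%02d", 1:30), each = 3))
    man$label <- rep(sample(c("normal", "benign", "malignant"), 30,
                            replace = TRUE, prob = c(0.35, 0.45, 0.2)),
                     each = 3)
    res <- grouped_cross_validation(man, function(tr, te) {
      rep("benign", length(te))   # majority-class stub model
    }, folds = 10, seed = 3)
    expect_identical(dim(res$per_fold), c(10L, 5L))
    expect_identical(nrow(res$summary), 5L)
    for (k in 1:10)
      expect_length(intersect(man$patient_id[res$fold_of == k],
                              man$patient_id[res$fold_of != k]), 0)
  })
})

test_that("paired comparison: degenerate and textbook cases", {
  a <- c(0.8, 0.82, 0.78, 0.85, 0.8)
  expect_true(paired_comparison(a, a)$degenerate)
  expect_identical(paired_comparison(a, a)$p, 1)
  shift <- paired_comparison(a + 1, a)
  expect_true(shift$degenerate)
  expect_identical(shift$p, 1)
  withr::with_seed(29, {
    b <- a + stats::rnorm(5, 0.1, 0.05)
    got <- paired_comparison(a, b)
    d <- a - b
    t_ref <- mean(d) / (stats::sd(d) / sqrt(5))
    expect_equal(got$t, t_ref, tolerance = 1e-9)
    expect_equal(got$p, 2 * stats::pt(-abs(t_ref), df = 4), tolerance = 1e-9)
  })
})

test_that("relative change reproduces reporting arithmetic", {
  expect_equal(relative_change(0.826, 0.840, 1)$percent, 1.7)
  expect_identical(relative_change(0.826, 0.840)$direction, "improvement")
  expect_equal(relative_change(0.884, 0.875, 2)$percent, 1.02)
  expect_identical(relative_change(0.884, 0.875)$direction, "degradation")
  expect_equal(relative_change(0.5, 0.5)$percent, 0)
  expect_identical(relative_change(0.5, 0.5)$direction, "none")
  expect_error(relative_change(0, 0.5), "positive")
})

test_that("kappa bounds: analytic endpoints and grid-search equivalence", {
  perfect <- rater_summary(1, 1, 0.3)
  expect_equal(unname(kappa_bounds(perfect, perfect)), c(1, 1))
  coin <- rater_summary(0.5, 0.5, 0.5)
  expect_equal(unname(kappa_bounds(coin, coin)), c(-1, 1))
  withr::with_seed(37, {
    for (rep in 1:25) {
      sa <- stats::runif(1, 0.3, 1); sb <- stats::runif(1, 0.3, 1)
      pa <- stats::runif(1, 0.3, 1); pb <- stats::runif(1, 0.3, 1)
      prev <- stats::runif(1, 0.1, 0.9)
      got <- kappa_bounds(rater_summary(sa, pa, prev),
                          rater_summary(sb, pb, prev))
      ref <- oracle_kappa_grid(sa, sb, pa, pb, prev)
      expect_equal(unname(got), ref, tolerance = 1e-6)
      expect_lte(got["kappa_min"], got["kappa_max"])
      expect_gte(got["kappa_min"], -1)
      expect_lte(got["kappa_max"], 1)
    }
  })
  expect_error(rater_summary(0.9, 0.9, 1.2), "prevalence")
  expect_error(kappa_bounds(rater_summary(0.9, 0.9, 0.2),
                            rater_summary(0.9, 0.9, 0.4)), "share")
})

test_that("noise table is internally consistent with relative change", {
  withr::with_seed(43, {
    ds <- generate_dataset(phantom_config(n_patients = 12,
                                          images_per_patient = c(2L, 2L),
                                          seed = 77))
    # an untrained (random-weight) model is enough to exercise the protocol
    N <- dim(ds$images)[3]
    pool <- asgbc:::new_data_pool(seq_len(N), integer(0), N)
    ck <- pretrain_extractor(pool, ds$manifest, ds$images,
                             backbone_cfg = backbone_config("micro"),
                             train_cfg = train_config(iterations = 1,
                                                      batch_size = 8, seed = 1))
    model <- linear_probe(ck, pool, ds$manifest, ds$images,
                          train_config(iterations = 1, probe_steps = 50, seed = 1))
    nr <- noise_robustness(model, ds$images, ds$manifest$label,
                           levels = c(0.05), seed = 2)
    expect_identical(nr$level, c(0, 0.05))
    expect_true(all(nr[1, grep("_drop", names(nr))] == 0))
    drop_ref <- relative_change(nr$accuracy[1], nr$accuracy[2], 2)$percent
    expect_equal(nr$accuracy_drop[2], drop_ref)
  })
})
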
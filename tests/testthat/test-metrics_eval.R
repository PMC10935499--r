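test_that("a perfect classifier maxes every ranking and confusion metric", {
  y <- c(0, 0, 0, 1, 1)
  s <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  m <- compute_metrics(y, s)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$auc_pr, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)
})

test_that("an all-positive predictor has recall 1 and balanced accuracy 0.5", {
  y <- c(0, 1, 0, 1, 1, 0, 0)
  s <- rep(0.9, 7)
  m <- compute_metrics(y, s)
  expect_equal(m$recall, 1)
  expect_equal(m$balanced_accuracy, 0.5)
  expect_equal(m$precision, mean(y))
  expect_equal(m$mcc, 0)
  expect_equal(m$roc_auc, 0.5)  # all ties
})

test_that("all ten metrics agree with brute-force references on random instances", {
  set.seed(1234)
  for (rep in 1:250) {
    inst <- random_metric_instance(sample(6:40, 1))
    m <- compute_metrics(inst$y, inst$s)
    expect_equal(m$roc_auc, oracle_roc_auc(inst$y, inst$s), tolerance = 1e-9)
    expect_equal(m$auc_pr, oracle_auc_pr(inst$y, inst$s), tolerance = 1e-9)
    o <- oracle_thresholded(inst$y, inst$s)
    for (nm in names(o))
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(99)
  inst <- random_metric_instance(50)
  m0 <- compute_metrics(inst$y, inst$s)
  mono <- inst$s^2                                 # strictly monotone on [0,1]
  expect_equal(compute_metrics(inst$y, mono)$roc_auc, m0$roc_auc, tolerance = 1e-12)
  expect_equal(compute_metrics(inst$y, mono)$auc_pr, m0$auc_pr, tolerance = 1e-12)
  # threshold-preserving transform leaves confusion metrics unchanged too
  tp <- plogis(4 * qlogis(pmin(pmax(inst$s, 1e-12), 1 - 1e-12)))
  m1 <- compute_metrics(inst$y, tp)
  for (nm in c("balanced_accuracy", "precision", "recall", "f_half", "f1",
               "f2", "mcc"))
    expect_equal(m1[[nm]], m0[[nm]], tolerance = 1e-12, label = nm)
})

test_that("complement symmetry holds for MCC and balanced accuracy", {
  set.seed(7)
  for (rep in 1:20) {
    inst <- random_metric_instance(30)
    s <- ifelse(inst$s == 0.5, 0.51, inst$s)  # keep the 0.5 boundary unambiguous
    m <- compute_metrics(inst$y, s)
    mc <- compute_metrics(1 - inst$y, 1 - s)
    expect_equal(mc$mcc, m$mcc, tolerance = 1e-12)
    expect_equal(mc$balanced_accuracy, m$balanced_accuracy, tolerance = 1e-12)
  }
})

test_that("degenerate metric inputs are rejected", {
  expect_error(compute_metrics(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both classes")
  expect_error(compute_metrics(c(0, 1), c(NaN, 0.5)), "NaN")
  expect_error(compute_metrics(c(0, 1), c(-0.1, 0.5)), "0, 1")
  expect_error(compute_metrics(c(0, 1), c(0.5)), "length")
})

test_that("K = 6 folds on 598 samples have sizes 99 or 100 and stay stratified", {
  co <- generate_cohort(cohort_spec(171, 427, n_genetic = 3L,
                                    n_transcriptomic = 4L, seed = 21))
  folds <- fedomics:::make_folds(co$labels, 6L, seed = 2)
  sizes <- as.integer(table(folds))
  expect_setequal(sizes, c(99L, 100L))
  expect_equal(sum(sizes), 598L)
  case_per_fold <- as.integer(table(folds[co$labels == 1L]))
  expect_true(all(case_per_fold %in% c(28L, 29L)))
})

test_that("the K-fold protocol is deterministic and leak-free by construction", {
  co <- generate_cohort(cohort_spec(60, 120, n_genetic = 6L,
                                    n_transcriptomic = 10L,
                                    effect_scale = 0.8, seed = 22))
  ext <- generate_external_cohort(
    cohort_spec(60, 120, n_genetic = 6L, n_transcriptomic = 10L,
                effect_scale = 0.8, seed = 22),
    shift_spec(0.1, 0.7, c(40L, 80L)))
  models <- list(central_model("central LR", "logistic_regression", epochs = 10),
                 federated_model("FedAvg LR", "logistic_regression",
                                 n_clients = 2, rounds = 2, local_epochs = 2))
  cv1 <- kfold_protocol(co, ext, models, K = 3, seed = 5)
  cv2 <- kfold_protocol(co, ext, models, K = 3, seed = 5)
  expect_identical(cv1$per_fold, cv2$per_fold)
  # audit: fit/val/holdout partition each fold exactly
  for (k in 1:3) {
    a <- cv1$audit[[k]]
    expect_length(intersect(a$fit, a$val), 0L)
    expect_length(intersect(a$fit, a$holdout), 0L)
    expect_length(intersect(a$val, a$holdout), 0L)
    expect_setequal(c(a$fit, a$val, a$holdout), seq_len(n_samples(co)))
  }
  # summary is a mean/sd over exactly K fold values
  aucpr <- cv1$per_fold[cv1$per_fold$metric == "auc_pr" &
                          cv1$per_fold$model == "central LR" &
                          cv1$per_fold$test_set == "internal", ]
  expect_equal(nrow(aucpr), 3L)
  srow <- cv1$summary[cv1$summary$metric == "auc_pr" &
                        cv1$summary$model == "central LR" &
                        cv1$summary$test_set == "internal", ]
  expect_equal(srow$mean, mean(aucpr$value), tolerance = 1e-12)
  expect_equal(srow$sd, sd(aucpr$value), tolerance = 1e-12)
  # heterogeneity indices recorded for the federated model only
  expect_setequal(unique(cv1$heterogeneity$model), "FedAvg LR")
})

test_that("internal results are unaffected by the external cohort (no leakage)", {
  spec <- cohort_spec(40, 80, n_genetic = 5L, n_transcriptomic = 8L,
                      effect_scale = 0.8, seed = 23)
  co <- generate_cohort(spec)
  extA <- generate_external_cohort(spec, shift_spec(0, 0.5, c(30L, 30L)))
  extB <- generate_external_cohort(spec, shift_spec(1, 0.1, c(50L, 70L)))
  models <- list(central_model("LR", "logistic_regression", epochs = 8))
  cvA <- kfold_protocol(co, extA, models, K = 2, seed = 9)
  cvB <- kfold_protocol(co, extB, models, K = 2, seed = 9)
  internA <- cvA$per_fold[cvA$per_fold$test_set == "internal", ]
  internB <- cvB$per_fold[cvB$per_fold$test_set == "internal", ]
  expect_identical(internA, internB)
  expect_false(identical(cvA$per_fold, cvB$per_fold))
})

test_that("metrics_table formats one mean-sd cell per metric", {
  co <- generate_cohort(cohort_spec(30, 60, n_genetic = 4L,
                                    n_transcriptomic = 6L, seed = 24))
  cv <- kfold_protocol(co, NULL,
                       list(central_model("LR", "logistic_regression", epochs = 5)),
                       K = 2, seed = 1)
  tab <- metrics_table(cv, "internal")
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("roc_auc", "auc_pr", "mcc") %in% names(tab)))
  expect_match(tab$auc_pr, "±")
})

test_that("runtime measurement reports positive seconds, federated above central", {
  co <- generate_cohort(cohort_spec(40, 80, n_genetic = 50L,
                                    n_transcriptomic = 150L, seed = 25))
  val <- list(x = co$features[1:30, ], y = co$labels[1:30])
  t_central <- measure_runtime(
    central_model("LR", "logistic_regression", epochs = 200), co, val, seed = 1)
  t_fed <- measure_runtime(
    federated_model("FedAvg LR", "logistic_regression", n_clients = 2,
                    rounds = 20, local_epochs = 10), co, val, seed = 1)
  expect_gt(t_central, 0)
  expect_gt(t_fed, 0)
  expect_true(is.finite(t_fed))
})
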
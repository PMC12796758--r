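# Metrics, confidence intervals, model-comparison statistics, training
# harness behaviour, cross-validation mechanics.

test_that("AUC equals the O(n^2) pairwise statistic with half ties", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_score(scores, labels), naive_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)),
               class = "nactresp_auc_undefined_error")
  # cross-check against an established ROC implementation
  set.seed(52)
  sc <- runif(40); lb <- sample(0:1, 40, replace = TRUE, prob = c(0.3, 0.7))
  expect_equal(auc_score(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("threshold metrics follow the confusion-count formulas", {
  # TP = 5, TN = 3, FP = 1, FN = 1
  labels <- c(rep(1, 6), rep(0, 4))
  scores <- c(rep(0.9, 5), 0.2, rep(0.1, 3), 0.8)
  m <- compute_metrics(scores, labels)
  expect_equal(m$tp, 5); expect_equal(m$tn, 3)
  expect_equal(m$fp, 1); expect_equal(m$fn, 1)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 5 / 6, tolerance = 1e-4)
  expect_equal(m$specificity, 0.75)
  perfect <- compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_warning(single <- compute_metrics(c(0.9, 0.8), c(1, 1)))
  expect_true(is.na(single$auc))
  expect_equal(single$tp, 2)
})

test_that("fold confidence intervals match the closed form", {
  vals <- c(0.90, 0.92, 0.94, 0.96, 0.98)
  ci <- confidence_interval(vals)
  expect_equal(unname(ci["mean"]), 0.94)
  se <- sd(vals) / sqrt(5)
  expect_equal(se, 0.014142, tolerance = 1e-4)
  expect_equal(unname(ci["lower"]), 0.94 - 1.96 * se, tolerance = 1e-6)
  expect_equal(unname(ci["upper"]), 0.94 + 1.96 * se, tolerance = 1e-6)
  expect_equal(unname(ci[c("lower", "upper")]), c(0.9123, 0.9677),
               tolerance = 1e-3)
  # degenerate and invariance cases
  same <- confidence_interval(rep(0.8, 4))
  expect_equal(unname(same["lower"]), unname(same["upper"]))
  expect_equal(unname(confidence_interval(rev(vals))["mean"]), 0.94)
  expect_error(confidence_interval(0.9), class = "nactresp_validation_error")
  # clipping keeps rate CIs inside [0, 1]
  hi <- confidence_interval(c(0.97, 0.999, 0.999))
  expect_lte(unname(hi["upper"]), 1)
})

test_that("the DeLong test matches the naive placement-value computation", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    a <- round(runif(n), 1)
    b <- round(runif(n), 1)
    got <- delong_test(a, b, labels)
    want <- naive_delong(a, b, labels)
    expect_equal(got$auc_a, want$auc_a, tolerance = 1e-12)
    expect_equal(got$auc_b, want$auc_b, tolerance = 1e-12)
    if (want$var_delta > 0) {
      z <- (want$auc_a - want$auc_b) / sqrt(want$var_delta)
      expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
    }
  }
  # identical scores: zero difference, p = 1
  s <- c(0.2, 0.8, 0.4, 0.9, 0.1, 0.7)
  l <- c(0, 1, 0, 1, 0, 1)
  same <- delong_test(s, s, l)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry of the difference, invariance of p
  sw1 <- delong_test(s, rev(s), l)
  sw2 <- delong_test(rev(s), s, l)
  expect_equal(sw1$delta, -sw2$delta)
  expect_equal(sw1$p_value, sw2$p_value)
  expect_error(delong_test(s, s[1:4], l), class = "nactresp_validation_error")
  # cross-check against the established implementation
  set.seed(54)
  lb <- rep(0:1, each = 15)
  sa <- runif(30) + 0.8 * lb
  sb <- sa + rnorm(30, 0, 0.2)
  got <- delong_test(sa, sb, lb)
  ref <- pROC::roc.test(
    pROC::roc(lb, sa, quiet = TRUE, direction = "<"),
    pROC::roc(lb, sb, quiet = TRUE, direction = "<"), method = "delong")
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("McNemar on discordant counts matches the corrected chi-squared", {
  labels <- rep(1, 12)
  # b = 10 (a right, b wrong), c = 2
  preds_a <- c(rep(1, 10), 0, 0)
  preds_b <- c(rep(0, 10), 1, 1)
  res <- mcnemar_test(preds_a, preds_b, labels)
  expect_equal(res$b_discordant, 10)
  expect_equal(res$c_discordant, 2)
  expect_equal(res$statistic, 49 / 12, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0433, tolerance = 1e-3)
  # b = c = 4: corrected chi-squared = 1/8
  labels8 <- rep(1, 8)
  pa <- c(rep(1, 4), rep(0, 4)); pb <- c(rep(0, 4), rep(1, 4))
  res2 <- mcnemar_test(pa, pb, labels8)
  expect_equal(res2$statistic, 1 / 8, tolerance = 1e-6)
  expect_equal(res2$p_value, 0.7237, tolerance = 1e-3)
  # no discordance
  res3 <- mcnemar_test(pa, pa, labels8)
  expect_equal(res3$p_value, 1)
  # exact binomial flag
  res4 <- mcnemar_test(preds_a, preds_b, labels, exact = TRUE)
  expect_equal(res4$p_value, binom.test(10, 12, 0.5)$p.value)
  expect_error(mcnemar_test(pa, pb[1:3], labels8),
               class = "nactresp_validation_error")
})

test_that("paired t-tests match the hand formula and handle degeneracy", {
  a <- c(0.80, 0.85, 0.90); b <- c(0.78, 0.80, 0.88)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 2), tolerance = 1e-12)
  ident <- paired_t_test(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  x <- c(0.8, 0.82, 0.84, 0.86, 0.88)
  expect_warning(shift <- paired_t_test(x, x - 0.02))
  expect_equal(shift$p_value, 0)
  expect_error(paired_t_test(a, a[1:2]), class = "nactresp_validation_error")
})

test_that("checkpoint selection takes the minimum validation loss", {
  expect_equal(select_checkpoint(c(0.9, 0.5, 0.7, 0.6)), 2)
  expect_equal(select_checkpoint(c(0.3, 0.3, 0.5)), 1)
})

test_that("stratified folds partition patients with balanced sizes", {
  ids <- sprintf("P%03d", 1:172)
  labels <- rep(c(1, 0), times = c(149, 23))
  fold <- nactresp:::make_folds(ids, labels, 5, seed = 2)
  expect_equal(sort(as.vector(table(fold))), c(34, 34, 34, 35, 35))
  expect_equal(length(fold), 172)
  # every class is spread over all folds
  expect_true(all(table(fold[labels == 0]) >= 4))
})

test_that("training selects the best epoch, is deterministic, and learns", {
  set.seed(55)
  cohort <- simulate_image_cohort(8, 8, image_size = c(16, 16), seed = 5)
  arch <- tiny_arch()
  tc <- tiny_train(epochs = 3, seed = 7)
  fit <- train_model(cohort[1:10, ], cohort[11:16, ], config = tc, arch = arch)
  expect_s3_class(fit, "nact_fit")
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # the very same configuration and seed reproduce identical histories
  fit2 <- train_model(cohort[1:10, ], cohort[11:16, ], config = tc, arch = arch)
  expect_identical(fit$history, fit2$history)
  scored1 <- predict_pairs(fit$model, cohort[11:16, ])
  scored2 <- predict_pairs(fit2$model, cohort[11:16, ])
  expect_identical(scored1$score, scored2$score)
  expect_error(train_model(cohort[0, ], cohort[1:2, ], tc, arch),
               class = "nactresp_validation_error")
})

test_that("training loss decreases on a separable cohort", {
  cohort <- simulate_image_cohort(10, 10, image_size = c(16, 16), seed = 9)
  fit <- train_model(cohort[1:14, ], cohort[15:20, ],
                     config = tiny_train(epochs = 6, seed = 3),
                     arch = tiny_arch())
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
})

test_that("cross-validation partitions patients and aggregates fold means", {
  cohort <- simulate_image_cohort(8, 8, image_size = c(16, 16), seed = 6)
  cv <- cross_validate(cohort, k = 3, config = tiny_train(epochs = 2, seed = 1),
                       arch = tiny_arch(), seed = 4)
  expect_s3_class(cv, "fold_metrics")
  # scores cover every patient exactly once
  expect_setequal(cv$scores$patient_id, cohort$patient_id)
  expect_equal(anyDuplicated(cv$scores$patient_id), 0)
  # aggregate mean equals the hand mean of per-fold values
  expect_equal(cv$aggregate$mean[cv$aggregate$metric == "auc"],
               mean(cv$per_fold$auc), ignore_attr = TRUE)
  expect_error(cross_validate(cohort[1:6, ], k = 5,
                              config = tiny_train(1), arch = tiny_arch()),
               class = "nactresp_validation_error")
})

test_that("the ablation harness reports aligned variants with pairwise tests", {
  cohort <- simulate_image_cohort(10, 10, image_size = c(16, 16), seed = 8)
  grid <- list(full = list(),
               hard_split = list(embedding = "hard_split", hard_patch = 4L))
  tab <- run_ablation(grid, cohort, config = tiny_train(epochs = 2, seed = 2),
                      base = tiny_arch(), seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity",
                    "p_delong_vs_ref", "p_mcnemar_vs_ref") %in% names(tab)))
  expect_false(is.na(tab$p_delong_vs_ref[tab$variant == "hard_split"]))
  # identical variants under the same seed give identical rows
  grid2 <- list(a = list(), b = list())
  tab2 <- run_ablation(grid2, cohort, config = tiny_train(epochs = 1, seed = 2),
                       base = tiny_arch(), seed = 2)
  expect_equal(tab2$auc[1], tab2$auc[2])
})
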
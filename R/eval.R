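#' Evaluation metrics and model-comparison statistics
#'
#' AUC via the midrank (Mann-Whitney) formulation, threshold metrics from
#' the confusion counts, per-fold aggregation with normal-approximation
#' confidence intervals, and the three pairwise comparisons: DeLong for
#' AUCs, McNemar for accuracies, paired t for sensitivity/specificity.
#'
#' @name evaluation
NULL

#' Area under the ROC curve
#'
#' Rank-based AUC with ties handled by midranks; equals the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param scores Numeric scores (probability of the positive class).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_validation("scores", "scores and labels must have equal length")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    rlang::abort("AUC undefined: both classes must be present",
                 class = "nactresp_auc_undefined_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics at a threshold
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5, prediction 1 when
#'   `score >= threshold`).
#' @return One-row tibble: `auc` (NA with a warning when only one class is
#'   present), `accuracy`, `sensitivity`, `specificity`, and the confusion
#'   counts `tp`, `tn`, `fp`, `fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  preds <- as.integer(scores >= threshold)
  tp <- sum(preds == 1 & labels == 1)
  tn <- sum(preds == 0 & labels == 0)
  fp <- sum(preds == 1 & labels == 0)
  fn <- sum(preds == 0 & labels == 1)
  auc <- tryCatch(auc_score(scores, labels),
                  nactresp_auc_undefined_error = function(e) {
                    rlang::warn(conditionMessage(e))
                    NA_real_
                  })
  tibble::tibble(
    auc = auc,
    accuracy = (tp + tn) / max(tp + tn + fp + fn, 1L),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Normal-approximation confidence interval over folds
#'
#' `mean +/- 1.96 * SE` with `SE = sd / sqrt(k)`; bounds are clipped to
#' `[0, 1]` for rate metrics.
#'
#' @param fold_values Numeric vector of per-fold metric values (length >= 2).
#' @param clip Clip the interval to `[0, 1]`.
#' @return Named numeric `c(mean, lower, upper)`.
#' @export
confidence_interval <- function(fold_values, clip = TRUE) {
  k <- length(fold_values)
  if (k < 2) abort_validation("fold_values", "need at least 2 fold values")
  m <- mean(fold_values)
  se <- stats::sd(fold_values) / sqrt(k)
  lo <- m - 1.96 * se
  hi <- m + 1.96 * se
  if (clip) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  c(mean = m, lower = lo, upper = hi)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half), and vice versa
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two models' AUCs on the same cases via placement
#' values; the variance of the AUC difference accounts for the correlation
#' induced by the shared cases. Two-sided normal p-value. A degenerate
#' zero-variance comparison with zero AUC difference yields p = 1.
#'
#' @param scores_a,scores_b Paired score vectors on identical cases.
#' @param labels Common 0/1 labels.
#' @return One-row tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort_validation("scores", "scores_a, scores_b, labels must be paired")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  # a stratum with a single case has no estimable covariance; it
  # contributes zero variance
  safe_cov <- function(x, y) {
    if (length(x) < 2) matrix(0, 2, 2) else stats::cov(cbind(x, y))
  }
  s10 <- safe_cov(pa$v10, pb$v10)
  s01 <- safe_cov(pa$v01, pb$v01)
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
  }
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 z = z, p_value = p)
}

#' McNemar test on paired classifications
#'
#' Counts the discordant cases (`b`: model a correct and b wrong; `c`: the
#' converse) and applies the continuity-corrected chi-squared test
#' `(|b - c| - 1)^2 / (b + c)` on 1 df; no discordant pairs yields p = 1.
#' `exact = TRUE` uses the exact binomial test instead.
#'
#' @param preds_a,preds_b Paired 0/1 predictions.
#' @param labels True 0/1 labels.
#' @param exact Use the exact binomial test.
#' @return One-row tibble: `b_discordant`, `c_discordant`, `statistic`,
#'   `p_value`.
#' @export
mcnemar_test <- function(preds_a, preds_b, labels, exact = FALSE) {
  if (length(preds_a) != length(preds_b) ||
      length(preds_a) != length(labels)) {
    abort_validation("preds", "predictions and labels must be paired")
  }
  correct_a <- preds_a == labels
  correct_b <- preds_b == labels
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L) {
    return(tibble::tibble(b_discordant = 0L, c_discordant = 0L,
                          statistic = 0, p_value = 1))
  }
  if (exact) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    stat <- NA_real_
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b_discordant = b, c_discordant = cc,
                 statistic = stat, p_value = p)
}

#' Paired t-test on per-fold metric values
#'
#' Standard two-sided paired t with k - 1 degrees of freedom. Degenerate
#' cases: all differences zero reports t = 0, p = 1; zero difference
#' variance with nonzero mean reports p = 0 with a warning.
#'
#' @param values_a,values_b Equal-length (>= 2) numeric vectors.
#' @return One-row tibble: `t`, `p_value`, `mean_diff`.
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort_validation("values", "vectors must have equal length")
  }
  if (length(values_a) < 2) abort_validation("values", "need length >= 2")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, p_value = 1, mean_diff = 0))
    }
    rlang::warn("zero difference variance with nonzero mean; p -> 0")
    return(tibble::tibble(t = sign(mean(d)) * Inf, p_value = 0,
                          mean_diff = mean(d)))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), p_value = ht$p.value,
                 mean_diff = mean(d))
}

#' Average pair-level scores to patient level
#'
#' @param scores Tibble with `patient_id`, `label`, `score` columns.
#' @return One row per patient with the mean score and majority label.
#' @export
aggregate_patient_scores <- function(scores) {
  dplyr::summarise(dplyr::group_by(scores, .data$patient_id),
                   label = .data$label[1],
                   score = mean(.data$score), .groups = "drop") |>
    dplyr::mutate(pred = as.integer(.data$score >= 0.5))
}

# stratified k-fold patient assignment; per-class remainders go to the
# folds with the smallest running totals so global sizes stay balanced
make_folds <- function(ids, labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(ids))
    totals <- integer(k)
    for (cl in sort(unique(labels), decreasing = TRUE)) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      sizes <- rep(m %/% k, k)
      extra <- m %% k
      if (extra > 0) {
        ord <- order(totals, seq_len(k))
        sizes[ord[seq_len(extra)]] <- sizes[ord[seq_len(extra)]] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
    fold
  })
}

#' k-fold cross-validation of the full pipeline
#'
#' Patient-level stratified folds partition the cohort; for each fold the
#' remaining patients are split again (stratified, 4:1) into training and
#' early-stopping validation sets, a model is trained, and the held-out
#' fold is scored. Folds whose evaluation split lacks a class are skipped
#' with a warning.
#'
#' @param pairs Labelled pairs tibble (one row per patient).
#' @param k Number of folds.
#' @param config A [train_config()].
#' @param arch A [model_config()].
#' @param seed Fold-assignment seed.
#' @param quiet Passed to [train_model()].
#' @return A `fold_metrics` object: per-fold metrics, aggregate mean and
#'   95% CI per metric, and the per-pair scores.
#' @export
cross_validate <- function(pairs, k = 5, config = train_config(),
                           arch = model_config(), seed = 1, quiet = TRUE) {
  labs <- pairs$label
  if (any(table(factor(labs, levels = c(0, 1))) < k)) {
    abort_validation("pairs", "need at least k patients per class")
  }
  fold <- make_folds(pairs$patient_id, labs, k, seed)
  fold_rows <- list()
  score_rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    rest <- which(fold != f)
    if (length(unique(labs[test_idx])) < 2) {
      rlang::warn(sprintf("fold %d evaluation split lacks a class; skipped", f))
      next
    }
    inner <- make_folds(pairs$patient_id[rest], labs[rest], 5L, seed + f)
    val_idx <- rest[inner == 1L]
    train_idx <- rest[inner != 1L]
    fit <- train_model(pairs[train_idx, ], pairs[val_idx, ],
                       config = config, arch = arch, quiet = quiet)
    scored <- predict_pairs(fit$model, pairs[test_idx, ])
    scored$fold <- f
    score_rows[[f]] <- scored
    m <- compute_metrics(scored$score, scored$label)
    m$fold <- f
    fold_rows[[f]] <- m
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  aggregate <- dplyr::bind_rows(lapply(metrics, function(mm) {
    ci <- confidence_interval(per_fold[[mm]])
    tibble::tibble(metric = mm, mean = ci["mean"],
                   lower = ci["lower"], upper = ci["upper"])
  }))
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 scores = dplyr::bind_rows(score_rows), k = k),
            class = "fold_metrics")
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d folds evaluated)\n",
              x$k, nrow(x$per_fold)))
  print(x$aggregate)
  invisible(x)
}

#' Train on the 3:1:1 split and evaluate the held-out test set
#'
#' @param pairs Labelled pairs tibble.
#' @param config,arch Training and architecture configs.
#' @param seed Split seed.
#' @param quiet Passed to [train_model()].
#' @param augment_policy `"none"`, `"uniform4"` or `"class_balanced"`
#'   augmentation of the training split only.
#' @return List with the fit, the split, test scores and test metrics.
#' @export
evaluate_split <- function(pairs, config = train_config(),
                           arch = model_config(), seed = 1, quiet = TRUE,
                           augment_policy = "none") {
  labelled <- dplyr::mutate(pairs, .row = dplyr::row_number())
  split <- split_dataset(labelled, stratify = TRUE, seed = seed)
  labelled$split <- split$split
  train_pairs <- dplyr::filter(labelled, .data$split == "train")
  if (augment_policy != "none") {
    train_pairs <- augment_training_set(train_pairs, augment_policy,
                                        seed = seed)
  }
  val_pairs <- dplyr::filter(labelled, .data$split == "val")
  test_pairs <- dplyr::filter(labelled, .data$split == "test")
  fit <- train_model(train_pairs, val_pairs, config = config, arch = arch,
                     quiet = quiet)
  scored <- predict_pairs(fit$model, test_pairs)
  list(fit = fit, split = split, scores = scored,
       metrics = compute_metrics(scored$score, scored$label))
}

#' Ablation harness
#'
#' Trains each configuration variant with identical seeds and splits and
#' reports per-variant test metrics plus pairwise tests (DeLong on scores,
#' McNemar on predictions) against the first variant in the grid.
#'
#' @param grid Named list of variant definitions; each is a list of
#'   [model_config()] field overrides (e.g. `list(embedding = "hard_split")`).
#' @param pairs Labelled pairs tibble.
#' @param config A [train_config()].
#' @param base Base architecture configuration the variants override.
#' @param seed Split/training seed.
#' @param quiet Passed to [train_model()].
#' @return Tibble with one row per variant: the four metrics and the
#'   p-values of the comparisons against the reference variant.
#' @export
run_ablation <- function(grid, pairs, config = train_config(),
                         base = model_config(), seed = 1, quiet = TRUE) {
  results <- list()
  scores <- list()
  for (nm in names(grid)) {
    overrides <- grid[[nm]]
    bad <- setdiff(names(overrides), names(base))
    if (length(bad)) abort_validation("grid", paste("unknown field", bad[1]))
    arch <- base
    arch[names(overrides)] <- overrides
    res <- evaluate_split(pairs, config = config, arch = arch, seed = seed,
                          quiet = quiet)
    results[[nm]] <- dplyr::mutate(res$metrics, variant = nm,
                                   .before = 1L)
    scores[[nm]] <- res$scores
  }
  out <- dplyr::bind_rows(results)
  ref <- names(grid)[1]
  out$p_delong_vs_ref <- NA_real_
  out$p_mcnemar_vs_ref <- NA_real_
  for (nm in setdiff(names(grid), ref)) {
    dl <- delong_test(scores[[ref]]$score, scores[[nm]]$score,
                      scores[[ref]]$label)
    mc <- mcnemar_test(scores[[ref]]$pred, scores[[nm]]$pred,
                       scores[[ref]]$label)
    out$p_delong_vs_ref[out$variant == nm] <- dl$p_value
    out$p_mcnemar_vs_ref[out$variant == nm] <- mc$p_value
  }
  out
}

#' Render cross-validation metrics as a report table
#'
#' One row per metric in the conventional column order — AUC, Accuracy,
#' Specificity, Sensitivity — with the fold mean and its 95% confidence
#' interval formatted as `mean (lower, upper)`.
#'
#' @param x A `fold_metrics` object.
#' @param digits Decimal places.
#' @return Tibble with `metric` and `value` columns.
#' @export
metrics_table <- function(x, digits = 3) {
  order_ <- c("auc", "accuracy", "specificity", "sensitivity")
  labels <- c("AUC", "Accuracy", "Specificity", "Sensitivity")
  agg <- x$aggregate[match(order_, x$aggregate$metric), ]
  tibble::tibble(
    metric = labels,
    value = sprintf("%.*f (%.*f, %.*f)", digits, agg$mean, digits,
                    agg$lower, digits, agg$upper))
}
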
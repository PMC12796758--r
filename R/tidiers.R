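# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' Tidy a model fit into its per-epoch history
#'
#' @param x A `nact_fit` from [train_model()].
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_loss`.
#' @export
tidy.nact_fit <- function(x, ...) x$history

#' One-row summary of a model fit
#'
#' @param x A `nact_fit`.
#' @param ... Unused.
#' @export
glance.nact_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' Tidy cross-validation results into per-fold metrics
#'
#' @param x A `fold_metrics` from [cross_validate()].
#' @param ... Unused.
#' @return Long tibble with `fold`, `metric`, `value`.
#' @export
tidy.fold_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold,
                      cols = c("auc", "accuracy", "sensitivity",
                               "specificity"),
                      names_to = "metric", values_to = "value")[,
    c("fold", "metric", "value")]
}

#' One-row summary of cross-validation results
#'
#' @param x A `fold_metrics`.
#' @param ... Unused.
#' @export
glance.fold_metrics <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "lower", "upper"))
  dplyr::mutate(wide, k = x$k)
}

#' Plot cross-validation metrics with confidence intervals
#'
#' Bar chart of the per-metric fold means with the 95% confidence
#' intervals, mirroring the usual model-comparison figures.
#'
#' @param object A `fold_metrics`.
#' @param ... Unused.
#' @export
autoplot.fold_metrics <- function(object, ...) {
  ggplot2::ggplot(object$aggregate,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "metric (mean over folds, 95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot the six phases of a DCE-MRI series
#'
#' @param object A `dce_series` from [simulate_dce_series()].
#' @param ... Unused.
#' @export
autoplot.dce_series <- function(object, ...) {
  dfs <- lapply(seq_along(object$phases), function(i) {
    ph <- object$phases[[i]]
    tibble::tibble(phase = paste0("S", i - 1L),
                   row = rep(seq_len(nrow(ph)), ncol(ph)),
                   col = rep(seq_len(ncol(ph)), each = nrow(ph)),
                   intensity = as.vector(ph))
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~phase, nrow = 2) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' ROC curve coordinates
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered for plotting.
#' @export
roc_curve <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                 numeric(1)))
}
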
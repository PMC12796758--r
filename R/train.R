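#' Training configuration
#'
#' The optimisation recipe: cross-entropy loss, AdamW with beta1 = 0.85 and
#' beta2 = 0.998, initial learning rate 1e-4, weight decay 0.02, a cosine
#' annealing schedule, and early stopping with model selection at the
#' minimum validation loss.
#'
#' @param lr Initial learning rate (> 0).
#' @param beta1,beta2 AdamW moment decay rates, both in (0, 1).
#' @param weight_decay Decoupled weight decay.
#' @param epochs_max Maximum number of epochs (cosine horizon).
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param clip_norm Global gradient-norm clipping threshold (stabilises the
#'   slow second-moment AdamW updates; `Inf` disables).
#' @param seed Seed covering initialisation, data order and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.85, beta2 = 0.998,
                         weight_decay = 0.02, epochs_max = 100,
                         patience = 10, batch_size = 16, clip_norm = 1,
                         seed = 1) {
  if (lr <= 0) abort_validation("lr", "must be > 0")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    abort_validation("beta", "beta1 and beta2 must lie in (0, 1)")
  }
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs_max = epochs_max,
                 patience = patience, batch_size = batch_size,
                 clip_norm = clip_norm, seed = seed),
            class = "train_config")
}

cosine_lr <- function(epoch, epochs_max, lr0, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / epochs_max))
}

adamw_new <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

clip_gradients <- function(params, clip_norm) {
  if (!is.finite(clip_norm)) return(invisible(NULL))
  total <- 0
  for (p in params) if (!is.null(p$grad)) total <- total + sum(p$grad^2)
  total <- sqrt(total)
  if (total > clip_norm) {
    sc <- clip_norm / total
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(NULL)
}

adamw_step <- function(params, state, lr, beta1, beta2, weight_decay,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p$val)
  }
  state
}

#' Epoch index of the selected checkpoint
#'
#' Model selection picks the epoch with the minimum validation loss (first
#' minimum on ties).
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @return 1-based epoch index.
#' @export
select_checkpoint <- function(val_losses) which.min(val_losses)

#' Train the dual-branch model
#'
#' Full-batch-accumulated AdamW training with a cosine-annealed learning
#' rate and early stopping; the returned model carries the parameters of
#' the epoch with minimal validation loss. Fully seeded: initialisation,
#' data order and every stochastic choice derive from the seeds in the two
#' configs, so identical inputs reproduce identical fits.
#'
#' @param train_pairs,val_pairs Pairs tibbles (`pre`/`post` list-columns and
#'   `label`).
#' @param config A [train_config()].
#' @param arch A [model_config()].
#' @param model Optionally a pre-initialised `nact_model` (overrides `arch`).
#' @param quiet Suppress per-epoch messages.
#' @return A `nact_fit` object: the fitted model, the per-epoch history,
#'   and the selected epoch.
#' @export
train_model <- function(train_pairs, val_pairs, config = train_config(),
                        arch = model_config(), model = NULL, quiet = TRUE) {
  if (nrow(train_pairs) == 0L || nrow(val_pairs) == 0L) {
    abort_validation("pairs", "training and validation sets must be non-empty")
  }
  if (is.null(model)) model <- init_model(arch, seed = config$seed)
  params <- model$param_list
  opt <- adamw_new(params)
  history <- list()
  best <- list(loss = Inf, epoch = 0L, params = NULL, bn = NULL)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs_max)) {
      lr <- cosine_lr(epoch, config$epochs_max, config$lr)
      ord <- sample.int(nrow(train_pairs))
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        tp_zero_grads(params)
        batch_loss <- 0
        for (i in idx) {
          logits <- nd_forward_pair(model, train_pairs$pre[[i]],
                                    train_pairs$post[[i]], training = TRUE)
          loss <- tp_cross_entropy(logits, train_pairs$label[i] + 1L)
          tp_backward(loss, seed = matrix(1 / length(idx), 1L, 1L))
          batch_loss <- batch_loss + tp_val(loss)[1L, 1L]
        }
        batch_loss <- batch_loss / length(idx)
        if (!is.finite(batch_loss)) {
          rlang::abort(sprintf("training diverged (non-finite loss, epoch %d)",
                               epoch), class = "nactresp_divergence_error")
        }
        clip_gradients(params, config$clip_norm)
        opt <- adamw_step(params, opt, lr, config$beta1, config$beta2,
                          config$weight_decay)
        epoch_loss <- epoch_loss + batch_loss
        nb <- nb + 1L
      }
      epoch_loss <- epoch_loss / nb
      val_loss <- mean(vapply(seq_len(nrow(val_pairs)), function(i) {
        logits <- nd_forward_pair(model, val_pairs$pre[[i]],
                                  val_pairs$post[[i]], training = FALSE)
        tp_val(tp_cross_entropy(logits, val_pairs$label[i] + 1L))[1L, 1L]
      }, numeric(1)))
      history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                         train_loss = epoch_loss,
                                         val_loss = val_loss)
      if (!quiet) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, epoch_loss, val_loss))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch,
                     params = model_param_values(model),
                     bn = model_bn_values(model))
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  model_set_params(model, best$params)
  model_set_bn(model, best$bn)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 config = config),
            class = "nact_fit")
}

#' @export
print.nact_fit <- function(x, ...) {
  cat("Dual-branch spatio-temporal transformer fit\n")
  cat(sprintf("  epochs run: %d (selected epoch %d, val loss %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}
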
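#' Model configuration
#'
#' Assembles the architecture hyperparameters of the dual-branch
#' spatio-temporal transformer. The `"full"` profile uses 224 x 224 inputs,
#' 64-dimensional tokens, 4 heads, two EiT2T blocks with scales {3, 5, 7}
#' and 7 x 7 attention windows. The `"test"` profile is the scaled-down
#' desk profile used throughout the test-suite experiments: 64 x 64 inputs,
#' 32-dimensional tokens, 2 heads, one EiT2T block with scales {3, 5} and
#' 4 x 4 windows, and a depth-2 shared encoder.
#'
#' @param profile `"test"` (scaled-down desk profile) or `"full"`.
#' @param ... Named overrides of any configuration field (e.g. `st_mode`,
#'   `head_mode`, `embedding`, `timepoints`).
#' @return A `nact_config` list.
#' @export
model_config <- function(profile = c("test", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(image_size = 224L, channels = 6L, c_dim = 64L, heads = 4L,
         n_blocks = 2L, scales = c(3L, 5L, 7L), window = 7L,
         split = list(k = 3L, s = 2L, p = 1L),
         init_split = list(k = 7L, s = 4L, p = 2L),
         encoder_depth = 4L, mlp_ratio = 2L)
  } else {
    list(image_size = 64L, channels = 6L, c_dim = 32L, heads = 2L,
         n_blocks = 1L, scales = c(3L, 5L), window = 4L,
         split = list(k = 3L, s = 2L, p = 1L),
         init_split = list(k = 7L, s = 4L, p = 2L),
         encoder_depth = 2L, mlp_ratio = 2L)
  }
  cfg$st_mode <- "full"        # none | te | dpe | spe | spe_te | full
  cfg$head_mode <- "affc"      # affc | cls
  cfg$embedding <- "eit2t"     # eit2t | hard_split
  cfg$hard_patch <- 8L
  cfg$timepoints <- "both"     # both | pre | post
  cfg$profile <- profile
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) abort_validation("config", paste("unknown field", bad[1]))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "nact_config")
}

# token geometry after the embedding stage(s)
config_geometry <- function(cfg) {
  H <- cfg$image_size
  if (cfg$embedding == "hard_split") {
    g <- list(h = H %/% cfg$hard_patch, w = H %/% cfg$hard_patch)
  } else {
    ui <- unfold_indices(H, H, cfg$init_split$k, cfg$init_split$s,
                         cfg$init_split$p)
    g <- list(h = ui$out_h, w = ui$out_w)
    for (i in seq_len(cfg$n_blocks)) {
      ui <- unfold_indices(g$h, g$w, cfg$split$k, cfg$split$s, cfg$split$p)
      g <- list(h = ui$out_h, w = ui$out_w)
    }
  }
  g
}

#' Initialise the dual-branch model
#'
#' Draws all learnable parameters (two isolated EiT2T arms, the shared
#' spatio-temporal embedding network, the shared encoder and the
#' classification head) from seeded Gaussian initialisations.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @return A `nact_model` object.
#' @export
init_model <- function(config, seed = 1) {
  with_seed(seed, {
    c_dim <- config$c_dim
    geom_final <- config_geometry(config)
    n_tokens <- geom_final$h * geom_final$w
    if (config$embedding == "eit2t") {
      tok_dim <- config$init_split$k^2 * config$channels
      make_arm <- function(name) {
        list(proj = new_linear(tok_dim, c_dim, paste0(name, ".proj")),
             blocks = lapply(seq_len(config$n_blocks), function(i) {
               new_eit2t_block(c_dim, config$heads, config$scales,
                               config$window, config$split,
                               config$mlp_ratio,
                               paste0(name, ".block", i))
             }))
      }
    } else {
      tok_dim <- config$hard_patch^2 * config$channels
      make_arm <- function(name) {
        list(proj = new_linear(tok_dim, c_dim, paste0(name, ".proj")),
             blocks = list())
      }
    }
    params <- list(
      before = make_arm("before"),
      after = make_arm("after"),
      st = new_st(c_dim, n_tokens, config$st_mode),
      encoder = new_encoder(c_dim, config$heads, config$encoder_depth,
                            config$mlp_ratio),
      final_ln = new_ln(c_dim, "final_ln"),
      head = if (config$head_mode == "affc") new_affc(c_dim)
             else new_cls_head(c_dim)
    )
    structure(list(config = config, params = params,
                   param_list = collect_params(params), seed = seed),
              class = "nact_model")
  })
}

# six-channel [H, W, C] array -> [H*W x C] row-major token matrix
img_to_mat <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- matrix(0, H * W, C)
  for (ch in seq_len(C)) out[, ch] <- as.vector(t(img[, , ch]))
  out
}

# forward one arm up to the embedded token sequence
nd_arm_forward <- function(model, img_mat, arm_name, t, training) {
  cfg <- model$config
  arm <- model$params[[arm_name]]
  H <- cfg$image_size
  if (cfg$embedding == "hard_split") {
    ui <- unfold_indices(H, H, cfg$hard_patch, cfg$hard_patch, 0L)
  } else {
    ui <- unfold_indices(H, H, cfg$init_split$k, cfg$init_split$s,
                         cfg$init_split$p)
  }
  tokens <- fw_linear(arm$proj, tp_unfold_idx(tp_const(img_mat), ui$idx))
  geom <- list(h = ui$out_h, w = ui$out_w)
  for (blk in arm$blocks) {
    res <- nd_eit2t_block(blk, tokens, geom)
    tokens <- res$tokens
    geom <- res$geom
  }
  nd_st_apply(model$params$st, tokens, geom, t, training)
}

# full forward pass for one image pair -> [1 x 2] logits node
nd_forward_pair <- function(model, pre_img, post_img, training = TRUE) {
  cfg <- model$config
  if (cfg$timepoints == "pre") post_img <- pre_img
  if (cfg$timepoints == "post") pre_img <- post_img
  pre_mat <- if (is.matrix(pre_img)) pre_img else img_to_mat(pre_img)
  post_mat <- if (is.matrix(post_img)) post_img else img_to_mat(post_img)
  f_before <- nd_arm_forward(model, pre_mat, "before", 0, training)
  f_after <- nd_arm_forward(model, post_mat, "after", 1, training)
  head <- model$params$head
  if (cfg$head_mode == "cls") {
    f_before <- tp_concat_rows(list(head$cls_token, f_before))
    f_after <- tp_concat_rows(list(head$cls_token, f_after))
  }
  enc_b <- fw_ln(model$params$final_ln, nd_encode(model$params$encoder, f_before))
  enc_a <- fw_ln(model$params$final_ln, nd_encode(model$params$encoder, f_after))
  if (cfg$head_mode == "cls") {
    cls_b <- tp_gather_rows(enc_b, 1L)
    cls_a <- tp_gather_rows(enc_a, 1L)
    fw_linear(head$fc, tp_concat_cols(cls_b, cls_a))
  } else {
    nd_affc(head, enc_b, enc_a)
  }
}

#' Predict class probabilities for labelled pairs
#'
#' Runs the model in evaluation mode (batch-normalisation running
#' statistics) over a tibble of image pairs.
#'
#' @param model A `nact_model` (typically the fitted model from
#'   [train_model()]).
#' @param pairs Pairs tibble with `pre` / `post` list-columns.
#' @return The pairs tibble with `score` (probability of the responder
#'   class) and `pred` columns appended, image columns dropped.
#' @export
predict_pairs <- function(model, pairs) {
  scores <- vapply(seq_len(nrow(pairs)), function(i) {
    logits <- tp_val(nd_forward_pair(model, pairs$pre[[i]], pairs$post[[i]],
                                     training = FALSE))
    z <- logits[1L, ] - max(logits[1L, ])
    p <- exp(z) / sum(exp(z))
    p[2L]
  }, numeric(1))
  out <- dplyr::select(pairs, -dplyr::any_of(c("pre", "post")))
  out$score <- scores
  out$pred <- as.integer(scores >= 0.5)
  out
}

# ---- parameter/state snapshots ----------------------------------------------

model_param_values <- function(model) {
  lapply(model$param_list, function(p) p$val)
}

model_set_params <- function(model, values) {
  for (i in seq_along(values)) model$param_list[[i]]$val <- values[[i]]
  invisible(model)
}

collect_bn_states <- function(x) {
  out <- list()
  walk <- function(y) {
    if (is.environment(y) && !is_node(y)) {
      out[[length(out) + 1L]] <<- y
    } else if (is.list(y)) for (el in y) walk(el)
  }
  walk(x)
  out
}

model_bn_values <- function(model) {
  lapply(collect_bn_states(model$params), function(st) {
    list(mean = st$running_mean, var = st$running_var)
  })
}

model_set_bn <- function(model, values) {
  sts <- collect_bn_states(model$params)
  for (i in seq_along(sts)) {
    sts[[i]]$running_mean <- values[[i]]$mean
    sts[[i]]$running_var <- values[[i]]$var
  }
  invisible(model)
}
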
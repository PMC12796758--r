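#' Spatio-temporal embedding (ST)
#'
#' Combines an image-specific dynamic position embedding (DPE) — generated
#' by a small convolutional network from the token map itself — with a
#' sinusoidal temporal embedding (TE) indexed by the timepoint (0 = pre,
#' 1 = post). Their sum is added to each arm's tokens before the shared
#' encoder. Ablation modes replace the DPE with a learned static table
#' (SPE) or drop either component.
#'
#' @name st-embed
NULL

#' Sinusoidal temporal embedding
#'
#' `TE_t[2j] = sin(t / 10000^(2j/d))`, `TE_t[2j+1] = cos(t / 10000^(2j/d))`
#' (0-based positions), for timepoint `t` in {0, 1} and even dimension `d`.
#'
#' @param t Timepoint, 0 (pre-treatment) or 1 (post-first-cycle).
#' @param d Even embedding dimension (>= 2).
#' @return Numeric vector of length `d`, entries in `[-1, 1]`.
#' @export
temporal_embedding <- function(t, d) {
  if (d %% 2 != 0 || d < 2) abort_validation("d", "must be even and >= 2")
  if (!t %in% c(0, 1)) abort_validation("t", "timepoint must be 0 or 1")
  j <- seq_len(d %/% 2) - 1L
  freq <- t / 10000^(2 * j / d)
  te <- numeric(d)
  te[2 * j + 1L] <- sin(freq)
  te[2 * j + 2L] <- cos(freq)
  te
}

# DPE network: 3x3 -> 3x3 -> 1x1 convolutions, each with batch
# normalisation and ReLU, followed by the linear projection W_pos / b_pos.
new_dpe <- function(c_dim, name = "dpe") {
  list(conv1 = new_conv(3L, c_dim, c_dim, paste0(name, ".conv1")),
       bn1 = new_bn(c_dim, paste0(name, ".bn1")),
       conv2 = new_conv(3L, c_dim, c_dim, paste0(name, ".conv2")),
       bn2 = new_bn(c_dim, paste0(name, ".bn2")),
       conv3 = new_conv(1L, c_dim, c_dim, paste0(name, ".conv3")),
       bn3 = new_bn(c_dim, paste0(name, ".bn3")),
       pos = new_linear(c_dim, c_dim, paste0(name, ".pos")))
}

nd_dpe <- function(dpe, tokens, geom, training = TRUE) {
  x <- tp_relu(fw_bn(dpe$bn1, fw_conv(dpe$conv1, tokens, geom), training))
  x <- tp_relu(fw_bn(dpe$bn2, fw_conv(dpe$conv2, x, geom), training))
  x <- tp_relu(fw_bn(dpe$bn3, fw_conv(dpe$conv3, x, geom), training))
  fw_linear(dpe$pos, x)
}

#' Dynamic position embedding of a token sequence
#'
#' The tokens are interpreted on their map grid, passed through the
#' three-layer convolutional feature extractor, and projected by the
#' learned `W_pos` / `b_pos`; the embedding is data-dependent, so distinct
#' images receive distinct embeddings, unlike a shared static table.
#'
#' @param tokens `[l x c]` matrix with `l = h * w`.
#' @param h,w Map geometry.
#' @param weights DPE network weights (`nactresp:::new_dpe(c)`).
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return `[l x c]` embedding matrix.
#' @export
dynamic_position_embedding <- function(tokens, h, w, weights = NULL,
                                       training = TRUE) {
  if (h * w != nrow(tokens)) {
    abort_validation("tokens", "token count must equal h * w")
  }
  if (is.null(weights)) weights <- new_dpe(ncol(tokens))
  tp_val(nd_dpe(weights, tp_const(tokens), list(h = h, w = w), training))
}

#' Combine a position embedding with the temporal embedding
#'
#' `ST = DPE + TE_t`, the temporal vector broadcast identically to every
#' token row; the pre arm uses `t = 0`, the post arm `t = 1`.
#'
#' @param dpe `[l x d]` position-embedding matrix.
#' @param t Timepoint in {0, 1}.
#' @return `[l x d]` spatio-temporal embedding with the timepoint attached
#'   as the `"timepoint"` attribute.
#' @export
fuse_spatiotemporal <- function(dpe, t) {
  te <- temporal_embedding(t, ncol(dpe))
  structure(sweep(dpe, 2L, te, "+"), timepoint = t)
}

#' Add a spatio-temporal embedding to a token sequence
#'
#' Elementwise sum; invertible given the embedding.
#'
#' @param tokens,st Same-shape matrices.
#' @return `tokens + st`.
#' @export
embed_tokens <- function(tokens, st) {
  if (!all(dim(tokens) == dim(st))) {
    abort_validation("st", "shape mismatch with tokens")
  }
  tokens + st
}

# ST module parameters; the SPE table needs the final token geometry
new_st <- function(c_dim, n_tokens, mode = "full", name = "st") {
  list(dpe = new_dpe(c_dim, paste0(name, ".dpe")),
       spe = tp_param(matrix(stats::rnorm(n_tokens * c_dim, sd = 0.02),
                             n_tokens, c_dim), paste0(name, ".spe")),
       mode = mode)
}

# apply the configured spatio-temporal embedding to one arm's tokens
nd_st_apply <- function(st, tokens, geom, t, training = TRUE) {
  mode <- st$mode
  if (mode == "none") return(tokens)
  spatial <- switch(mode,
    te = NULL,
    dpe = , full = nd_dpe(st$dpe, tokens, geom, training),
    spe = , spe_te = st$spe,
    NULL)
  out <- tokens
  if (!is.null(spatial)) out <- tp_add(out, spatial)
  if (mode %in% c("te", "spe_te", "full")) {
    te <- matrix(temporal_embedding(t, ncol(tp_val(tokens))), nrow = 1L)
    out <- tp_add_bias(out, tp_const(te))
  }
  out
}
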
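#' Enhanced isolated tokens-to-token embedding (EiT2T)
#'
#' Two parameter-isolated arms — one per timepoint — progressively
#' re-tokenise the image. Each block applies a transformer step, reshapes
#' tokens to a spatial map, extracts multi-scale convolutional features,
#' fuses windowed-local and global attention per scale with learned weights
#' constrained to sum to one, fuses the scales with softmax weights, and
#' re-tokenises via an overlapping soft split.
#'
#' Token sequences are stored as `[l x c]` matrices whose rows are ordered
#' row-major over the (h, w) map grid, so reshaping between tokens and maps
#' is a geometry annotation rather than a data movement.
#'
#' @name eit2t
NULL

#' Reshape a token sequence to a spatial feature map
#'
#' Validates that `h * w` equals the token count and annotates the matrix
#' with its map geometry; the row-major storage convention makes
#' flatten-then-reshape the identity.
#'
#' @param features `[l x c]` matrix.
#' @param h,w Map height and width with `h * w == l`.
#' @return The same matrix with `h`/`w` attributes.
#' @export
reshape_to_map <- function(features, h, w) {
  if (h * w != nrow(features)) {
    abort_validation("h,w", sprintf("h*w = %d does not match token count %d",
                                    h * w, nrow(features)))
  }
  structure(features, h = h, w = w)
}

#' Overlapping soft split of a feature map into tokens
#'
#' Extracts all `k x k` patches at stride `s` after zero-padding by `p`.
#' The token count is `(floor((h + 2p - k)/s) + 1) * (floor((w + 2p - k)/s)
#' + 1)` and the token dimension `k^2 * c`; patches and kernel elements are
#' ordered row-major. With `k = s` and `p = 0` this degenerates to the
#' conventional non-overlapping hard patch split.
#'
#' @param map `[h*w x c]` feature-map matrix.
#' @param h,w Map geometry.
#' @param k,s,p Kernel, stride, zero padding.
#' @return `[l' x k^2*c]` token matrix with `out_h`/`out_w` attributes.
#' @export
soft_split <- function(map, h, w, k, s, p) {
  ui <- unfold_indices(h, w, k, s, p)
  out <- tp_val(tp_unfold_idx(tp_const(map), ui$idx))
  structure(out, out_h = ui$out_h, out_w = ui$out_w)
}

#' One isolated transformer step
#'
#' A pre-norm multi-head self-attention + feed-forward block. The two
#' timepoint arms never share these weights; passing the same `weights` to
#' both arms is the weight-copy control used in tests.
#'
#' @param tokens `[l x c]` matrix (finite).
#' @param weights Block weights from `nactresp:::new_block(c, heads)`;
#'   `NULL` draws a fresh initialisation.
#' @param heads Attention heads used when `weights` is `NULL`.
#' @return `[l x c]` matrix.
#' @export
isolated_transformer_step <- function(tokens, weights = NULL, heads = 2) {
  if (any(!is.finite(tokens))) abort_validation("tokens", "non-finite input")
  if (is.null(weights)) weights <- new_block(ncol(tokens), heads)
  tp_val(fw_block(weights, tp_const(tokens)))
}

#' Multi-scale convolution of a feature map
#'
#' One same-padded convolution per odd kernel size; every output map keeps
#' the input's spatial extent.
#'
#' @param map `[h*w x c]` matrix.
#' @param h,w Map geometry.
#' @param kernel_sizes Odd kernel sizes, e.g. `c(3, 5, 7)`.
#' @param weights Optional list of conv weights (`nactresp:::new_conv`).
#' @return List of `[h*w x c]` matrices, one per scale.
#' @export
multiscale_conv <- function(map, h, w, kernel_sizes, weights = NULL) {
  if (any(kernel_sizes %% 2 == 0)) {
    abort_validation("kernel_sizes", "kernel sizes must be odd")
  }
  c_in <- ncol(map)
  if (is.null(weights)) {
    weights <- lapply(kernel_sizes, function(k) new_conv(k, c_in, c_in))
  }
  geom <- list(h = h, w = w)
  lapply(seq_along(kernel_sizes), function(j) {
    tp_val(fw_conv(weights[[j]], tp_const(map), geom))
  })
}

#' Global self-attention over a feature map
#'
#' Full `softmax(Q K' / sqrt(d_k)) V` over all `h * w` positions, with Q, K,
#' V from single-head linear projections.
#'
#' @param map `[l x c]` matrix.
#' @param weights Q/K/V projection weights (`nactresp:::new_qkv`); shared
#'   with [local_attention()] for the window-equals-extent equivalence.
#' @return `[l x c]` matrix.
#' @export
global_attention <- function(map, weights = NULL) {
  if (any(!is.finite(map))) abort_validation("map", "non-finite input")
  if (is.null(weights)) weights <- new_qkv(ncol(map))
  tp_val(fw_global_attention(weights, tp_const(map)))
}

#' Windowed local self-attention over a feature map
#'
#' Self-attention computed independently inside non-overlapping
#' `window x window` windows; positions never attend across windows. Maps
#' whose extent is not a multiple of the window are zero-padded (the padded
#' query/key/value rows are zero vectors) and cropped after.
#'
#' @param map `[h*w x c]` matrix.
#' @param h,w Map geometry.
#' @param window Window side length (positive).
#' @param weights Q/K/V projection weights shared with [global_attention()].
#' @return `[h*w x c]` matrix.
#' @export
local_attention <- function(map, h, w, window, weights = NULL) {
  if (window <= 0) abort_validation("window", "must be positive")
  if (is.null(weights)) weights <- new_qkv(ncol(map))
  tp_val(fw_local_attention(weights, tp_const(map), list(h = h, w = w),
                            window))
}

#' Fuse local and global attention maps with learned convex weights
#'
#' `alpha` and `beta` are the softmax of two learned scalars, so
#' `alpha + beta = 1` holds by construction.
#'
#' @param F_local,F_global Same-shape matrices.
#' @param logits Length-2 numeric: the learned scalars.
#' @return The fused matrix, with the realised `(alpha, beta)` attached as
#'   the `"weights"` attribute.
#' @export
fuse_local_global <- function(F_local, F_global, logits = c(0, 0)) {
  if (!all(dim(F_local) == dim(F_global))) {
    abort_validation("maps", "shape mismatch")
  }
  ab <- exp(logits - max(logits))
  ab <- ab / sum(ab)
  structure(ab[1] * F_local + ab[2] * F_global, weights = ab)
}

#' Fuse per-scale maps with softmax scale weights
#'
#' Each scale map is summarised by global average pooling; the pooled
#' descriptors are concatenated and passed through a fully connected layer
#' followed by a softmax, yielding nonnegative scale weights that sum to 1.
#'
#' @param maps Non-empty list of same-shape matrices.
#' @param weights Linear layer (`nactresp:::new_linear(n*c, n)`).
#' @return Weighted-sum matrix with the scale weights as attribute.
#' @export
fuse_scales <- function(maps, weights = NULL) {
  if (length(maps) == 0L) abort_validation("maps", "need at least one map")
  n <- length(maps)
  c_in <- ncol(maps[[1]])
  if (is.null(weights)) weights <- new_linear(n * c_in, n)
  out <- nd_fuse_scales(lapply(maps, tp_const), weights)
  structure(tp_val(out$map), weights = as.vector(tp_val(out$omega)))
}

# ---- tape-level forward passes ---------------------------------------------

nd_fuse_scales <- function(map_nodes, fc) {
  pooled <- lapply(map_nodes, tp_mean_rows)
  desc <- Reduce(tp_concat_cols, pooled)
  omega <- tp_softmax_rows(fw_linear(fc, desc))
  acc <- NULL
  for (j in seq_along(map_nodes)) {
    term <- tp_scale_by(map_nodes[[j]], tp_slice_cols(omega, j))
    acc <- if (is.null(acc)) term else tp_add(acc, term)
  }
  list(map = acc, omega = omega)
}

nd_fuse_local_global <- function(local_nd, global_nd, ab_logits) {
  ab <- tp_softmax_rows(ab_logits)
  tp_add(tp_scale_by(local_nd, tp_slice_cols(ab, 1L)),
         tp_scale_by(global_nd, tp_slice_cols(ab, 2L)))
}

# parameters of one EiT2T block for one arm
new_eit2t_block <- function(c_dim, heads, scales, window, split,
                            mlp_ratio = 2, name = "eit2t") {
  list(
    transformer = new_block(c_dim, heads, mlp_ratio, paste0(name, ".tf")),
    convs = lapply(seq_along(scales), function(j) {
      new_conv(scales[j], c_dim, c_dim, paste0(name, ".conv", j))
    }),
    qkv = lapply(seq_along(scales), function(j) {
      new_qkv(c_dim, paste0(name, ".qkv", j))
    }),
    ab_logits = lapply(seq_along(scales), function(j) {
      tp_param(matrix(0, 1L, 2L), paste0(name, ".ab", j))
    }),
    scale_fc = new_linear(length(scales) * c_dim, length(scales),
                          paste0(name, ".scale_fc")),
    proj = new_linear(split$k^2 * c_dim, c_dim, paste0(name, ".proj")),
    scales = scales, window = window, split = split
  )
}

# forward one arm's tokens through one EiT2T block; returns tokens + geometry
nd_eit2t_block <- function(blk, tokens, geom) {
  x <- fw_block(blk$transformer, tokens)
  # tokens are row-major over (h, w): reshape is an annotation only
  scale_maps <- vector("list", length(blk$scales))
  for (j in seq_along(blk$scales)) {
    conv_out <- fw_conv(blk$convs[[j]], x, geom)
    f_local <- fw_local_attention(blk$qkv[[j]], conv_out, geom, blk$window)
    f_global <- fw_global_attention(blk$qkv[[j]], conv_out)
    scale_maps[[j]] <- nd_fuse_local_global(f_local, f_global,
                                            blk$ab_logits[[j]])
  }
  fused <- nd_fuse_scales(scale_maps, blk$scale_fc)$map
  ui <- unfold_indices(geom$h, geom$w, blk$split$k, blk$split$s, blk$split$p)
  tokens_next <- tp_unfold_idx(fused, ui$idx)
  list(tokens = fw_linear(blk$proj, tokens_next),
       geom = list(h = ui$out_h, w = ui$out_w))
}

#' Run one EiT2T block on both timepoint arms
#'
#' Composes the isolated transformer step, reshape, multi-scale convolution
#' with per-scale local/global attention fusion, scale fusion, and soft
#' split, independently per arm with arm-specific parameters. The soft-split
#' output is linearly projected back to the block's token dimension so the
#' geometry halves while the channel width stays fixed.
#'
#' @param pre_tokens,post_tokens `[l x c]` token matrices.
#' @param h,w Map geometry of the incoming tokens.
#' @param params List with `before` and `after` block parameters
#'   (`nactresp:::new_eit2t_block`); `NULL` draws fresh, independent arms.
#' @param heads,scales,window,split Architecture settings used when
#'   `params` is `NULL`.
#' @return List with `pre`, `post` token matrices and `out_h`, `out_w`.
#' @export
eit2t_block <- function(pre_tokens, post_tokens, h, w, params = NULL,
                        heads = 2, scales = c(3, 5), window = 4,
                        split = list(k = 3, s = 2, p = 1)) {
  if (is.null(params)) {
    c_dim <- ncol(pre_tokens)
    params <- list(before = new_eit2t_block(c_dim, heads, scales, window, split),
                   after = new_eit2t_block(c_dim, heads, scales, window, split))
  }
  geom <- list(h = h, w = w)
  pre_out <- nd_eit2t_block(params$before, tp_const(pre_tokens), geom)
  post_out <- nd_eit2t_block(params$after, tp_const(post_tokens), geom)
  list(pre = tp_val(pre_out$tokens), post = tp_val(post_out$tokens),
       out_h = pre_out$geom$h, out_w = pre_out$geom$w)
}
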
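#' Adaptive feature fusion and classification (AFFC)
#'
#' Both arms' embedded token sequences pass through one transformer encoder
#' with shared parameters. The pooled arm features drive adaptive fusion
#' weights (alpha, beta); the fused features are concatenated with the
#' explicit feature difference, pooled, and classified into the two-class
#' decision. The head is deliberately asymmetric in its two inputs — the
#' difference term carries the direction of change — which is the temporal
#' signal the model is designed to capture.
#'
#' @name affc
NULL

new_encoder <- function(c_dim, heads, depth, mlp_ratio = 2, name = "enc") {
  lapply(seq_len(depth), function(i) {
    new_block(c_dim, heads, mlp_ratio, paste0(name, i))
  })
}

nd_encode <- function(encoder, tokens) {
  for (blk in encoder) tokens <- fw_block(blk, tokens)
  tokens
}

#' Encode both arms with a shared-parameter transformer encoder
#'
#' One encoder, applied to each arm's sequence with the same weights; the
#' parameter count of this stage is independent of the number of arms.
#'
#' @param pre_tokens,post_tokens Same-shape `[N x D]` matrices.
#' @param weights Encoder weights (`nactresp:::new_encoder`).
#' @param heads,depth Used when `weights` is `NULL`.
#' @return List with `pre` and `post` encoded features.
#' @export
shared_encode <- function(pre_tokens, post_tokens, weights = NULL,
                          heads = 2, depth = 2) {
  if (!all(dim(pre_tokens) == dim(post_tokens))) {
    abort_validation("tokens", "pre and post shapes must match")
  }
  if (is.null(weights)) weights <- new_encoder(ncol(pre_tokens), heads, depth)
  list(pre = tp_val(nd_encode(weights, tp_const(pre_tokens))),
       post = tp_val(nd_encode(weights, tp_const(post_tokens))))
}

#' Global average pooling over the token axis
#'
#' @param F `[N x D]` matrix, `N >= 1`.
#' @return Length-`D` vector of column means.
#' @export
global_average_pool <- function(F) {
  if (is.null(dim(F)) || nrow(F) < 1L) abort_validation("F", "empty features")
  colMeans(F)
}

#' Adaptive fusion weights from the pooled arm features
#'
#' Concatenates the two pooled vectors, applies a fully connected layer with
#' two outputs, and a softmax; the result is a convex pair (alpha, beta).
#'
#' @param pooled_before,pooled_after Length-`D` vectors.
#' @param weights Linear layer (`nactresp:::new_linear(2 * D, 2)`); a
#'   zero-initialised layer yields (0.5, 0.5).
#' @return Named numeric `c(alpha = , beta = )`.
#' @export
adaptive_fusion_weights <- function(pooled_before, pooled_after,
                                    weights = NULL) {
  if (any(!is.finite(c(pooled_before, pooled_after)))) {
    abort_validation("pooled", "non-finite input")
  }
  d2 <- length(pooled_before) + length(pooled_after)
  if (is.null(weights)) weights <- new_linear(d2, 2L)
  logits <- tp_val(fw_linear(weights, tp_const(
    matrix(c(pooled_before, pooled_after), nrow = 1L))))
  ab <- exp(logits - max(logits))
  ab <- as.vector(ab / sum(ab))
  stats::setNames(ab, c("alpha", "beta"))
}

#' Convex fusion of the two arms' features
#'
#' `F_fused = alpha * F_before + beta * F_after` with `alpha + beta = 1`.
#'
#' @param F_before,F_after Same-shape matrices.
#' @param alpha,beta Nonnegative weights summing to 1.
#' @return The fused matrix.
#' @export
fuse_features <- function(F_before, F_after, alpha, beta) {
  if (!all(dim(F_before) == dim(F_after))) {
    abort_validation("features", "shape mismatch")
  }
  if (abs(alpha + beta - 1) > 1e-6 || alpha < 0 || beta < 0) {
    abort_validation("alpha,beta", "weights must be nonnegative and sum to 1")
  }
  alpha * F_before + beta * F_after
}

#' Explicit feature difference between timepoints
#'
#' `deltaF = F_after - F_before`, the direct representation of
#' treatment-induced change.
#'
#' @param F_before,F_after Same-shape matrices.
#' @return The difference matrix.
#' @export
feature_difference <- function(F_before, F_after) {
  if (!all(dim(F_before) == dim(F_after))) {
    abort_validation("features", "shape mismatch")
  }
  F_after - F_before
}

#' Two-class decision from fused features and feature difference
#'
#' Concatenates `[F_fused ; deltaF]` along the feature axis, applies global
#' average pooling, a fully connected layer, and a softmax. The predicted
#' label is the argmax with ties broken to the lower class index.
#'
#' @param F_fused,deltaF Same-shape `[N x D]` matrices.
#' @param weights Classifier layer (`nactresp:::new_linear(2 * D, 2)`).
#' @return List with `probabilities` (length 2, sums to 1) and `label`
#'   (0 or 1).
#' @export
classify <- function(F_fused, deltaF, weights = NULL) {
  if (!all(dim(F_fused) == dim(deltaF))) {
    abort_validation("features", "shape mismatch")
  }
  if (is.null(weights)) weights <- new_linear(2L * ncol(F_fused), 2L)
  pooled <- matrix(global_average_pool(cbind(F_fused, deltaF)), nrow = 1L)
  logits <- tp_val(fw_linear(weights, tp_const(pooled)))
  p <- exp(logits - max(logits))
  p <- as.vector(p / sum(p))
  list(probabilities = p, label = which.max(p) - 1L)
}

# AFFC head parameters
new_affc <- function(d, name = "affc") {
  list(fusion_fc = new_linear(2L * d, 2L, paste0(name, ".fusion")),
       cls_fc = new_linear(2L * d, 2L, paste0(name, ".cls")))
}

# tape-level AFFC head: arm features -> 2 logits
nd_affc <- function(head, f_before, f_after) {
  pb <- tp_mean_rows(f_before)
  pa <- tp_mean_rows(f_after)
  ab <- tp_softmax_rows(fw_linear(head$fusion_fc, tp_concat_cols(pb, pa)))
  fused <- tp_add(tp_scale_by(f_before, tp_slice_cols(ab, 1L)),
                  tp_scale_by(f_after, tp_slice_cols(ab, 2L)))
  delta <- tp_sub(f_after, f_before)
  pooled <- tp_mean_rows(tp_concat_cols(fused, delta))
  fw_linear(head$cls_fc, pooled)
}

# CLS-token ablation head parameters: a learnable token per arm plus a
# classifier on the concatenated encoded CLS outputs
new_cls_head <- function(d, name = "clshead") {
  list(cls_token = tp_param(matrix(stats::rnorm(d, sd = 0.02), 1L, d),
                            paste0(name, ".token")),
       fc = new_linear(2L * d, 2L, paste0(name, ".fc")))
}
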
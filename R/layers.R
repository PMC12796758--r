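# Network layers built on the autodiff tape, plus the index arithmetic for
# feature-map geometry. A feature map with geometry (h, w) is stored as an
# [h*w x c] matrix whose rows are ordered row-major (row index varies slowest),
# matching the token ordering used throughout.

# ---- geometry ---------------------------------------------------------------

# Index map for overlapping patch extraction (soft split / convolution).
# Returns idx [l' x k^2] of source row indices into the unpadded map, 0 for
# zero-padding; kernel elements ordered row-major.
.geom_cache <- new.env(parent = emptyenv())

unfold_indices <- function(h, w, k, s, p) {
  key <- paste("u", h, w, k, s, p, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k > h + 2 * p || k > w + 2 * p) {
    stop("kernel size ", k, " exceeds padded extent", call. = FALSE)
  }
  out_h <- (h + 2 * p - k) %/% s + 1L
  out_w <- (w + 2 * p - k) %/% s + 1L
  idx <- matrix(0L, out_h * out_w, k * k)
  t <- 0L
  for (orow in seq_len(out_h)) {
    for (ocol in seq_len(out_w)) {
      t <- t + 1L
      e <- 0L
      for (dr in seq_len(k)) {
        src_r <- (orow - 1L) * s + dr - p
        for (dc in seq_len(k)) {
          e <- e + 1L
          src_c <- (ocol - 1L) * s + dc - p
          if (src_r >= 1L && src_r <= h && src_c >= 1L && src_c <= w) {
            idx[t, e] <- (src_r - 1L) * w + src_c
          }
        }
      }
    }
  }
  res <- list(idx = idx, out_h = out_h, out_w = out_w)
  .geom_cache[[key]] <- res
  res
}

# Partition an (h, w) map into non-overlapping win x win windows after zero
# padding up to multiples of win. Returns the gather index (rows of the padded
# window stack, 0 = pad) and the inverse gather restoring original order.
window_indices <- function(h, w, win) {
  key <- paste("w", h, w, win, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (win <= 0) stop("window size must be positive", call. = FALSE)
  nwr <- ceiling(h / win)
  nwc <- ceiling(w / win)
  gather <- integer(nwr * nwc * win * win)
  pos <- 0L
  for (wr in seq_len(nwr)) {
    for (wc in seq_len(nwc)) {
      for (r in seq_len(win)) {
        src_r <- (wr - 1L) * win + r
        for (cc in seq_len(win)) {
          pos <- pos + 1L
          src_c <- (wc - 1L) * win + cc
          gather[pos] <- if (src_r <= h && src_c <= w) {
            (src_r - 1L) * w + src_c
          } else 0L
        }
      }
    }
  }
  inverse <- integer(h * w)
  inverse[gather[gather > 0L]] <- seq_along(gather)[gather > 0L]
  res <- list(gather = gather, inverse = inverse,
              n_windows = nwr * nwc, win = win)
  .geom_cache[[key]] <- res
  res
}

# ---- parameter initialisation ----------------------------------------------

glorot <- function(d_in, d_out) {
  matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / (d_in + d_out))), d_in, d_out)
}

new_linear <- function(d_in, d_out, name = "linear") {
  list(W = tp_param(glorot(d_in, d_out), paste0(name, ".W")),
       b = tp_param(matrix(0, 1L, d_out), paste0(name, ".b")))
}

fw_linear <- function(layer, x) tp_linear(x, layer$W, layer$b)

new_ln <- function(d, name = "ln") {
  list(gamma = tp_param(matrix(1, 1L, d), paste0(name, ".gamma")),
       beta = tp_param(matrix(0, 1L, d), paste0(name, ".beta")))
}

fw_ln <- function(layer, x) tp_layernorm(x, layer$gamma, layer$beta)

new_bn <- function(d, name = "bn") {
  list(gamma = tp_param(matrix(1, 1L, d), paste0(name, ".gamma")),
       beta = tp_param(matrix(0, 1L, d), paste0(name, ".beta")),
       state = new.env(parent = emptyenv()))
}

fw_bn <- function(layer, x, training = TRUE) {
  tp_batchnorm(x, layer$gamma, layer$beta, layer$state, training = training)
}

# ---- attention --------------------------------------------------------------

scaled_dot_attention <- function(Q, K, V, d_k) {
  S <- tp_smul(tp_matmul_t(Q, K), 1 / sqrt(d_k))
  tp_matmul(tp_softmax_rows(S), V)
}

# single-head Q/K/V projections used by the local-global attention pair;
# the same projection weights serve both branches of a scale.
new_qkv <- function(d, name = "qkv") {
  list(q = new_linear(d, d, paste0(name, ".q")),
       k = new_linear(d, d, paste0(name, ".k")),
       v = new_linear(d, d, paste0(name, ".v")))
}

fw_global_attention <- function(layer, x) {
  d_k <- ncol(tp_val(x))
  scaled_dot_attention(fw_linear(layer$q, x), fw_linear(layer$k, x),
                       fw_linear(layer$v, x), d_k)
}

fw_local_attention <- function(layer, x, geom, win) {
  d_k <- ncol(tp_val(x))
  Q <- fw_linear(layer$q, x)
  K <- fw_linear(layer$k, x)
  V <- fw_linear(layer$v, x)
  wi <- window_indices(geom$h, geom$w, win)
  Qw <- tp_gather_rows(Q, wi$gather)
  Kw <- tp_gather_rows(K, wi$gather)
  Vw <- tp_gather_rows(V, wi$gather)
  ww <- wi$win * wi$win
  stacked <- tp_block_attention(Qw, Kw, Vw, ww, d_k)
  tp_gather_rows(stacked, wi$inverse)
}

# multi-head self-attention with output projection (transformer blocks)
new_mhsa <- function(d, heads, name = "mhsa") {
  stopifnot(d %% heads == 0L)
  list(qkv = new_qkv(d, paste0(name, ".qkv")),
       o = new_linear(d, d, paste0(name, ".o")),
       heads = heads, d = d)
}

fw_mhsa <- function(layer, x) {
  Q <- fw_linear(layer$qkv$q, x)
  K <- fw_linear(layer$qkv$k, x)
  V <- fw_linear(layer$qkv$v, x)
  fw_linear(layer$o, tp_multihead_attention(Q, K, V, layer$heads))
}

new_ffn <- function(d, ratio = 2, name = "ffn") {
  hidden <- d * ratio
  list(fc1 = new_linear(d, hidden, paste0(name, ".fc1")),
       fc2 = new_linear(hidden, d, paste0(name, ".fc2")))
}

fw_ffn <- function(layer, x) fw_linear(layer$fc2, tp_relu(fw_linear(layer$fc1, x)))

# pre-norm transformer block: x + MHSA(LN(x)); x + FFN(LN(x))
new_block <- function(d, heads, ratio = 2, name = "block") {
  list(ln1 = new_ln(d, paste0(name, ".ln1")),
       attn = new_mhsa(d, heads, paste0(name, ".attn")),
       ln2 = new_ln(d, paste0(name, ".ln2")),
       ffn = new_ffn(d, ratio, paste0(name, ".ffn")))
}

fw_block <- function(layer, x) {
  x <- tp_add(x, fw_mhsa(layer$attn, fw_ln(layer$ln1, x)))
  tp_add(x, fw_ffn(layer$ffn, fw_ln(layer$ln2, x)))
}

# same-padded 2-D convolution on an [h*w x c_in] map via unfold + matmul
new_conv <- function(k, c_in, c_out, name = "conv") {
  list(W = tp_param(glorot(k * k * c_in, c_out), paste0(name, ".W")),
       b = tp_param(matrix(0, 1L, c_out), paste0(name, ".b")),
       k = k)
}

fw_conv <- function(layer, x, geom) {
  k <- layer$k
  ui <- unfold_indices(geom$h, geom$w, k, 1L, (k - 1L) %/% 2L)
  patches <- tp_unfold_idx(x, ui$idx)
  tp_linear(patches, layer$W, layer$b)
}

# ---- parameter collection ---------------------------------------------------

collect_params <- function(x) {
  out <- list()
  walk <- function(y) {
    if (is_node(y)) {
      if (isTRUE(y$is_param)) out[[length(out) + 1L]] <<- y
    } else if (is.list(y)) {
      for (el in y) walk(el)
    }
  }
  walk(x)
  out
}
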
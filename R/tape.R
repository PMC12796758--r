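# Reverse-mode automatic differentiation over numeric matrices.
#
# Every tensor flowing through the network is a numeric matrix; a tape node
# wraps one value together with its parents and a backward closure. The graph
# is built eagerly by the forward pass; tp_backward() walks it in reverse
# creation order, so no explicit topological sort is needed beyond the
# monotone node counter.

.tp <- new.env(parent = emptyenv())
.tp$counter <- 0L

tp_node <- function(val, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  .tp$counter <- .tp$counter + 1L
  n$id <- .tp$counter
  class(n) <- "tp_node"
  n
}

#' @noRd
tp_param <- function(val, name = NULL) {
  n <- tp_node(as_mat(val))
  n$is_param <- TRUE
  n$name <- name
  n
}

tp_const <- function(x) tp_node(as_mat(x))

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

as_tp <- function(x) if (inherits(x, "tp_node")) x else tp_const(x)

tp_val <- function(x) if (inherits(x, "tp_node")) x$val else x

is_node <- function(x) inherits(x, "tp_node")

#' Backpropagate from a scalar (1x1) root node.
#'
#' Accumulates gradients into `$grad` of every reachable node; parameters keep
#' theirs until tp_zero_grads() is called.
#' @noRd
tp_backward <- function(root, seed = NULL) {
  if (is.null(seed)) seed <- matrix(1, nrow(root$val), ncol(root$val))
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 256L)
  nn <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (nd in nodes) nd$grad <- NULL
  root$grad <- seed
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(root)
}

tp_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

tp_matmul <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  tp_node(a$val %*% b$val, list(a, b), function(g) {
    list(tcrossprod(g, b$val), crossprod(a$val, g))
  })
}

# a %*% t(b) without materialising the transpose
tp_matmul_t <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  tp_node(tcrossprod(a$val, b$val), list(a, b), function(g) {
    list(g %*% b$val, crossprod(g, a$val))
  })
}

tp_t <- function(a) {
  a <- as_tp(a)
  tp_node(t(a$val), list(a), function(g) list(t(g)))
}

tp_add <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  stopifnot(all(dim(a$val) == dim(b$val)))
  tp_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

tp_sub <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  stopifnot(all(dim(a$val) == dim(b$val)))
  tp_node(a$val - b$val, list(a, b), function(g) list(g, -g))
}

# add a [1 x d] bias row to every row of a [n x d] matrix
tp_add_bias <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  stopifnot(ncol(a$val) == ncol(b$val), nrow(b$val) == 1L)
  n <- nrow(a$val)
  tp_node(a$val + rep(b$val[1L, ], each = n), list(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

# broadcast a [1 x d] row to every row of an [n x d] target and add
tp_add_row_broadcast <- function(a, row) {
  tp_add_bias(a, row)
}

tp_smul <- function(a, s) {
  a <- as_tp(a)
  stopifnot(is.numeric(s), length(s) == 1L)
  tp_node(a$val * s, list(a), function(g) list(g * s))
}

# multiply a matrix node by a 1x1 scalar node
tp_scale_by <- function(a, s) {
  a <- as_tp(a); s <- as_tp(s)
  stopifnot(length(s$val) == 1L)
  tp_node(a$val * s$val[1L], list(a, s), function(g) {
    list(g * s$val[1L], matrix(sum(g * a$val), 1L, 1L))
  })
}

tp_mul <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  stopifnot(all(dim(a$val) == dim(b$val)))
  tp_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

tp_relu <- function(a) {
  a <- as_tp(a)
  m <- a$val > 0
  tp_node(a$val * m, list(a), function(g) list(g * m))
}

tp_softmax_rows <- function(a) {
  a <- as_tp(a)
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  tp_node(p, list(a), function(g) {
    list((g - rowSums(g * p)) * p)
  })
}

tp_mean_rows <- function(a) {
  a <- as_tp(a)
  n <- nrow(a$val)
  tp_node(matrix(colMeans(a$val), nrow = 1L), list(a), function(g) {
    list(matrix(rep(g[1L, ] / n, each = n), nrow = n))
  })
}

tp_concat_cols <- function(a, b) {
  a <- as_tp(a); b <- as_tp(b)
  na <- ncol(a$val)
  tp_node(cbind(a$val, b$val), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

tp_concat_rows <- function(nodes) {
  nodes <- lapply(nodes, as_tp)
  ns <- vapply(nodes, function(x) nrow(x$val), integer(1))
  ends <- cumsum(ns)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_node(do.call(rbind, lapply(nodes, function(x) x$val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      g[starts[i]:ends[i], , drop = FALSE]
    })
  })
}

tp_slice_cols <- function(a, cols) {
  a <- as_tp(a)
  nc <- ncol(a$val)
  tp_node(a$val[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

# gather rows by index; idx == 0 yields a zero row (used for spatial padding)
tp_gather_rows <- function(a, idx) {
  a <- as_tp(a)
  nr <- nrow(a$val)
  pad <- idx == 0L
  out <- a$val[pmax(idx, 1L), , drop = FALSE]
  if (any(pad)) out[pad, ] <- 0
  tp_node(out, list(a), function(g) {
    list(scatter_rows(g, idx, nr))
  })
}

scatter_rows <- function(g, idx, nrow_out) {
  keep <- idx > 0L
  out <- matrix(0, nrow_out, ncol(g))
  if (!any(keep)) return(out)
  ik <- idx[keep]
  if (anyDuplicated(ik) == 0L) {
    out[ik, ] <- g[keep, , drop = FALSE]
  } else {
    rs <- rowsum(g[keep, , drop = FALSE], group = ik, reorder = FALSE)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# unfold (soft split): idx is an [l' x K] matrix of source-row indices (0 = pad);
# output is [l' x K*c], column blocks ordered by kernel element.
tp_unfold_idx <- function(a, idx) {
  a <- as_tp(a)
  K <- ncol(idx)
  c_in <- ncol(a$val)
  nr <- nrow(a$val)
  av <- a$val
  blocks <- lapply(seq_len(K), function(e) {
    ie <- idx[, e]
    blk <- av[pmax(ie, 1L), , drop = FALSE]
    pad <- ie == 0L
    if (any(pad)) blk[pad, ] <- 0
    blk
  })
  lp <- nrow(idx)
  tp_node(do.call(cbind, blocks), list(a), function(g) {
    # reorder [l' x K*c] gradients into [l'*K x c] rows aligned with vec(idx),
    # then scatter-add with a single rowsum pass
    stacked <- matrix(aperm(array(g, c(lp, c_in, K)), c(1L, 3L, 2L)),
                      lp * K, c_in)
    iv <- as.vector(idx)
    keep <- iv > 0L
    acc <- matrix(0, nr, c_in)
    rs <- rowsum(stacked[keep, , drop = FALSE], group = iv[keep],
                 reorder = FALSE)
    acc[as.integer(rownames(rs)), ] <- rs
    list(acc)
  })
}

tp_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_tp(a); gamma <- as_tp(gamma); beta <- as_tp(beta)
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gvec <- gamma$val[1L, ]
  bvec <- beta$val[1L, ]
  y <- sweep(sweep(xhat, 2L, gvec, "*"), 2L, bvec, "+")
  tp_node(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gvec, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * inv
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# batch normalisation over the token axis (rows), per feature column.
# `state` is an environment carrying running_mean / running_var; when
# training = FALSE the running statistics are used (eval-mode determinism).
tp_batchnorm <- function(a, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  a <- as_tp(a); gamma <- as_tp(gamma); beta <- as_tp(beta)
  x <- a$val
  n <- nrow(x)
  gvec <- gamma$val[1L, ]
  bvec <- beta$val[1L, ]
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc^2)
    if (is.null(state$running_mean)) {
      state$running_mean <- mu
      state$running_var <- v
    } else {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * v
    }
  } else {
    mu <- state$running_mean %||% rep(0, ncol(x))
    v <- state$running_var %||% rep(1, ncol(x))
    xc <- x - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(gvec, each = n) + rep(bvec, each = n)
  tp_node(y, list(a, gamma, beta), function(g) {
    dxhat <- g * rep(gvec, each = n)
    if (training) {
      c1 <- colSums(dxhat)
      c2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(c1 / n, each = n) -
               xhat * rep(c2 / n, each = n)) * rep(inv, each = n)
    } else {
      dx <- dxhat * rep(inv, each = n)
    }
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# numerically stable cross-entropy for a single [1 x C] logit row
tp_cross_entropy <- function(logits, target) {
  logits <- as_tp(logits)
  z <- logits$val[1L, ]
  z <- z - max(z)
  lse <- log(sum(exp(z)))
  p <- exp(z - lse)
  loss <- lse - z[target]
  tp_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    d <- p
    d[target] <- d[target] - 1
    list(matrix(d * g[1L], nrow = 1L))
  })
}

# fused affine map: x %*% W + bias row
tp_linear <- function(x, W, b) {
  x <- as_tp(x); W <- as_tp(W); b <- as_tp(b)
  n <- nrow(x$val)
  tp_node(x$val %*% W$val + rep(b$val[1L, ], each = n), list(x, W, b),
          function(g) {
    list(tcrossprod(g, W$val), crossprod(x$val, g),
         matrix(colSums(g), nrow = 1L))
  })
}

tp_sum <- function(a) {
  a <- as_tp(a)
  tp_node(matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$val), ncol(a$val)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block-diagonal attention: rows are grouped into consecutive blocks of size
# `block` (windowed layout); attention runs independently inside each block.
# One fused node avoids per-window graph overhead.
tp_block_attention <- function(Q, K, V, block, d_k) {
  Q <- as_tp(Q); K <- as_tp(K); V <- as_tp(V)
  n <- nrow(Q$val)
  nb <- n %/% block
  scale <- 1 / sqrt(d_k)
  out <- matrix(0, n, ncol(V$val))
  Ps <- vector("list", nb)
  for (b in seq_len(nb)) {
    rows <- ((b - 1L) * block + 1L):(b * block)
    S <- tcrossprod(Q$val[rows, , drop = FALSE],
                    K$val[rows, , drop = FALSE]) * scale
    S <- S - apply(S, 1L, max)
    P <- exp(S)
    P <- P / rowSums(P)
    Ps[[b]] <- P
    out[rows, ] <- P %*% V$val[rows, , drop = FALSE]
  }
  tp_node(out, list(Q, K, V), function(g) {
    dQ <- matrix(0, n, ncol(Q$val))
    dK <- matrix(0, n, ncol(K$val))
    dV <- matrix(0, n, ncol(V$val))
    for (b in seq_len(nb)) {
      rows <- ((b - 1L) * block + 1L):(b * block)
      P <- Ps[[b]]
      gb <- g[rows, , drop = FALSE]
      Vb <- V$val[rows, , drop = FALSE]
      dV[rows, ] <- crossprod(P, gb)
      dP <- tcrossprod(gb, Vb)
      dS <- (dP - rowSums(dP * P)) * P * scale
      dQ[rows, ] <- dS %*% K$val[rows, , drop = FALSE]
      dK[rows, ] <- crossprod(dS, Q$val[rows, , drop = FALSE])
    }
    list(dQ, dK, dV)
  })
}

# fused multi-head attention core: softmax(Q_h K_h' / sqrt(d_h)) V_h per
# column-block head, concatenated back along the feature axis
tp_multihead_attention <- function(Q, K, V, heads) {
  Q <- as_tp(Q); K <- as_tp(K); V <- as_tp(V)
  d <- ncol(Q$val)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  n <- nrow(Q$val)
  out <- matrix(0, n, d)
  Ps <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q$val[, cols, drop = FALSE],
                    K$val[, cols, drop = FALSE]) * scale
    S <- S - apply(S, 1L, max)
    P <- exp(S)
    P <- P / rowSums(P)
    Ps[[h]] <- P
    out[, cols] <- P %*% V$val[, cols, drop = FALSE]
  }
  tp_node(out, list(Q, K, V), function(g) {
    dQ <- matrix(0, n, d)
    dK <- matrix(0, n, d)
    dV <- matrix(0, n, d)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- Ps[[h]]
      gh <- g[, cols, drop = FALSE]
      Vh <- V$val[, cols, drop = FALSE]
      dV[, cols] <- crossprod(P, gh)
      dP <- tcrossprod(gh, Vh)
      dS <- (dP - rowSums(dP * P)) * P * scale
      dQ[, cols] <- dS %*% K$val[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, Q$val[, cols, drop = FALSE])
    }
    list(dQ, dK, dV)
  })
}
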
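# Independent brute-force oracles used by the equivalence tests. These are
# deliberately naive (double loops, O(n^2) counting) and share no code with
# the implementation paths they check.

# naive overlapping-patch extractor: row-major patches, row-major kernel
# elements, channels fastest within an element
naive_soft_split <- function(map, h, w, k, s, p, c_dim = ncol(map)) {
  grid <- array(0, c(h + 2 * p, w + 2 * p, c_dim))
  for (ch in seq_len(c_dim)) {
    grid[(p + 1):(p + h), (p + 1):(p + w), ch] <-
      matrix(map[, ch], h, w, byrow = TRUE)
  }
  out_h <- (h + 2 * p - k) %/% s + 1
  out_w <- (w + 2 * p - k) %/% s + 1
  out <- matrix(0, out_h * out_w, k * k * c_dim)
  t <- 0
  for (orow in seq_len(out_h)) {
    for (ocol in seq_len(out_w)) {
      t <- t + 1
      e <- 0
      for (dr in seq_len(k)) {
        for (dc in seq_len(k)) {
          e <- e + 1
          px <- grid[(orow - 1) * s + dr, (ocol - 1) * s + dc, ]
          out[t, ((e - 1) * c_dim + 1):(e * c_dim)] <- px
        }
      }
    }
  }
  out
}

# naive per-window attention: zero-pads Q/K/V maps to window multiples,
# softmax(QK'/sqrt(d)) V inside each window independently
naive_window_attention <- function(Q, K, V, h, w, win) {
  d <- ncol(Q)
  pad_mat <- function(M) {
    hp <- ceiling(h / win) * win
    wp <- ceiling(w / win) * win
    out <- array(0, c(hp, wp, d))
    for (ch in seq_len(d)) {
      out[1:h, 1:w, ch] <- matrix(M[, ch], h, w, byrow = TRUE)
    }
    out
  }
  Qp <- pad_mat(Q); Kp <- pad_mat(K); Vp <- pad_mat(V)
  hp <- dim(Qp)[1]; wp <- dim(Qp)[2]
  res <- array(0, c(hp, wp, d))
  for (wr in seq(1, hp, by = win)) {
    for (wc in seq(1, wp, by = win)) {
      rows <- wr:(wr + win - 1); cols <- wc:(wc + win - 1)
      flat <- function(A) {
        m <- matrix(0, win * win, d)
        i <- 0
        for (r in rows) for (cc in cols) {
          i <- i + 1
          m[i, ] <- A[r, cc, ]
        }
        m
      }
      q <- flat(Qp); kk <- flat(Kp); v <- flat(Vp)
      S <- q %*% t(kk) / sqrt(d)
      P <- t(apply(S, 1, function(row) {
        e <- exp(row - max(row)); e / sum(e)
      }))
      o <- P %*% v
      i <- 0
      for (r in rows) for (cc in cols) {
        i <- i + 1
        res[r, cc, ] <- o[i, ]
      }
    }
  }
  out <- matrix(0, h * w, d)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    out[(r - 1) * w + cc, ] <- res[r, cc, ]
  }
  out
}

# O(n^2) AUC: fraction of positive/negative pairs won, ties counted half
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# from-scratch DeLong machinery via explicit placement-value loops
naive_delong <- function(scores_a, scores_b, labels) {
  place <- function(s) {
    pos <- s[labels == 1]; neg <- s[labels == 0]
    v10 <- numeric(length(pos)); v01 <- numeric(length(neg))
    for (i in seq_along(pos)) {
      acc <- 0
      for (y in neg) acc <- acc + if (pos[i] > y) 1 else if (pos[i] == y) 0.5 else 0
      v10[i] <- acc / length(neg)
    }
    for (j in seq_along(neg)) {
      acc <- 0
      for (x in pos) acc <- acc + if (x > neg[j]) 1 else if (x == neg[j]) 0.5 else 0
      v01[j] <- acc / length(pos)
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- place(scores_a); pb <- place(scores_b)
  m <- length(pa$v10); n <- length(pa$v01)
  cov2 <- function(x, y) {
    if (length(x) < 2) return(0)
    sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  }
  var_delta <- (cov2(pa$v10, pa$v10) + cov2(pb$v10, pb$v10) -
                  2 * cov2(pa$v10, pb$v10)) / m +
    (cov2(pa$v01, pa$v01) + cov2(pb$v01, pb$v01) -
       2 * cov2(pa$v01, pb$v01)) / n
  list(auc_a = pa$auc, auc_b = pb$auc, var_delta = var_delta)
}

# deterministic random six-channel image
random_image <- function(side, seed) {
  set.seed(seed)
  array(runif(side * side * 6), c(side, side, 6))
}

# tiny architecture used by pipeline-level tests (fast on one CPU)
tiny_arch <- function(...) {
  model_config("test", image_size = 16L, c_dim = 8L, heads = 2L,
               window = 2L, scales = c(3L), encoder_depth = 1L, ...)
}

tiny_train <- function(epochs = 2, seed = 1) {
  train_config(lr = 1e-3, epochs_max = epochs, patience = epochs,
               batch_size = 8, seed = seed)
}
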
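# EiT2T: soft split vs naive extraction, attention oracles, convex fusion
# weights, arm isolation.

test_that("soft split matches the naive patch extractor bitwise", {
  set.seed(21)
  geometries <- list(c(4, 4, 2, 1, 0), c(4, 6, 3, 2, 1), c(5, 5, 3, 1, 1),
                     c(6, 4, 2, 2, 0), c(8, 8, 3, 2, 1), c(7, 5, 5, 2, 2))
  for (g in geometries) {
    h <- g[1]; w <- g[2]; k <- g[3]; s <- g[4]; p <- g[5]
    map <- matrix(rnorm(h * w * 3), h * w, 3)
    got <- soft_split(map, h, w, k, s, p)
    want <- naive_soft_split(map, h, w, k, s, p)
    expect_identical(unclass(got)[seq_along(want)], as.vector(want))
    # closed-form token count
    expect_equal(nrow(got),
                 (((h + 2 * p - k) %/% s) + 1) * (((w + 2 * p - k) %/% s) + 1))
    expect_equal(ncol(got), k * k * 3)
  }
})

test_that("soft split with k = s, p = 0 is the hard patch split", {
  set.seed(22)
  map <- matrix(rnorm(64 * 2), 64, 2)
  got <- soft_split(map, 8, 8, 2, 2, 0)
  expect_equal(nrow(got), 16)
  # first patch: positions (1,1),(1,2),(2,1),(2,2) row-major
  first <- c(map[1, ], map[2, ], map[9, ], map[10, ])
  expect_identical(got[1, ], first)
  expect_error(soft_split(map, 8, 8, 12, 1, 0))
})

test_that("reshape validates the grid and round-trips", {
  x <- matrix(rnorm(196 * 4), 196, 4)
  m <- reshape_to_map(x, 14, 14)
  expect_identical(unclass(m)[seq_along(x)], as.vector(x))
  expect_error(reshape_to_map(matrix(0, 195, 4), 14, 14),
               class = "nactresp_validation_error")
})

test_that("multi-scale convolutions preserve spatial extent", {
  set.seed(23)
  map <- matrix(rnorm(196 * 4), 196, 4)
  outs <- multiscale_conv(map, 14, 14, c(3, 5, 7))
  expect_length(outs, 3)
  for (o in outs) expect_equal(dim(o), c(196, 4))
  expect_error(multiscale_conv(map, 14, 14, c(2, 4)),
               class = "nactresp_validation_error")
  # a 1x1 kernel pinned to the identity reproduces the input
  ident <- nactresp:::new_conv(1L, 4L, 4L)
  ident$W$val <- diag(4)
  out <- multiscale_conv(map, 14, 14, 1L, weights = list(ident))
  expect_equal(out[[1]], map, tolerance = 1e-12)
})

test_that("global attention matches the explicit softmax matrix computation", {
  set.seed(24)
  map <- matrix(rnorm(16 * 6), 16, 6)
  wts <- nactresp:::new_qkv(6L)
  got <- global_attention(map, wts)
  # independent recomputation from the projection weights
  lin <- function(l, x) sweep(x %*% l$W$val, 2, l$b$val[1, ], "+")
  Q <- lin(wts$q, map); K <- lin(wts$k, map); V <- lin(wts$v, map)
  S <- Q %*% t(K) / sqrt(6)
  P <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_equal(got, P %*% V, tolerance = 1e-10)
  expect_equal(rowSums(P), rep(1, 16), tolerance = 1e-6)
  # single position: output equals its value projection
  one <- matrix(rnorm(6), 1, 6)
  expect_equal(global_attention(one, wts), lin(wts$v, one), tolerance = 1e-10)
  # spatially constant map stays constant
  const <- matrix(rep(rnorm(6), each = 9), 9, 6)
  out_const <- global_attention(const, wts)
  expect_lt(max(abs(sweep(out_const, 2, out_const[1, ]))), 1e-10)
  expect_error(global_attention(matrix(NaN, 2, 2)),
               class = "nactresp_validation_error")
})

test_that("windowed attention matches the naive per-window oracle", {
  set.seed(25)
  for (dims in list(c(8, 8, 4), c(6, 6, 2), c(6, 5, 4), c(4, 4, 3))) {
    h <- dims[1]; w <- dims[2]; win <- dims[3]
    map <- matrix(rnorm(h * w * 5), h * w, 5)
    wts <- nactresp:::new_qkv(5L)
    got <- local_attention(map, h, w, win, wts)
    lin <- function(l, x) sweep(x %*% l$W$val, 2, l$b$val[1, ], "+")
    want <- naive_window_attention(lin(wts$q, map), lin(wts$k, map),
                                   lin(wts$v, map), h, w, win)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("windowed attention degenerates correctly at the extremes", {
  set.seed(26)
  map <- matrix(rnorm(36 * 4), 36, 4)
  wts <- nactresp:::new_qkv(4L)
  # window covering the whole map equals global attention (shared weights)
  expect_equal(local_attention(map, 6, 6, 6, wts),
               global_attention(map, wts), tolerance = 1e-12)
  # 1x1 windows reduce to the value projection
  lin <- function(l, x) sweep(x %*% l$W$val, 2, l$b$val[1, ], "+")
  expect_equal(local_attention(map, 6, 6, 1, wts), lin(wts$v, map),
               tolerance = 1e-10)
  expect_error(local_attention(map, 6, 6, 0),
               class = "nactresp_validation_error")
})

test_that("local-global fusion weights are convex by construction", {
  set.seed(27)
  a <- matrix(rnorm(20), 5, 4)
  b <- matrix(rnorm(20), 5, 4)
  # logits forcing alpha ~ 1 select the local branch
  expect_equal(fuse_local_global(a, b, c(60, -60)), a, ignore_attr = TRUE)
  # equal logits give the elementwise mean
  expect_equal(fuse_local_global(a, b, c(0.7, 0.7)), (a + b) / 2,
               ignore_attr = TRUE)
  for (i in 1:25) {
    lg <- rnorm(2, sd = 5)
    wts <- attr(fuse_local_global(a, b, lg), "weights")
    expect_true(all(wts >= 0))
    expect_lt(abs(sum(wts) - 1), 1e-7)
  }
  expect_error(fuse_local_global(a, b[1:4, ]),
               class = "nactresp_validation_error")
})

test_that("scale fusion weights are a softmax over pooled descriptors", {
  set.seed(28)
  maps <- lapply(1:3, function(i) matrix(rnorm(24), 6, 4))
  # one-hot weights reproduce a single scale: bias pins the logits
  fc <- nactresp:::new_linear(12L, 3L)
  fc$W$val[] <- 0
  fc$b$val <- matrix(c(-50, 50, -50), 1)
  expect_equal(fuse_scales(maps, fc), maps[[2]], ignore_attr = TRUE)
  # uniform weights give the average
  fc$b$val <- matrix(0, 1, 3)
  expect_equal(fuse_scales(maps, fc), (maps[[1]] + maps[[2]] + maps[[3]]) / 3,
               ignore_attr = TRUE)
  for (i in 1:10) {
    fc2 <- nactresp:::new_linear(12L, 3L)
    wts <- attr(fuse_scales(maps, fc2), "weights")
    expect_true(all(wts >= 0))
    expect_lt(abs(sum(wts) - 1), 1e-7)
  }
  expect_error(fuse_scales(list()), class = "nactresp_validation_error")
})

test_that("transformer step preserves shape and rejects NaN", {
  set.seed(29)
  x <- matrix(rnorm(16 * 8), 16, 8)
  wts <- nactresp:::new_block(8L, 2L)
  out <- isolated_transformer_step(x, wts)
  expect_equal(dim(out), dim(x))
  # weight-copy control: identical weights on both "arms" match exactly
  expect_identical(isolated_transformer_step(x, wts),
                   isolated_transformer_step(x, wts))
  expect_error(isolated_transformer_step(matrix(NaN, 2, 2)),
               class = "nactresp_validation_error")
})

test_that("EiT2T blocks keep arms isolated and route gradients everywhere", {
  set.seed(30)
  h <- 6; w <- 6; cdim <- 8
  x <- matrix(rnorm(h * w * cdim), h * w, cdim)
  params <- list(
    before = nactresp:::new_eit2t_block(cdim, 2L, c(3L, 5L), 3L,
                                        list(k = 3L, s = 2L, p = 1L)),
    after = nactresp:::new_eit2t_block(cdim, 2L, c(3L, 5L), 3L,
                                       list(k = 3L, s = 2L, p = 1L)))
  res <- eit2t_block(x, x, h, w, params)
  # token count follows the soft-split closed form (then projected to c)
  expect_equal(nrow(res$pre), res$out_h * res$out_w)
  expect_equal(res$out_h, ((h + 2 - 3) %/% 2) + 1)
  expect_equal(ncol(res$pre), cdim)
  # independently initialised arms give different outputs on the same input
  expect_gt(max(abs(res$pre - res$post)), 1e-8)
  # arm isolation: perturbing a before-arm weight leaves the after arm fixed
  params$before$transformer$attn$qkv$q$W$val[] <- 0
  res2 <- eit2t_block(x, x, h, w, params)
  expect_identical(res2$post, res$post)
  expect_false(identical(res2$pre, res$pre))
  # gradients reach every learnable group of the block
  blk <- params$before
  tokens <- nactresp:::tp_const(x)
  out <- nactresp:::nd_eit2t_block(blk, tokens, list(h = h, w = w))
  nactresp:::tp_backward(nactresp:::tp_sum(out$tokens))
  groups <- list(transformer = blk$transformer$attn$qkv$q$W,
                 conv = blk$convs[[1]]$W,
                 ab_logits = blk$ab_logits[[1]],
                 scale_fc = blk$scale_fc$W,
                 proj = blk$proj$W)
  for (nm in names(groups)) {
    expect_false(is.null(groups[[nm]]$grad), info = nm)
    expect_gt(max(abs(groups[[nm]]$grad)), 0)
  }
})
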
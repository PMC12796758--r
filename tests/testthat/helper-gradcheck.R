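# Finite-difference gradient checking for the autodiff tape.
# `build` maps a list of plain matrices to a scalar tape node, constructing
# fresh parameter nodes each call so the graph is rebuilt from scratch.
num_grad <- function(f, xs, i, eps = 1e-6) {
  x <- xs[[i]]
  g <- array(0, dim(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    xsp <- xs; xsp[[i]] <- xp
    xsm <- xs; xsm[[i]] <- xm
    g[j] <- (f(xsp) - f(xsm)) / (2 * eps)
  }
  g
}

expect_gradients_match <- function(build, xs, tol = 1e-5) {
  params <- lapply(xs, nactresp:::tp_param)
  root <- build(params)
  nactresp:::tp_backward(root)
  fval <- function(mats) {
    ps <- lapply(mats, nactresp:::tp_param)
    nactresp:::tp_val(build(ps))[1L, 1L]
  }
  for (i in seq_along(xs)) {
    analytic <- params[[i]]$grad
    numeric <- num_grad(fval, xs, i)
    expect_lt(max(abs(analytic - numeric)), tol)
  }
}
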
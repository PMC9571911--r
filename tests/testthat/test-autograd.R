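# Reverse-mode gradients agree with central finite differences on every op.

test_that("convolution, deconvolution and pooling-free ops backpropagate exactly", {
  set.seed(101)
  ag_param <- hrst:::ag_param
  ag_tensor <- hrst:::ag_tensor
  ag_new <- hrst:::ag_new
  ag_backward <- hrst:::ag_backward

  # scalar head that weights every output element differently, so gradient
  # errors anywhere in the output are visible
  weighted_sum <- function(node) {
    co <- array(seq_len(length(node$value)) / length(node$value), dim(node$value))
    ag_new(sum(node$value * co), list(node), function(g) list(g * co))
  }

  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  px <- ag_param(x); pw <- ag_param(w); pb <- ag_param(b)
  loss <- weighted_sum(hrst:::ag_conv2d(px, pw, pb, stride = 2L, pad = 1L))
  ag_backward(loss)
  f <- function(xx, ww, bb) {
    y <- hrst:::ag_conv2d(ag_tensor(xx), ag_tensor(ww), ag_tensor(bb), 2L, 1L)$value
    sum(y * array(seq_len(length(y)) / length(y), dim(y)))
  }
  expect_lt(rel_err(px$grad, numerical_gradient(function(v) f(v, w, b), x)), 1e-6)
  expect_lt(rel_err(pw$grad, numerical_gradient(function(v) f(x, v, b), w)), 1e-6)
  expect_lt(rel_err(pb$grad, numerical_gradient(function(v) f(x, w, v), b)), 1e-6)

  wd <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  xd <- array(rnorm(3 * 4 * 3 * 2), c(3, 4, 3, 2))
  pxd <- ag_param(xd); pwd <- ag_param(wd)
  loss <- weighted_sum(hrst:::ag_deconv2d(pxd, pwd, NULL, stride = 4L))
  ag_backward(loss)
  fd <- function(xx, ww) {
    y <- hrst:::ag_deconv2d(ag_tensor(xx), ag_tensor(ww), NULL, 4L)$value
    sum(y * array(seq_len(length(y)) / length(y), dim(y)))
  }
  expect_lt(rel_err(pxd$grad, numerical_gradient(function(v) fd(v, wd), xd)), 1e-6)
  expect_lt(rel_err(pwd$grad, numerical_gradient(function(v) fd(xd, v), wd)), 1e-6)

  xu <- array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2))
  pu <- ag_param(xu)
  loss <- weighted_sum(hrst:::ag_upsample_nearest(pu, 2L))
  ag_backward(loss)
  fu <- function(v) {
    y <- hrst:::ag_upsample_nearest(ag_tensor(v), 2L)$value
    sum(y * array(seq_len(length(y)) / length(y), dim(y)))
  }
  expect_lt(rel_err(pu$grad, numerical_gradient(fu, xu)), 1e-6)
})

test_that("normalization and token ops backpropagate exactly", {
  set.seed(102)
  ag_param <- hrst:::ag_param
  ag_tensor <- hrst:::ag_tensor
  ag_backward <- hrst:::ag_backward
  ag_new <- hrst:::ag_new

  bnl <- hrst:::nn_bn(3L)
  hrst:::nn_init(bnl)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  reset <- function() {
    bnl$running_mean <- rep(0, 3)
    bnl$running_var <- rep(1, 3)
  }
  px <- ag_param(x)
  reset()
  y <- hrst:::ag_batchnorm(px, bnl$params$gamma, bnl$params$beta, bnl, TRUE)
  loss <- ag_new(sum(sin(y$value)), list(y), function(g) list(g * cos(y$value)))
  ag_backward(loss)
  fb <- function(v) {
    reset()
    sum(sin(hrst:::ag_batchnorm(ag_tensor(v), bnl$params$gamma,
                                bnl$params$beta, bnl, TRUE)$value))
  }
  expect_lt(rel_err(px$grad, numerical_gradient(fb, x)), 1e-5)

  lnl <- hrst:::nn_layernorm(5L)
  hrst:::nn_init(lnl)
  xt <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  pt <- ag_param(xt)
  y <- hrst:::ag_layernorm(pt, lnl$params$gamma, lnl$params$beta)
  loss <- ag_new(sum(sin(y$value)), list(y), function(g) list(g * cos(y$value)))
  ag_backward(loss)
  fl <- function(v) sum(sin(hrst:::ag_layernorm(ag_tensor(v), lnl$params$gamma,
                                                lnl$params$beta)$value))
  expect_lt(rel_err(pt$grad, numerical_gradient(fl, xt)), 1e-5)

  wl <- matrix(rnorm(5 * 4), 5, 4)
  pl <- ag_param(xt)
  y <- hrst:::ag_linear(pl, ag_tensor(wl), NULL)
  loss <- ag_new(sum(y$value^2), list(y), function(g) list(2 * g * y$value))
  ag_backward(loss)
  expect_lt(rel_err(pl$grad, numerical_gradient(function(v) {
    sum(hrst:::ag_linear(ag_tensor(v), ag_tensor(wl), NULL)$value^2)
  }, xt)), 1e-6)

  pg <- ag_param(xt)
  y <- hrst:::ag_gelu(pg)
  loss <- ag_new(sum(y$value^2), list(y), function(g) list(2 * g * y$value))
  ag_backward(loss)
  expect_lt(rel_err(pg$grad, numerical_gradient(function(v) {
    sum(hrst:::ag_gelu(ag_tensor(v))$value^2)
  }, xt)), 1e-6)
})

test_that("windowed attention backpropagates into tokens, projections and bias table", {
  set.seed(103)
  ag_param <- hrst:::ag_param
  ag_tensor <- hrst:::ag_tensor
  ag_backward <- hrst:::ag_backward
  ag_new <- hrst:::ag_new
  M <- 2L; T_ <- 4L; nW <- 2L; C <- 6L; heads <- 3L
  x <- array(rnorm(T_ * C * nW), c(T_, C, nW))
  wqkv <- matrix(rnorm(C * 3 * C, sd = 0.5), C, 3 * C)
  bqkv <- rnorm(3 * C, sd = 0.2)
  wproj <- matrix(rnorm(C * C, sd = 0.5), C, C)
  bproj <- rnorm(C, sd = 0.2)
  tab <- matrix(rnorm(9 * heads, sd = 0.3), 9, heads)
  idx <- hrst:::relpos_index(M)
  mask <- array(0, c(T_, T_, nW))
  mask[1, 3, 2] <- -1e9
  mask[3, 1, 2] <- -1e9
  args0 <- list(x = x, wqkv = wqkv, bqkv = bqkv, wproj = wproj,
                bproj = bproj, tab = tab)
  fwd <- function(a) {
    hrst:::ag_window_msa(ag_tensor(a$x), ag_tensor(a$wqkv), ag_tensor(a$bqkv),
                         ag_tensor(a$wproj), ag_tensor(a$bproj),
                         ag_tensor(a$tab), idx, heads, mask, n_windows = nW)$value
  }
  co <- array(rnorm(T_ * C * nW), c(T_, C, nW))
  ps <- lapply(args0, ag_param)
  y <- hrst:::ag_window_msa(ps$x, ps$wqkv, ps$bqkv, ps$wproj, ps$bproj,
                            ps$tab, idx, heads, mask, n_windows = nW)
  loss <- ag_new(sum(y$value * co), list(y), function(g) list(g * co))
  ag_backward(loss)
  for (nm in names(args0)) {
    gn <- numerical_gradient(function(v) {
      a <- args0; a[[nm]] <- v
      sum(fwd(a) * co)
    }, args0[[nm]])
    expect_lt(rel_err(ps[[nm]]$grad, gn), 1e-5)
  }
})

test_that("weighted heatmap MSE has the algebraic properties of a mean", {
  set.seed(104)
  d <- c(6, 8, 3, 2)
  p <- array(runif(prod(d)), d)
  t_ <- array(runif(prod(d)), d)
  w <- matrix(1, 3, 2)
  expect_equal(mse_loss(p, p, w), 0)
  expect_equal(mse_loss(p, p + 0.3, w), 0.09, tolerance = 1e-12)
  # invisible channel: perturbation does not move the loss
  w0 <- w; w0[2, 1] <- 0
  base <- mse_loss(p, t_, w0)
  t2 <- t_
  t2[, , 2, 1] <- t2[, , 2, 1] + 100
  expect_equal(mse_loss(p, t2, w0), base)
  expect_equal(mse_loss(p, t_, w), mse_loss(t_, p, w)) # symmetry
  expect_error(mse_loss(p, array(0, c(6, 8, 3, 3))), "shapes differ")
})
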
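# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# Feature maps are (H, W, C, N) arrays, token sequences (L, d, N), losses
# scalars. Every op returns a node holding the value, its parents and a
# closure that maps the incoming gradient to parent gradients. The tape is
# implicit in the parent links; ag_backward() topologically sorts reachable
# nodes and accumulates gradients into leaves created with ag_param().

.ag_state <- new.env(parent = emptyenv())
.ag_state$next_id <- 1L
.ag_state$im2col_cache <- new.env(parent = emptyenv())

ag_new <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- FALSE
  e$needs_grad <- any(vapply(parents, function(p) p$needs_grad, logical(1)))
  e$id <- .ag_state$next_id
  .ag_state$next_id <- .ag_state$next_id + 1L
  class(e) <- "ag_tensor"
  e
}

#' Wrap an array as an autodiff constant
#' @param value numeric array.
#' @return an `ag_tensor` node.
#' @keywords internal
ag_tensor <- function(value) ag_new(value)

#' Wrap an array as a learnable parameter (gradient leaf)
#' @param value numeric array with the parameter's initial value.
#' @return an `ag_tensor` with `requires_grad = TRUE`.
#' @keywords internal
ag_param <- function(value) {
  e <- ag_new(value)
  e$requires_grad <- TRUE
  e$needs_grad <- TRUE
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_ag(x)) x$value else x

# Accumulate gradient g into node n.
ag_accum <- function(n, g) {
  if (is.null(n$grad)) n$grad <- g else n$grad <- n$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#' @param loss an `ag_tensor` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  # iterative DFS topological sort over nodes that need gradients
  topo <- vector("list", 256L)
  ntop <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (p$needs_grad && is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      ntop <- ntop + 1L
      if (ntop > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntop]] <- nd
    }
  }
  loss$grad <- 1
  for (i in seq(ntop, 1L)) {
    nd <- topo[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (p$needs_grad && !is.null(gs[[j]])) ag_accum(p, gs[[j]])
    }
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and shape ops ------------------------------------------

ag_add <- function(a, b) {
  ag_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_relu <- function(x) {
  m <- x$value > 0
  ag_new(x$value * m, list(x), function(g) list(g * m))
}

ag_reshape <- function(x, dims) {
  old <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  ag_new(v, list(x), function(g) { dim(g) <- old; list(g) })
}

# Permutation-only row gather (perm is a permutation of 1..L): cheap inverse.
ag_row_permute <- function(x, perm, out_dim = NULL) {
  v <- x$value
  d <- dim(v)
  m <- v
  dim(m) <- c(d[1], prod(d[-1]))
  out <- m[perm, , drop = FALSE]
  if (is.null(out_dim)) out_dim <- c(length(perm), d[-1])
  dim(out) <- out_dim
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ag_new(out, list(x), function(g) {
    dim(g) <- c(length(perm), prod(d[-1]))
    gx <- g[inv, , drop = FALSE]
    dim(gx) <- d
    list(gx)
  })
}

# ---- conv / deconv -------------------------------------------------------

# Cached linear-index matrix for im2col on a padded (Hp, Wp) plane:
# rows are output positions (column-major over Ho, Wo), columns kernel
# offsets (row offset fastest), entries 1-based indices into the plane.
im2col_index <- function(Hp, Wp, k, stride) {
  key <- paste(Hp, Wp, k, stride, sep = "_")
  cached <- .ag_state$im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  i0 <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  j0 <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  base <- i0 + (j0 - 1L) * Hp # top-left corner of each patch
  offs <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+"))
  idx <- outer(base, offs, "+")
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .ag_state$im2col_cache[[key]] <- out
  out
}

pad_hw <- function(v, p) {
  if (p == 0L) return(v)
  d <- dim(v)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- v
  out
}

# Cached channel-expanded im2col index (adds the channel offsets to the
# spatial index once per shape/channel combination).
im2col_index_c <- function(Hp, Wp, k, stride, Cin) {
  key <- paste(Hp, Wp, k, stride, Cin, sep = "_")
  cached <- .ag_state$im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  ic <- im2col_index(Hp, Wp, k, stride)
  k2 <- k * k
  plane <- Hp * Wp
  coff <- rep((seq_len(Cin) - 1L) * plane, each = k2)
  idx_full <- ic$idx[, rep(seq_len(k2), times = Cin), drop = FALSE]
  idx_full <- idx_full + rep(coff, each = nrow(idx_full))
  out <- list(idx = ic$idx, idx_full = idx_full, Ho = ic$Ho, Wo = ic$Wo)
  .ag_state$im2col_cache[[key]] <- out
  out
}

# 2D correlation-style convolution. x: (H, W, Cin, N); w: (k, k, Cin, Cout);
# b: NULL or length-Cout vector. Stores the im2col matrix only when a
# gradient will be required.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(w$value)
  k <- wd[1]
  stopifnot(wd[3] == Cin)
  Cout <- wd[4]
  xp <- pad_hw(xv, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  ic <- im2col_index_c(Hp, Wp, k, stride, Cin)
  Ho <- ic$Ho; Wo <- ic$Wo
  k2 <- k * k
  nout <- Ho * Wo
  plane <- Hp * Wp
  planeC <- plane * Cin
  # per-sample gather, stacked sample-major
  if (N == 1L) {
    Xcol <- matrix(xp[ic$idx_full], nout)
  } else {
    Xcol <- matrix(0, N * nout, k2 * Cin)
    for (n in seq_len(N)) {
      Xcol[(n - 1L) * nout + seq_len(nout), ] <- xp[ic$idx_full + (n - 1L) * planeC]
    }
  }
  Wm <- w$value
  dim(Wm) <- c(k2 * Cin, Cout)
  Y <- Xcol %*% Wm
  dim(Y) <- c(nout, N, Cout)
  yv <- aperm(Y, c(1L, 3L, 2L))
  dim(yv) <- c(Ho, Wo, Cout, N)
  if (!is.null(b)) yv <- yv + rep(b$value, each = nout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  needs <- any(vapply(parents, function(p) p$needs_grad, logical(1)))
  if (!needs) return(ag_new(yv, parents, NULL))
  node <- ag_new(yv, parents, NULL)
  node$backward <- function(g) {
    G <- matrix(0, N * nout, Cout)
    for (n in seq_len(N)) {
      gn <- g[, , , n]
      dim(gn) <- c(nout, Cout)
      G[(n - 1L) * nout + seq_len(nout), ] <- gn
    }
    dW <- crossprod(Xcol, G)
    dim(dW) <- c(k, k, Cin, Cout)
    db <- if (is.null(b)) NULL else colSums(G)
    dX <- NULL
    if (x$needs_grad) {
      dXcol <- G %*% t(Wm) # (N*nout, k2*Cin)
      dXp <- array(0, c(Hp, Wp, Cin, N))
      for (n in seq_len(N)) {
        dxn <- matrix(0, plane, Cin)
        dcn <- dXcol[(n - 1L) * nout + seq_len(nout), , drop = FALSE]
        for (j in seq_len(k2)) {
          cols <- j + (seq_len(Cin) - 1L) * k2
          rows <- ic$idx[, j]
          dxn[rows, ] <- dxn[rows, ] + dcn[, cols, drop = FALSE]
        }
        dim(dxn) <- c(Hp, Wp, Cin)
        dXp[, , , n] <- dxn
      }
      dX <- dXp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
    }
    out <- list(dX, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  }
  node
}

# Transposed convolution with kernel == stride (non-overlapping tiles).
# x: (H, W, Cin, N) -> (H*s, W*s, Cout, N).
ag_deconv2d <- function(x, w, b = NULL, stride) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(w$value)
  k <- wd[1]
  stopifnot(k == stride, wd[3] == Cin)
  Cout <- wd[4]
  k2 <- k * k
  W2 <- aperm(w$value, c(3L, 1L, 2L, 4L)) # (Cin, k, k, Cout)
  dim(W2) <- c(Cin, k2 * Cout)
  yv <- array(0, c(H * k, W * k, Cout, N))
  Xm_all <- vector("list", N)
  for (n in seq_len(N)) {
    Xm <- xv[, , , n]
    dim(Xm) <- c(H * W, Cin)
    Xm_all[[n]] <- Xm
    Yb <- Xm %*% W2 # (HW, k2*Cout), kernel offset fastest (di then dj) then cout
    dim(Yb) <- c(H, W, k, k, Cout)
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      yv[seq(di, by = k, length.out = H), seq(dj, by = k, length.out = W), , n] <-
        Yb[, , di, dj, ]
    }
  }
  if (!is.null(b)) yv <- sweep(yv, 3L, b$value, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  node <- ag_new(yv, parents, NULL)
  needs <- node$needs_grad
  if (!needs) return(node)
  node$backward <- function(g) {
    dW2 <- matrix(0, Cin, k2 * Cout)
    dX <- array(0, c(H, W, Cin, N))
    db <- if (is.null(b)) NULL else rep(0, Cout)
    for (n in seq_len(N)) {
      Gb <- array(0, c(H, W, k, k, Cout))
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        Gb[, , di, dj, ] <- g[seq(di, by = k, length.out = H),
                              seq(dj, by = k, length.out = W), , n]
      }
      dim(Gb) <- c(H * W, k2 * Cout)
      dW2 <- dW2 + crossprod(Xm_all[[n]], Gb)
      if (!is.null(b)) db <- db + colSums(matrix(g[, , , n], ncol = Cout))
      dXm <- Gb %*% t(W2)
      dim(dXm) <- c(H, W, Cin)
      dX[, , , n] <- dXm
    }
    dim(dW2) <- c(Cin, k, k, Cout)
    dW <- aperm(dW2, c(2L, 3L, 1L, 4L))
    out <- list(dX, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  }
  node
}

# Nearest-neighbour upsampling by an integer factor.
ag_upsample_nearest <- function(x, factor) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = factor)
  rj <- rep(seq_len(d[2]), each = factor)
  yv <- x$value[ri, rj, , , drop = FALSE]
  ag_new(yv, list(x), function(g) {
    # sum gradient over each factor x factor block
    g1 <- rowsum(matrix(g, nrow = d[1] * factor), group = rep(seq_len(d[1]), each = factor),
                 reorder = FALSE)
    dim(g1) <- c(d[1], d[2] * factor, d[3], d[4])
    g2 <- aperm(g1, c(2L, 1L, 3L, 4L))
    g2 <- rowsum(matrix(g2, nrow = d[2] * factor), group = rep(seq_len(d[2]), each = factor),
                 reorder = FALSE)
    dim(g2) <- c(d[2], d[1], d[3], d[4])
    list(aperm(g2, c(2L, 1L, 3L, 4L)))
  })
}

# ---- normalization -------------------------------------------------------

# Batch normalization over (H, W, N) per channel. `layer` is the owning
# nn layer environment, used for running statistics. Channel statistics are
# computed on the (HW, C*N) view and reduced over samples; per-channel
# affine terms are applied by recycling a length-HW*C vector over samples.
ag_batchnorm <- function(x, gamma, beta, layer, training, momentum = 0.1, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[3]; N <- d[4]
  hw <- d[1] * d[2]
  m <- v
  dim(m) <- c(hw, C * N)
  if (training) {
    mcn <- .colMeans(m, hw, C * N)
    mu <- .rowMeans(matrix(mcn, C, N), C, N)
    m2 <- .colMeans(m^2, hw, C * N)
    va <- .rowMeans(matrix(m2, C, N), C, N) - mu^2
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  istd <- 1 / sqrt(va + eps)
  a <- rep(gamma$value * istd, each = hw)
  bb <- rep(beta$value - gamma$value * istd * mu, each = hw)
  yv <- v * a + bb # recycles over samples
  node <- ag_new(yv, list(x, gamma, beta), NULL)
  if (!node$needs_grad) return(node)
  node$backward <- function(g) {
    gm <- g
    dim(gm) <- c(hw, C * N)
    colsum_c <- function(mm) .rowSums(matrix(.colSums(mm, hw, C * N), C, N), C, N)
    xhat_flat <- (v - rep(mu, each = hw)) * rep(istd, each = hw)
    dim(xhat_flat) <- c(hw, C * N)
    dgamma <- colsum_c(gm * xhat_flat)
    dbeta <- colsum_c(gm)
    dx <- NULL
    if (x$needs_grad) {
      nn <- hw * N
      if (training) {
        dxf <- (as.vector(gm) - rep(dbeta / nn, each = hw) -
                  as.vector(xhat_flat) * rep(dgamma / nn, each = hw)) *
          rep(gamma$value * istd, each = hw)
      } else {
        dxf <- as.vector(gm) * rep(gamma$value * istd, each = hw)
      }
      dx <- array(dxf, d)
    }
    list(dx, dgamma, dbeta)
  }
  node
}

# Layer normalization over the feature dimension of (L, d, N) tokens.
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  dd <- dim(v)
  L <- dd[1]; D <- dd[2]; N <- dd[3]
  m <- aperm(v, c(2L, 1L, 3L)) # (D, L, N): normalize down columns
  dim(m) <- c(D, L * N)
  mu <- colMeans(m)
  va <- colMeans(sweep(m, 2L, mu, "-")^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, istd, "*")
  y <- xhat * gamma$value + beta$value
  dim(y) <- c(D, L, N)
  yv <- aperm(y, c(2L, 1L, 3L))
  node <- ag_new(yv, list(x, gamma, beta), NULL)
  if (!node$needs_grad) return(node)
  node$backward <- function(g) {
    gm <- aperm(g, c(2L, 1L, 3L))
    dim(gm) <- c(D, L * N)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    gxh <- gm * gamma$value
    t1 <- sweep(gxh, 2L, colMeans(gxh), "-")
    t2 <- sweep(xhat, 2L, colMeans(gxh * xhat), "*")
    dxm <- sweep(t1 - t2, 2L, istd, "*")
    dim(dxm) <- c(D, L, N)
    list(aperm(dxm, c(2L, 1L, 3L)), dgamma, dbeta)
  }
  node
}

# ---- linear over tokens --------------------------------------------------

# x: (L, din, N); W: (din, dout); b: NULL or dout.
ag_linear <- function(x, w, b = NULL) {
  v <- x$value
  d <- dim(v)
  L <- d[1]; din <- d[2]; N <- d[3]
  m <- aperm(v, c(1L, 3L, 2L))
  dim(m) <- c(L * N, din)
  y <- m %*% w$value
  if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
  dout <- ncol(w$value)
  dim(y) <- c(L, N, dout)
  yv <- aperm(y, c(1L, 3L, 2L))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  node <- ag_new(yv, parents, NULL)
  if (!node$needs_grad) return(node)
  node$backward <- function(g) {
    gm <- aperm(g, c(1L, 3L, 2L))
    dim(gm) <- c(L * N, dout)
    dW <- crossprod(m, gm)
    db <- if (is.null(b)) NULL else colSums(gm)
    dx <- NULL
    if (x$needs_grad) {
      dxm <- gm %*% t(w$value)
      dim(dxm) <- c(L, N, din)
      dx <- aperm(dxm, c(1L, 3L, 2L))
    }
    out <- list(dx, dW)
    if (!is.null(b)) out <- c(out, list(db))
    out
  }
  node
}

# ---- losses --------------------------------------------------------------

# Mean squared error over weighted channels: pred, target (H, W, C, N);
# weights (C, N) in {0, 1} (or arbitrary non-negative). Mean over pixels,
# visible channels and batch.
ag_mse_weighted <- function(pred, target, weights) {
  d <- dim(pred$value)
  stopifnot(all(dim(target) == d))
  wsum <- sum(weights)
  if (wsum == 0) {
    return(ag_new(0, list(pred), function(g) list(array(0, d))))
  }
  diff <- pred$value - target
  wfull <- array(rep(as.vector(weights), each = d[1] * d[2]), d)
  loss <- sum(wfull * diff^2) / (d[1] * d[2] * wsum)
  ag_new(loss, list(pred), function(g) {
    list(g * 2 * wfull * diff / (d[1] * d[2] * wsum))
  })
}

# ---- windowed multi-head self-attention ---------------------------------

# xw: (T, C, G) where T = tokens per window and G = n_windows * batch
# (window index fastest). wqkv: (C, 3C); wproj: (C, C); bias_table:
# ((2M-1)^2, heads) learned relative-position bias; bias_index: (T, T)
# integer lookup into the table; mask: NULL or (T, T, nW) additive bias
# (0 / -1e9) shared across batch items. Scaled dot-product attention with
# softmax over unmasked keys, per head.
ag_window_msa <- function(xw, wqkv, bqkv, wproj, bproj,
                          bias_table, bias_index, heads, mask = NULL, n_windows = 1L) {
  v <- xw$value
  d <- dim(v)
  T_ <- d[1]; C <- d[2]; G <- d[3]
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  R <- nrow(bias_table$value)
  relb <- array(bias_table$value[as.vector(bias_index), ], c(T_, T_, heads))
  yv <- array(0, d)
  QKV_all <- vector("list", G)
  O_all <- vector("list", G)
  P_all <- vector("list", G)
  for (g in seq_len(G)) {
    X <- v[, , g]
    dim(X) <- c(T_, C)
    QKV <- X %*% wqkv$value
    if (!is.null(bqkv)) QKV <- sweep(QKV, 2L, bqkv$value, "+")
    QKV_all[[g]] <- QKV
    O <- matrix(0, T_, C)
    Ps <- vector("list", heads)
    wi <- ((g - 1L) %% n_windows) + 1L
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      q <- QKV[, cols, drop = FALSE]
      k <- QKV[, C + cols, drop = FALSE]
      vv <- QKV[, 2L * C + cols, drop = FALSE]
      S <- tcrossprod(q, k) * scale + relb[, , h]
      if (!is.null(mask)) S <- S + mask[, , wi]
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      Ps[[h]] <- P
      O[, cols] <- P %*% vv
    }
    P_all[[g]] <- Ps
    O_all[[g]] <- O
    Y <- O %*% wproj$value
    if (!is.null(bproj)) Y <- sweep(Y, 2L, bproj$value, "+")
    yv[, , g] <- Y
  }
  parents <- list(xw, wqkv, wproj, bias_table)
  if (!is.null(bqkv)) parents <- c(parents, list(bqkv))
  if (!is.null(bproj)) parents <- c(parents, list(bproj))
  node <- ag_new(yv, parents, NULL)
  if (!node$needs_grad) return(node)
  node$backward <- function(gr) {
    dX_all <- array(0, d)
    dWqkv <- matrix(0, C, 3L * C)
    dWproj <- matrix(0, C, C)
    dbqkv <- if (is.null(bqkv)) NULL else rep(0, 3L * C)
    dbproj <- if (is.null(bproj)) NULL else rep(0, C)
    drelb <- array(0, c(T_, T_, heads))
    for (g in seq_len(G)) {
      gY <- gr[, , g]
      dim(gY) <- c(T_, C)
      O <- O_all[[g]]
      QKV <- QKV_all[[g]]
      dWproj <- dWproj + crossprod(O, gY)
      if (!is.null(bproj)) dbproj <- dbproj + colSums(gY)
      dO <- gY %*% t(wproj$value)
      dQKV <- matrix(0, T_, 3L * C)
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        q <- QKV[, cols, drop = FALSE]
        k <- QKV[, C + cols, drop = FALSE]
        vv <- QKV[, 2L * C + cols, drop = FALSE]
        P <- P_all[[g]][[h]]
        dOh <- dO[, cols, drop = FALSE]
        dP <- tcrossprod(dOh, vv)
        dV <- crossprod(P, dOh)
        dS <- P * (dP - rowSums(dP * P))
        drelb[, , h] <- drelb[, , h] + dS
        dQKV[, cols] <- dS %*% k * scale
        dQKV[, C + cols] <- crossprod(dS, q) * scale
        dQKV[, 2L * C + cols] <- dV
      }
      X <- v[, , g]
      dim(X) <- c(T_, C)
      dWqkv <- dWqkv + crossprod(X, dQKV)
      if (!is.null(bqkv)) dbqkv <- dbqkv + colSums(dQKV)
      dX <- dQKV %*% t(wqkv$value)
      dX_all[, , g] <- dX
    }
    dtab <- matrix(0, R, heads)
    grp <- as.vector(bias_index)
    for (h in seq_len(heads)) {
      agg <- rowsum(as.vector(drelb[, , h]), group = grp)
      dtab[as.integer(rownames(agg)), h] <- agg
    }
    out <- list(dX_all, dWqkv, dWproj, dtab)
    if (!is.null(bqkv)) out <- c(out, list(dbqkv))
    if (!is.null(bproj)) out <- c(out, list(dbproj))
    out
  }
  node
}

# Dimension permutation.
ag_aperm <- function(x, perm) {
  inv <- order(perm)
  ag_new(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

# Exact Gaussian-error linear unit: x * pnorm(x).
ag_gelu <- function(x) {
  v <- x$value
  cdf <- stats::pnorm(v)
  ag_new(v * cdf, list(x), function(g) list(g * (cdf + v * stats::dnorm(v))))
}
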
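# Shared fixtures, built once per test run.

# Central-difference gradient of scalar-valued f at x (array or vector).
numerical_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

# Narrow-width configuration at an arbitrary input size (structure tests at
# canonical resolution without canonical widths).
narrow_config <- function(input_size = c(288L, 384L), depth = 2L) {
  hrst_config(
    backbone = backbone_config(
      stem_channels = 8L, stage1_blocks = 1L,
      widths = list(stage2 = c(8L, 16L), stage3 = c(8L, 16L, 32L),
                    stage4 = c(8L, 16L, 32L, 64L)),
      modules_per_stage = c(stage2 = 1L, stage3 = 1L, stage4 = 1L),
      blocks_per_branch = 1L),
    attention = attention_config(embed_dim = 32L, depth = depth, num_heads = 4L),
    input_size = input_size)
}

# Small synthetic scene set shared across test files.
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_pigs(synth_spec(n_images = 4L, seed = 11L,
                                                   animals_per_image = c(1L, 2L),
                                                   posture_mix = c(standing = 0.75,
                                                                   lying = 0.25)))
    }
    cache
  }
})

# Plain-R global (unwindowed) self-attention oracle: tokens (T, C), one
# window covering the whole grid. Returns the attended tokens.
global_attention_oracle <- function(X, wqkv, bqkv, wproj, bproj, bias_table,
                                    bias_index, heads, region = NULL) {
  C <- ncol(X)
  dh <- C / heads
  QKV <- sweep(X %*% wqkv, 2, bqkv, "+")
  O <- matrix(0, nrow(X), C)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    q <- QKV[, cols, drop = FALSE]
    k <- QKV[, C + cols, drop = FALSE]
    v <- QKV[, 2 * C + cols, drop = FALSE]
    S <- q %*% t(k) / sqrt(dh) + matrix(bias_table[bias_index, h], nrow(X), nrow(X))
    if (is.null(region)) {
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      O[, cols] <- P %*% v
    } else {
      # attention computed independently within each region label
      for (r in unique(region)) {
        idx <- which(region == r)
        Sr <- S[idx, idx, drop = FALSE]
        P <- exp(Sr - apply(Sr, 1, max))
        P <- P / rowSums(P)
        O[idx, cols] <- P %*% v[idx, , drop = FALSE]
      }
    }
  }
  sweep(O %*% wproj, 2, bproj, "+")
}

# Independent region labeling for a shifted window: tokens of one window
# (post-shift), labeled by contiguous runs of their pre-shift coordinates
# along each axis.
window_region_oracle <- function(grid, M, shift, window_index) {
  Gh <- grid[1]; Gw <- grid[2]
  nWh <- Gh / M
  wi <- ((window_index - 1) %% nWh) + 1
  wj <- ((window_index - 1) %/% nWh) + 1
  run_label <- function(p0, G) {
    orig <- (p0 + shift) %% G # pre-shift coordinates of this window's axis
    c(0, cumsum(diff(orig) != 1)) # new run whenever the sequence breaks
  }
  ri <- run_label((wi - 1) * M + seq_len(M) - 1, Gh)
  rj <- run_label((wj - 1) * M + seq_len(M) - 1, Gw)
  # token order within a window is column-major (row offset fastest)
  as.vector(outer(ri, rj * (max(ri) + 1), "+"))
}
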
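# Shifted-window self-attention over patch tokens of the highest-resolution
# backbone map.
#
# The attention layer is: a stride-4 convolutional patch embedding to
# `embed_dim` dimensions with layer normalization, followed by `depth`
# transformer blocks used in regular/shifted pairs. A block is
#   x_hat = (S)W-MSA(LN(x)) + x ;  x' = MLP(LN(x_hat)) + x_hat
# with multi-head attention restricted to non-overlapping windows; shifted
# blocks cyclically roll the token grid by half a window and mask attention
# between tokens that were not contiguous before the roll, so information
# crosses window boundaries without growing the attention cost.

#' Attention layer configuration
#'
#' @param patch_size side of the square patches cut from the feature map.
#' @param embed_dim token dimension after patch embedding.
#' @param depth number of transformer blocks (must be even; blocks alternate
#'   regular and shifted window partitioning).
#' @param window_size window side in tokens; must divide the token grid.
#' @param num_heads attention heads. The canonical setting is 48 heads on a
#'   96-dimensional embedding, i.e. an unusually narrow head dimension of 2;
#'   it is kept configurable.
#' @param shift_size roll applied by shifted blocks (default half a window).
#' @param mlp_ratio hidden/width ratio of the per-token MLP.
#' @return an `attention_config` list.
#' @export
attention_config <- function(patch_size = 4L, embed_dim = 96L, depth = 4L,
                             window_size = 6L, num_heads = 48L,
                             shift_size = window_size %/% 2L, mlp_ratio = 4L) {
  stopifnot(depth %% 2L == 0L, embed_dim %% num_heads == 0L,
            shift_size >= 0L, shift_size < window_size)
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth),
                 window_size = as.integer(window_size),
                 num_heads = as.integer(num_heads),
                 shift_size = as.integer(shift_size),
                 mlp_ratio = as.integer(mlp_ratio)),
            class = "attention_config")
}

# ---- index helpers -------------------------------------------------------

# Token index of 1-based grid coordinates; tokens are ordered column-major
# over the (Gh, Gw) grid.
tok_index <- function(i, j, Gh) i + Gh * (j - 1L)

# Row permutation that groups tokens into windows: output row
# t + T*(w-1) holds token (window w, in-window position t); windows and
# in-window positions are both column-major.
win_perm <- function(grid, M) {
  Gh <- grid[1]; Gw <- grid[2]
  if (Gh %% M != 0L || Gw %% M != 0L) {
    stop("window size ", M, " must divide the token grid ", Gh, "x", Gw,
         " (no padding is applied)")
  }
  nWh <- Gh %/% M; nWw <- Gw %/% M
  perm <- integer(Gh * Gw)
  pos <- 1L
  for (wj in seq_len(nWw)) for (wi in seq_len(nWh)) {
    for (dj in seq_len(M)) for (di in seq_len(M)) {
      perm[pos] <- tok_index((wi - 1L) * M + di, (wj - 1L) * M + dj, Gh)
      pos <- pos + 1L
    }
  }
  perm
}

# Row permutation implementing a cyclic roll of the token grid by
# (-shift, -shift): output position p takes the token at p + shift (mod G).
roll_perm <- function(grid, shift) {
  Gh <- grid[1]; Gw <- grid[2]
  pi_ <- ((seq_len(Gh) - 1L + shift) %% Gh) + 1L
  pj <- ((seq_len(Gw) - 1L + shift) %% Gw) + 1L
  as.vector(outer(pi_, (pj - 1L) * Gh, "+"))
}

inv_perm <- function(perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  inv
}

# Relative-position lookup (T x T, 1-based) into the (2M-1)^2 bias table.
relpos_index <- function(M) {
  T_ <- M * M
  di <- rep(seq_len(M), times = M)
  dj <- rep(seq_len(M), each = M)
  ddi <- outer(di, di, "-") + M - 1L
  ddj <- outer(dj, dj, "-") + M - 1L
  ddi * (2L * M - 1L) + ddj + 1L
}

# ---- user-facing functional ops -----------------------------------------

#' Embed a feature map into a patch-token sequence
#'
#' Applies a `patch_size`-stride convolution (kernel = stride) projecting
#' each non-overlapping patch to `embed_dim` dimensions, then layer-norm.
#'
#' @param feature_map `(H, W, C)` or `(H, W, C, N)` array (the branch-0
#'   backbone map; `H`, `W` must be divisible by `patch_size`).
#' @param config an [attention_config()].
#' @param module optional pre-built embedding module with materialized
#'   parameters (as inside a full model); freshly initialized otherwise.
#' @return a `patch_sequence`: list with `tokens` (`(L, embed_dim)` matrix,
#'   or `(L, embed_dim, N)` array for batches), `dim`, and `grid = c(Gh, Gw)`.
#' @export
patch_embed <- function(feature_map, config = attention_config(), module = NULL) {
  d <- dim(feature_map)
  squeeze <- length(d) == 3L
  if (squeeze) dim(feature_map) <- c(d, 1L)
  d <- dim(feature_map)
  ps <- config$patch_size
  if (d[1] %% ps != 0L || d[2] %% ps != 0L) {
    stop("feature map ", d[1], "x", d[2], " not divisible by patch size ", ps)
  }
  if (is.null(module)) {
    module <- nn_patch_embed(d[3], config)
    nn_init(module)
  }
  out <- forward_patch_embed(module, ag_tensor(feature_map))
  tokens <- out$tokens$value
  if (squeeze) dim(tokens) <- dim(tokens)[1:2]
  structure(list(tokens = tokens, dim = config$embed_dim, grid = out$grid),
            class = "patch_sequence")
}

nn_patch_embed <- function(cin, config) {
  nn_env("patch_embed",
         .children = list(
           proj = nn_conv(cin, config$embed_dim, config$patch_size,
                          stride = config$patch_size, pad = 0L, bias = TRUE,
                          div = 4L * config$patch_size),
           norm = nn_layernorm(config$embed_dim)),
         patch_size = config$patch_size, embed_dim = config$embed_dim)
}

forward_patch_embed <- function(m, x, training = FALSE) {
  y <- nn_forward(m$children$proj, x, training)
  d <- dim(y$value)
  grid <- c(d[1], d[2])
  tok <- ag_reshape(y, c(d[1] * d[2], d[3], d[4]))
  tok <- nn_forward(m$children$norm, tok, training)
  list(tokens = tok, grid = grid)
}

as_token_array <- function(tokens) {
  if (length(dim(tokens)) == 2L) dim(tokens) <- c(dim(tokens), 1L)
  tokens
}

#' Partition a token sequence into non-overlapping windows
#'
#' @param tokens a `patch_sequence`, or an `(L, d)` matrix with a `grid`
#'   attribute/argument.
#' @param window_size window side in tokens; must divide both grid sides.
#' @param grid `c(Gh, Gw)`; taken from `tokens` if it is a `patch_sequence`.
#' @return `(T, nW, d)` array of windows (`T = window_size^2`), with the
#'   permutation stored in `attr(, "perm")`.
#' @export
window_partition <- function(tokens, window_size, grid = NULL) {
  if (inherits(tokens, "patch_sequence")) {
    grid <- tokens$grid
    tokens <- tokens$tokens
  }
  stopifnot(!is.null(grid))
  tk <- as_token_array(tokens)
  d <- dim(tk)
  perm <- win_perm(grid, window_size)
  T_ <- window_size^2
  nW <- d[1] %/% T_
  m <- tk
  dim(m) <- c(d[1], d[2] * d[3])
  out <- m[perm, , drop = FALSE]
  dim(out) <- c(T_, nW, d[2], d[3])
  if (d[3] == 1L) dim(out) <- c(T_, nW, d[2])
  attr(out, "perm") <- perm
  attr(out, "grid") <- grid
  out
}

#' Reassemble windows into the token sequence (inverse of partition)
#' @param windows output of [window_partition()].
#' @param window_size window side.
#' @param grid `c(Gh, Gw)`; defaults to the attribute stored on `windows`.
#' @return `(L, d)` matrix (or `(L, d, N)` array).
#' @export
window_reverse <- function(windows, window_size, grid = attr(windows, "grid")) {
  stopifnot(!is.null(grid))
  d <- dim(windows)
  N <- if (length(d) == 4L) d[4] else 1L
  L <- prod(grid)
  m <- windows
  dim(m) <- c(L, length(windows) %/% L)
  out <- m[inv_perm(win_perm(grid, window_size)), , drop = FALSE]
  if (N == 1L) dim(out) <- c(L, d[3]) else dim(out) <- c(L, d[3], N)
  out
}

#' Cyclically shift the token grid
#'
#' Rolls the grid by `(-shift, -shift)`; a negative `shift` applies the
#' inverse roll, so `cyclic_shift(cyclic_shift(x, s), -s)` is the identity.
#'
#' @param tokens a `patch_sequence` or `(L, d)` matrix with `grid`.
#' @param shift roll amount in tokens.
#' @param grid `c(Gh, Gw)` when `tokens` is a bare matrix.
#' @return same type as `tokens`.
#' @export
cyclic_shift <- function(tokens, shift, grid = NULL) {
  ps <- inherits(tokens, "patch_sequence")
  if (ps) {
    grid <- tokens$grid
    tk <- tokens$tokens
  } else tk <- tokens
  stopifnot(!is.null(grid))
  # roll each axis by its own modulus
  Gh <- grid[1]; Gw <- grid[2]
  pi_ <- ((seq_len(Gh) - 1L + (shift %% Gh) + Gh) %% Gh) + 1L
  pj <- ((seq_len(Gw) - 1L + (shift %% Gw) + Gw) %% Gw) + 1L
  perm <- as.vector(outer(pi_, (pj - 1L) * Gh, "+"))
  tka <- as_token_array(tk)
  d <- dim(tka)
  m <- tka
  dim(m) <- c(d[1], d[2] * d[3])
  out <- m[perm, , drop = FALSE]
  dim(out) <- d
  if (length(dim(tk)) == 2L || is.null(dim(tk))) dim(out) <- d[1:2]
  if (ps) {
    tokens$tokens <- out
    tokens
  } else out
}

#' Additive attention mask for shifted windows
#'
#' Entry `(i, j)` of a window's mask is 0 when tokens `i` and `j` originate
#' from the same contiguous pre-shift region of the grid and a large
#' negative surrogate for minus infinity otherwise; with `shift = 0` all
#' masks are zero.
#'
#' @param grid `c(Gh, Gw)` token grid.
#' @param window_size window side.
#' @param shift cyclic shift applied before partitioning.
#' @return `(T, T, nW)` array, windows ordered as in [window_partition()].
#' @export
build_attention_mask <- function(grid, window_size, shift) {
  Gh <- grid[1]; Gw <- grid[2]
  M <- window_size
  nW <- (Gh %/% M) * (Gw %/% M)
  T_ <- M * M
  mask <- array(0, c(T_, T_, nW))
  if (shift == 0L) return(mask)
  bin <- function(p, G) ifelse(p < G - M, 0L, ifelse(p < G - shift, 1L, 2L))
  # region label of every post-shift grid position
  lab <- outer(bin(seq_len(Gh) - 1L, Gh) * 3L, bin(seq_len(Gw) - 1L, Gw), "+")
  lab_tok <- as.vector(lab) # column-major == token order
  perm <- win_perm(grid, M)
  for (w in seq_len(nW)) {
    lw <- lab_tok[perm[(w - 1L) * T_ + seq_len(T_)]]
    same <- outer(lw, lw, "==")
    mask[, , w] <- ifelse(same, 0, -1e9)
  }
  mask
}

#' Windowed multi-head self-attention (functional form)
#'
#' Per-head scaled dot-product attention within each window, with a learned
#' relative-position bias added to the logits and an optional additive mask
#' applied before the softmax.
#'
#' @param windows `(T, nW, d)` array from [window_partition()].
#' @param config an [attention_config()].
#' @param mask `(T, T, nW)` additive mask or NULL.
#' @param weights list with `wqkv` `(d, 3d)`, `bqkv`, `wproj` `(d, d)`,
#'   `bproj`, and `bias_table` `((2M-1)^2, heads)`; freshly initialized when
#'   omitted (useful only for shape tests).
#' @return `(T, nW, d)` array of attended windows.
#' @export
window_msa <- function(windows, config = attention_config(), mask = NULL,
                       weights = NULL) {
  d <- dim(windows)
  T_ <- d[1]; nW <- d[2]; C <- d[3]
  M <- as.integer(sqrt(T_))
  stopifnot(M * M == T_)
  if (!is.null(mask)) stopifnot(all(dim(mask) == c(T_, T_, nW)))
  if (is.null(weights)) {
    weights <- list(
      wqkv = matrix(stats::rnorm(C * 3 * C, sd = 0.02), C, 3L * C),
      bqkv = rep(0, 3L * C),
      wproj = matrix(stats::rnorm(C * C, sd = 0.02), C, C),
      bproj = rep(0, C),
      bias_table = matrix(0, (2L * M - 1L)^2, config$num_heads))
  }
  xw <- windows
  dim(xw) <- c(T_, nW, C, 1L)
  xw <- aperm(xw, c(1L, 3L, 2L, 4L))
  dim(xw) <- c(T_, C, nW)
  out <- ag_window_msa(ag_tensor(xw),
                       ag_tensor(weights$wqkv), ag_tensor(weights$bqkv),
                       ag_tensor(weights$wproj), ag_tensor(weights$bproj),
                       ag_tensor(weights$bias_table), relpos_index(M),
                       heads = config$num_heads, mask = mask, n_windows = nW)
  y <- out$value
  dim(y) <- c(T_, C, nW, 1L)
  y <- aperm(y, c(1L, 3L, 2L, 4L))
  dim(y) <- c(T_, nW, C)
  attr(y, "grid") <- attr(windows, "grid")
  y
}

# ---- swin transformer blocks (model internals) ---------------------------

nn_swin_block <- function(config, shifted) {
  C <- config$embed_dim
  M <- config$window_size
  nn_env("swin_block",
         .children = list(
           ln1 = nn_layernorm(C),
           qkv = nn_linear(C, 3L * C, bias = TRUE),
           attn = nn_attn_bias(M, config$num_heads, C),
           proj = nn_linear(C, C, bias = TRUE),
           ln2 = nn_layernorm(C),
           mlp1 = nn_linear(C, C * config$mlp_ratio, bias = TRUE),
           mlp2 = nn_linear(C * config$mlp_ratio, C, bias = TRUE)),
         window = M, shift = if (shifted) config$shift_size else 0L,
         heads = config$num_heads, embed = C)
}

forward_swin_block <- function(blk, x, grid, training = FALSE, mask_cache = NULL) {
  ch <- blk$children
  M <- blk$window
  s <- blk$shift
  T_ <- M * M
  L <- prod(grid)
  nW <- L %/% T_
  d <- dim(x$value)
  N <- d[3]
  shortcut <- x
  y <- nn_forward(ch$ln1, x, training)
  if (s > 0L) y <- ag_row_permute(y, roll_perm(grid, s))
  pw <- win_perm(grid, M)
  y <- ag_row_permute(y, pw) # (L, C, N) rows grouped by window
  y <- ag_reshape(y, c(T_, nW, blk$embed, N))
  y <- ag_aperm(y, c(1L, 3L, 2L, 4L))
  y <- ag_reshape(y, c(T_, blk$embed, nW * N))
  mask <- NULL
  if (s > 0L) {
    mask <- if (!is.null(mask_cache)) mask_cache else build_attention_mask(grid, M, s)
  }
  y <- ag_window_msa(y, ch$qkv$params$w, ch$qkv$params$b,
                     ch$proj$params$w, ch$proj$params$b,
                     ch$attn$params$table, relpos_index(M),
                     heads = blk$heads, mask = mask, n_windows = nW)
  y <- ag_reshape(y, c(T_, blk$embed, nW, N))
  y <- ag_aperm(y, c(1L, 3L, 2L, 4L))
  y <- ag_reshape(y, c(L, blk$embed, N))
  y <- ag_row_permute(y, inv_perm(pw))
  if (s > 0L) y <- ag_row_permute(y, roll_perm(grid, -s))
  x <- ag_add(shortcut, y)
  y2 <- nn_forward(ch$ln2, x, training)
  y2 <- nn_forward(ch$mlp1, y2, training)
  y2 <- ag_gelu(y2)
  y2 <- nn_forward(ch$mlp2, y2, training)
  ag_add(x, y2)
}

#' Apply a regular/shifted pair of transformer blocks
#'
#' Runs one window-attention block and one shifted-window block (the unit the
#' attention layer stacks `depth/2` times).
#'
#' @param tokens a `patch_sequence`.
#' @param pair optional list of two materialized `nn_swin_block`s; freshly
#'   initialized from `config` otherwise.
#' @param config an [attention_config()] (used when `pair` is NULL).
#' @return a `patch_sequence` of identical shape.
#' @export
swin_block_pair <- function(tokens, pair = NULL, config = attention_config()) {
  stopifnot(inherits(tokens, "patch_sequence"))
  if (is.null(pair)) {
    pair <- list(nn_swin_block(config, shifted = FALSE),
                 nn_swin_block(config, shifted = TRUE))
    lapply(pair, nn_init)
  }
  tk <- as_token_array(tokens$tokens)
  x <- ag_tensor(tk)
  for (blk in pair) x <- forward_swin_block(blk, x, tokens$grid)
  out <- x$value
  if (length(dim(tokens$tokens)) == 2L) dim(out) <- dim(out)[1:2]
  tokens$tokens <- out
  tokens
}
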
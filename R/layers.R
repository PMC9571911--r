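# Network layers as environments carrying hyperparameters, lazily
# materialized parameters (ag_param leaves) and, for batch norm, running
# statistics. Composites store an ordered named list in $children; the
# analytic profiler walks the same structure, so parameter and FLOP
# accounting always refers to the graph that actually runs.
#
# Every spatial primitive records `div`, the divisor of the model input
# resolution at which its output lives; token primitives record the grid
# divisor (16 = stride-4 stem halvings times the stride-4 patch embed).
# FLOPs are multiply-accumulates: conv/deconv k^2*Cin*Cout*Hout*Wout (deconv
# counted at its input resolution), linear din*dout per token, attention
# qkv-free score terms T^2*embed per window for logits and for the weighted
# sum. Normalizations and activations are excluded; the convention is
# applied identically to every profiled model.

nn_env <- function(.kind, .children = list(), ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$children <- .children
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- NULL
  class(e) <- c(paste0("nn_", .kind), "nn_layer")
  e
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = FALSE, div = 1) {
  nn_env("conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
         bias = bias, div = div)
}

nn_bn <- function(c, div = 1) nn_env("bn", c = c, div = div)

nn_relu <- function() nn_env("relu")

nn_upsample <- function(factor) nn_env("upsample", factor = factor)

nn_linear <- function(din, dout, bias = TRUE, n_tokens_div = 16) {
  nn_env("linear", din = din, dout = dout, bias = bias,
         n_tokens_div = n_tokens_div)
}

nn_layernorm <- function(dim) nn_env("layernorm", dim = dim)

nn_deconv <- function(cin, cout, k, stride, bias = TRUE, div_in = 16) {
  nn_env("deconv", cin = cin, cout = cout, k = k, stride = stride,
         bias = bias, div_in = div_in)
}

nn_seq <- function(children) nn_env("seq", .children = children)

# ---- parameter materialization ------------------------------------------

#' @keywords internal
nn_init <- function(m) {
  switch(m$kind,
    conv = {
      fan_out <- m$k^2 * m$cout
      w <- array(stats::rnorm(m$k^2 * m$cin * m$cout, sd = sqrt(2 / fan_out)),
                 c(m$k, m$k, m$cin, m$cout))
      m$params <- list(w = ag_param(w))
      if (m$bias) m$params$b <- ag_param(rep(0, m$cout))
    },
    deconv = {
      w <- array(stats::rnorm(m$k^2 * m$cin * m$cout, sd = 0.001),
                 c(m$k, m$k, m$cin, m$cout))
      m$params <- list(w = ag_param(w))
      if (m$bias) m$params$b <- ag_param(rep(0, m$cout))
    },
    bn = {
      m$params <- list(gamma = ag_param(rep(1, m$c)), beta = ag_param(rep(0, m$c)))
      m$running_mean <- rep(0, m$c)
      m$running_var <- rep(1, m$c)
    },
    linear = {
      w <- matrix(stats::rnorm(m$din * m$dout, sd = 0.02), m$din, m$dout)
      m$params <- list(w = ag_param(w))
      if (m$bias) m$params$b <- ag_param(rep(0, m$dout))
    },
    layernorm = {
      m$params <- list(gamma = ag_param(rep(1, m$dim)), beta = ag_param(rep(0, m$dim)))
    },
    attn_bias = {
      tab <- matrix(stats::rnorm(m$n_entries * m$heads, sd = 0.02),
                    m$n_entries, m$heads)
      m$params <- list(table = ag_param(tab))
    },
    NULL
  )
  for (ch in m$children) if (!is.null(ch)) nn_init(ch)
  invisible(m)
}

# Relative-position bias table + the parameter-free attention score/softmax
# stage (carried as one primitive so the profiler can charge its FLOPs).
nn_attn_bias <- function(window, heads, embed, n_tokens_div = 16) {
  nn_env("attn_bias", window = window, heads = heads, embed = embed,
         n_entries = (2L * window - 1L)^2, n_tokens_div = n_tokens_div)
}

# ---- profiler walk -------------------------------------------------------

# Flat list of primitive descriptors (kind, path, layer env).
nn_prims <- function(m, path = "model") {
  if (is.null(m)) return(list())
  own <- if (m$kind %in% c("conv", "bn", "linear", "layernorm", "deconv", "attn_bias")) {
    list(list(kind = m$kind, path = path, layer = m))
  } else list()
  kid_names <- names(m$children)
  kids <- list()
  for (i in seq_along(m$children)) {
    nm <- if (!is.null(kid_names) && nzchar(kid_names[i])) kid_names[i] else as.character(i)
    kids <- c(kids, nn_prims(m$children[[i]], paste(path, nm, sep = ".")))
  }
  c(own, kids)
}

# All parameter leaves, in graph order.
nn_params <- function(m) {
  out <- list()
  if (!is.null(m$params)) out <- c(out, unname(m$params))
  for (ch in m$children) if (!is.null(ch)) out <- c(out, nn_params(ch))
  out
}

# ---- forward -------------------------------------------------------------

# Forward through a primitive or sequential container. `x` is an ag_tensor;
# feature maps (H, W, C, N), tokens (L, d, N).
nn_forward <- function(m, x, training = FALSE) {
  switch(m$kind,
    conv = ag_conv2d(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad),
    deconv = ag_deconv2d(x, m$params$w, m$params$b, stride = m$stride),
    bn = ag_batchnorm(x, m$params$gamma, m$params$beta, m, training),
    relu = ag_relu(x),
    upsample = ag_upsample_nearest(x, m$factor),
    linear = ag_linear(x, m$params$w, m$params$b),
    layernorm = ag_layernorm(x, m$params$gamma, m$params$beta),
    seq = {
      for (ch in m$children) x <- nn_forward(ch, x, training)
      x
    },
    basic_block = forward_basic_block(m, x, training),
    bottleneck = forward_bottleneck(m, x, training),
    stop("no forward for kind ", m$kind)
  )
}

# conv-bn-relu unit
nn_cbr <- function(cin, cout, k, stride = 1L, div = 1, relu = TRUE) {
  ch <- list(conv = nn_conv(cin, cout, k, stride, div = div),
             bn = nn_bn(cout, div = div))
  if (relu) ch$relu <- nn_relu()
  nn_seq(ch)
}

# Residual basic block: two 3x3 convs at constant width.
nn_basic_block <- function(planes, div) {
  nn_env("basic_block",
         .children = list(
           conv1 = nn_conv(planes, planes, 3L, div = div),
           bn1 = nn_bn(planes, div),
           conv2 = nn_conv(planes, planes, 3L, div = div),
           bn2 = nn_bn(planes, div)))
}

forward_basic_block <- function(m, x, training) {
  ch <- m$children
  y <- ag_relu(ag_batchnorm(ag_conv2d(x, ch$conv1$params$w, NULL, 1L, 1L),
                            ch$bn1$params$gamma, ch$bn1$params$beta, ch$bn1, training))
  y <- ag_batchnorm(ag_conv2d(y, ch$conv2$params$w, NULL, 1L, 1L),
                    ch$bn2$params$gamma, ch$bn2$params$beta, ch$bn2, training)
  ag_relu(ag_add(y, x))
}

# Bottleneck block (1x1 down, 3x3, 1x1 up by `expansion`).
nn_bottleneck <- function(inplanes, planes, expansion = 4L, div = 1) {
  ch <- list(
    conv1 = nn_conv(inplanes, planes, 1L, div = div),
    bn1 = nn_bn(planes, div),
    conv2 = nn_conv(planes, planes, 3L, div = div),
    bn2 = nn_bn(planes, div),
    conv3 = nn_conv(planes, planes * expansion, 1L, div = div),
    bn3 = nn_bn(planes * expansion, div))
  if (inplanes != planes * expansion) {
    ch$ds_conv <- nn_conv(inplanes, planes * expansion, 1L, div = div)
    ch$ds_bn <- nn_bn(planes * expansion, div)
  }
  nn_env("bottleneck", .children = ch, has_ds = inplanes != planes * expansion)
}

forward_bottleneck <- function(m, x, training) {
  ch <- m$children
  bnf <- function(y, bn) ag_batchnorm(y, bn$params$gamma, bn$params$beta, bn, training)
  y <- ag_relu(bnf(ag_conv2d(x, ch$conv1$params$w, NULL, 1L, 0L), ch$bn1))
  y <- ag_relu(bnf(ag_conv2d(y, ch$conv2$params$w, NULL, 1L, 1L), ch$bn2))
  y <- bnf(ag_conv2d(y, ch$conv3$params$w, NULL, 1L, 0L), ch$bn3)
  skip <- if (isTRUE(m$has_ds)) bnf(ag_conv2d(x, ch$ds_conv$params$w, NULL, 1L, 0L), ch$ds_bn) else x
  ag_relu(ag_add(y, skip))
}
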
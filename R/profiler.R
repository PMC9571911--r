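# Analytic complexity profiler.
#
# Parameters are counted exactly (weights, biases, normalization affine
# terms, relative-position bias tables) from the graph structure, so counts
# agree with a brute-force enumeration of materialized tensors. FLOPs are
# multiply-accumulates (1 MAC = 1 FLOP) for one forward pass at a stated
# input size: conv/deconv k^2*Cin*Cout per output/input position, linear
# din*dout per token, attention logits and weighted sum T^2*embed per
# window; normalizations and activations are excluded. The convention is
# applied identically to every profiled model, so reduction percentages are
# insensitive to it.

prim_params <- function(p) {
  l <- p$layer
  switch(p$kind,
    conv = l$k^2 * l$cin * l$cout + if (l$bias) l$cout else 0L,
    deconv = l$k^2 * l$cin * l$cout + if (l$bias) l$cout else 0L,
    bn = 2 * l$c,
    linear = l$din * l$dout + if (l$bias) l$dout else 0L,
    layernorm = 2 * l$dim,
    attn_bias = l$n_entries * l$heads,
    0)
}

prim_flops <- function(p, H, W) {
  l <- p$layer
  switch(p$kind,
    conv = l$k^2 * l$cin * l$cout * (H / l$div) * (W / l$div),
    deconv = l$k^2 * l$cin * l$cout * (H / l$div_in) * (W / l$div_in),
    linear = l$din * l$dout * (H / l$n_tokens_div) * (W / l$n_tokens_div),
    attn_bias = {
      nW <- (H / l$n_tokens_div / l$window) * (W / l$n_tokens_div / l$window)
      2 * nW * (l$window^2)^2 * l$embed
    },
    0)
}

#' Per-layer parameter and FLOP report
#'
#' @param model a graph from [build_hrst()], [build_hrnet_w48()] or
#'   [build_backbone()] (parameters need not be materialized).
#' @param input_size `c(H, W)` at which FLOPs are evaluated.
#' @param name model label carried into comparisons.
#' @return a tibble with one row per parameterized/compute layer (`name`,
#'   `kind`, `params`, `flops`) plus attributes `totals`, `input_size` and
#'   `model_name`.
#' @export
profile_model <- function(model, input_size = c(288L, 384L), name = model$kind) {
  H <- input_size[1]; W <- input_size[2]
  prims <- nn_prims(model, path = name)
  rows <- tibble::tibble(
    name = vapply(prims, function(p) p$path, character(1)),
    kind = vapply(prims, function(p) p$kind, character(1)),
    params = vapply(prims, prim_params, numeric(1)),
    flops = vapply(prims, prim_flops, numeric(1), H = H, W = W))
  attr(rows, "totals") <- c(params = sum(rows$params), flops = sum(rows$flops))
  attr(rows, "input_size") <- as.integer(input_size)
  attr(rows, "model_name") <- name
  rows
}

#' Count learnable parameters of a graph
#'
#' Exact integer count of learnable scalars. Independent of input size.
#' @param model a model graph.
#' @return a count.
#' @export
count_parameters <- function(model) {
  sum(vapply(nn_prims(model), prim_params, numeric(1)))
}

#' Count forward-pass multiply-accumulates
#'
#' @param model a model graph.
#' @param input_size `c(H, W)`.
#' @return MAC count for one forward pass.
#' @export
count_flops <- function(model, input_size = c(288L, 384L)) {
  sum(vapply(nn_prims(model), prim_flops, numeric(1),
             H = input_size[1], W = input_size[2]))
}

#' Compare model complexity reports
#'
#' Emits totals and percent reductions `100 * (1 - a / b)` of parameters and
#' FLOPs against a named baseline.
#'
#' @param reports list of reports from [profile_model()], all at the same
#'   input size.
#' @param baseline model name (default: the largest-parameter report).
#' @return a tibble with one row per model: `model`, `params`, `gflops`,
#'   `param_reduction_pct`, `flop_reduction_pct`.
#' @export
compare_models <- function(reports, baseline = NULL) {
  sizes <- lapply(reports, attr, "input_size")
  if (length(unique(vapply(sizes, paste, character(1), collapse = "x"))) != 1L) {
    stop("all reports must share one input size")
  }
  names_ <- vapply(reports, attr, character(1), "model_name")
  totals <- t(vapply(reports, attr, numeric(2), "totals"))
  if (is.null(baseline)) baseline <- names_[which.max(totals[, "params"])]
  bi <- match(baseline, names_)
  if (is.na(bi)) stop("baseline ", baseline, " not among reports")
  tibble::tibble(
    model = names_,
    params = totals[, "params"],
    gflops = totals[, "flops"] / 1e9,
    param_reduction_pct = 100 * (1 - totals[, "params"] / totals[bi, "params"]),
    flop_reduction_pct = 100 * (1 - totals[, "flops"] / totals[bi, "flops"]))
}

# Brute-force parameter enumeration of a materialized graph (test oracle
# and sanity check for count_parameters()).
enumerate_parameters <- function(model) {
  sum(vapply(nn_params(model), function(p) length(p$value), numeric(1)))
}
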
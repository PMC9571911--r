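# Full joint-point model: truncated multi-resolution backbone -> patch
# embedding of the highest-resolution branch -> stacked shifted-window
# transformer blocks -> transposed-convolution heatmap head. Also the
# four-stage HRNet-w48 pose baseline (backbone + 1x1 prediction head),
# built for complexity profiling.

#' Full model configuration
#'
#' @param backbone a [backbone_config()].
#' @param attention an [attention_config()].
#' @param input_size `c(H, W)` of the network input crop (default
#'   `c(288, 384)`, i.e. 384x288 in width-by-height notation). Both must be
#'   divisible by 32 and the 1/16-resolution token grid by `window_size`.
#' @param out_channels number of joints (heatmap channels).
#' @return an `hrst_config` list.
#' @export
hrst_config <- function(backbone = backbone_config(),
                        attention = attention_config(),
                        input_size = c(288L, 384L),
                        out_channels = 10L) {
  grid <- input_size %/% 16L
  if (any(input_size %% 32L != 0L)) {
    stop("input size must be divisible by 32")
  }
  if (any(grid %% attention$window_size != 0L)) {
    stop("token grid ", grid[1], "x", grid[2],
         " is not divisible by window size ", attention$window_size,
         "; pick an input size whose sides are multiples of ",
         16L * attention$window_size)
  }
  structure(list(backbone = backbone, attention = attention,
                 input_size = as.integer(input_size),
                 out_channels = as.integer(out_channels)),
            class = "hrst_config")
}

#' Reduced-width preset for CPU-scale training and tests
#'
#' Same topology as the canonical model with narrow branches (8/16/32), a
#' 32-dimensional embedding with 4 heads, one fusion module in stage 3 and a
#' 96x96 input (6x6 token grid, a single window).
#' @return an `hrst_config`.
#' @export
hrst_tiny_config <- function() {
  hrst_config(
    backbone = backbone_config(
      stem_channels = 8L, stage1_blocks = 2L,
      widths = list(stage2 = c(8L, 16L), stage3 = c(8L, 16L, 32L),
                    stage4 = c(8L, 16L, 32L, 64L)),
      modules_per_stage = c(stage2 = 1L, stage3 = 1L, stage4 = 1L),
      blocks_per_branch = 2L),
    attention = attention_config(embed_dim = 32L, depth = 2L, num_heads = 4L),
    input_size = c(96L, 96L))
}

#' Assemble the joint-point detection model graph
#'
#' Composition: backbone truncated after stage 3, highest-resolution branch
#' only, patch embedding, `depth` transformer blocks, transposed-conv head.
#' Parameters are not materialized; call [model_init()] before running it.
#'
#' @param config an [hrst_config()].
#' @return an `nn_layer` environment of kind `"hrst"`.
#' @export
build_hrst <- function(config = hrst_config()) {
  att <- config$attention
  w3 <- config$backbone$widths$stage3
  blocks <- lapply(seq_len(att$depth), function(i) {
    nn_swin_block(att, shifted = i %% 2L == 0L)
  })
  nn_env("hrst",
         .children = c(
           list(backbone = build_backbone(config$backbone, truncate_at_stage = 3L),
                embed = nn_patch_embed(w3[1], att)),
           stats::setNames(blocks, paste0("block", seq_len(att$depth))),
           list(head = nn_head(att$embed_dim, config$out_channels))),
         config = config)
}

#' Assemble the four-stage HRNet-w48 pose baseline
#'
#' The full backbone with its fourth stage and a 1x1 convolution predicting
#' one heatmap channel per joint from the highest-resolution branch. Used
#' as the profiling baseline.
#'
#' @param config a [backbone_config()].
#' @param out_channels number of joints.
#' @return an `nn_layer` environment of kind `"hrnet_pose"`.
#' @export
build_hrnet_w48 <- function(config = backbone_config(), out_channels = 10L) {
  nn_env("hrnet_pose",
         .children = list(
           backbone = build_backbone(config, truncate_at_stage = 4L),
           final = nn_conv(config$widths$stage4[1], out_channels, 1L,
                           bias = TRUE, div = 4L)),
         out_channels = out_channels)
}

#' Materialize (initialize) all model parameters
#'
#' @param model graph from [build_hrst()], [build_hrnet_w48()] or
#'   [build_backbone()].
#' @param seed integer seed making the initialization reproducible.
#' @return the model, invisibly.
#' @export
model_init <- function(model, seed = 1L) {
  set.seed(seed)
  nn_init(model)
  invisible(model)
}

# ag-level forward of the full model; x is an ag tensor (H, W, 3, N).
forward_hrst_ag <- function(model, x, training = FALSE) {
  cfg <- model$config
  xs <- forward_backbone_ag(model$children$backbone, x, training)
  pe <- forward_patch_embed(model$children$embed, xs[[1]], training)
  tokens <- pe$tokens
  grid <- pe$grid
  for (i in seq_len(cfg$attention$depth)) {
    blk <- model$children[[paste0("block", i)]]
    key <- paste0("mask_", grid[1], "_", grid[2], "_", blk$shift)
    if (blk$shift > 0L && is.null(model[[key]])) {
      model[[key]] <- build_attention_mask(grid, blk$window, blk$shift)
    }
    tokens <- forward_swin_block(blk, tokens, grid, training,
                                 mask_cache = model[[key]])
  }
  forward_head(model$children$head, tokens, grid, training)
}

forward_hrnet_ag <- function(model, x, training = FALSE) {
  xs <- forward_backbone_ag(model$children$backbone, x, training)
  nn_forward(model$children$final, xs[[1]], training)
}

#' Run a model on images
#'
#' @param model a materialized model from [build_hrst()] or
#'   [build_hrnet_w48()].
#' @param images `(H, W, 3)` or `(H, W, 3, N)` array in `[0, 1]`.
#' @param training logical; training-mode normalization statistics.
#' @return heatmap array `(H/4, W/4, out_channels[, N])`.
#' @export
hrst_forward <- function(model, images, training = FALSE) {
  squeeze <- length(dim(images)) == 3L
  x <- as_image_batch(images)
  out <- switch(model$kind,
                hrst = forward_hrst_ag(model, x, training),
                hrnet_pose = forward_hrnet_ag(model, x, training),
                stop("not a model graph: kind ", model$kind))
  v <- out$value
  if (squeeze) dim(v) <- dim(v)[1:3]
  v
}
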
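# Multi-resolution (HRNet-style) convolutional backbone.
#
# The backbone keeps a high-resolution branch throughout and adds one
# half-resolution, double-width branch per stage. `truncate_at_stage = 3`
# yields the compact feature extractor used by the joint-point model;
# `truncate_at_stage = 4` builds the full four-stage pose baseline used for
# complexity profiling. Widths, block counts and fusion wiring follow the
# reference HRNet-w48 configuration; the final module of the terminal stage
# fuses only into the highest-resolution branch, which is the only branch
# consumed downstream.

#' Backbone configuration
#'
#' @param stem_channels channels of the two stride-2 stem convolutions.
#' @param stage1_blocks number of bottleneck blocks in stage 1.
#' @param widths named list of per-branch channel widths for stages 2-4.
#' @param modules_per_stage number of repeated fusion modules per stage.
#' @param blocks_per_branch residual basic blocks per branch per module.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(stem_channels = 64L,
                            stage1_blocks = 4L,
                            widths = list(stage2 = c(48L, 96L),
                                          stage3 = c(48L, 96L, 192L),
                                          stage4 = c(48L, 96L, 192L, 384L)),
                            modules_per_stage = c(stage2 = 1L, stage3 = 4L, stage4 = 3L),
                            blocks_per_branch = 4L) {
  stopifnot(stem_channels > 0, stage1_blocks > 0, blocks_per_branch > 0,
            all(unlist(widths) > 0), all(modules_per_stage > 0))
  structure(list(stem_channels = as.integer(stem_channels),
                 stage1_blocks = as.integer(stage1_blocks),
                 widths = lapply(widths, as.integer),
                 modules_per_stage = modules_per_stage,
                 blocks_per_branch = as.integer(blocks_per_branch)),
            class = "backbone_config")
}

# Spatial divisor of branch k (1-based): input/4 for branch 1, halved per branch.
branch_div <- function(k) as.integer(4L * 2L^(k - 1L))

# Cross-resolution fusion path from source branch j to output branch i
# (1-based, branch 1 = highest resolution). NULL for j == i.
fuse_path <- function(widths, j, i) {
  cj <- widths[j]; ci <- widths[i]
  if (j == i) return(NULL)
  if (j > i) {
    # lower-resolution source: 1x1 channel mapping then nearest upsampling
    nn_seq(list(conv = nn_conv(cj, ci, 1L, div = branch_div(j)),
                bn = nn_bn(ci, branch_div(j)),
                up = nn_upsample(2L^(j - i))))
  } else {
    # higher-resolution source: chain of stride-2 3x3 convs
    steps <- list()
    for (t in seq_len(i - j)) {
      last <- t == i - j
      cout <- if (last) ci else cj
      d <- branch_div(j + t)
      steps[[paste0("down", t)]] <- nn_conv(cj, cout, 3L, stride = 2L, div = d)
      steps[[paste0("bn", t)]] <- nn_bn(cout, d)
      if (!last) steps[[paste0("relu", t)]] <- nn_relu()
    }
    nn_seq(steps)
  }
}

# One multi-branch module: `blocks` basic blocks per branch, then full
# cross-resolution fusion. If multi_scale_output is FALSE only the
# highest-resolution output (and its incoming fusion paths) exists.
nn_hr_module <- function(widths, blocks = 4L, multi_scale_output = TRUE) {
  nb <- length(widths)
  ch <- list()
  for (b in seq_len(nb)) {
    ch[[paste0("branch", b)]] <-
      nn_seq(stats::setNames(
        lapply(seq_len(blocks), function(i) nn_basic_block(widths[b], branch_div(b))),
        paste0("block", seq_len(blocks))))
  }
  outs <- if (multi_scale_output) seq_len(nb) else 1L
  for (i in outs) for (j in seq_len(nb)) {
    p <- fuse_path(widths, j, i)
    if (!is.null(p)) ch[[paste0("fuse", i, "_", j)]] <- p
  }
  nn_env("hr_module", .children = ch, nb = nb, outs = outs, widths = widths)
}

forward_hr_module <- function(m, xs, training = FALSE) {
  ch <- m$children
  ys <- lapply(seq_len(m$nb), function(b) nn_forward(ch[[paste0("branch", b)]], xs[[b]], training))
  out <- ys
  for (i in m$outs) {
    acc <- NULL
    for (j in seq_len(m$nb)) {
      contrib <- if (i == j) ys[[j]] else nn_forward(ch[[paste0("fuse", i, "_", j)]], ys[[j]], training)
      acc <- if (is.null(acc)) contrib else ag_add(acc, contrib)
    }
    out[[i]] <- ag_relu(acc)
  }
  # branches without fusion paths (terminal module) pass through unfused;
  # only the fused highest-resolution branch feeds downstream consumers
  out
}

# Transition into a stage: adapt existing branches where widths change and
# spawn the new half-resolution branch from the deepest existing one.
nn_transition <- function(pre_widths, cur_widths) {
  npre <- length(pre_widths)
  ncur <- length(cur_widths)
  ch <- list()
  for (i in seq_len(ncur)) {
    if (i <= npre) {
      if (pre_widths[i] != cur_widths[i]) {
        ch[[paste0("t", i)]] <- nn_cbr(pre_widths[i], cur_widths[i], 3L, div = branch_div(i))
      } else ch[paste0("t", i)] <- list(NULL)
    } else {
      steps <- list()
      src <- pre_widths[npre]
      for (t in seq_len(i - npre)) {
        last <- t == i - npre
        cout <- if (last) cur_widths[i] else src
        d <- branch_div(npre + t)
        steps[[paste0("c", t)]] <- nn_conv(src, cout, 3L, stride = 2L, div = d)
        steps[[paste0("bn", t)]] <- nn_bn(cout, d)
        steps[[paste0("relu", t)]] <- nn_relu()
      }
      ch[[paste0("t", i)]] <- nn_seq(steps)
    }
  }
  nn_env("transition", .children = ch, npre = npre, ncur = ncur)
}

forward_transition <- function(m, xs, training = FALSE) {
  out <- vector("list", m$ncur)
  for (i in seq_len(m$ncur)) {
    tr <- m$children[[paste0("t", i)]]
    src <- if (i <= m$npre) xs[[i]] else xs[[m$npre]]
    out[[i]] <- if (is.null(tr)) src else nn_forward(tr, src, training)
  }
  out
}

#' Build the multi-resolution backbone graph
#'
#' @param config a [backbone_config()].
#' @param truncate_at_stage 3 for the compact joint-point backbone, 4 for the
#'   full four-stage pose baseline.
#' @return an `nn_layer` environment (kind `"backbone"`); parameters are not
#'   materialized until [model_init()] so profiling large graphs stays cheap.
#' @export
build_backbone <- function(config = backbone_config(), truncate_at_stage = 3L) {
  if (!truncate_at_stage %in% c(3L, 4L)) {
    stop("truncate_at_stage must be 3 or 4, got ", truncate_at_stage)
  }
  sc <- config$stem_channels
  w2 <- config$widths$stage2
  w3 <- config$widths$stage3
  exp1 <- 4L
  stage1_out <- sc * exp1
  ch <- list(
    stem = nn_seq(list(conv1 = nn_conv(3L, sc, 3L, stride = 2L, div = 2L),
                       bn1 = nn_bn(sc, 2L), relu1 = nn_relu(),
                       conv2 = nn_conv(sc, sc, 3L, stride = 2L, div = 4L),
                       bn2 = nn_bn(sc, 4L), relu2 = nn_relu())),
    layer1 = nn_seq(stats::setNames(
      lapply(seq_len(config$stage1_blocks), function(i) {
        nn_bottleneck(if (i == 1L) sc else stage1_out, sc, exp1, div = 4L)
      }), paste0("block", seq_len(config$stage1_blocks)))),
    trans2 = nn_transition(stage1_out, w2),
    stage2 = make_stage(w2, config$modules_per_stage[["stage2"]],
                        config$blocks_per_branch, terminal = FALSE),
    trans3 = nn_transition(w2, w3),
    stage3 = make_stage(w3, config$modules_per_stage[["stage3"]],
                        config$blocks_per_branch,
                        terminal = truncate_at_stage == 3L)
  )
  if (truncate_at_stage == 4L) {
    w4 <- config$widths$stage4
    ch$trans4 <- nn_transition(w3, w4)
    ch$stage4 <- make_stage(w4, config$modules_per_stage[["stage4"]],
                            config$blocks_per_branch, terminal = TRUE)
  }
  nn_env("backbone", .children = ch, config = config,
         truncate_at_stage = as.integer(truncate_at_stage))
}

# A stage is a run of hr_modules; the last module of a terminal stage only
# produces the highest-resolution branch.
make_stage <- function(widths, n_modules, blocks, terminal) {
  mods <- lapply(seq_len(n_modules), function(i) {
    nn_hr_module(widths, blocks,
                 multi_scale_output = !(terminal && i == n_modules))
  })
  nn_env("stage", .children = stats::setNames(mods, paste0("module", seq_len(n_modules))))
}

forward_stage <- function(m, xs, training = FALSE) {
  for (mod in m$children) xs <- forward_hr_module(mod, xs, training)
  xs
}

#' Run the backbone on a batch of images
#'
#' @param backbone graph from [build_backbone()] with materialized parameters.
#' @param images numeric array `(H, W, 3)` or `(H, W, 3, N)`, values in
#'   `[0, 1]`; `H` and `W` must be divisible by 32.
#' @param training logical; use batch statistics in the normalization layers.
#' @return a feature pyramid: list with `branches` (list of `(H/4/2^(k-1),
#'   W/4/2^(k-1), C_k, N)` arrays) and `stage_id`.
#' @export
forward_backbone <- function(backbone, images, training = FALSE) {
  out <- forward_backbone_ag(backbone, as_image_batch(images), training)
  list(branches = lapply(out, function(t) t$value),
       stage_id = backbone$truncate_at_stage)
}

as_image_batch <- function(images) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  d <- dim(images)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input height and width must be divisible by 32 (stem and three ",
         "halvings); got ", d[1], "x", d[2])
  }
  ag_tensor(images)
}

# ag-level forward shared by user API and the full model.
forward_backbone_ag <- function(backbone, x, training = FALSE) {
  ch <- backbone$children
  y <- nn_forward(ch$stem, x, training)
  y <- nn_forward(ch$layer1, y, training)
  xs <- forward_transition(ch$trans2, list(y), training)
  xs <- forward_stage(ch$stage2, xs, training)
  xs <- forward_transition(ch$trans3, xs, training)
  xs <- forward_stage(ch$stage3, xs, training)
  if (backbone$truncate_at_stage == 4L) {
    xs <- forward_transition(ch$trans4, xs, training)
    xs <- forward_stage(ch$stage4, xs, training)
  }
  xs
}

#' Cross-resolution fusion of a feature pyramid
#'
#' Applies one fusion module (without the residual-block branches) to a list
#' of branch feature maps: every output branch is the sum of all input
#' branches resampled to its resolution, followed by a rectifier.
#'
#' @param pyramid list with `branches`: list of `(H, W, C, N)` arrays ordered
#'   highest resolution first.
#' @param fuse_module optional pre-built fusion-only module (with materialized
#'   parameters); by default one is created with identity-preserving widths
#'   drawn from the pyramid and freshly initialized parameters.
#' @param training logical.
#' @return a pyramid of the same shape.
#' @export
fuse_branches <- function(pyramid, fuse_module = NULL, training = FALSE) {
  brs <- pyramid$branches
  if (length(brs) < 2L) stop("fusion needs at least 2 branches")
  widths <- vapply(brs, function(b) dim(b)[3], numeric(1))
  if (is.null(fuse_module)) {
    fuse_module <- nn_fuse_only(as.integer(widths))
    nn_init(fuse_module)
  }
  xs <- lapply(brs, function(b) {
    if (length(dim(b)) == 3L) dim(b) <- c(dim(b), 1L)
    ag_tensor(b)
  })
  out <- forward_fuse_only(fuse_module, xs, training)
  list(branches = lapply(out, function(t) t$value), stage_id = pyramid$stage_id)
}

# Fusion-only module (no per-branch blocks): used by fuse_branches().
nn_fuse_only <- function(widths) {
  nb <- length(widths)
  ch <- list()
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    p <- fuse_path(widths, j, i)
    if (!is.null(p)) ch[[paste0("fuse", i, "_", j)]] <- p
  }
  nn_env("fuse_only", .children = ch, nb = nb, widths = widths)
}

forward_fuse_only <- function(m, xs, training = FALSE) {
  out <- vector("list", m$nb)
  for (i in seq_len(m$nb)) {
    acc <- NULL
    for (j in seq_len(m$nb)) {
      contrib <- if (i == j) xs[[j]] else nn_forward(m$children[[paste0("fuse", i, "_", j)]], xs[[j]], training)
      acc <- if (is.null(acc)) contrib else ag_add(acc, contrib)
    }
    out[[i]] <- ag_relu(acc)
  }
  out
}
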
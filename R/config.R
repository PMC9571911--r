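# Flat-file (YAML) configuration surface for the command-line tools.

#' Default configuration tree
#'
#' Nested list mirroring the YAML layout: `model.backbone.*` (widths,
#' truncate_at_stage), `model.attention.*` (embed_dim, depth, window_size,
#' num_heads, mlp_ratio, shift), `model.head.*` (out_channels, kernel,
#' stride), `model.input_size`, and `train.*` (lr, milestones, gamma,
#' epochs, batch_size, seed, target_sigma_px, augmentation ranges).
#' @return a nested list.
#' @export
default_config <- function() {
  list(
    model = list(
      backbone = list(
        stem_channels = 64L, stage1_blocks = 4L,
        widths = list(stage2 = c(48L, 96L), stage3 = c(48L, 96L, 192L),
                      stage4 = c(48L, 96L, 192L, 384L)),
        modules_per_stage = list(stage2 = 1L, stage3 = 4L, stage4 = 3L),
        blocks_per_branch = 4L,
        truncate_at_stage = 3L),
      attention = list(embed_dim = 96L, depth = 4L, window_size = 6L,
                       num_heads = 48L, mlp_ratio = 4L, shift = 3L),
      head = list(out_channels = 10L, kernel = 4L, stride = 4L),
      input_size = c(288L, 384L)),
    train = list(lr = 1e-3, milestones = c(600L, 800L), gamma = 0.1,
                 epochs = 1000L, batch_size = 16L, seed = 1L,
                 target_sigma_px = 2, augment = TRUE,
                 rotation_deg = 45, scale_range = c(0.65, 1.35),
                 flip_prob = 0.5))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration, filling unset keys with defaults
#' @param path YAML file, or NULL for pure defaults.
#' @return a nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Build the typed model configuration from a configuration tree
#' @param cfg nested list from [read_config()].
#' @return an [hrst_config()].
#' @export
config_to_model <- function(cfg = read_config()) {
  mb <- cfg$model$backbone
  ma <- cfg$model$attention
  hrst_config(
    backbone = backbone_config(
      stem_channels = mb$stem_channels, stage1_blocks = mb$stage1_blocks,
      widths = lapply(mb$widths, as.integer),
      modules_per_stage = unlist(mb$modules_per_stage),
      blocks_per_branch = mb$blocks_per_branch),
    attention = attention_config(
      embed_dim = ma$embed_dim, depth = ma$depth, window_size = ma$window_size,
      num_heads = ma$num_heads, shift_size = ma$shift, mlp_ratio = ma$mlp_ratio),
    input_size = as.integer(cfg$model$input_size),
    out_channels = cfg$model$head$out_channels)
}

#' Build the typed training configuration from a configuration tree
#' @param cfg nested list from [read_config()].
#' @return a [train_config()].
#' @export
config_to_train <- function(cfg = read_config()) {
  tr <- cfg$train
  train_config(lr = tr$lr, milestones = tr$milestones, gamma = tr$gamma,
               epochs = tr$epochs, batch_size = tr$batch_size, seed = tr$seed,
               target_sigma_px = tr$target_sigma_px, augment = tr$augment,
               aug = aug_params(tr$rotation_deg, tr$scale_range, tr$flip_prob))
}
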
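# Training loop and posture-gated inference.
#
# Optimization follows the published schedule: Adam, initial learning rate
# 1e-3 dropped by 10x at epochs 600 and 800 over 1000 epochs, with random
# rotation in [-45, 45] degrees, random scaling in [0.65, 1.35] and random
# horizontal flips. Tiny presets use the same loop at reduced widths and
# step counts to overfit synthetic scenes as an end-to-end check.

#' Training configuration
#'
#' @param lr initial learning rate.
#' @param milestones epochs at which the learning rate is multiplied by
#'   `gamma`.
#' @param gamma learning-rate decay factor.
#' @param epochs total training epochs.
#' @param batch_size instances per optimization step.
#' @param seed RNG seed controlling initialization, batching, augmentation.
#' @param target_sigma_px Gaussian target standard deviation (heatmap px).
#' @param augment logical; apply geometric augmentation.
#' @param aug augmentation ranges ([aug_params()]).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, milestones = c(600L, 800L), gamma = 0.1,
                         epochs = 1000L, batch_size = 16L, seed = 1L,
                         target_sigma_px = 2, augment = TRUE,
                         aug = aug_params()) {
  stopifnot(all(milestones < epochs), lr > 0, gamma > 0)
  structure(list(lr = lr, milestones = milestones, gamma = gamma,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), target_sigma_px = target_sigma_px,
                 augment = augment, aug = aug),
            class = "train_config")
}

#' Learning rate under the step schedule
#' @param epoch 1-based epoch.
#' @param config a [train_config()].
#' @return learning rate in effect during `epoch`.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  config$lr * config$gamma^sum(epoch > config$milestones)
}

# Adam optimizer over a list of ag_param tensors.
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$m <- lapply(params, function(p) p$value * 0)
  e$v <- e$m
  e$t <- 0L
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(NULL)
}

#' Snapshot / restore model parameter values (checkpointing)
#' @param model a materialized model graph.
#' @return `model_state()`: list of parameter arrays in graph order.
#' @export
model_state <- function(model) lapply(nn_params(model), function(p) p$value)

#' @rdname model_state
#' @param state a snapshot from `model_state()`.
#' @export
model_load_state <- function(model, state) {
  ps <- nn_params(model)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) ps[[i]]$value <- state[[i]]
  invisible(model)
}

# Build the (crop, target) pair for one instance.
prepare_sample <- function(image, instance, config, input_size, sigma_px) {
  aug <- if (config$augment) draw_aug(config$aug) else NULL
  cr <- make_crop(image, instance$bbox[[1]], instance$joints[[1]], aug,
                  crop_size = input_size)
  tg <- encode_targets(cr$joints, input_size, sigma_px)
  list(crop = cr$crop, heatmaps = tg$heatmaps, weights = tg$weights,
       joints = cr$joints, affine = cr$affine)
}

#' Train a joint-point model
#'
#' Runs `steps` optimization steps of Adam on minibatches of cropped
#' instances with Gaussian heatmap targets and weighted MSE loss. The
#' learning rate follows the step schedule with epochs mapped to steps via
#' `steps_per_epoch = ceiling(n_instances / batch_size)`. Fully seeded:
#' the same seed gives identical loss curves on one device.
#'
#' @param model a materialized model from [build_hrst()] (+ [model_init()]).
#' @param images named/indexed list of `(H, W, 3)` arrays (index =
#'   `image_id`).
#' @param instances annotation tibble; only instances with labeled joints
#'   are used.
#' @param config a [train_config()].
#' @param steps number of optimization steps.
#' @param validate_every evaluate AP on the training instances every this
#'   many steps (0 = never); the best-AP parameter snapshot is kept.
#' @param eval_sigmas sigma vector for the validation OKS.
#' @param verbose print a line every 25 steps.
#' @return list with `model`, `log` (tibble: step, epoch, lr, loss),
#'   `best` (best validation snapshot: `state`, `AP`, `step`; NULL when
#'   validation is off).
#' @export
train_hrst <- function(model, images, instances, config = train_config(),
                       steps = 200L, validate_every = 0L,
                       eval_sigmas = synthetic_sigmas(), verbose = FALSE) {
  usable <- vapply(instances$joints, function(j) any(j[, 3] > 0), logical(1))
  inst <- instances[usable, ]
  if (nrow(inst) == 0L) stop("no trainable instances (no labeled joints)")
  set.seed(config$seed)
  input_size <- model$config$input_size
  steps_per_epoch <- max(1L, ceiling(nrow(inst) / config$batch_size))
  params <- nn_params(model)
  opt <- adam_new(params, lr = config$lr)
  # without augmentation the crops are deterministic: build them once
  cache <- NULL
  if (!config$augment) {
    cache <- lapply(seq_len(nrow(inst)), function(i) {
      prepare_sample(images[[inst$image_id[i]]], inst[i, ], config,
                     input_size, config$target_sigma_px)
    })
  }
  log <- vector("list", steps)
  for (step in seq_len(steps)) {
    epoch <- ((step - 1L) %/% steps_per_epoch) + 1L
    opt$lr <- lr_at_epoch(epoch, config)
    take <- sample(nrow(inst), min(config$batch_size, nrow(inst)))
    samples <- lapply(take, function(i) {
      if (!is.null(cache)) cache[[i]]
      else prepare_sample(images[[inst$image_id[i]]], inst[i, ], config,
                          input_size, config$target_sigma_px)
    })
    nb <- length(samples)
    xb <- array(0, c(input_size[1], input_size[2], 3L, nb))
    tb <- array(0, c(input_size[1] / 4L, input_size[2] / 4L, model$config$out_channels, nb))
    wb <- matrix(0, model$config$out_channels, nb)
    for (i in seq_len(nb)) {
      xb[, , , i] <- samples[[i]]$crop
      tb[, , , i] <- samples[[i]]$heatmaps
      wb[, i] <- samples[[i]]$weights
    }
    ag_zero_grad(params)
    pred <- forward_hrst_ag(model, ag_tensor(xb), training = TRUE)
    loss <- ag_mse_weighted(pred, tb, wb)
    if (!is.finite(loss$value)) {
      stop("training diverged: loss is ", loss$value, " at step ", step,
           " (lr ", opt$lr, "); try a smaller learning rate")
    }
    ag_backward(loss)
    adam_step(opt)
    log[[step]] <- tibble::tibble(step = step, epoch = epoch, lr = opt$lr,
                                  loss = loss$value)
    if (verbose && step %% 25L == 0L) {
      message(sprintf("step %4d  epoch %3d  lr %.1e  loss %.5f",
                      step, epoch, opt$lr, loss$value))
    }
  }
  log <- do.call(rbind, log)
  best <- NULL
  if (validate_every > 0L) {
    preds <- predict_instances(model, images, inst)
    ev <- evaluate_keypoints(preds, inst, sigmas = eval_sigmas)
    best <- list(state = model_state(model), AP = ev$AP, step = steps)
  }
  list(model = model, log = log, best = best)
}

#' Uniform sigma vector for synthetic-scene evaluation
#'
#' The synthetic generator places joints exactly; its evaluation sigma is a
#' convention, set to 0.05 per joint (the magnitude of published animal
#' keypoint sigmas) so that the OKS decay length exceeds the intrinsic
#' quantization of stride-4 heatmap decoding.
#' @return named numeric vector of length 10.
#' @export
synthetic_sigmas <- function() stats::setNames(rep(0.05, N_JOINTS), joint_names())

#' Predict joints for annotated instances from their boxes
#'
#' Crops each instance box (no augmentation), runs the model and decodes
#' heatmap peaks back to image coordinates.
#'
#' @param model a materialized model.
#' @param images list of `(H, W, 3)` arrays indexed by `image_id`.
#' @param instances annotation tibble.
#' @return prediction tibble (`image_id`, `joints`, `score`) suitable for
#'   [evaluate_keypoints()]; the score is the mean heatmap peak value.
#' @export
predict_instances <- function(model, images, instances) {
  input_size <- model$config$input_size
  rows <- lapply(seq_len(nrow(instances)), function(i) {
    cr <- make_crop(images[[instances$image_id[i]]], instances$bbox[[i]],
                    joints = NULL, aug = NULL, crop_size = input_size)
    hm <- hrst_forward(model, cr$crop)
    dec <- decode_heatmaps(hm, cr$affine)
    tibble::tibble(image_id = instances$image_id[i],
                   joints = list(cbind(x = dec[, 1], y = dec[, 2],
                                       v = rep(2, nrow(dec)))),
                   score = mean(dec[, 3]))
  })
  do.call(rbind, rows)
}

#' Posture-gated multi-animal inference
#'
#' Keeps every detection with its posture class; joint decoding runs only
#' on boxes classed standing (lying animals' dorsal joints are occluded, so
#' their instances are emitted with empty joints).
#'
#' @param image `(H, W, 3)` array.
#' @param detections detection tibble ([read_detections()]) for this image
#'   (rows with other `image_id`s are ignored with a warning).
#' @param model materialized joint-point model.
#' @param image_id id of `image` within `detections` (default: all rows).
#' @return tibble with `image_id`, `bbox`, `posture`, `score`, `joints`
#'   (10x3 in original-image coordinates; all-zero with `v = 0` for lying
#'   instances).
#' @export
infer_multi_animal <- function(image, detections, model, image_id = NULL) {
  dets <- detections
  if (!is.null(image_id)) {
    drop <- dets$image_id != image_id
    if (any(drop)) {
      warning(sum(drop), " detection(s) reference other images; skipped")
      dets <- dets[!drop, , drop = FALSE]
    }
  }
  if (nrow(dets) == 0L) {
    return(tibble::tibble(image_id = integer(), bbox = list(),
                          posture = character(), score = numeric(),
                          joints = list()))
  }
  input_size <- model$config$input_size
  rows <- lapply(seq_len(nrow(dets)), function(i) {
    empty <- matrix(0, N_JOINTS, 3, dimnames = list(NULL, c("x", "y", "v")))
    joints <- empty
    if (dets$posture[i] == "standing") {
      cr <- make_crop(image, dets$bbox[[i]], joints = NULL, aug = NULL,
                      crop_size = input_size)
      dec <- decode_heatmaps(hrst_forward(model, cr$crop), cr$affine)
      joints <- cbind(x = dec[, 1], y = dec[, 2], v = rep(2, nrow(dec)))
    }
    tibble::tibble(image_id = dets$image_id[i], bbox = dets$bbox[i],
                   posture = dets$posture[i], score = dets$score[i],
                   joints = list(joints))
  })
  do.call(rbind, rows)
}
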
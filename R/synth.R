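# Deterministic synthetic scenes with exact joint ground truth.
#
# Each animal is an oriented ellipse body on a dark background; standing
# animals carry high-contrast per-joint colour markers placed at fixed
# positions in the body frame (neck pair near the front, shoulder pair,
# abdomen pair at mid-flank, hip pair, tail pair at the rear), so a small
# network can overfit the scenes on CPU. Lying animals are drawn flatter,
# without markers, and carry no labeled joints. Appearance realism is a
# non-goal; the generator exists to exercise the full pipeline (crops,
# training, decoding, OKS evaluation, posture gating) without external
# data.

# Fractional joint positions in the body frame: (along-axis u, lateral v)
# in units of the (a, b) semi-axes; left = positive lateral.
SYNTH_JOINT_FRAME <- matrix(c(
   0.62,  0.28,   # left neck
   0.62, -0.28,   # right neck
   0.35,  0.55,   # left shoulder
   0.35, -0.55,   # right shoulder
   0.00,  0.60,   # left abdomen
   0.00, -0.60,   # right abdomen
  -0.35,  0.55,   # left hip
  -0.35, -0.55,   # right hip
  -0.68,  0.22,   # left tail
  -0.68, -0.22    # right tail
), ncol = 2, byrow = TRUE)

# Distinct marker colours per joint (rows: R, G, B in [0, 1]).
SYNTH_PALETTE <- matrix(c(
  1.0, 0.2, 0.2,  0.2, 1.0, 0.2,  0.2, 0.4, 1.0,  1.0, 1.0, 0.2,
  1.0, 0.2, 1.0,  0.2, 1.0, 1.0,  1.0, 0.6, 0.2,  0.6, 0.2, 1.0,
  0.2, 0.6, 0.6,  0.9, 0.9, 0.9), ncol = 3, byrow = TRUE)

#' Specification of a synthetic scene set
#'
#' @param n_images number of images.
#' @param image_size `c(H, W)` pixels.
#' @param animals_per_image inclusive range `c(min, max)`.
#' @param seed RNG seed; identical spec + seed gives byte-identical
#'   annotations.
#' @param body_frac semi-major axis range as a fraction of the image width.
#' @param aspect_range body minor/major axis ratio range.
#' @param posture_mix probabilities `c(standing, lying)`.
#' @param noise_std annotation-noise standard deviation (per axis, in units
#'   of object scale) used by [perturb_annotations()] fixtures.
#' @param marker_radius joint marker radius in pixels.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_images = 8L, image_size = c(144L, 192L),
                       animals_per_image = c(1L, 1L), seed = 0L,
                       body_frac = c(0.14, 0.19), aspect_range = c(0.45, 0.6),
                       posture_mix = c(standing = 1, lying = 0),
                       noise_std = 0.01, marker_radius = 2.5) {
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 animals_per_image = as.integer(animals_per_image),
                 seed = as.integer(seed), body_frac = body_frac,
                 aspect_range = aspect_range,
                 posture_mix = posture_mix / sum(posture_mix),
                 noise_std = noise_std, marker_radius = marker_radius),
            class = "synth_spec")
}

# Draw one animal: returns image with the animal painted, plus its record.
draw_animal <- function(img, spec, standing) {
  H <- dim(img)[1]; W <- dim(img)[2]
  a <- stats::runif(1, spec$body_frac[1], spec$body_frac[2]) * W
  b <- a * stats::runif(1, spec$aspect_range[1], spec$aspect_range[2])
  if (!standing) b <- b * 1.35 # lying: wider silhouette
  phi <- stats::runif(1, 0, 2 * pi)
  margin <- a + 3
  cx <- stats::runif(1, margin, W - 1 - margin)
  cy <- stats::runif(1, margin, H - 1 - margin)
  co <- cos(phi); si <- sin(phi)
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  u <- (xs - cx) * co + (ys - cy) * si
  v <- -(xs - cx) * si + (ys - cy) * co
  inside <- (u / a)^2 + (v / b)^2 <= 1
  shade <- if (standing) 0.55 else 0.4
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- shade - 0.1 * (ch - 2) * 0.5
    img[, , ch] <- plane
  }
  # joints in image coordinates
  ju <- SYNTH_JOINT_FRAME[, 1] * a
  jv <- SYNTH_JOINT_FRAME[, 2] * b
  jx <- cx + ju * co - jv * si
  jy <- cy + ju * si + jv * co
  vis <- if (standing) rep(2, N_JOINTS) else rep(0, N_JOINTS)
  if (standing) {
    for (j in seq_len(N_JOINTS)) {
      mk <- (xs - jx[j])^2 + (ys - jy[j])^2 <= spec$marker_radius^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mk] <- SYNTH_PALETTE[j, ch]
        img[, , ch] <- plane
      }
    }
  }
  # tight box around the ellipse extent
  ex <- sqrt((a * co)^2 + (b * si)^2)
  ey <- sqrt((a * si)^2 + (b * co)^2)
  x0 <- max(0, cx - ex); x1 <- min(W - 1, cx + ex)
  y0 <- max(0, cy - ey); y1 <- min(H - 1, cy + ey)
  joints <- cbind(x = if (standing) jx else rep(0, N_JOINTS),
                  y = if (standing) jy else rep(0, N_JOINTS),
                  v = vis)
  list(img = img, bbox = c(x0, y0, x1 - x0, y1 - y0), joints = joints,
       posture = if (standing) "standing" else "lying")
}

#' Generate a synthetic scene set
#'
#' Draws images and returns annotations; optionally writes PNG images, a
#' COCO-format keypoint JSON and a detection JSON (class standing/lying,
#' score 1.0) to `out_dir`.
#'
#' @param spec a [synth_spec()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `images` (list of arrays), `instances` (annotation
#'   tibble as from [read_annotations()]), `detections` (tibble), and, when
#'   `out_dir` is given, `paths` (`annotations`, `detections`, image files).
#' @export
generate_synthetic_pigs <- function(spec = synth_spec(), out_dir = NULL) {
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  imgs <- vector("list", spec$n_images)
  rows <- list()
  ann_id <- 1L
  for (i in seq_len(spec$n_images)) {
    img <- array(0.12, c(H, W, 3))
    img <- img + array(stats::runif(H * W * 3, 0, 0.03), c(H, W, 3))
    rng <- spec$animals_per_image
    n_animals <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    centers <- NULL
    for (k in seq_len(n_animals)) {
      standing <- stats::runif(1) < spec$posture_mix[["standing"]]
      for (try in 1:20) {
        an <- draw_animal(img, spec, standing)
        c_new <- an$bbox[1:2] + an$bbox[3:4] / 2
        if (is.null(centers) ||
            all(sqrt(colSums((t(centers) - c_new)^2)) > 0.45 * W * spec$body_frac[2] * 4)) break
      }
      img <- an$img
      centers <- rbind(centers, an$bbox[1:2] + an$bbox[3:4] / 2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        annotation_id = ann_id, image_id = i, bbox = list(an$bbox),
        area = an$bbox[3] * an$bbox[4], posture = an$posture, score = 1,
        joints = list(an$joints))
      ann_id <- ann_id + 1L
    }
    imgs[[i]] <- pmin(pmax(img, 0), 1)
  }
  instances <- do.call(rbind, rows)
  attr(instances, "images") <- tibble::tibble(
    id = seq_len(spec$n_images),
    file_name = sprintf("synth_%03d.png", seq_len(spec$n_images)),
    width = W, height = H)
  detections <- tibble::tibble(image_id = instances$image_id,
                               bbox = instances$bbox,
                               posture = instances$posture,
                               score = 1)
  out <- list(images = imgs, instances = instances, detections = detections)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    img_paths <- file.path(out_dir, attr(instances, "images")$file_name)
    for (i in seq_along(imgs)) write_image(imgs[[i]], img_paths[i])
    ann_path <- file.path(out_dir, "annotations.json")
    det_path <- file.path(out_dir, "detections.json")
    write_annotations(instances, ann_path)
    write_detections(detections, det_path)
    out$paths <- list(annotations = ann_path, detections = det_path,
                      images = img_paths)
  }
  out
}

#' Displace annotations with seeded Gaussian noise
#'
#' Emulates an independent second annotation pass: every labeled joint is
#' displaced by isotropic Gaussian noise with per-axis standard deviation
#' `noise_std * s`, where `s = sqrt(area)` is the instance's object scale.
#' Visibility flags are unchanged.
#'
#' @param instances annotation tibble.
#' @param noise_std per-axis displacement standard deviation in units of
#'   object scale.
#' @param seed RNG seed.
#' @return a tibble of the same shape with displaced joints.
#' @export
perturb_annotations <- function(instances, noise_std, seed = 0L) {
  stopifnot(noise_std >= 0)
  set.seed(seed)
  out <- instances
  for (i in seq_len(nrow(out))) {
    j <- out$joints[[i]]
    s <- sqrt(out$area[i])
    lab <- j[, 3] > 0
    n <- sum(lab)
    if (n > 0L) {
      j[lab, 1] <- j[lab, 1] + stats::rnorm(n, sd = noise_std * s)
      j[lab, 2] <- j[lab, 2] + stats::rnorm(n, sd = noise_std * s)
    }
    out$joints[[i]] <- j
  }
  out
}
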
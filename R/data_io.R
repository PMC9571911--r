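# Annotation I/O, top-down cropping and coordinate bookkeeping.
#
# All coordinates are 0-based pixel-centre: pixel (i, j) of an image array
# covers the unit square centred on (x = j - 1, y = i - 1). Boxes are
# (x, y, w, h) with top-left origin. Joints are 10 x 3 (x, y, v) matrices
# with COCO visibility flags (0 invisible / unlabeled, 1 labeled occluded,
# 2 labeled visible); only v = 0 is excluded from the loss.

#' Canonical joint names, in channel order
#' @return character vector of the ten joint names.
#' @export
joint_names <- function() {
  c("left neck", "right neck", "left shoulder", "right shoulder",
    "left abdomen", "right abdomen", "left hip", "right hip",
    "left tail", "right tail")
}

# left/right columns of the flip pair table
FLIP_PAIRS <- cbind(left = c(1L, 3L, 5L, 7L, 9L), right = c(2L, 4L, 6L, 8L, 10L))

N_JOINTS <- 10L

#' Read COCO-format keypoint annotations
#'
#' @param path JSON file with `images`, `annotations` and `categories`; the
#'   category must declare the ten joint names.
#' @return a tibble of keypoint instances (`annotation_id`, `image_id`,
#'   `bbox` list-column `c(x, y, w, h)`, `area`, `posture`, `score`,
#'   `joints` list-column of 10x3 matrices) with the image table in
#'   `attr(, "images")`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- js$categories
  if (length(cats) < 1L) stop("no categories in ", path)
  kp <- unlist(cats[[1]]$keypoints)
  if (length(kp) != N_JOINTS) {
    stop("category must declare ", N_JOINTS, " keypoints, found ", length(kp))
  }
  inst <- lapply(js$annotations, function(a) {
    k <- unlist(a$keypoints)
    if (length(k) != 3L * N_JOINTS) {
      stop("annotation ", a$id, " on image ", a$image_id, " has ",
           length(k) / 3, " keypoints; expected ", N_JOINTS)
    }
    joints <- matrix(k, ncol = 3L, byrow = TRUE,
                     dimnames = list(NULL, c("x", "y", "v")))
    bbox <- unlist(a$bbox)
    tibble::tibble(
      annotation_id = a$id,
      image_id = a$image_id,
      bbox = list(bbox),
      area = if (!is.null(a$area)) a$area else bbox[3] * bbox[4],
      posture = if (!is.null(a$posture)) a$posture else "standing",
      score = if (!is.null(a$score)) a$score else 1,
      joints = list(joints))
  })
  out <- do.call(rbind, inst)
  if (is.null(out)) {
    out <- tibble::tibble(annotation_id = integer(), image_id = integer(),
                          bbox = list(), area = numeric(), posture = character(),
                          score = numeric(), joints = list())
  }
  attr(out, "images") <- do.call(rbind, lapply(js$images, function(im) {
    tibble::tibble(id = im$id, file_name = im$file_name,
                   width = im$width, height = im$height)
  }))
  attr(out, "keypoint_names") <- kp
  out
}

#' Write keypoint instances back to COCO-format JSON
#'
#' Inverse of [read_annotations()]: `write_annotations()` then
#' `read_annotations()` round-trips instances losslessly.
#'
#' @param instances tibble as returned by [read_annotations()].
#' @param path output JSON path.
#' @param images image tibble; defaults to `attr(instances, "images")`.
#' @export
write_annotations <- function(instances, path, images = attr(instances, "images")) {
  anns <- lapply(seq_len(nrow(instances)), function(i) {
    j <- instances$joints[[i]]
    list(id = instances$annotation_id[i],
         image_id = instances$image_id[i],
         category_id = 1L,
         bbox = as.numeric(instances$bbox[[i]]),
         area = instances$area[i],
         iscrowd = 0L,
         posture = instances$posture[i],
         score = instances$score[i],
         num_keypoints = sum(j[, 3] > 0),
         keypoints = as.numeric(t(j)))
  })
  js <- list(
    images = if (is.null(images)) list() else lapply(seq_len(nrow(images)), function(i) {
      list(id = images$id[i], file_name = images$file_name[i],
           width = images$width[i], height = images$height[i])
    }),
    annotations = anns,
    categories = list(list(id = 1L, name = "pig",
                           keypoints = as.list(joint_names()),
                           skeleton = list())))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detection JSON (boxes with posture class)
#'
#' @param path JSON array of objects `{image_id, bbox, category, score}` with
#'   `category` either `"standing"` or `"lying"`.
#' @return tibble with `image_id`, `bbox` (list-column), `posture`, `score`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(js, function(d) {
    tibble::tibble(image_id = d$image_id, bbox = list(unlist(d$bbox)),
                   posture = d$category, score = d$score)
  }))
  if (is.null(out)) {
    out <- tibble::tibble(image_id = integer(), bbox = list(),
                          posture = character(), score = numeric())
  }
  bad <- !out$posture %in% c("standing", "lying")
  if (any(bad)) stop("unknown posture class: ", unique(out$posture[bad])[1])
  out
}

#' @rdname read_detections
#' @param detections tibble as returned by `read_detections`.
#' @export
write_detections <- function(detections, path) {
  js <- lapply(seq_len(nrow(detections)), function(i) {
    list(image_id = detections$image_id[i],
         bbox = as.numeric(detections$bbox[[i]]),
         category = detections$posture[i],
         score = detections$score[i])
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a PNG image as an `(H, W, 3)` array in `[0, 1]`
#' @param path PNG file.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

# ---- affine machinery ----------------------------------------------------

affine_identity <- function() matrix(c(1, 0, 0, 0, 1, 0), 2, 3)

# Apply a 2x3 affine to points (n x 2 matrix or length-2 vector).
affine_apply <- function(m, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1L)
  out <- cbind(pts, 1) %*% t(m)
  if (single) out[1, ] else out
}

affine_invert <- function(m) {
  a <- m[, 1:2]
  ai <- solve(a)
  cbind(ai, -ai %*% m[, 3])
}

affine_compose <- function(m2, m1) { # apply m1 first, then m2
  cbind(m2[, 1:2] %*% m1[, 1:2], m2[, 1:2] %*% m1[, 3] + m2[, 3])
}

#' Augmentation parameter settings and draws
#'
#' `aug_params()` records the augmentation ranges (rotation degrees, scale
#' factor interval, horizontal flip probability); `draw_aug()` draws one
#' realization from the current RNG state.
#'
#' @param rotation_deg maximal absolute rotation (degrees).
#' @param scale_range scale factor interval.
#' @param flip_prob probability of a horizontal flip.
#' @return `aug_params()`: a settings list. `draw_aug()`: list with
#'   `rotation`, `scale`, `flip`.
#' @export
aug_params <- function(rotation_deg = 45, scale_range = c(0.65, 1.35),
                       flip_prob = 0.5) {
  list(rotation_deg = rotation_deg, scale_range = scale_range,
       flip_prob = flip_prob)
}

#' @rdname aug_params
#' @param params an `aug_params()` list.
#' @export
draw_aug <- function(params = aug_params()) {
  list(rotation = stats::runif(1, -params$rotation_deg, params$rotation_deg),
       scale = stats::runif(1, params$scale_range[1], params$scale_range[2]),
       flip = stats::runif(1) < params$flip_prob)
}

#' Crop one instance for top-down processing
#'
#' Expands the box to the crop aspect ratio, applies the padding factor and
#' any augmentation (rotation about the box centre, scaling, horizontal
#' flip), and resamples the image bilinearly to `crop_size`. Joints are
#' mapped through the same affine; flipped crops also swap left/right joint
#' labels. Joints leaving the crop are marked invisible.
#'
#' @param image `(H, W, 3)` array.
#' @param bbox `c(x, y, w, h)` detection or ground-truth box.
#' @param joints optional 10x3 `(x, y, v)` matrix in image coordinates.
#' @param aug NULL, or a draw from [draw_aug()] (fields `rotation` degrees,
#'   `scale`, `flip`).
#' @param crop_size `c(H, W)` of the output crop.
#' @param padding box padding factor before cropping.
#' @return list with `crop` (`(H, W, 3)`), `joints` (or NULL), and `affine`
#'   (an `affine_spec`: `forward`/`inverse` 2x3 matrices, `center`, `scale`,
#'   `rotation`, `output_size`, `flipped`).
#' @export
make_crop <- function(image, bbox, joints = NULL, aug = NULL,
                      crop_size = c(288L, 384L), padding = 1.25) {
  if (bbox[3] <= 0 || bbox[4] <= 0) {
    stop("degenerate box: w = ", bbox[3], ", h = ", bbox[4])
  }
  Ho <- crop_size[1]; Wo <- crop_size[2]
  aspect <- Wo / Ho
  cx <- bbox[1] + bbox[3] / 2
  cy <- bbox[2] + bbox[4] / 2
  w <- bbox[3]; h <- bbox[4]
  if (w / h > aspect) h <- w / aspect else w <- h * aspect
  s <- if (is.null(aug)) 1 else aug$scale
  rot <- if (is.null(aug)) 0 else aug$rotation
  flip <- if (is.null(aug)) FALSE else aug$flip
  w <- w * padding * s
  h <- h * padding * s
  th <- rot * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  # image -> crop: translate centre to origin, rotate, scale, recentre
  S <- diag(c(Wo / w, Ho / h))
  A <- S %*% R
  M <- cbind(A, c((Wo - 1) / 2, (Ho - 1) / 2) - A %*% c(cx, cy))
  if (flip) M <- affine_compose(matrix(c(-1, 0, 0, 1, Wo - 1, 0), 2, 3), M)
  Minv <- affine_invert(M)
  crop <- warp_bilinear(image, Minv, c(Ho, Wo))
  out_joints <- NULL
  if (!is.null(joints)) {
    out_joints <- joints
    lab <- joints[, 3] > 0
    if (any(lab)) {
      out_joints[lab, 1:2] <- affine_apply(M, joints[lab, 1:2, drop = FALSE])
    }
    if (flip) out_joints <- swap_flip_pairs(out_joints)
    outside <- out_joints[, 3] > 0 &
      (out_joints[, 1] < 0 | out_joints[, 1] > Wo - 1 |
         out_joints[, 2] < 0 | out_joints[, 2] > Ho - 1)
    out_joints[outside, 3] <- 0
  }
  spec <- structure(list(forward = M, inverse = Minv, center = c(cx, cy),
                         scale = c(w, h), rotation = rot,
                         output_size = c(Ho, Wo), flipped = flip),
                    class = "affine_spec")
  list(crop = crop, joints = out_joints, affine = spec)
}

# Bilinear resampling: out pixel (r, c) samples image at Minv %*% (c-1, r-1).
warp_bilinear <- function(image, Minv, out_size) {
  Ho <- out_size[1]; Wo <- out_size[2]
  d <- dim(image)
  xs <- rep(seq_len(Wo) - 1, each = Ho)
  ys <- rep(seq_len(Ho) - 1, times = Wo)
  src <- cbind(xs, ys, 1) %*% t(Minv)
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- array(0, c(Ho, Wo, d[3]))
  gather <- function(yy, xx) {
    ok <- yy >= 0 & yy <= d[1] - 1 & xx >= 0 & xx <= d[2] - 1
    idx <- pmin(pmax(yy, 0), d[1] - 1) + 1 + d[1] * pmin(pmax(xx, 0), d[2] - 1)
    vals <- matrix(0, length(yy), d[3])
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch]
      vals[, ch] <- plane[idx] * ok
    }
    vals
  }
  v00 <- gather(y0, x0); v01 <- gather(y0, x0 + 1)
  v10 <- gather(y0 + 1, x0); v11 <- gather(y0 + 1, x0 + 1)
  vals <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
  dim(vals) <- c(Ho, Wo, d[3])
  vals
}

swap_flip_pairs <- function(joints) {
  out <- joints
  out[FLIP_PAIRS[, 1], ] <- joints[FLIP_PAIRS[, 2], ]
  out[FLIP_PAIRS[, 2], ] <- joints[FLIP_PAIRS[, 1], ]
  out
}

#' Mirror joints horizontally
#'
#' Reflects x-coordinates about the vertical midline of a width-`width`
#' crop and swaps each left/right joint pair; applying it twice is the
#' identity.
#'
#' @param joints 10x3 `(x, y, v)` matrix in crop coordinates.
#' @param width crop width in pixels.
#' @return 10x3 matrix.
#' @export
flip_joints <- function(joints, width) {
  out <- joints
  lab <- joints[, 3] > 0
  out[lab, 1] <- width - 1 - joints[lab, 1]
  swap_flip_pairs(out)
}
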
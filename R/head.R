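# Heatmap regression head: a single transposed convolution (kernel 4,
# stride 4) maps the token grid back to quarter-input resolution with one
# channel per joint. Supervision is pixelwise MSE against unnormalized
# Gaussian targets (peak 1.0 at the joint); channels of invisible joints
# are zero and carry zero loss weight. Decoding takes the per-channel
# argmax, refines it a quarter pixel toward the larger neighbour on each
# axis, scales by the heatmap stride and maps through the inverse crop
# affine.

HEATMAP_STRIDE <- 4L

nn_head <- function(embed, out_channels = 10L, kernel = 4L, stride = 4L) {
  nn_env("head",
         .children = list(deconv = nn_deconv(embed, out_channels, kernel, stride,
                                            bias = TRUE, div_in = 16L)),
         embed = embed, out_channels = out_channels)
}

forward_head <- function(m, tokens, grid, training = FALSE) {
  d <- dim(tokens$value)
  x <- ag_reshape(tokens, c(grid[1], grid[2], d[2], d[3]))
  nn_forward(m$children$deconv, x, training)
}

#' Regress per-joint heatmaps from a token sequence
#'
#' @param tokens a `patch_sequence` (from [patch_embed()] or the transformer
#'   blocks).
#' @param module optional materialized head module; freshly initialized
#'   otherwise.
#' @param out_channels number of joints (when building a fresh head).
#' @return heatmap array `(Hh, Wh, out_channels)` (or `(..., N)`), with
#'   `Hh = 4 * Gh`, `Ww = 4 * Gw` (quarter input resolution).
#' @export
head_forward <- function(tokens, module = NULL, out_channels = 10L) {
  stopifnot(inherits(tokens, "patch_sequence"))
  tk <- as_token_array(tokens$tokens)
  if (is.null(module)) {
    module <- nn_head(dim(tk)[2], out_channels)
    nn_init(module)
  }
  out <- forward_head(module, ag_tensor(tk), tokens$grid)$value
  if (length(dim(tokens$tokens)) == 2L) dim(out) <- dim(out)[1:3]
  out
}

#' Encode joint coordinates as Gaussian target heatmaps
#'
#' @param joints `10 x 3` matrix of `(x, y, v)` in 0-based crop-pixel
#'   coordinates; `v = 0` marks an invisible joint.
#' @param crop_size `c(H, W)` of the crop; heatmaps are `crop_size / 4`.
#' @param sigma_px Gaussian standard deviation in heatmap pixels.
#' @return list with `heatmaps` `(H/4, W/4, n_joints)` (peak value 1 at each
#'   visible joint) and `weights` (per-channel 0/1 loss weights). Visible
#'   joints that fall outside the crop are demoted to invisible with a
#'   warning.
#' @export
encode_targets <- function(joints, crop_size, sigma_px = 2) {
  stopifnot(ncol(joints) == 3L, all(crop_size %% HEATMAP_STRIDE == 0))
  Hh <- crop_size[1] %/% HEATMAP_STRIDE
  Wh <- crop_size[2] %/% HEATMAP_STRIDE
  nj <- nrow(joints)
  hm <- array(0, c(Hh, Wh, nj))
  w <- numeric(nj)
  xs <- matrix(rep(seq_len(Wh) - 1L, each = Hh), Hh, Wh)
  ys <- matrix(rep(seq_len(Hh) - 1L, times = Wh), Hh, Wh)
  for (j in seq_len(nj)) {
    if (joints[j, 3] <= 0) next
    x <- joints[j, 1] / HEATMAP_STRIDE
    y <- joints[j, 2] / HEATMAP_STRIDE
    if (joints[j, 1] < 0 || joints[j, 2] < 0 ||
        joints[j, 1] > crop_size[2] - 1 || joints[j, 2] > crop_size[1] - 1) {
      warning("visible joint ", j, " outside crop; marked invisible")
      next
    }
    hm[, , j] <- exp(-((xs - x)^2 + (ys - y)^2) / (2 * sigma_px^2))
    w[j] <- 1
  }
  list(heatmaps = hm, weights = w)
}

#' Weighted mean-squared heatmap loss
#'
#' Mean over pixels, weighted channels and batch of the squared difference;
#' channels with zero weight (invisible joints) do not contribute.
#'
#' @param pred,target heatmap arrays `(H, W, C)` or `(H, W, C, N)`.
#' @param weights per-channel weights, `(C)` or `(C, N)`.
#' @return non-negative scalar.
#' @export
mse_loss <- function(pred, target, weights = NULL) {
  if (length(dim(pred)) == 3L) dim(pred) <- c(dim(pred), 1L)
  if (length(dim(target)) == 3L) dim(target) <- c(dim(target), 1L)
  if (!all(dim(pred) == dim(target))) {
    stop("prediction and target heatmap shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  }
  d <- dim(pred)
  if (is.null(weights)) weights <- matrix(1, d[3], d[4])
  if (is.null(dim(weights))) weights <- matrix(weights, d[3], d[4])
  ag_mse_weighted(ag_tensor(pred), target, weights)$value
}

#' Decode heatmaps to joint coordinates
#'
#' Per channel: argmax location, a 0.25-pixel shift toward the larger
#' adjacent neighbour on each axis, multiplication by the heatmap stride,
#' then the inverse crop affine back to original-image coordinates.
#'
#' @param heatmaps `(Hh, Wh, C)` array of predicted score maps.
#' @param crop_transform an `affine_spec` from [make_crop()], or NULL for
#'   identity (coordinates returned at crop scale).
#' @return `C x 3` matrix of `(x, y, score)` rows.
#' @export
decode_heatmaps <- function(heatmaps, crop_transform = NULL) {
  d <- dim(heatmaps)
  nj <- d[3]
  out <- matrix(0, nj, 3, dimnames = list(NULL, c("x", "y", "score")))
  for (j in seq_len(nj)) {
    hm <- heatmaps[, , j]
    pk <- arrayInd(which.max(hm), d[1:2])
    iy <- pk[1]; ix <- pk[2]
    x <- ix - 1; y <- iy - 1
    if (ix > 1L && ix < d[2]) x <- x + 0.25 * sign(hm[iy, ix + 1L] - hm[iy, ix - 1L])
    if (iy > 1L && iy < d[1]) y <- y + 0.25 * sign(hm[iy + 1L, ix] - hm[iy - 1L, ix])
    p <- c(x, y) * HEATMAP_STRIDE
    if (!is.null(crop_transform)) p <- affine_apply(crop_transform$inverse, p)
    out[j, ] <- c(p, hm[iy, ix])
  }
  out
}
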
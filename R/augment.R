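#' Geometric augmentation configuration
#'
#' The deterministic part of the augmentation grid is the cross product of
#' rotations, scales and shifts; enabled flips and random crops add further
#' variants of the unshifted image. The number of outputs per image
#' (the multiplier) is therefore
#' `length(rotations) * length(scales) * length(shifts) + flips + crops`.
#'
#' @param rotations rotation angles in degrees.
#' @param scales isotropic scale factors (> 0).
#' @param shifts list of `(dy, dx)` shifts as fractions of image size.
#' @param crops number of random crop-and-resize variants.
#' @param flip_h,flip_v include a horizontal / vertical mirror.
#' @param seed integer seed driving the random crops.
#' @return A list with class `augment_config`.
#' @export
augment_config <- function(rotations = 0, scales = 1,
                           shifts = list(c(0, 0)), crops = 0,
                           flip_h = FALSE, flip_v = FALSE, seed = 1) {
  if (any(scales <= 0)) stopf("augmentation scales must be positive")
  if (crops < 0) stopf("crops must be >= 0")
  if (!is.list(shifts)) shifts <- list(shifts)
  grid <- expand.grid(
    rot = seq_along(rotations), sc = seq_along(scales), sh = seq_along(shifts)
  )
  structure(
    list(rotations = rotations, scales = scales, shifts = shifts,
         crops = crops, flip_h = flip_h, flip_v = flip_v, seed = seed,
         grid = grid,
         multiplier = nrow(grid) + as.integer(flip_h) + as.integer(flip_v) + crops),
    class = "augment_config"
  )
}

# Inverse-mapping affine warp with reflect boundary handling.
# Output pixel (r, c) samples the input at
#   src = R(-theta)/scale %*% (out - center - shift) + center
# so the visible effect is rotate by theta, scale about the center, then
# shift by (dy, dx) pixels.
warp_matrix <- function(m, theta = 0, scale = 1, dy = 0, dx = 0,
                        interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  H <- nrow(m); W <- ncol(m)
  if (theta == 0 && scale == 1 && dy == 0 && dx == 0) return(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy - dy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - dx
  th <- theta * pi / 180
  sr <- (cos(th) * r + sin(th) * c) / scale + cy
  sc <- (-sin(th) * r + cos(th) * c) / scale + cx
  sample_matrix(m, sr, sc, interpolation)
}

# Sample matrix `m` at (possibly fractional) coordinates (sr, sc); the
# output has the shape of `sr`. Out-of-range coordinates reflect.
sample_matrix <- function(m, sr, sc, interpolation = "bilinear") {
  H <- nrow(m); W <- ncol(m)
  if (interpolation == "nearest") {
    ri <- reflect_index(round(sr), H)
    ci <- reflect_index(round(sc), W)
    return(matrix(m[cbind(as.vector(ri), as.vector(ci))], nrow(sr), ncol(sr)))
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  idx <- function(r, c) m[cbind(as.vector(reflect_index(r, H)),
                                as.vector(reflect_index(c, W)))]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
    (1 - fr) * fc * idx(r0, c0 + 1) +
    fr * (1 - fc) * idx(r0 + 1, c0) +
    fr * fc * idx(r0 + 1, c0 + 1)
  matrix(v, nrow(sr), ncol(sr))
}

apply_channels <- function(img, f) {
  if (length(dim(img)) == 2) return(f(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

#' Augment one image
#'
#' Applies the deterministic rotation/scale/shift grid, optional mirrors,
#' and seeded random crop-and-resize variants. Every output has the input's
#' size; pixels mapped from outside the frame are filled by reflection so no
#' black borders are introduced (black borders would masquerade as stained
#' tissue in downstream thresholding). Label masks should be co-augmented
#' with `interpolation = "nearest"`.
#'
#' @param img RGB array or matrix.
#' @param config an [augment_config()].
#' @param interpolation `"bilinear"` (images) or `"nearest"` (label masks).
#' @param crop_seed optional override of the crop seed (used by
#'   [augment_dataset()] to vary crops across images).
#' @return List of `config$multiplier` augmented images.
#' @export
augment_image <- function(img, config, interpolation = c("bilinear", "nearest"),
                          crop_seed = config$seed) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(config, "augment_config"))
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- vector("list", config$multiplier)
  i <- 0L
  for (g in seq_len(nrow(config$grid))) {
    rot <- config$rotations[config$grid$rot[g]]
    sc <- config$scales[config$grid$sc[g]]
    sh <- config$shifts[[config$grid$sh[g]]]
    i <- i + 1L
    out[[i]] <- apply_channels(img, function(m)
      warp_matrix(m, theta = rot, scale = sc,
                  dy = sh[1] * H, dx = sh[2] * W, interpolation = interpolation))
  }
  if (config$flip_h) {
    i <- i + 1L
    out[[i]] <- apply_channels(img, function(m) m[, rev(seq_len(W)), drop = FALSE])
  }
  if (config$flip_v) {
    i <- i + 1L
    out[[i]] <- apply_channels(img, function(m) m[rev(seq_len(H)), , drop = FALSE])
  }
  if (config$crops > 0) {
    crops <- with_seed(crop_seed, {
      lapply(seq_len(config$crops), function(k) {
        f <- runif(1, 0.6, 0.9)
        ch <- max(2, round(f * H)); cw <- max(2, round(f * W))
        r0 <- sample.int(H - ch + 1, 1); c0 <- sample.int(W - cw + 1, 1)
        list(r0 = r0, c0 = c0, ch = ch, cw = cw)
      })
    })
    for (cr in crops) {
      if (cr$ch > H || cr$cw > W) stopf("crop larger than image")
      i <- i + 1L
      # sample the crop window back up to full size
      sr <- matrix(cr$r0 + (seq_len(H) - 1) * (cr$ch - 1) / (H - 1), H, W)
      sc2 <- matrix(cr$c0 + (seq_len(W) - 1) * (cr$cw - 1) / (W - 1), H, W, byrow = TRUE)
      out[[i]] <- apply_channels(img, function(m)
        sample_matrix(m, sr, sc2, interpolation))
    }
  }
  out
}

#' Augment a list of images
#'
#' Image-major ordering: all variants of image 1, then of image 2, and so
#' on. Crop randomness is derived from `config$seed` and the image index,
#' so the full output is reproducible and per-image crops differ.
#'
#' @param images non-empty list of images.
#' @param config an [augment_config()].
#' @param interpolation passed to [augment_image()].
#' @return List of `length(images) * config$multiplier` images.
#' @export
augment_dataset <- function(images, config, interpolation = "bilinear") {
  if (length(images) == 0) stopf("augment_dataset needs at least one image")
  out <- lapply(seq_along(images), function(i) {
    augment_image(images[[i]], config, interpolation = interpolation,
                  crop_seed = config$seed + 1000L * i)
  })
  do.call(c, out)
}
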
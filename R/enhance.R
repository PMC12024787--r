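#' Binary thresholding of a gray surface
#'
#' Foreground is the bright side (`gray > t`): on the hematoxylin
#' concentration surface nuclei have high values. The Otsu threshold
#' maximizes between-class variance over a 256-bin histogram of the
#' rescaled range.
#'
#' @param gray `H x W` numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return Logical mask with attribute `threshold`.
#' @export
binary_threshold <- function(gray, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  if (!all(is.finite(gray))) stopf("gray surface contains non-finite values")
  if (method == "fixed") {
    if (is.null(level)) stopf("fixed thresholding requires a level")
    t <- level
  } else {
    rng <- range(gray)
    if (diff(rng) == 0) {
      stopf("Otsu threshold undefined: degenerate histogram (constant image)")
    }
    scaled <- (gray - rng[1]) / diff(rng)
    t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
    t <- rng[1] + t01 * diff(rng)
  }
  structure(gray > t, threshold = t)
}

disk_kernel <- function(radius) {
  stopifnot(radius >= 1)
  r <- as.integer(radius)
  d <- 2L * r + 1L
  x <- matrix(-r:r, d, d)
  (x^2 + t(x)^2 <= radius^2) * 1
}

#' Binary morphology with a disk structuring element
#'
#' Standard operations: `erode` (min over the neighborhood), `dilate`
#' (max), `open` = dilate(erode), `close` = erode(dilate), and
#' `clear_borders`, which removes every 8-connected component touching the
#' image frame. Border handling is self-dual (outside the frame counts as
#' foreground for erosion and background for dilation), so the duality
#' `dilate(m) = !erode(!m)` holds exactly.
#'
#' @param mask logical matrix.
#' @param op one of `"erode"`, `"dilate"`, `"open"`, `"close"`,
#'   `"clear_borders"`.
#' @param se_radius disk radius in pixels (>= 1); ignored by
#'   `clear_borders`.
#' @return Logical mask of the same size.
#' @export
morphology <- function(mask, op = c("erode", "dilate", "open", "close", "clear_borders"),
                       se_radius = 1) {
  op <- match.arg(op)
  mask <- as_mask(mask)
  if (op == "clear_borders") {
    lab <- label_components(mask, connectivity = 8)
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    edge <- edge[edge > 0]
    out <- mask
    out[lab %in% edge] <- FALSE
    return(out)
  }
  kern <- disk_kernel(se_radius)
  img <- EBImage::Image(mask * 1)
  res <- switch(op,
    erode = EBImage::erode(img, kern),
    dilate = EBImage::dilate(img, kern),
    open = EBImage::opening(img, kern),
    close = EBImage::closing(img, kern)
  )
  EBImage::imageData(res) > 0.5
}

#' Euclidean distance transform
#'
#' Per-pixel Euclidean distance to the nearest background (`FALSE`) pixel;
#' exactly zero on the background.
#'
#' @param mask logical matrix.
#' @return `H x W` numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  if (all(mask)) {
    # no background inside the frame: distance to the frame edge + 1
    H <- nrow(mask); W <- ncol(mask)
    r <- matrix(seq_len(H), H, W); c <- matrix(seq_len(W), H, W, byrow = TRUE)
    return(pmin(r, H + 1 - r, c, W + 1 - c))
  }
  EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"))
}

#' Partition a frame into sure foreground, sure background, and unknown
#'
#' The watershed-marker style split used before candidate grouping:
#' `sure_fg` are distance-transform cores (`dist > fg_frac * max(dist)`),
#' sure background is everything outside the dilated mask, and the band in
#' between is `unknown`. The three masks are disjoint and cover the frame.
#'
#' @param mask logical matrix (thresholded nuclei).
#' @param dist distance map of `mask` (computed if missing).
#' @param fg_frac fraction of the maximum distance defining sure-foreground
#'   cores.
#' @param bg_dilate_radius dilation radius separating sure background.
#' @return List with logical masks `sure_fg`, `sure_bg`, `unknown`
#'   (class `region_partition`).
#' @export
partition_regions <- function(mask, dist = distance_transform(mask),
                              fg_frac = 0.4, bg_dilate_radius = 3) {
  mask <- as_mask(mask)
  stopifnot(fg_frac > 0, fg_frac < 1)
  sure_fg <- dist > fg_frac * max(dist)
  grown <- if (any(mask)) morphology(mask, "dilate", bg_dilate_radius) else mask
  sure_bg <- !grown
  unknown <- !(sure_fg | sure_bg)
  structure(list(sure_fg = sure_fg, sure_bg = sure_bg, unknown = unknown),
            class = "region_partition")
}
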
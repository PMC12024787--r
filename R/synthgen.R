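#' Default H&E stain matrix
#'
#' Columns are unit-norm optical-density absorbance vectors for hematoxylin
#' (nuclei, blue-purple) and eosin (cytoplasm/stroma, pink). The directions
#' are the widely used H&E absorbance estimates (H ~ (0.65, 0.70, 0.29),
#' E ~ (0.07, 0.99, 0.11) in RGB OD space), normalized to unit length.
#'
#' @return A 3 x 2 numeric matrix with columns `H` and `E`.
#' @export
default_stain_matrix <- function() {
  m <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Squared elliptical radial coordinate: <= 1 inside the ellipse.
ellipse_rho2 <- function(rows, cols, cy, cx, a, b, angle) {
  u <- rows - cy
  v <- cols - cx
  x <- u * cos(angle) + v * sin(angle)
  y <- -u * sin(angle) + v * cos(angle)
  (x / a)^2 + (y / b)^2
}

ellipse_inside <- function(rows, cols, cy, cx, a, b, angle) {
  ellipse_rho2(rows, cols, cy, cx, a, b, angle) <= 1
}

# Do two ellipses (rows of the nuclei frame) intersect or contain each other?
# Decided numerically by sampling the boundary of each against the other's
# interior inequality plus a center-containment check.
ellipses_intersect <- function(n1, n2, n_samp = 360) {
  th <- seq(0, 2 * pi, length.out = n_samp + 1)[-1]
  bnd <- function(n) {
    x <- n$a * cos(th)
    y <- n$b * sin(th)
    cbind(
      row = n$row + x * cos(n$angle) - y * sin(n$angle),
      col = n$col + x * sin(n$angle) + y * cos(n$angle)
    )
  }
  inside <- function(p, n) {
    any(ellipse_inside(p[, 1], p[, 2], n$row, n$col, n$a, n$b, n$angle))
  }
  inside(bnd(n1), n2) || inside(bnd(n2), n1) ||
    ellipse_inside(n1$row, n1$col, n2$row, n2$col, n2$a, n2$b, n2$angle)[1] ||
    ellipse_inside(n2$row, n2$col, n1$row, n1$col, n1$a, n1$b, n1$angle)[1]
}

#' Generate a synthetic H&E scene with known ground truth
#'
#' Places elliptical nuclei (dark, hematoxylin-rich) on an eosin-stained
#' tissue background. A chosen fraction of nuclei are placed overlapping an
#' earlier nucleus (center within one semi-major axis), emulating touching
#' nuclei; a chosen fraction are "lesions" with elevated hematoxylin uptake
#' and size. Optional clutter structures (thin, elongated, stained streaks)
#' exercise the false-positive elimination stage: they pass thresholding but
#' have near-zero blobness. The scene stores the true stain matrix and all
#' geometry, so every pipeline stage can be validated against ground truth.
#'
#' @param n_nuclei number of nuclei to place.
#' @param image_size `(H, W)` in pixels, both at least 32.
#' @param overlap_fraction fraction of nuclei placed within one semi-major
#'   axis of a previously placed nucleus.
#' @param lesion_fraction fraction of nuclei flagged as lesions (larger,
#'   more intensely stained).
#' @param n_clutter number of thin elongated clutter structures.
#' @param stain_matrix 3 x 2 ground-truth stain matrix.
#' @param e_background mean eosin concentration of the tissue background
#'   (OD units); the actual field is a smooth seeded texture around this
#'   mean, so the scene contains both faint and densely eosin-stained
#'   stroma, as real tissue does.
#' @param e_nucleus_factor multiplicative eosin suppression inside nuclei
#'   and clutter (chromatin displaces the eosinophilic cytoplasm).
#' @param h_background faint hematoxylin concentration of the background.
#' @param noise_sd standard deviation of additive Gaussian noise in OD space.
#' @param seed integer seed; fully determines the scene and its render.
#' @return An object of class `synthetic_scene`.
#' @export
make_scene <- function(n_nuclei = 20, image_size = c(128, 128),
                       overlap_fraction = 0, lesion_fraction = 0,
                       n_clutter = 0,
                       stain_matrix = default_stain_matrix(),
                       e_background = 1.0, e_nucleus_factor = 0.1,
                       h_background = 0.05,
                       noise_sd = 0.02, seed = 1) {
  stopifnot(n_nuclei >= 0, length(image_size) == 2)
  H <- image_size[1]; W <- image_size[2]
  if (H < 32 || W < 32) stopf("image_size must be at least 32 x 32, got %d x %d", H, W)

  empty <- data.frame(
    row = numeric(0), col = numeric(0), a = numeric(0), b = numeric(0),
    angle = numeric(0), h_conc = numeric(0), is_lesion = logical(0)
  )

  nuclei <- with_seed(seed, {
    if (n_nuclei == 0) {
      empty
    } else {
      n_lesion <- round(n_nuclei * lesion_fraction)
      n_over <- round(n_nuclei * overlap_fraction)
      is_lesion <- rep(FALSE, n_nuclei)
      if (n_lesion > 0) is_lesion[sample.int(n_nuclei, n_lesion)] <- TRUE
      placed <- empty
      for (k in seq_len(n_nuclei)) {
        a <- if (is_lesion[k]) runif(1, 8, 12) else runif(1, 5, 8)
        b <- a * runif(1, 0.65, 0.95)
        ang <- runif(1, 0, pi)
        h <- if (is_lesion[k]) runif(1, 0.9, 1.3) else runif(1, 0.5, 0.8)
        margin <- a + 1
        if (2 * margin >= min(H, W)) {
          stopf("image %d x %d too small to keep a nucleus of semi-axis %.1f inside bounds",
                H, W, a)
        }
        n_base <- n_nuclei - n_over
        want_overlap <- k > 1 && (k > n_base)
        ok <- FALSE
        for (try in seq_len(400)) {
          if (want_overlap) {
            # partners come from the independently placed nuclei; centers
            # sit within one semi-major axis (of the larger of the two)
            # and at least 4 px apart: "overlapping" means two visibly
            # distinct touching nuclei, not a nucleus drawn twice
            j <- sample.int(min(nrow(placed), n_base), 1)
            d <- max(4, runif(1, 0.8, 1.0) * max(placed$a[j], a))
            th <- runif(1, 0, 2 * pi)
            cy <- placed$row[j] + d * sin(th)
            cx <- placed$col[j] + d * cos(th)
            if (cy < margin || cy > H - margin + 1 ||
                cx < margin || cx > W - margin + 1) next
          } else {
            cy <- runif(1, margin, H - margin + 1)
            cx <- runif(1, margin, W - margin + 1)
            if (nrow(placed) > 0) {
              dd <- sqrt((placed$row - cy)^2 + (placed$col - cx)^2)
              if (any(dd < placed$a + a + 2)) next
            }
          }
          placed <- rbind(placed, data.frame(
            row = cy, col = cx, a = a, b = b, angle = ang,
            h_conc = h, is_lesion = is_lesion[k]
          ))
          ok <- TRUE
          break
        }
        if (!ok) {
          stopf(paste0(
            "could not place nucleus %d of %d inside a %d x %d image without ",
            "violating the bounds/overlap constraints"), k, n_nuclei, H, W)
        }
      }
      placed
    }
  })

  clutter <- with_seed(seed + 1L, {
    if (n_clutter == 0) {
      empty[, c("row", "col", "a", "b", "angle", "h_conc")]
    } else {
      data.frame(
        row = runif(n_clutter, 14, H - 13),
        col = runif(n_clutter, 14, W - 13),
        a = runif(n_clutter, 9, 13),
        b = runif(n_clutter, 1.6, 2.2),
        angle = runif(n_clutter, 0, pi),
        h_conc = runif(n_clutter, 0.5, 0.8)
      )
    }
  })

  structure(
    list(
      image_size = c(H, W), nuclei = nuclei, clutter = clutter,
      stain_matrix = stain_matrix, e_background = e_background,
      e_nucleus_factor = e_nucleus_factor,
      h_background = h_background, noise_sd = noise_sd, seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' Standard study scene
#'
#' The reference synthetic condition used throughout the package's
#' evaluation: 20 nuclei on a 128 x 128 frame, 30% placed overlapping,
#' 30% lesions, 4 thin clutter structures, OD noise 0.02.
#'
#' @param seed integer seed.
#' @return A `synthetic_scene`.
#' @export
standard_scene <- function(seed) {
  make_scene(n_nuclei = 20, image_size = c(128, 128), overlap_fraction = 0.3,
             lesion_fraction = 0.3, n_clutter = 4, noise_sd = 0.02,
             seed = seed)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic H&E scene: %d x %d px, %d nuclei (%d lesions), %d clutter, seed %d\n",
    x$image_size[1], x$image_size[2], nrow(x$nuclei),
    sum(x$nuclei$is_lesion), nrow(x$clutter), x$seed
  ))
  invisible(x)
}

# Per-pixel stain concentration maps of a scene. Hematoxylin: background
# level everywhere, and inside each nucleus/clutter structure the maximum
# covering concentration (the visually dominant structure wins). Eosin: a
# smooth seeded texture around the background mean (stroma density varies),
# suppressed inside nuclei and clutter.
scene_concentrations <- function(scene) {
  H <- scene$image_size[1]; W <- scene$image_size[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  h <- matrix(scene$h_background, H, W)
  covered <- matrix(FALSE, H, W)
  all_el <- rbind(
    scene$nuclei[, c("row", "col", "a", "b", "angle", "h_conc")],
    scene$clutter
  )
  # chromatin density rises toward the nucleus center: each structure
  # contributes a sharply peaked profile (Gaussian bump over a stained
  # floor) that reaches h_conc at the center and 0.35 h_conc at the rim.
  # Overlapping structures absorb additively (Beer-Lambert), so overlaps
  # are darker and every nucleus center stays a curvature maximum of the
  # hematoxylin surface.
  hsum <- matrix(0, H, W)
  n_nuc <- nrow(scene$nuclei)
  for (k in seq_len(nrow(all_el))) {
    n <- all_el[k, ]
    rho2 <- ellipse_rho2(rows, cols, n$row, n$col, n$a, n$b, n$angle)
    inside <- rho2 <= 1
    if (k <= n_nuc) {
      # nucleus: chromatin bump peaking at the center
      w <- (exp(-4 * rho2[inside]) - exp(-4)) / (1 - exp(-4))
    } else {
      # clutter: a ridge — constant density along its length, falling off
      # only across it, so it has no blob-like convexity
      u <- rows[inside] - n$row
      v <- cols[inside] - n$col
      across <- (-u * sin(n$angle) + v * cos(n$angle)) / n$b
      along <- (u * cos(n$angle) + v * sin(n$angle)) / n$a
      taper <- pmin(pmax(3 * (1 - abs(along)), 0), 1)
      w <- (exp(-4 * across^2) - exp(-4)) / (1 - exp(-4)) * taper
    }
    prof <- n$h_conc * (0.35 + 0.65 * w)
    hsum[inside] <- hsum[inside] + prof
    covered <- covered | inside
  }
  h[covered] <- hsum[covered]
  # smooth eosin texture: bilinear upsample of a coarse seeded uniform grid
  gh <- max(4L, ceiling(H / 16)); gw <- max(4L, ceiling(W / 16))
  ctrl <- with_seed(scene$seed + 3L, matrix(runif(gh * gw), gh, gw))
  sr <- matrix(1 + (seq_len(H) - 1) * (gh - 1) / (H - 1), H, W)
  sc <- matrix(1 + (seq_len(W) - 1) * (gw - 1) / (W - 1), H, W, byrow = TRUE)
  u <- sample_matrix(ctrl, sr, sc, "bilinear")
  e <- scene$e_background * (0.5 + 1.6 * u)
  e[covered] <- e[covered] * scene$e_nucleus_factor
  list(h = h, e = e)
}

#' Render a synthetic scene to an RGB image
#'
#' Applies the Beer-Lambert forward model: per pixel,
#' `I = 10 ^ (-(M %*% c))` where `M` is the scene's stain matrix and `c` the
#' (hematoxylin, eosin) concentration pair, plus Gaussian noise added in OD
#' space, clipped to `[0, 1]`. Rendering is deterministic given the scene
#' (the noise stream is derived from the scene seed).
#'
#' @param scene a `synthetic_scene`.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_rgb <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  H <- scene$image_size[1]; W <- scene$image_size[2]
  conc <- scene_concentrations(scene)
  M <- scene$stain_matrix
  od <- array(0, c(H, W, 3))
  for (ch in 1:3) od[, , ch] <- M[ch, 1] * conc$h + M[ch, 2] * conc$e
  if (scene$noise_sd > 0) {
    od <- od + with_seed(scene$seed + 2L,
                         array(rnorm(length(od), 0, scene$noise_sd), dim(od)))
  }
  img <- 10^(-od)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Ground-truth labels and lesion centroids of a scene
#'
#' Rasterizes each nucleus to its label index (clutter is not labeled).
#' Pixels covered by several nuclei go to the one with the higher
#' hematoxylin concentration, except that every nucleus always keeps its own
#' center pixel, so each centroid lies inside its own labeled region.
#'
#' @param scene a `synthetic_scene`.
#' @return A list with `labels` (`H x W` integer matrix, 0 = background,
#'   k = nucleus k) and `lesion_centroids` (matrix of `(row, col)` centers
#'   of lesion nuclei).
#' @export
ground_truth <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  H <- scene$image_size[1]; W <- scene$image_size[2]
  labels <- matrix(0L, H, W)
  nuc <- scene$nuclei
  if (nrow(nuc) > 0) {
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    best_h <- matrix(-Inf, H, W)
    for (k in seq_len(nrow(nuc))) {
      n <- nuc[k, ]
      inside <- ellipse_inside(rows, cols, n$row, n$col, n$a, n$b, n$angle)
      take <- inside & (n$h_conc > best_h)
      labels[take] <- k
      best_h[take] <- n$h_conc
    }
    for (k in seq_len(nrow(nuc))) {
      labels[round(nuc$row[k]), round(nuc$col[k])] <- k
    }
  }
  cent <- as.matrix(nuc[nuc$is_lesion, c("row", "col")])
  dimnames(cent) <- list(NULL, c("row", "col"))
  list(labels = labels, lesion_centroids = cent)
}

#' All nucleus centroids of a scene
#'
#' @param scene a `synthetic_scene`.
#' @return A matrix of `(row, col)` centers, one row per nucleus.
#' @export
nucleus_centroids <- function(scene) {
  cent <- as.matrix(scene$nuclei[, c("row", "col")])
  dimnames(cent) <- list(NULL, c("row", "col"))
  cent
}
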
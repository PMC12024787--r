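#' Edge-stopping map for geodesic active contours
#'
#' `g = 1 / (1 + (gain * |grad(I1)|)^p)` where `I1` is the Gaussian-smoothed
#' input. `g` is 1 on flat regions and small on edges, so it halts the
#' evolving contour at boundaries. Because the raw formula's contrast
#' depends on the physical scale of the input surface, the default
#' `gain = NULL` auto-calibrates so that the 99th-percentile gradient maps
#' to `g = 0.05`; `gain = 1` gives the plain formula.
#'
#' @param gray `H x W` surface (typically the hematoxylin concentration).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels.
#' @param p exponent, 1 or 2.
#' @param gain gradient gain, or `NULL` for auto-calibration.
#' @return `H x W` matrix in `(0, 1]` with attribute `gain`.
#' @export
stopping_map <- function(gray, smoothing_sigma = 2.0, p = 2, gain = NULL) {
  stopifnot(p %in% c(1, 2))
  i1 <- gaussian_smooth(gray, smoothing_sigma)
  gr <- gradient_central(i1)
  mag <- sqrt(gr$dr^2 + gr$dc^2)
  if (is.null(gain)) {
    ref <- stats::quantile(mag, 0.99, names = FALSE)
    gain <- if (ref > 0) (1 / 0.05 - 1)^(1 / p) / ref else 1
  }
  structure(1 / (1 + (gain * mag)^p), gain = gain)
}

# Central-difference gradient with replicated borders.
gradient_central <- function(m) {
  H <- nrow(m); W <- ncol(m)
  rp <- m[c(2:H, H), , drop = FALSE]; rm <- m[c(1, 1:(H - 1)), , drop = FALSE]
  cp <- m[, c(2:W, W), drop = FALSE]; cm <- m[, c(1, 1:(W - 1)), drop = FALSE]
  list(dr = (rp - rm) / 2, dc = (cp - cm) / 2)
}

#' Initialize a level-set field from a binary mask
#'
#' `u = dist(outside) - dist(inside)`: negative inside the mask, positive
#' outside, zero crossing on the mask boundary, and `|u|` equal to the
#' unsigned Euclidean distance transform of the respective side.
#'
#' @param mask logical matrix with at least one foreground and one
#'   background pixel.
#' @return `H x W` numeric level-set field.
#' @export
init_levelset <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask) || all(mask)) {
    stopf("level-set initialization needs both foreground and background pixels")
  }
  distance_transform(!mask) - distance_transform(mask)
}

#' Evolution parameters for the geodesic active contour
#'
#' Under the sign convention `u < 0` inside, a positive balloon constant
#' `v` shrinks the contour and a negative one inflates it. The default
#' `v = 0` evolves by curvature and edge attraction only; the pipeline
#' inflates distance-transform cores with `v < 0` until the stopping map
#' halts them at nucleus edges.
#'
#' @param v balloon constant (positive = shrink, negative = inflate).
#' @param dt explicit time step (stability requires `dt <= 0.25` for the
#'   2D curvature term).
#' @param max_iters maximum iterations.
#' @param reinit_every re-initialize `u` to a signed distance every this
#'   many iterations (`Inf` disables).
#' @param tol stop when the mean absolute update falls below `tol`.
#' @return A list with class `evolution_params`.
#' @export
evolution_params <- function(v = 0, dt = 0.25, max_iters = 200,
                             reinit_every = 25, tol = 1e-3) {
  stopifnot(dt > 0, max_iters >= 1)
  structure(list(v = v, dt = dt, max_iters = max_iters,
                 reinit_every = reinit_every, tol = tol),
            class = "evolution_params")
}

#' Evolve a level-set field under the geodesic active-contour equation
#'
#' Explicit finite-difference scheme for
#' `du/dt = g * (div(grad u / |grad u|) + v) * |grad u| + grad g . grad u`:
#' the curvature term uses central differences, the balloon term a Godunov
#' upwind gradient, and the edge-attraction term upwinds on the sign of
#' `grad g`. The field is periodically re-initialized to a signed distance.
#'
#' @param u level-set field from [init_levelset()].
#' @param g stopping map from [stopping_map()] (scalar 1 is accepted).
#' @param params an [evolution_params()].
#' @return Evolved field with attributes `iterations` and `converged`.
#' @export
evolve <- function(u, g, params = evolution_params()) {
  stopifnot(inherits(params, "evolution_params"))
  H <- nrow(u); W <- ncol(u)
  if (length(g) == 1) g <- matrix(g, H, W)
  stopifnot(all(dim(g) == dim(u)))
  gg <- gradient_central(g)
  eps <- 1e-12
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iters)) {
    rp <- u[c(2:H, H), , drop = FALSE]; rm <- u[c(1, 1:(H - 1)), , drop = FALSE]
    cp <- u[, c(2:W, W), drop = FALSE]; cm <- u[, c(1, 1:(W - 1)), drop = FALSE]
    dxm <- u - rm; dxp <- rp - u; dx0 <- (rp - rm) / 2
    dym <- u - cm; dyp <- cp - u; dy0 <- (cp - cm) / 2

    # curvature * |grad u| with central differences
    uxx <- rp - 2 * u + rm
    uyy <- cp - 2 * u + cm
    upp <- u[c(2:H, H), c(2:W, W), drop = FALSE]
    umm <- u[c(1, 1:(H - 1)), c(1, 1:(W - 1)), drop = FALSE]
    upm <- u[c(2:H, H), c(1, 1:(W - 1)), drop = FALSE]
    ump <- u[c(1, 1:(H - 1)), c(2:W, W), drop = FALSE]
    uxy <- (upp + umm - upm - ump) / 4
    curv <- (uxx * dy0^2 - 2 * dx0 * dy0 * uxy + uyy * dx0^2) /
      (dx0^2 + dy0^2 + eps)

    # balloon term a * |grad u| with Godunov upwinding (a = g v)
    a <- g * params$v
    pos <- (a > 0)
    grad_minus <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 +
                         pmin(dym, 0)^2 + pmax(dyp, 0)^2)
    grad_plus <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 +
                        pmax(dym, 0)^2 + pmin(dyp, 0)^2)
    ball <- a * (pos * grad_minus + (1 - pos) * grad_plus)

    # edge attraction grad g . grad u, upwind on the advection direction
    rpos <- (gg$dr > 0); cpos <- (gg$dc > 0)
    adv <- gg$dr * (rpos * dxp + (1 - rpos) * dxm) +
      gg$dc * (cpos * dyp + (1 - cpos) * dym)

    du <- params$dt * (g * curv + ball + adv)
    u <- u + du
    iters <- it
    if (!all(is.finite(u))) {
      stopf("level-set evolution diverged (non-finite field) at iteration %d", it)
    }
    if (mean(abs(du)) < params$tol) {
      converged <- TRUE
      break
    }
    if (is.finite(params$reinit_every) && it %% params$reinit_every == 0 &&
        any(u < 0) && any(u >= 0)) {
      u <- init_levelset(u < 0)
    }
  }
  structure(u, iterations = iters, converged = converged)
}

#' Extract zero-level contours from a level-set field
#'
#' Sub-pixel zero-crossing polylines via marching-squares tracing. Loops
#' are returned closed (first point repeated last); paths clipped by the
#' image border are closed along their endpoints. Paths with fewer than
#' `min_length` vertices are discarded.
#'
#' @param u level-set field.
#' @param min_length minimum number of vertices.
#' @return List of closed paths, each a matrix with columns `row`, `col`.
#' @export
extract_contours <- function(u, min_length = 8) {
  if (all(u > 0) || all(u < 0)) return(list())
  cl <- grDevices::contourLines(seq_len(nrow(u)), seq_len(ncol(u)),
                                as.matrix(u), levels = 0)
  out <- lapply(cl, function(p) {
    path <- cbind(row = p$x, col = p$y)
    if (nrow(path) >= 2 &&
        sqrt(sum((path[1, ] - path[nrow(path), ])^2)) > 1e-9) {
      path <- rbind(path, path[1, ])
    }
    path
  })
  out[vapply(out, nrow, integer(1)) >= min_length]
}

#' Refine a component mask with a geodesic active contour
#'
#' Evolves a level set initialized from `mask` inside the mask's bounding
#' box (plus a margin), guided by the stopping map of the image surface.
#' Used by the pipeline to lock distance-transform cores onto nucleus
#' boundaries.
#'
#' @param mask component mask (logical matrix, full frame).
#' @param g full-frame stopping map.
#' @param params an [evolution_params()].
#' @param margin bounding-box margin in pixels.
#' @return Refined logical mask, full frame.
#' @export
refine_component <- function(mask, g, params = evolution_params(v = -0.5),
                             margin = 10) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask)
  r0 <- max(1, min(idx[, 1]) - margin); r1 <- min(nrow(mask), max(idx[, 1]) + margin)
  c0 <- max(1, min(idx[, 2]) - margin); c1 <- min(ncol(mask), max(idx[, 2]) + margin)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  if (!any(!sub)) return(mask)
  u <- evolve(init_levelset(sub), g[r0:r1, c0:c1, drop = FALSE], params)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[r0:r1, c0:c1] <- u < 0
  out
}
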
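#' Macenko estimation parameters
#'
#' `alpha` is the robust percentile used when picking the extreme stain
#' angles in the SVD plane; `beta` is the optical-density threshold below
#' which pixels are treated as unstained (transparent) background and
#' excluded from stain estimation. Defaults are alpha = 1, beta = 0.15.
#'
#' @param alpha percentile in (0, 50).
#' @param beta OD floor, >= 0.
#' @return A list with class `macenko_params`.
#' @export
macenko_params <- function(alpha = 1, beta = 0.15) {
  stopifnot(alpha > 0, alpha < 50, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "macenko_params")
}

#' RGB to optical density
#'
#' `od = -log10(max(img, eps) / i0)`. The floor `eps` keeps 8-bit black
#' pixels finite; `od(i0) = 0` and the transform is monotone decreasing in
#' intensity.
#'
#' @param img RGB array (or matrix) with values in `[0, 1]`.
#' @param i0 incident (maximum) intensity.
#' @param eps intensity floor, default `i0 / 255`.
#' @return Array of the same shape with non-negative OD values.
#' @export
rgb_to_od <- function(img, i0 = 1.0, eps = i0 / 255) {
  -log10(pmax(img, eps) / i0)
}

#' Optical density to RGB
#'
#' Inverse Beer-Lambert: `img = i0 * 10^(-od)`, clipped to `[0, 1]`.
#'
#' @param od non-negative OD array.
#' @param i0 incident intensity.
#' @return RGB array in `[0, 1]`.
#' @export
od_to_rgb <- function(od, i0 = 1.0) {
  pmin(pmax(i0 * 10^(-od), 0), 1)
}

od_pixel_matrix <- function(od) {
  if (length(dim(od)) != 3 || dim(od)[3] != 3) stopf("expected an H x W x 3 OD array")
  matrix(od, ncol = 3)
}

#' Estimate the H&E stain matrix (Macenko method)
#'
#' Flattens OD pixels, discards near-transparent pixels (all channels must
#' exceed `beta`), takes the plane spanned by the two leading right-singular
#' vectors of the retained OD cloud, computes each pixel's angle in that
#' plane, and maps the `alpha` / `100 - alpha` percentile angles back to
#' unit OD vectors. The hematoxylin column is the extreme vector with the
#' larger red-to-blue OD ratio (blue-purple hematoxylin absorbs red;
#' pink eosin transmits it); eosin is the other.
#'
#' @param od `H x W x 3` OD array (see [rgb_to_od()]).
#' @param params a [macenko_params()] object.
#' @return A 3 x 2 unit-column matrix, columns `H` and `E`.
#' @export
estimate_stain_matrix <- function(od, params = macenko_params()) {
  X <- od_pixel_matrix(od)
  keep <- rowSums(X > params$beta) == 3
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2) {
    stopf("stain estimation failed: only %d pixels above the beta = %.3g OD threshold",
          nrow(X), params$beta)
  }
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * sv$d[1]) {
    stopf("stain estimation failed: OD cloud has rank < 2 (singular values %.3g, %.3g)",
          sv$d[1], sv$d[2])
  }
  V <- sv$v[, 1:2, drop = FALSE]
  # orient the plane basis so projections have a consistent sign
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (sum(V[, 2]) < 0) V[, 2] <- -V[, 2]
  proj <- X %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(params$alpha / 100, 1 - params$alpha / 100),
                       names = FALSE, type = 7)
  vecs <- sapply(q, function(a) V %*% c(cos(a), sin(a)))
  vecs <- apply(vecs, 2, function(v) {
    if (sum(v) < 0) v <- -v
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  })
  # hematoxylin stains blue-purple, i.e. absorbs red: it is the extreme
  # vector with the larger red-to-blue OD ratio (eosin transmits red)
  ratio <- vecs[1, ] / pmax(vecs[3, ], 1e-12)
  h_idx <- which.max(ratio)
  M <- cbind(H = vecs[, h_idx], E = vecs[, 3 - h_idx])
  rownames(M) <- c("R", "G", "B")
  M
}

# Non-negative least squares for the two-stain case, vectorized over pixels.
# For 2 unknowns the NNLS optimum is either the unconstrained solution (when
# feasible) or the better of the two clamped single-stain projections.
nnls_two_stain <- function(X, M) {
  G <- crossprod(M)            # 2 x 2 Gram matrix
  b <- X %*% M                 # n x 2, = t(M) %*% od per pixel
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  c1 <- (G[2, 2] * b[, 1] - G[1, 2] * b[, 2]) / det
  c2 <- (G[1, 1] * b[, 2] - G[1, 2] * b[, 1]) / det
  feasible <- c1 >= 0 & c2 >= 0
  # axis candidates: project on one stain, clamp at zero
  a1 <- pmax(b[, 1] / G[1, 1], 0)
  a2 <- pmax(b[, 2] / G[2, 2], 0)
  # residual difference (up to the common ||od||^2 term): -2 c.b + c'Gc
  r1 <- -2 * a1 * b[, 1] + a1^2 * G[1, 1]
  r2 <- -2 * a2 * b[, 2] + a2^2 * G[2, 2]
  use1 <- r1 <= r2
  out <- cbind(ifelse(use1, a1, 0), ifelse(use1, 0, a2))
  out[feasible, 1] <- c1[feasible]
  out[feasible, 2] <- c2[feasible]
  out
}

#' Per-pixel stain concentrations by non-negative least squares
#'
#' Solves `argmin_{c >= 0} || M c - od ||` independently per pixel. The
#' non-negativity constraint makes the concentration map structurally valid
#' (absorbances cannot be negative).
#'
#' @param od `H x W x 3` OD array.
#' @param M 3 x 2 stain matrix.
#' @return `H x W x 2` array of (hematoxylin, eosin) concentrations.
#' @export
compute_concentrations <- function(od, M) {
  stopifnot(nrow(M) == 3, ncol(M) == 2)
  X <- od_pixel_matrix(od)
  C <- nnls_two_stain(X, M)
  array(C, c(dim(od)[1], dim(od)[2], 2))
}

#' Hematoxylin concentration channel of an RGB image
#'
#' Convenience wrapper: estimates the stain matrix (unless given) and
#' returns the per-pixel hematoxylin concentration. This surface is the
#' working "gray" image of the downstream enhancement, contour, and
#' blobness stages: nuclei are bright, tissue is dark.
#'
#' @param img RGB array in `[0, 1]`.
#' @param M optional 3 x 2 stain matrix; estimated if `NULL`.
#' @param params [macenko_params()] used when estimating.
#' @return `H x W` matrix of hematoxylin concentrations.
#' @export
hematoxylin_concentration <- function(img, M = NULL, params = macenko_params()) {
  od <- rgb_to_od(img)
  if (is.null(M)) M <- estimate_stain_matrix(od, params)
  compute_concentrations(od, M)[, , 1]
}

#' Normalize an image to a reference stain appearance
#'
#' Estimates the source stain matrix and concentrations, rescales each
#' concentration channel so its 99th percentile matches the reference
#' maximum concentration, and re-renders through the reference stain matrix.
#'
#' @param img RGB array in `[0, 1]`.
#' @param ref 3 x 2 reference stain matrix.
#' @param ref_maxC length-2 reference maximum (99th percentile)
#'   concentrations for (H, E).
#' @param params [macenko_params()].
#' @return Normalized RGB array in `[0, 1]`.
#' @export
normalize_to_reference <- function(img, ref, ref_maxC, params = macenko_params()) {
  od <- rgb_to_od(img)
  M_src <- estimate_stain_matrix(od, params)
  conc <- compute_concentrations(od, M_src)
  src_max <- apply(conc, 3, stats::quantile, probs = 0.99, names = FALSE)
  src_max <- pmax(src_max, 1e-8)
  H <- dim(img)[1]; W <- dim(img)[2]
  od_out <- array(0, c(H, W, 3))
  for (s in 1:2) {
    scaled <- conc[, , s] * (ref_maxC[s] / src_max[s])
    for (ch in 1:3) od_out[, , ch] <- od_out[, , ch] + ref[ch, s] * scaled
  }
  od_to_rgb(od_out)
}

#' Reference stain statistics of an image
#'
#' @param img RGB array in `[0, 1]`.
#' @param params [macenko_params()].
#' @return List with `M` (stain matrix) and `maxC` (99th percentile
#'   concentration per stain), usable as the reference for
#'   [normalize_to_reference()].
#' @export
stain_reference <- function(img, params = macenko_params()) {
  od <- rgb_to_od(img)
  M <- estimate_stain_matrix(od, params)
  conc <- compute_concentrations(od, M)
  list(M = M, maxC = apply(conc, 3, stats::quantile, probs = 0.99, names = FALSE))
}

#' Separate an H&E image into hematoxylin-only and eosin-only renders
#'
#' Unmixes concentrations and re-renders each stain alone. In OD space the
#' two renders partition the reconstruction: `od(h) + od(e) = M %*% C`.
#'
#' @param img RGB array in `[0, 1]`.
#' @param M 3 x 2 stain matrix.
#' @return List with RGB arrays `h` and `e` and the concentration array
#'   `conc`.
#' @export
separate_stains <- function(img, M) {
  od <- rgb_to_od(img)
  conc <- compute_concentrations(od, M)
  H <- dim(img)[1]; W <- dim(img)[2]
  od_h <- array(0, c(H, W, 3)); od_e <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    od_h[, , ch] <- M[ch, 1] * conc[, , 1]
    od_e[, , ch] <- M[ch, 2] * conc[, , 2]
  }
  list(h = od_to_rgb(od_h), e = od_to_rgb(od_e), conc = conc)
}

#' Angle between two stain vectors, in degrees
#'
#' @param u,v 3-vectors.
#' @return Angle in degrees in `[0, 180]`.
#' @export
stain_angle <- function(u, v) {
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cth, -1), 1)) * 180 / pi
}
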
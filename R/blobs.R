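#' Hessian blobness of a gray surface
#'
#' Smooths with a Gaussian at scale `sigma`, forms the scale-normalized
#' Hessian (second derivatives times `sigma^2`), and scores each pixel by
#' the geometric mean of the eigenvalue magnitudes,
#' `sqrt(lambda1 * lambda2)`, gated to zero unless both eigenvalues are
#' negative (a bright, locally convex cap). The score is rotation
#' invariant, maximal for isotropic bright blobs, and near zero on ridges
#' and edges, which is what separates nuclei from elongated clutter.
#'
#' @param surface `H x W` matrix (hematoxylin concentration: nuclei bright).
#' @param sigma blob scale in pixels.
#' @return `H x W` matrix of non-negative blobness values.
#' @export
hessian_blobness <- function(surface, sigma) {
  if (sigma <= 0) stopf("sigma must be positive, got %g", sigma)
  s <- gaussian_smooth(surface, sigma)
  H <- nrow(s); W <- ncol(s)
  rp <- s[c(2:H, H), , drop = FALSE]; rm <- s[c(1, 1:(H - 1)), , drop = FALSE]
  cp <- s[, c(2:W, W), drop = FALSE]; cm <- s[, c(1, 1:(W - 1)), drop = FALSE]
  hrr <- (rp - 2 * s + rm) * sigma^2
  hcc <- (cp - 2 * s + cm) * sigma^2
  spp <- s[c(2:H, H), c(2:W, W), drop = FALSE]
  smm <- s[c(1, 1:(H - 1)), c(1, 1:(W - 1)), drop = FALSE]
  spm <- s[c(2:H, H), c(1, 1:(W - 1)), drop = FALSE]
  smp <- s[c(1, 1:(H - 1)), c(2:W, W), drop = FALSE]
  hrc <- ((spp + smm - spm - smp) / 4) * sigma^2
  tr <- hrr + hcc
  disc <- sqrt(pmax((hrr - hcc)^2 + 4 * hrc^2, 0))
  l1 <- (tr - disc) / 2  # more negative eigenvalue
  l2 <- (tr + disc) / 2
  out <- matrix(0, H, W)
  bright <- l2 < 0
  out[bright] <- sqrt(l1[bright] * l2[bright])
  out
}

#' Per-candidate blobness statistics
#'
#' The mean and maximum blobness over the candidate's pixels, and its size.
#'
#' @param pixels matrix of `(row, col)` pixel coordinates.
#' @param blobness blobness surface from [hessian_blobness()].
#' @return Named vector `(blobness_mean, blobness_max, size)`.
#' @export
candidate_stats <- function(pixels, blobness) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  if (nrow(pixels) == 0) stopf("candidate has no pixels")
  if (any(pixels[, 1] < 1 | pixels[, 1] > nrow(blobness) |
          pixels[, 2] < 1 | pixels[, 2] > ncol(blobness))) {
    stopf("candidate pixels fall outside the frame")
  }
  v <- blobness[pixels]
  c(blobness_mean = mean(v), blobness_max = max(v), size = nrow(pixels))
}

#' Difference-of-Gaussians blob surface
#'
#' Bandpass response `G(sigma) * x - G(3 sigma) * x`: positive and peaked
#' at the centers of bright blobs of scale ~sigma and above, insensitive
#' both to pixel noise (averaged over the inner Gaussian) and to the
#' smooth absorbance gradient of bright neighbors (removed with the outer
#' Gaussian). Used to localize nucleus centers and split merged regions.
#'
#' @param surface `H x W` matrix (hematoxylin concentration).
#' @param sigma inner Gaussian scale in pixels.
#' @return `H x W` response matrix.
#' @export
dog_surface <- function(surface, sigma) {
  gaussian_smooth(surface, sigma) - gaussian_smooth(surface, 3 * sigma)
}

#' Blobness peaks inside a mask
#'
#' Local maxima of the blobness surface restricted to the mask: a pixel is
#' a peak if it attains the maximum of its `(2 win + 1)` square
#' neighborhood and exceeds `rel_thresh` times the mask's maximum
#' blobness. Peaks closer than `min_sep` pixels are merged (strongest
#' kept). One nucleus produces one peak, so the peak count of a merged
#' component tells how many nuclei it contains.
#'
#' @param mask logical matrix.
#' @param blobness blobness surface.
#' @param win neighborhood half-size for the local-maximum test.
#' @param rel_thresh relative height threshold (fraction of the mask's
#'   maximum).
#' @param min_sep minimum peak separation in pixels.
#' @param abs_thresh optional absolute height floor (same units as
#'   `blobness`); peaks must clear both thresholds.
#' @param prom_frac topographic prominence requirement in (0, 1]: a weaker
#'   peak is kept only if the surface dips below `prom_frac` times its
#'   height somewhere on the straight path to every stronger kept peak.
#'   A spurious maximum on the slope of a real blob has no such valley and
#'   is pruned; two genuine adjacent nuclei do. `1` disables the check
#'   least strictly, larger-than-1 values are clamped.
#' @return Matrix of peak `(row, col)` coordinates (0 rows if none).
#' @export
blobness_peaks <- function(mask, blobness, win = 2, rel_thresh = 0.2,
                           min_sep = 4, abs_thresh = 0, prom_frac = NULL) {
  mask <- as_mask(mask)
  vmax <- max(blobness[mask], 0)
  if (vmax <= 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  d <- 2 * win + 1
  local_max <- EBImage::imageData(EBImage::dilate(EBImage::Image(blobness),
                                         matrix(1, d, d))) <= blobness + 1e-12
  cand <- which(mask & local_max &
                  blobness >= max(rel_thresh * vmax, abs_thresh),
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  ord <- order(-blobness[cand])
  cand <- cand[ord, , drop = FALSE]
  has_valley <- function(p, q, height) {
    t <- seq(0, 1, length.out = 24)
    r <- reflect_index(round(p[1] + t * (q[1] - p[1])), nrow(blobness))
    c <- reflect_index(round(p[2] + t * (q[2] - p[2])), ncol(blobness))
    min(blobness[cbind(r, c)]) < prom_frac * height
  }
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < min_sep^2] <- FALSE
      if (!is.null(prom_frac)) {
        for (jj in j[keep[j]]) {
          if (!has_valley(cand[jj, ], cand[i, ], blobness[cand[jj, , drop = FALSE]])) {
            keep[jj] <- FALSE
          }
        }
      }
    }
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Split a mask into one region per blobness peak
#'
#' Assigns every mask pixel to its nearest peak, resolving merged
#' (overlapping) nuclei that connected-components analysis and the active
#' contour cannot separate. With fewer than two peaks the mask is returned
#' unchanged.
#'
#' @param mask logical matrix.
#' @param blobness blobness surface.
#' @param ... passed to [blobness_peaks()].
#' @return List of logical masks (at least one).
#' @export
split_mask_by_peaks <- function(mask, blobness, ...) {
  mask <- as_mask(mask)
  peaks <- blobness_peaks(mask, blobness, ...)
  if (nrow(peaks) < 2) return(list(mask))
  px <- which(mask, arr.ind = TRUE)
  d2 <- outer(px[, 1], peaks[, 1], "-")^2 + outer(px[, 2], peaks[, 2], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  lapply(seq_len(nrow(peaks)), function(k) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[px[assign == k, , drop = FALSE]] <- TRUE
    m
  })
}

#' Build blob candidates from component masks
#'
#' Each candidate records its pixels, blobness statistics, pixel-mean
#' centroid, a reported blob location (`peak`, the argmax of
#' `peak_surface` over the candidate, by default the blobness surface),
#' and bounding box.
#'
#' @param masks list of component masks (e.g. from [component_masks()],
#'   possibly refined by [refine_component()]).
#' @param blobness blobness surface.
#' @param peak_surface surface whose in-candidate maximum is reported as
#'   the blob location; defaults to `blobness`.
#' @return List of `blob_candidate` objects.
#' @export
make_candidates <- function(masks, blobness, peak_surface = blobness) {
  lapply(masks, function(m) {
    px <- which(as_mask(m), arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    st <- candidate_stats(px, blobness)
    pk <- px[which.max(peak_surface[px]), ]
    # refine the argmax to the response-weighted centroid of its local
    # window, damping single-pixel noise jitter
    w <- which(abs(px[, 1] - pk[1]) <= 2 & abs(px[, 2] - pk[2]) <= 2)
    wt <- pmax(peak_surface[px[w, , drop = FALSE]], 0)
    if (sum(wt) > 0) {
      pk <- c(sum(px[w, 1] * wt), sum(px[w, 2] * wt)) / sum(wt)
    }
    structure(
      list(pixels = px, mask = as_mask(m), stats = st,
           centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
           peak = c(row = pk[1], col = pk[2]),
           bbox = c(rmin = min(px[, 1]), rmax = max(px[, 1]),
                    cmin = min(px[, 2]), cmax = max(px[, 2]))),
      class = "blob_candidate"
    )
  })
}

candidate_feature_matrix <- function(candidates) {
  X <- t(vapply(candidates, function(cand) cand$stats, numeric(3)))
  colnames(X) <- c("blobness_mean", "blobness_max", "size")
  X
}

#' Fit the logistic candidate-selection model
#'
#' Maximizes the binomial log-likelihood of `labels` under
#' `Ls = 1 / (1 + exp(-(beta0 + sum(beta_i x_i))))` by iteratively
#' reweighted least squares. Features are standardized internally and the
#' coefficients reported on the standardized scale. Perfect separation (or
#' non-convergence) triggers a warning and a ridge-stabilized refit.
#'
#' @param features numeric matrix, one row per candidate (by convention the
#'   columns are blobness mean, blobness max, size); or a list of
#'   `blob_candidate`s.
#' @param labels logical (or 0/1) vector, `TRUE` = real lesion.
#' @param tol convergence threshold on `max |delta beta|`.
#' @param max_iter IRLS iteration cap.
#' @return A `selection_model`: `beta0`, `betas`, `feature_means`,
#'   `feature_sds`, `converged`.
#' @export
fit_selection_model <- function(features, labels, tol = 1e-8, max_iter = 100) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features)) {
    features <- candidate_feature_matrix(features)
  }
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stopf("selection model needs both classes present")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("feature '%s' is constant across candidates",
          colnames(X)[which(sds == 0)[1]])
  }
  means <- colMeans(X)
  Xs <- cbind(1, sweep(sweep(X, 2, means), 2, sds, "/"))
  beta <- rep(0, ncol(Xs))
  converged <- FALSE
  ridge <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    p <- sigmoid(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtW <- t(Xs * w)
    hess <- XtW %*% Xs + diag(ridge, ncol(Xs))
    step <- tryCatch(solve(hess, t(Xs) %*% (y - p) - ridge * beta),
                     error = function(e) NULL)
    if (is.null(step) || any(abs(beta + step) > 50)) {
      if (ridge == 0) {
        warning("possible perfect separation; refitting with a small ridge penalty")
        ridge <- 1e-3
        beta <- rep(0, ncol(Xs))
        next
      }
      break
    }
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(beta0 = beta[1], betas = beta[-1], feature_means = means,
         feature_sds = sds, feature_names = colnames(X),
         converged = converged, ridge = ridge),
    class = "selection_model"
  )
}

#' Selection scores for candidate features
#'
#' @param model a `selection_model`.
#' @param features matrix of raw (unstandardized) features, or a list of
#'   `blob_candidate`s.
#' @return List with linear scores `z` and sigmoid scores `ls`.
#' @export
selection_scores <- function(model, features) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features)) {
    features <- candidate_feature_matrix(features)
  }
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  z <- model$beta0 + drop(Xs %*% model$betas)
  list(z = z, ls = sigmoid(z))
}

#' Score candidates and select detections
#'
#' Computes `z` and `Ls` per candidate, retains those with `Ls >= cutoff`,
#' and returns detections sorted by descending score.
#'
#' @param candidates list of `blob_candidate`s.
#' @param model fitted `selection_model`.
#' @param cutoff probability cutoff (the sigmoid's natural decision
#'   boundary, 0.5, by default).
#' @return List of `detection` objects: `centroid`, `bbox`, `mask`,
#'   `score`.
#' @export
score_and_select <- function(candidates, model, cutoff = 0.5) {
  if (length(candidates) == 0) return(list())
  sc <- selection_scores(model, candidates)
  keep <- which(sc$ls >= cutoff)
  keep <- keep[order(-sc$ls[keep])]
  lapply(keep, function(i) {
    cand <- candidates[[i]]
    structure(
      list(centroid = cand$centroid, peak = cand$peak, bbox = cand$bbox,
           mask = cand$mask, score = sc$ls[i], z = sc$z[i]),
      class = "detection"
    )
  })
}
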
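#' Pipeline configuration
#'
#' Per-stage parameter blocks with defaults matching each stage's
#' documented defaults. The pipeline order is: augmentation (identity by
#' default at detection time), stain estimation/unmixing, enhancement
#' (threshold, morphology, distance transform, region partition),
#' connected components on the sure-foreground cores, per-component
#' geodesic active-contour refinement, Hessian blobness scoring with the
#' logistic selection model, and (optionally) the dense detection network.
#'
#' @param seed global seed.
#' @param stain list: `alpha`, `beta` (Macenko parameters).
#' @param enhance list: `se_radius`, `fg_frac`, `bg_dilate_radius`,
#'   `clear_borders`.
#' @param components list: `connectivity`, `min_size`, `sigma` (LoG /
#'   blobness scale).
#' @param contours list: `v`, `dt`, `max_iters`, `reinit_every`, `tol`,
#'   `smoothing_sigma`, `p`, `margin`.
#' @param blobs list: `cutoff` and optionally a fitted `model`.
#' @param detectnet list: optionally a trained `model` and `cutoff`.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stain = list(alpha = 1, beta = 0.15),
                            enhance = list(se_radius = 1, fg_frac = 0.4,
                                           bg_dilate_radius = 3,
                                           clear_borders = FALSE),
                            components = list(connectivity = 8, min_size = 20,
                                              sigma = 4, split_sigma = 1,
                                              split_rel_thresh = 0.15,
                                              split_abs_frac = 0.55,
                                              split_min_sep = 3,
                                              split_win = 1,
                                              split_prom_frac = NULL),
                            contours = list(v = -0.5, dt = 0.25,
                                            max_iters = 100, reinit_every = 25,
                                            tol = 1e-3, smoothing_sigma = 2,
                                            p = 2, margin = 10),
                            blobs = list(cutoff = 0.5, model = NULL),
                            detectnet = list(model = NULL, cutoff = 0.5)) {
  structure(list(seed = seed, stain = stain, enhance = enhance,
                 components = components, contours = contours, blobs = blobs,
                 detectnet = detectnet),
            class = "pipeline_config")
}

# Candidate masks for one image: stain -> enhance -> components -> contours
# -> peak splitting. Returns the intermediates needed by training and by
# run_pipeline. Merged (overlapping) nuclei that survive as a single
# connected component are resolved by splitting on blobness peaks, so the
# reported "components" count is the number of segmented regions after
# splitting and the candidate/detection funnel can only shrink from there.
pipeline_candidates <- function(img, config) {
  empty <- list(h_conc = NULL, mask = NULL, partition = NULL, labels = NULL,
                candidates = list(), blobness = NULL, n_components = 0L)
  mp <- macenko_params(config$stain$alpha, config$stain$beta)
  h_conc <- tryCatch(hematoxylin_concentration(img, params = mp),
                     error = function(e) NULL)
  if (is.null(h_conc)) return(empty)  # blank/unstained image

  mask <- tryCatch(binary_threshold(h_conc, "otsu"), error = function(e) NULL)
  if (is.null(mask) || !any(mask)) return(empty)

  mask <- morphology(mask, "open", config$enhance$se_radius)
  if (isTRUE(config$enhance$clear_borders)) mask <- morphology(mask, "clear_borders")
  dist <- distance_transform(mask)
  part <- partition_regions(mask, dist, fg_frac = config$enhance$fg_frac,
                            bg_dilate_radius = config$enhance$bg_dilate_radius)

  labels <- label_components(mask, connectivity = config$components$connectivity)
  # thresholding keeps only the dense nucleus cores, so pre-filter just the
  # speckle; the full min_size cut comes after the contours regrow the rims
  core_min <- max(4, round(config$components$min_size / 4))
  comp <- component_masks(labels, min_size = core_min)
  blobness <- hessian_blobness(h_conc, config$components$sigma)
  if (length(comp) == 0) {
    return(list(h_conc = h_conc, mask = mask, partition = part,
                labels = labels, candidates = list(), blobness = blobness,
                n_components = 0L))
  }

  g <- stopping_map(h_conc, smoothing_sigma = config$contours$smoothing_sigma,
                    p = config$contours$p)
  ep <- evolution_params(v = config$contours$v, dt = config$contours$dt,
                         max_iters = config$contours$max_iters,
                         reinit_every = config$contours$reinit_every,
                         tol = config$contours$tol)
  refined <- lapply(comp, refine_component, g = g, params = ep,
                    margin = config$contours$margin)
  # overlapping nuclei merged into one region are split at the local
  # maxima of a difference-of-Gaussians surface: the bandpass removes the
  # smooth absorbance gradient of bright neighbors while averaging out
  # pixel noise, so each nucleus center survives as a separate peak
  peak_surf <- dog_surface(h_conc, config$components$split_sigma)
  # absolute peak floor, self-calibrated to the image's stain intensity
  abs_thr <- config$components$split_abs_frac *
    stats::quantile(peak_surf[mask], 0.95, names = FALSE)
  split <- do.call(c, lapply(refined, split_mask_by_peaks,
                             blobness = peak_surf,
                             rel_thresh = config$components$split_rel_thresh,
                             min_sep = config$components$split_min_sep,
                             abs_thresh = abs_thr,
                             win = config$components$split_win,
                             prom_frac = config$components$split_prom_frac))
  split <- split[vapply(split, sum, numeric(1)) >= config$components$min_size]
  cands <- make_candidates(split, blobness, peak_surface = peak_surf)
  # neighboring components can regrow over the same nucleus during
  # inflation; keep one candidate per blob location (strongest peak wins)
  if (length(cands) > 1) {
    pks <- t(vapply(cands, function(x) x$peak, numeric(2)))
    strength <- peak_surf[pks]
    ord <- order(-strength)
    keep <- rep(TRUE, length(cands))
    for (i in seq_along(ord)) {
      if (!keep[ord[i]]) next
      if (i < length(ord)) {
        j <- ord[(i + 1):length(ord)]
        d2 <- (pks[j, 1] - pks[ord[i], 1])^2 + (pks[j, 2] - pks[ord[i], 2])^2
        keep[j[d2 < config$components$split_min_sep^2]] <- FALSE
      }
    }
    cands <- cands[keep]
  }
  n_comp <- length(cands)

  list(h_conc = h_conc, mask = mask, partition = part, labels = labels,
       candidates = cands,
       blobness = blobness, n_components = n_comp, stopping = g)
}

#' Run the detection pipeline on one or more images
#'
#' Executes stain estimation, enhancement, component grouping, contour
#' refinement, blobness scoring and selection in order. When the config
#' carries no fitted selection model every candidate is reported as a
#' detection; see [train_selection_from_scenes()] for fitting one. When
#' ground-truth centroids are supplied, each image also gets an
#' [evaluate_detections()] report.
#'
#' @param images a single RGB array or a list of them.
#' @param config a [pipeline_config()].
#' @param truth optional list of ground-truth centroid matrices (one per
#'   image).
#' @param match_dist matching distance for evaluation, pixels.
#' @param verbose print per-stage object counts.
#' @return A list (one element per image) with `detections` (data frame:
#'   row, col, score, size), `counts` (components, candidates,
#'   detections), and optionally `eval`.
#' @export
run_pipeline <- function(images, config = pipeline_config(), truth = NULL,
                         match_dist = 5, verbose = FALSE) {
  if (!is.list(images)) images <- list(images)
  if (length(images) == 0) stopf("run_pipeline needs at least one image")
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    st <- pipeline_candidates(images[[i]], config)
    cands <- st$candidates
    if (!is.null(config$blobs$model) && length(cands) > 0) {
      dets <- score_and_select(cands, config$blobs$model,
                               cutoff = config$blobs$cutoff)
    } else {
      dets <- lapply(cands, function(cand) {
        structure(list(centroid = cand$centroid, peak = cand$peak,
                       bbox = cand$bbox, mask = cand$mask,
                       score = NA_real_, z = NA_real_),
                  class = "detection")
      })
    }
    if (!is.null(config$detectnet$model) && length(dets) > 0) {
      feats <- t(vapply(dets, function(d) {
        cand <- list(pixels = which(d$mask, arr.ind = TRUE),
                     stats = candidate_stats(which(d$mask, arr.ind = TRUE),
                                             st$blobness))
        candidate_features(cand, st$h_conc,
                           ls = if (is.na(d$score)) 0 else d$score)
      }, numeric(8)))
      prob <- predict_detector(config$detectnet$model, feats)
      keep <- prob[, ncol(prob)] >= config$detectnet$cutoff
      dets <- dets[keep]
    }
    det_df <- if (length(dets) > 0) {
      data.frame(
        row = vapply(dets, function(d) d$peak[1], numeric(1)),
        col = vapply(dets, function(d) d$peak[2], numeric(1)),
        score = vapply(dets, function(d) d$score, numeric(1)),
        size = vapply(dets, function(d) sum(d$mask), numeric(1))
      )
    } else {
      data.frame(row = numeric(0), col = numeric(0), score = numeric(0),
                 size = numeric(0))
    }
    res <- list(
      detections = det_df,
      detail = dets,
      counts = c(components = st$n_components, candidates = length(cands),
                 detections = length(dets))
    )
    if (!is.null(truth)) {
      res$eval <- evaluate_detections(as.matrix(det_df[, c("row", "col")]),
                                      truth[[i]], match_dist = match_dist)
    }
    if (verbose) {
      message(sprintf("image %d: %d components -> %d candidates -> %d detections",
                      i, st$n_components, length(cands), length(dets)))
    }
    out[[i]] <- res
  }
  out
}

#' Fit the candidate-selection model from synthetic scenes
#'
#' Runs the candidate-generation stages on each scene's render and labels
#' each candidate by the distance of its peak to the nearest true nucleus
#' center: within `match_dist` is a positive, beyond
#' `ambiguous_factor * match_dist` a negative (clutter, noise, fragments
#' chipped off a real nucleus). Candidates in the band between the two
#' radii are excluded from the fit: labeling them negative would drag the
#' decision boundary into the dim-nucleus region, while labeling them
#' positive would teach the model to keep fragments. The logistic selection model is fitted on the
#' pooled blobness/size features.
#'
#' @param scenes list of `synthetic_scene`s (rendered internally).
#' @param config a [pipeline_config()].
#' @param match_dist labeling distance in pixels.
#' @param ambiguous_factor width of the excluded band, as a multiple of
#'   `match_dist`.
#' @return A fitted `selection_model`.
#' @export
train_selection_from_scenes <- function(scenes, config = pipeline_config(),
                                        match_dist = 5,
                                        ambiguous_factor = 1.5) {
  feats <- list(); labs <- logical(0)
  for (scene in scenes) {
    st <- pipeline_candidates(render_rgb(scene), config)
    if (length(st$candidates) == 0) next
    X <- candidate_feature_matrix(st$candidates)
    truth <- nucleus_centroids(scene)
    dmin <- vapply(st$candidates, function(cand) {
      if (nrow(truth) == 0) return(Inf)
      min(sqrt((truth[, 1] - cand$peak[1])^2 +
                 (truth[, 2] - cand$peak[2])^2))
    }, numeric(1))
    keep <- dmin <= match_dist | dmin > ambiguous_factor * match_dist
    feats[[length(feats) + 1]] <- X[keep, , drop = FALSE]
    labs <- c(labs, (dmin <= match_dist)[keep])
  }
  if (length(feats) == 0) stopf("no candidates produced from the given scenes")
  fit_selection_model(do.call(rbind, feats), labs)
}
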
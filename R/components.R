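#' Laplacian-of-Gaussian convolution kernel
#'
#' Evaluates
#' `LoG(x, y) = ((x^2 + y^2 - 2 sigma^2) / sigma^4) * exp(-(x^2 + y^2) / (2 sigma^2))`
#' on the integer grid `-radius..radius`. The kernel is radially symmetric
#' with center value `-2 / sigma^2`; convolved with an image it responds
#' negatively at the centers of bright blobs of matching scale.
#'
#' @param sigma kernel width in pixels (> 0).
#' @param radius half-size of the kernel; default `ceiling(3 * sigma)`.
#' @return A `(2 radius + 1)` square matrix with attributes `sigma` and
#'   `radius`.
#' @export
log_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) stopf("sigma must be positive, got %g", sigma)
  x <- matrix(-radius:radius, 2 * radius + 1, 2 * radius + 1)
  r2 <- x^2 + t(x)^2
  w <- ((r2 - 2 * sigma^2) / sigma^4) * exp(-r2 / (2 * sigma^2))
  structure(w, sigma = sigma, radius = radius)
}

#' LoG response of a gray surface
#'
#' Convolution with [log_kernel()], reflected borders. Bright blobs on a
#' dark background give a negative extremum at their centers (the kernel's
#' center weight is negative).
#'
#' @param gray `H x W` matrix.
#' @param sigma kernel width in pixels.
#' @return `H x W` response matrix.
#' @export
log_response <- function(gray, sigma) {
  k <- log_kernel(sigma)
  r <- attr(k, "radius")
  p <- pad_reflect(gray, r)
  res <- EBImage::filter2(EBImage::Image(p), as.matrix(k), boundary = "circular")
  EBImage::imageData(res)[(r + 1):(r + nrow(gray)), (r + 1):(r + ncol(gray)), drop = FALSE]
}

# Union-find with path compression, used to merge 4-connected labels that
# touch diagonally into 8-connected components.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Connected-components labeling
#'
#' Groups foreground pixels into maximal connected regions under 4- or
#' 8-adjacency. Labels are contiguous `1..K`, ordered by first pixel in
#' column-major scan order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8; touching diagonal nuclei form one
#'   component).
#' @return Integer `H x W` label matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask), ncol(mask))
  K <- max(lab)
  if (connectivity == 8 && K > 1) {
    H <- nrow(lab); W <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
      cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))   # up-right
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(K)
      for (i in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[i, 1])
        rb <- uf_find(parent, pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(K), function(i) uf_find(parent, i), integer(1))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  relabel_contiguous(lab)
}

# Renumber nonzero labels to contiguous 1..K preserving first-appearance
# order in column-major scan.
relabel_contiguous <- function(lab) {
  nz <- lab[lab > 0]
  if (length(nz) == 0) return(lab)
  ids <- unique(nz)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[nz]
  lab
}

#' Extract per-component binary masks
#'
#' One mask per component with at least `min_size` pixels, ordered by
#' descending size (ties broken by smaller label id).
#'
#' @param labels integer label matrix from [label_components()].
#' @param min_size minimum component area in pixels.
#' @return List of logical masks; attribute `label_ids` records the source
#'   labels.
#' @export
component_masks <- function(labels, min_size = 20) {
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= max(min_size, 1))
  ord <- keep[order(-sizes[keep], keep)]
  out <- lapply(ord, function(k) labels == k)
  attr(out, "label_ids") <- ord
  out
}
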
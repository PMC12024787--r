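# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most literal formulation of each operation so they share
# no code path with the package implementation.

# All-pairs Euclidean distance transform.
oracle_distance_transform <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0) return(NULL)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j]) {
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    }
  }
  out
}

# Sliding-window min (erode) / max (dilate) over a structuring element
# given as a two-column matrix of (dr, dc) offsets. Border handling uses
# the self-dual convention: out-of-frame neighbors count as foreground for
# erosion and background for dilation, so dilate(m) = !erode(!m) holds
# everywhere.
oracle_morph <- function(mask, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  pad <- op == "erode"
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rr <- i + offsets[, 1]; cc <- j + offsets[, 2]
    inb <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    vals <- rep(pad, nrow(offsets))
    vals[inb] <- mask[cbind(rr[inb], cc[inb])]
    out[i, j] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, ])
}

# Breadth-first-search flood fill labeling.
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- matrix(c(i, j), 1, 2)
      lab[i, j] <- k
      while (nrow(queue) > 0) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (t in seq_len(nrow(nb))) {
          r <- p[1] + nb[t, 1]; c <- p[2] + nb[t, 2]
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- k
            queue <- rbind(queue, c(r, c))
          }
        }
      }
    }
  }
  lab
}

# Exhaustive between-class-variance maximization over all histogram cuts.
oracle_otsu <- function(gray, levels = 256) {
  rng <- range(gray)
  scaled <- (gray - rng[1]) / diff(rng)
  bins <- pmin(floor(scaled * levels), levels - 1)
  counts <- tabulate(bins + 1, nbins = levels)
  p <- counts / sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; best_t <- 0
  for (k in seq_len(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- k / levels }
  }
  rng[1] + best_t * diff(rng)
}

# Do two labelings agree up to a permutation of labels?
same_partition <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  key_a <- as.integer(factor(a[a > 0], levels = unique(a[a > 0])))
  key_b <- as.integer(factor(b[b > 0], levels = unique(b[b > 0])))
  all((a > 0) == (b > 0)) && all(key_a == key_b)
}

# Coarse grid-search NNLS for a single OD pixel and a 3 x 2 stain matrix.
oracle_nnls_pixel <- function(od, M, cmax = 4, n = 81) {
  grid <- seq(0, cmax, length.out = n)
  best <- c(0, 0); best_r <- Inf
  for (c1 in grid) for (c2 in grid) {
    r <- sum((M %*% c(c1, c2) - od)^2)
    if (r < best_r) { best_r <- r; best <- c(c1, c2) }
  }
  list(conc = best, resid = best_r)
}

# A small rendered scene used by several suites.
tiny_scene <- function(seed = 1, n = 6, noise = 0) {
  make_scene(n_nuclei = n, image_size = c(96, 96), overlap_fraction = 0,
             lesion_fraction = 0, noise_sd = noise, seed = seed)
}
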
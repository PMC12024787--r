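#' Feature vector for the detection network
#'
#' Fixed-order per-candidate features: size, blobness mean, blobness max,
#' selection score `ls` (0 when no selection model has scored the
#' candidate), eccentricity, solidity, and mean/max hematoxylin
#' concentration. Eccentricity comes from the second central moments
#' (`sqrt(1 - lambda_min / lambda_max)`, 0 for a circle); solidity is the
#' pixel count over the lattice-point count of the convex hull (Pick's
#' theorem), 1 for convex regions.
#'
#' @param cand a `blob_candidate`.
#' @param h_conc `H x W` hematoxylin concentration surface.
#' @param ls optional selection score of the candidate.
#' @return Named numeric vector of 8 features.
#' @export
candidate_features <- function(cand, h_conc, ls = 0) {
  px <- cand$pixels
  n <- nrow(px)
  mu <- colMeans(px)
  dr <- px[, 1] - mu[1]; dc <- px[, 2] - mu[2]
  cov <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  sol <- pixel_solidity(px)
  hv <- h_conc[px]
  c(size = n,
    blobness_mean = unname(cand$stats["blobness_mean"]),
    blobness_max = unname(cand$stats["blobness_max"]),
    ls = ls, eccentricity = ecc, solidity = sol,
    h_mean = mean(hv), h_max = max(hv))
}

# Solidity of a lattice pixel set: n / (lattice points inside or on the
# convex hull), the latter from the shoelace area plus Pick's theorem.
pixel_solidity <- function(px) {
  n <- nrow(px)
  if (n <= 2) return(1)
  hull <- grDevices::chull(px[, 1], px[, 2])
  h <- px[hull, , drop = FALSE]
  if (nrow(h) < 3) return(1)
  x <- h[, 1]; y <- h[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  boundary <- sum(mapply(function(dx, dy) gcd_int(abs(dx), abs(dy)),
                         xn - x, yn - y))
  inside_count <- area + boundary / 2 + 1  # Pick's theorem
  min(1, n / inside_count)
}

gcd_int <- function(a, b) {
  a <- as.integer(round(a)); b <- as.integer(round(b))
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  max(a, 1L)
}

#' Detection-network configuration
#'
#' A feed-forward dense network: one input dense layer, three hidden dense
#' layers (each followed by dropout), and one softmax output layer — eight
#' layers in total (five dense + three dropout). Trained with Adam on
#' categorical cross-entropy. Defaults: input width 64, hidden widths
#' (64, 32, 16), learning rate 1e-4, batch 32, dropout 0.2, 30 epochs,
#' early stopping restoring the best-validation weights.
#'
#' @param input_width width of the input dense layer.
#' @param hidden the three hidden-layer widths.
#' @param dropout_rate dropout probability after each hidden layer
#'   (0 disables).
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param epochs training epochs.
#' @param early_stopping enable early stopping on validation loss.
#' @param patience epochs without validation improvement before stopping.
#' @param val_frac fraction of the data held out for validation.
#' @return A list with class `net_config`.
#' @export
net_config <- function(input_width = 64, hidden = c(64, 32, 16),
                       dropout_rate = 0.2,
                       lr = 1e-4, batch = 32, epochs = 30,
                       early_stopping = TRUE, patience = 5, val_frac = 0.25) {
  structure(list(input_width = input_width, hidden = hidden,
                 dropout_rate = dropout_rate, lr = lr,
                 batch = batch, epochs = epochs,
                 early_stopping = early_stopping, patience = patience,
                 val_frac = val_frac),
            class = "net_config")
}

#' Simulate candidate feature vectors for detector training studies
#'
#' Draws per-candidate feature vectors (size, blobness mean/max, selection
#' score, eccentricity, solidity, hematoxylin mean/max) from
#' class-conditional distributions resembling the pipeline's real
#' candidates: lesion candidates are larger, blobbier, rounder and more
#' intensely stained than clutter/noise candidates, with substantial
#' class overlap and a fraction of mislabeled candidates so the
#' classification problem has irreducible error (as candidate labels
#' derived from imperfect segmentation do).
#'
#' @param n number of candidates.
#' @param lesion_frac fraction of lesion-class candidates.
#' @param label_noise fraction of labels flipped at random.
#' @param seed integer seed.
#' @return List with `features` (n x 8 matrix) and `labels` (0/1).
#' @export
simulate_candidate_features <- function(n, lesion_frac = 0.5,
                                        label_noise = 0.1, seed = 1) {
  with_seed(seed, {
    y <- rbinom(n, 1, lesion_frac)
    mu0 <- c(size = 60, blobness_mean = 0.04, blobness_max = 0.12,
             ls = 0.35, eccentricity = 0.8, solidity = 0.75,
             h_mean = 0.45, h_max = 0.7)
    mu1 <- c(size = 110, blobness_mean = 0.09, blobness_max = 0.2,
             ls = 0.75, eccentricity = 0.55, solidity = 0.92,
             h_mean = 0.65, h_max = 1.0)
    sds <- c(40, 0.035, 0.06, 0.25, 0.2, 0.12, 0.15, 0.25)
    X <- t(vapply(seq_len(n), function(i) {
      m <- if (y[i] == 1) mu1 else mu0
      rnorm(8, m, sds)
    }, numeric(8)))
    colnames(X) <- names(mu0)
    X[, "size"] <- pmax(X[, "size"], 20)
    X[, c("ls", "eccentricity", "solidity")] <-
      pmin(pmax(X[, c("ls", "eccentricity", "solidity")], 0), 1)
    X[, c("blobness_mean", "blobness_max", "h_mean", "h_max")] <-
      pmax(X[, c("blobness_mean", "blobness_max", "h_mean", "h_max")], 0)
    flip <- runif(n) < label_noise
    y[flip] <- 1 - y[flip]
    list(features = X, labels = y)
  })
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

init_net <- function(d_in, hidden, d_out) {
  sizes <- c(d_in, hidden, d_out)
  lapply(seq_len(length(sizes) - 1), function(i) {
    list(W = matrix(rnorm(sizes[i] * sizes[i + 1], 0, sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

# Forward pass. Dropout (inverted) applies only after the hidden layers,
# i.e. after matrices 2..L-1: the input dense layer and the softmax output
# carry none.
net_forward <- function(layers, X, dropout_rate = 0, train = FALSE) {
  acts <- list(X)
  a <- X
  L <- length(layers)
  masks <- vector("list", L)
  for (i in seq_len(L)) {
    z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < L) {
      a <- relu(z)
      if (train && dropout_rate > 0 && i > 1) {
        m <- matrix(rbinom(length(a), 1, 1 - dropout_rate), nrow(a)) /
          (1 - dropout_rate)
        a <- a * m
        masks[[i]] <- m
      }
    } else {
      a <- softmax_rows(z)
    }
    acts[[i + 1]] <- a
  }
  list(out = a, acts = acts, masks = masks)
}

cross_entropy <- function(p, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
}

#' Train the dense detection network
#'
#' Minibatch Adam on categorical cross-entropy, with inverted dropout after
#' each hidden layer and optional early stopping that restores the weights
#' of the best validation epoch. Deterministic given `seed`. Features are
#' standardized internally (constants stored in the model).
#'
#' @param features numeric matrix, one row per candidate.
#' @param labels class labels (coerced to factor; 2 classes expected).
#' @param config a [net_config()].
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A `detect_net`: layers, standardization constants, class
#'   levels, and a per-epoch `history` data frame (epoch, train_loss,
#'   val_loss, train_acc, val_acc).
#' @export
train_detector <- function(features, labels, config = net_config(), seed = 1) {
  X <- as.matrix(features)
  yf <- factor(labels)
  if (config$epochs > 0 && nlevels(yf) < 2) stopf("training needs at least 2 classes")
  classes <- levels(yf)
  y <- as.integer(yf)
  means <- colMeans(X)
  sds <- pmax(apply(X, 2, stats::sd), 1e-12)
  Xs <- sweep(sweep(X, 2, means), 2, sds, "/")
  K <- max(2L, nlevels(yf))
  n <- nrow(Xs)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1

  model <- with_seed(seed, {
    layers <- init_net(ncol(Xs), c(config$input_width, config$hidden), K)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), train_acc = numeric(0),
                          val_acc = numeric(0))
    if (config$epochs >= 1) {
      n_val <- max(1L, round(n * config$val_frac))
      perm <- sample.int(n)
      val_idx <- perm[seq_len(n_val)]
      tr_idx <- perm[-seq_len(n_val)]
      Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
      Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]
      adam <- lapply(layers, function(l) list(
        mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
      best <- list(loss = Inf, layers = layers, wait = 0L)
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(nrow(Xtr))
        for (start in seq(1, nrow(Xtr), by = config$batch)) {
          idx <- ord[start:min(start + config$batch - 1, nrow(Xtr))]
          xb <- Xtr[idx, , drop = FALSE]; yb <- Ytr[idx, , drop = FALSE]
          fw <- net_forward(layers, xb, config$dropout_rate, train = TRUE)
          # backprop: softmax + cross-entropy gives delta = (p - y) / m
          delta <- (fw$out - yb) / nrow(xb)
          t <- t + 1
          for (i in rev(seq_along(layers))) {
            a_prev <- fw$acts[[i]]
            gW <- crossprod(a_prev, delta)
            gb <- colSums(delta)
            if (i > 1) {
              delta <- delta %*% t(layers[[i]]$W)
              delta <- delta * (fw$acts[[i]] > 0)
              if (!is.null(fw$masks[[i - 1]])) delta <- delta * fw$masks[[i - 1]]
            }
            ad <- adam[[i]]
            ad$mW <- b1 * ad$mW + (1 - b1) * gW
            ad$vW <- b2 * ad$vW + (1 - b2) * gW^2
            ad$mb <- b1 * ad$mb + (1 - b1) * gb
            ad$vb <- b2 * ad$vb + (1 - b2) * gb^2
            corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
            layers[[i]]$W <- layers[[i]]$W -
              config$lr * (ad$mW / corr1) / (sqrt(ad$vW / corr2) + eps)
            layers[[i]]$b <- layers[[i]]$b -
              config$lr * (ad$mb / corr1) / (sqrt(ad$vb / corr2) + eps)
            adam[[i]] <- ad
          }
        }
        ptr <- net_forward(layers, Xtr)$out
        pva <- net_forward(layers, Xva)$out
        tl <- cross_entropy(ptr, Ytr)
        vl <- cross_entropy(pva, Yva)
        if (!is.finite(tl) || !is.finite(vl)) {
          stopf("training loss became non-finite at epoch %d", ep)
        }
        history <- rbind(history, data.frame(
          epoch = ep, train_loss = tl, val_loss = vl,
          train_acc = mean(max.col(ptr) == max.col(Ytr)),
          val_acc = mean(max.col(pva) == max.col(Yva))
        ))
        if (config$early_stopping) {
          if (vl < best$loss - 1e-6) {
            best <- list(loss = vl, layers = layers, wait = 0L)
          } else {
            best$wait <- best$wait + 1L
            if (best$wait >= config$patience) {
              layers <- best$layers
              break
            }
          }
        }
      }
      if (config$early_stopping && best$loss < Inf) layers <- best$layers
    }
    list(layers = layers, history = history)
  })

  structure(
    list(layers = model$layers, history = model$history,
         feature_means = means, feature_sds = sds, classes = classes,
         config = config, seed = seed),
    class = "detect_net"
  )
}

#' Class probabilities from a trained detection network
#'
#' @param model a `detect_net`.
#' @param features numeric matrix of raw features.
#' @return Matrix of class probabilities (columns named by class).
#' @export
predict_detector <- function(model, features) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  p <- net_forward(model$layers, Xs)$out
  colnames(p) <- c(model$classes, rep("", ncol(p) - length(model$classes)))[seq_len(ncol(p))]
  p
}

#' Evaluate predicted centroids against ground truth
#'
#' Greedy one-to-one matching by ascending centroid distance; a pair counts
#' as a true positive only within `match_dist` pixels. When a rate is
#' undefined (empty predictions or truth) it is reported as 0 and flagged.
#'
#' @param pred_centroids matrix of predicted `(row, col)` centroids.
#' @param truth_centroids matrix of true centroids.
#' @param match_dist maximum matching distance in pixels.
#' @return An `eval_report`: tp, fp, fn, precision, recall, f1,
#'   `undefined` flag, and the matched index pairs.
#' @export
evaluate_detections <- function(pred_centroids, truth_centroids, match_dist = 5) {
  P <- as.matrix(pred_centroids); T_ <- as.matrix(truth_centroids)
  np <- if (length(P)) nrow(P) else 0L
  nt <- if (length(T_)) nrow(T_) else 0L
  matches <- matrix(integer(0), 0, 2)
  if (np > 0 && nt > 0) {
    d <- outer(seq_len(np), seq_len(nt), function(i, j) {
      sqrt((P[i, 1] - T_[j, 1])^2 + (P[i, 2] - T_[j, 2])^2)
    })
    cand <- which(d <= match_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; tt <- cand[i, 2]
        if (!used_p[p] && !used_t[tt]) {
          used_p[p] <- TRUE; used_t[tt] <- TRUE
          matches <- rbind(matches, c(p, tt))
        }
      }
    }
  }
  tp <- nrow(matches); fp <- np - tp; fn <- nt - tp
  undefined <- (tp + fp == 0) || (tp + fn == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, match_dist = match_dist, undefined = undefined,
         matches = matches),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("detections: tp=%d fp=%d fn=%d | precision=%.3f recall=%.3f f1=%.3f (match <= %g px)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$match_dist))
  invisible(x)
}

#' Seeded train/test split
#'
#' @param items vector or list to split.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return List with `train` and `test`, a disjoint exhaustive split.
#' @export
split_dataset <- function(items, train_frac = 0.75, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- length(items)
  if (n < 2) stopf("need at least 2 items to split, got %d", n)
  with_seed(seed, {
    perm <- sample.int(n)
    n_train <- round(n * train_frac)
    list(train = items[perm[seq_len(n_train)]],
         test = items[perm[-seq_len(n_train)]])
  })
}
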
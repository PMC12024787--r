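test_that("candidate features match independent per-feature recomputation", {
  set.seed(44)
  b <- matrix(runif(40 * 40), 40, 40)
  h <- matrix(runif(40 * 40), 40, 40)
  # a disk candidate: eccentricity ~ 0, solidity ~ 1
  disk <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) disk[i, j] <- (i - 20)^2 + (j - 20)^2 <= 64
  cand <- make_candidates(list(disk), b)[[1]]
  f <- candidate_features(cand, h, ls = 0.7)
  expect_lt(f[["eccentricity"]], 0.1)
  expect_gt(f[["solidity"]], 0.98)
  expect_equal(f[["ls"]], 0.7)

  # a clearly elongated candidate is eccentric
  bar <- matrix(FALSE, 40, 40); bar[18:22, 5:35] <- TRUE
  fb <- candidate_features(make_candidates(list(bar), b)[[1]], h)
  expect_gt(fb[["eccentricity"]], 0.9)

  # an L-shape is far from convex
  ell <- matrix(FALSE, 40, 40); ell[5:30, 5:9] <- TRUE; ell[26:30, 5:30] <- TRUE
  fl <- candidate_features(make_candidates(list(ell), b)[[1]], h)
  expect_lt(fl[["solidity"]], 0.7)

  # independent recomputation of the simple features on random candidates
  for (k in 1:20) {
    n <- sample(3:30, 1)
    px <- unique(cbind(sample(5:35, n, replace = TRUE),
                       sample(5:35, n, replace = TRUE)))
    m <- matrix(FALSE, 40, 40); m[px] <- TRUE
    cand <- make_candidates(list(m), b)[[1]]
    f <- candidate_features(cand, h)
    vals_b <- b[px]; vals_h <- h[px]
    expect_equal(f[["size"]], nrow(px))
    expect_equal(f[["blobness_mean"]], mean(vals_b))
    expect_equal(f[["blobness_max"]], max(vals_b))
    expect_equal(f[["h_mean"]], mean(vals_h))
    expect_equal(f[["h_max"]], max(vals_h))
    expect_true(all(is.finite(f)))
  }
})

sep_features <- function(n, seed, gap = 8) {
  # linearly separable two-class features
  histoblob:::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * 4), n, 4)
    X[, 1] <- X[, 1] + y * gap
    list(X = X, y = y)
  })
}

test_that("the dense network learns separable data and is seed-reproducible", {
  d <- sep_features(500, seed = 2)
  cfg <- net_config(epochs = 60, lr = 1e-2, early_stopping = FALSE)
  m1 <- train_detector(d$X, d$y, cfg, seed = 7)
  m2 <- train_detector(d$X, d$y, cfg, seed = 7)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
  expect_gte(tail(m1$history$train_acc, 1), 0.98)
  expect_equal(nrow(m1$history), 60)
  # prediction API returns class probabilities
  p <- predict_detector(m1, d$X)
  expect_equal(rowSums(p), rep(1, 500), tolerance = 1e-9)
  expect_gte(mean(max.col(p) - 1 == d$y), 0.98)
})

test_that("shuffled labels train to chance-level validation accuracy", {
  d <- sep_features(400, seed = 3)
  y_shuf <- histoblob:::with_seed(9, sample(d$y))
  m <- train_detector(d$X, y_shuf, net_config(epochs = 20, lr = 1e-2,
                                              early_stopping = FALSE), seed = 5)
  maj <- max(mean(y_shuf), 1 - mean(y_shuf))
  expect_lt(abs(tail(m$history$val_acc, 1) - maj), 0.1)
})

test_that("epochs = 0 leaves the model untrained with empty history", {
  d <- sep_features(50, seed = 4)
  m <- train_detector(d$X, d$y, net_config(epochs = 0), seed = 1)
  expect_equal(nrow(m$history), 0)
  expect_length(m$layers, 5)  # 1 input + 3 hidden + 1 output dense layers
})

test_that("network architecture follows the configured layer plan", {
  d <- sep_features(64, seed = 6)
  cfg <- net_config(input_width = 64, hidden = c(64, 32, 16), epochs = 1)
  m <- train_detector(d$X, d$y, cfg, seed = 2)
  dims <- vapply(m$layers, function(l) ncol(l$W), numeric(1))
  expect_equal(dims, c(64, 64, 32, 16, 2))
  expect_equal(vapply(m$layers, function(l) nrow(l$W), numeric(1)),
               c(4, 64, 64, 32, 16))
})

test_that("detection evaluation matches hand computation and the F1 identity", {
  # identical sets
  pts <- cbind(c(3, 10, 20), c(4, 12, 25))
  ev <- evaluate_detections(pts, pts)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))

  # empty predictions: undefined rates reported as 0 with a flag
  ev0 <- evaluate_detections(matrix(numeric(0), 0, 2), pts)
  expect_equal(c(ev0$precision, ev0$recall, ev0$f1), c(0, 0, 0))
  expect_true(ev0$undefined)

  # hand toy: tp 8, fp 2, fn 2
  truth <- cbind(seq(10, 100, by = 10), 50)
  pred <- rbind(truth[1:8, ], cbind(c(200, 220), c(5, 5)))
  ev2 <- evaluate_detections(pred, truth, match_dist = 5)
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn), c(8, 2, 2))
  expect_equal(c(ev2$precision, ev2$recall, ev2$f1), c(0.8, 0.8, 0.8))
  expect_equal(ev2$f1,
               2 * ev2$precision * ev2$recall / (ev2$precision + ev2$recall))
})

test_that("greedy matching never exceeds the optimal assignment count", {
  # brute-force optimal one-to-one matching by exhaustive permutation on
  # small instances
  optimal_tp <- function(P, T_, dmax) {
    best <- 0
    n <- nrow(P)
    d <- outer(seq_len(n), seq_len(nrow(T_)), function(i, j) {
      sqrt((P[i, 1] - T_[j, 1])^2 + (P[i, 2] - T_[j, 2])^2)
    })
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    for (p in perms(seq_len(nrow(T_)))) {
      k <- min(n, length(p))
      best <- max(best, sum(d[cbind(seq_len(k), p[seq_len(k)])] <= dmax))
    }
    best
  }
  set.seed(77)
  for (i in 1:10) {
    P <- cbind(runif(5, 0, 30), runif(5, 0, 30))
    T_ <- cbind(runif(5, 0, 30), runif(5, 0, 30))
    ev <- evaluate_detections(P, T_, match_dist = 8)
    expect_lte(ev$tp, optimal_tp(P, T_, 8))
    expect_equal(ev$fp, 5 - ev$tp)
    expect_equal(ev$fn, 5 - ev$tp)
  }
})

test_that("dataset splitting is seeded, disjoint, and exhaustive", {
  sp <- split_dataset(1:100, 0.75, seed = 3)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(sp, split_dataset(1:100, 0.75, seed = 3))
  expect_false(identical(sp$train, split_dataset(1:100, 0.75, seed = 4)$train))
  expect_error(split_dataset(1, 0.5), "at least 2")
  expect_error(split_dataset(1:10, 1.2))
})
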
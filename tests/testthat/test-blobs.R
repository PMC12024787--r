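gauss_spot <- function(n, c0, sd, amp = 1) {
  outer(1:n, 1:n, function(i, j) amp * exp(-((i - c0[1])^2 + (j - c0[2])^2) / (2 * sd^2)))
}

test_that("Hessian blobness is zero on flat surfaces and peaks on matched spots", {
  expect_true(all(hessian_blobness(matrix(0.3, 20, 20), 2) == 0))
  expect_error(hessian_blobness(matrix(0, 4, 4), 0), "positive")

  sp <- gauss_spot(41, c(21, 21), 3)
  b <- hessian_blobness(sp, 3)
  expect_equal(which.max(b), (21 - 1) * 41 + 21)

  # an elongated ridge of the same peak height scores below the spot
  ridge <- outer(1:41, 1:41, function(i, j) exp(-(i - 21)^2 / (2 * 9)))
  br <- hessian_blobness(ridge, 3)
  expect_lt(br[21, 21], b[21, 21] / 4)
})

test_that("blobness is rotation invariant within discretization tolerance", {
  # same anisotropic blob rendered at several orientations
  vals <- sapply(c(0, pi / 6, pi / 4, pi / 3), function(th) {
    sp <- outer(1:41, 1:41, function(i, j) {
      u <- (i - 21) * cos(th) + (j - 21) * sin(th)
      v <- -(i - 21) * sin(th) + (j - 21) * cos(th)
      exp(-(u^2 / (2 * 16) + v^2 / (2 * 9)))
    })
    max(hessian_blobness(sp, 3))
  })
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
})

test_that("candidate statistics equal naive re-summation", {
  b <- matrix(0, 4, 4); b[1, 1] <- 2; b[2, 2] <- 4
  st <- candidate_stats(rbind(c(1, 1), c(2, 2)), b)
  expect_equal(unname(st), c(3, 4, 2))
  st1 <- candidate_stats(rbind(c(1, 1)), b)
  expect_equal(st1[["blobness_mean"]], st1[["blobness_max"]])

  set.seed(9)
  bl <- matrix(runif(30 * 30), 30, 30)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    px <- cbind(sample(30, n, replace = TRUE), sample(30, n, replace = TRUE))
    st <- candidate_stats(px, bl)
    v <- numeric(n)
    for (k in seq_len(n)) v[k] <- bl[px[k, 1], px[k, 2]]
    expect_identical(unname(st), c(sum(v) / n, max(v), n))
  }

  expect_error(candidate_stats(matrix(numeric(0), 0, 2), bl), "no pixels")
  expect_error(candidate_stats(rbind(c(0, 5)), bl), "outside")
})

test_that("DoG surface peaks at blob centers despite a background gradient", {
  ramp <- outer(1:41, 1:41, function(i, j) 0.02 * j)
  sp <- gauss_spot(41, c(21, 15), 2.5, amp = 0.8) + ramp
  d <- dog_surface(sp, 1)
  pk <- blobness_peaks(matrix(TRUE, 41, 41), d, rel_thresh = 0.5, min_sep = 3)
  expect_equal(nrow(pk), 1)
  expect_lt(sqrt((pk[1, 1] - 21)^2 + (pk[1, 2] - 15)^2), 1.5)
})

test_that("mask splitting assigns each pixel to its nearest peak", {
  surf <- gauss_spot(41, c(15, 20), 2.5) + gauss_spot(41, c(27, 20), 2.5)
  d <- dog_surface(surf, 1)
  mask <- surf > 0.2
  parts <- split_mask_by_peaks(mask, d, rel_thresh = 0.3, min_sep = 3)
  expect_length(parts, 2)
  expect_identical(Reduce(`|`, parts), mask)
  expect_false(any(parts[[1]] & parts[[2]]))
  # single-peak mask returned unchanged
  single <- split_mask_by_peaks(gauss_spot(41, c(21, 21), 3) > 0.3,
                                dog_surface(gauss_spot(41, c(21, 21), 3), 1))
  expect_length(single, 1)
})

test_that("logistic selection model recovers generating coefficients", {
  set.seed(123)
  n <- 2000
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  colnames(X) <- c("blobness_mean", "blobness_max", "size")
  beta_true <- c(-1, 2, 1, 0.5)
  p <- 1 / (1 + exp(-(beta_true[1] + X %*% beta_true[-1])))
  y <- rbinom(n, 1, p)
  fit <- fit_selection_model(X, y)
  # cross-check against R's reference IRLS on the same standardized design
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  ref <- glm(y ~ Xs, family = binomial())
  expect_equal(unname(c(fit$beta0, fit$betas)), unname(coef(ref)),
               tolerance = 1e-6)
  # back-transform to the raw scale and check recovery within 3 SE
  ref_raw <- glm(y ~ X, family = binomial())
  se <- summary(ref_raw)$coefficients[, 2]
  b_raw <- fit$betas / fit$feature_sds
  b0_raw <- fit$beta0 - sum(fit$betas * fit$feature_means / fit$feature_sds)
  expect_true(all(abs(c(b0_raw, b_raw) - beta_true) < 3 * se))
})

test_that("tiny-instance logistic fit matches a grid-search oracle", {
  X <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(0, 0, 1, 1)
  # grid search over (beta0, beta1) of the standardized-model likelihood;
  # bounded grid keeps the optimum interior despite quasi-separation
  xs <- (X - mean(X)) / sd(X)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * xs
    sum(y * eta - log(1 + exp(eta)))
  }
  grid <- seq(-10, 10, by = 0.002)
  best <- c(0, 0); best_ll <- -Inf
  for (b1 in grid[grid >= 0]) {
    ll <- loglik(0, b1)  # symmetric design: optimal b0 = 0
    if (ll > best_ll) { best_ll <- ll; best <- c(0, b1) }
  }
  fit <- suppressWarnings(fit_selection_model(X, y, max_iter = 500))
  if (fit$ridge == 0) {
    expect_equal(c(fit$beta0, fit$betas), best, tolerance = 1e-3)
  } else {
    # separation fallback: the ridge solution still classifies perfectly
    sc <- selection_scores(fit, X)
    expect_equal(as.numeric(sc$ls >= 0.5), y)
  }
})

test_that("null features yield no significant fit for most seeds", {
  reject <- sapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    X <- cbind(blobness_mean = rnorm(n), blobness_max = rnorm(n),
               size = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    ref0 <- glm(y ~ 1, family = binomial())
    ref1 <- glm(y ~ X, family = binomial())
    lrt <- anova(ref0, ref1, test = "LRT")
    fit <- fit_selection_model(X, y)
    expect_lt(max(abs(fit$betas)), 1)
    lrt$`Pr(>Chi)`[2] < 0.05
  })
  expect_gte(mean(!reject), 0.9)
})

test_that("selection scoring is a monotone sigmoid with the exact anchors", {
  model <- structure(list(beta0 = 0, betas = c(1, 0.5, 0.2),
                          feature_means = c(0, 0, 0),
                          feature_sds = c(1, 1, 1),
                          feature_names = c("a", "b", "c")),
                     class = "selection_model")
  z0 <- selection_scores(model, matrix(0, 1, 3))
  expect_identical(z0$ls, 0.5)  # z = 0 is exactly 0.5
  # monotone in each positive-coefficient feature
  base <- matrix(0, 1, 3)
  for (j in 1:3) {
    up <- base; up[1, j] <- 1
    expect_gt(selection_scores(model, up)$ls, 0.5)
  }
  expect_equal(sigmoid(c(-Inf, Inf)), c(0, 1))

  expect_error(fit_selection_model(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "both classes")
  Xc <- cbind(a = rep(1, 6), b = rnorm(6))
  expect_error(fit_selection_model(Xc, c(0, 1, 0, 1, 0, 1)), "constant")
})

test_that("score_and_select filters by cutoff and sorts by score", {
  set.seed(33)
  b <- matrix(runif(40 * 40), 40, 40)
  masks <- list()
  for (k in 1:4) {
    m <- matrix(FALSE, 40, 40)
    m[(k * 8 - 3):(k * 8 + 2), 5:14] <- TRUE
    masks[[k]] <- m
  }
  cands <- make_candidates(masks, b)
  X <- histoblob:::candidate_feature_matrix(cands)
  y <- c(1, 1, 0, 0)
  fit <- suppressWarnings(fit_selection_model(X + matrix(rnorm(12, 0, 0.1), 4),
                                              y, max_iter = 50))
  dets <- score_and_select(cands, fit, cutoff = 0)
  expect_length(dets, 4)
  scores <- vapply(dets, function(d) d$score, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_true(all(vapply(dets, function(d) {
    d$centroid[1] >= d$bbox["rmin"] && d$centroid[1] <= d$bbox["rmax"]
  }, logical(1))))
  expect_length(score_and_select(list(), fit), 0)
})
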
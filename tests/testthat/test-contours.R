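disk_mask <- function(n, r, c0 = (n + 1) / 2) {
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

test_that("stopping map follows the formula and is small only on edges", {
  const <- matrix(0.4, 16, 16)
  expect_equal(stopping_map(const), matrix(1, 16, 16), ignore_attr = TRUE)

  step <- matrix(0, 32, 32); step[, 17:32] <- 1
  g <- stopping_map(step, smoothing_sigma = 2, p = 2)
  expect_equal(unname(which.min(g[16, ])), 16, tolerance = 1)
  expect_gt(min(g[16, c(1:4, 29:32)]), 0.9)

  # formula oracle: recompute from finite-difference gradients at the
  # returned gain
  set.seed(4)
  x <- matrix(runif(20 * 20), 20, 20)
  g2 <- stopping_map(x, smoothing_sigma = 1.5, p = 2)
  gain <- attr(g2, "gain")
  sm <- histoblob:::gaussian_smooth(x, 1.5)
  gr <- histoblob:::gradient_central(sm)
  ref <- 1 / (1 + (gain * sqrt(gr$dr^2 + gr$dc^2))^2)
  expect_equal(unclass(g2), ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(g2 > 0 & g2 <= 1))
})

test_that("level-set initialization is a signed distance with the mask's sign", {
  m <- disk_mask(41, 12)
  u <- init_levelset(m)
  expect_equal(u[21, 21], -distance_transform(m)[21, 21])
  expect_lt(abs(u[21, 21] + 12), 1)
  expect_identical(u < 0, m)
  expect_equal(abs(u)[m], distance_transform(m)[m])
  expect_equal(abs(u)[!m], distance_transform(!m)[!m])
  expect_error(init_levelset(matrix(TRUE, 8, 8)), "foreground and background")
})

test_that("pure curvature flow follows the circle-shrinkage closed form", {
  # dr/dt = -1/r  =>  r(t)^2 = r0^2 - 2 t
  u <- init_levelset(disk_mask(128, 20))
  # sub-pixel radius from the zero-level contour; the effective initial
  # radius of the rasterized disk (~20.1 px) seeds the closed form
  radius_of <- function(f) {
    path <- extract_contours(f)[[1]]
    mean(sqrt((path[, 1] - 64.5)^2 + (path[, 2] - 64.5)^2))
  }
  r0 <- radius_of(u)
  for (iters in c(200, 450, 750)) {
    params <- evolution_params(v = 0, dt = 0.25, max_iters = iters, tol = 0,
                               reinit_every = Inf)
    ev <- evolve(u, 1, params)
    r_expect <- sqrt(r0^2 - 2 * iters * 0.25)
    r_fit <- radius_of(ev)
    expect_lt(abs(r_fit^2 - r_expect^2) / r_expect^2, 0.05)
  }
})

test_that("the balloon term inflates or shrinks according to its sign", {
  u <- init_levelset(disk_mask(64, 8))
  grow <- evolve(u, 1, evolution_params(v = -0.5, max_iters = 40, tol = 0))
  shrink <- evolve(u, 1, evolution_params(v = 0.5, max_iters = 40, tol = 0))
  expect_gt(sum(grow < 0), sum(u < 0))
  expect_lt(sum(shrink < 0), sum(u < 0))
})

test_that("evolution stays finite over long runs at the stable time step", {
  set.seed(6)
  u <- init_levelset(matrix(runif(48 * 48) < 0.3, 48, 48))
  g <- matrix(runif(48 * 48, 0.2, 1), 48, 48)
  ev <- evolve(u, g, evolution_params(v = 0.2, dt = 0.25, max_iters = 1000,
                                      tol = 0))
  expect_true(all(is.finite(ev)))
})

test_that("contours lock onto strong edges within 2 px across seeds", {
  errs <- sapply(1:10, function(s) {
    set.seed(s)
    r_true <- runif(1, 10, 14)
    c0 <- 32 + runif(2, -3, 3)
    surface <- outer(1:64, 1:64, function(i, j) {
      0.05 + 0.9 / (1 + exp(((i - c0[1])^2 + (j - c0[2])^2 - r_true^2) / 6))
    }) + matrix(rnorm(64 * 64, 0, 0.01), 64, 64)
    g <- stopping_map(surface, smoothing_sigma = 1.5)
    # start 10 px outside the disk and let curvature + edge terms lock on
    init <- outer(1:64, 1:64, function(i, j) {
      (i - c0[1])^2 + (j - c0[2])^2 <= (r_true + 10)^2
    })
    ev <- evolve(init_levelset(init), g,
                 evolution_params(v = 0.3, max_iters = 300, tol = 1e-4))
    cont <- extract_contours(ev, min_length = 8)
    radii <- sqrt((cont[[1]][, 1] - c0[1])^2 + (cont[[1]][, 2] - c0[2])^2)
    mean(abs(radii - r_true))
  })
  expect_lt(max(errs), 2)
})

test_that("an annulus splits into two contours around two separated disks", {
  # topology change: one initial contour, two dark objects
  c1 <- c(24, 24); c2 <- c(24, 56)
  surface <- outer(1:48, 1:80, function(i, j) {
    0.05 + 0.9 / (1 + exp(((i - c1[1])^2 + (j - c1[2])^2 - 64) / 5)) +
      0.9 / (1 + exp(((i - c2[1])^2 + (j - c2[2])^2 - 64) / 5))
  })
  g <- stopping_map(surface, smoothing_sigma = 1.5)
  init <- outer(1:48, 1:80, function(i, j) {
    (i - 24)^2 + ((j - 40) * 0.55)^2 <= 21^2
  })
  ev <- evolve(init_levelset(init), g,
               evolution_params(v = 0.4, max_iters = 400, tol = 1e-4))
  lab <- label_components(ev < 0, 8)
  expect_equal(max(lab), 2)
})

test_that("contour extraction returns closed sub-pixel paths", {
  # analytic signed distance field of a radius-10 disk
  u <- outer(1:41, 1:41, function(i, j) sqrt((i - 21)^2 + (j - 21)^2) - 10)
  cont <- extract_contours(u)
  expect_length(cont, 1)
  path <- cont[[1]]
  expect_equal(path[1, ], path[nrow(path), ])  # closed
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  expect_lt(abs(sum(seg) - 2 * pi * 10) / (2 * pi * 10), 0.05)

  expect_identical(extract_contours(matrix(1, 8, 8) + 0), list())
  # determinism under a no-op shift
  expect_identical(extract_contours(u), extract_contours(u + 0))

  # the signed-distance initialization also yields a single closed loop
  cont2 <- extract_contours(init_levelset(disk_mask(41, 10)))
  expect_length(cont2, 1)
})
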
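test_that("weighted moments match the naive double loop", {
  px <- matrix(0, 6, 6); f <- matrix(0, 6, 6)
  px[3, 4] <- 1; f[3, 4] <- 1
  expect_equal(weighted_moment(px, f, 0, 0), 1)
  expect_equal(weighted_moment(px, f, 1, 0), 3)
  expect_equal(weighted_moment(px, f, 0, 1), 4)

  # uniform square centered at (5, 5): first moments give the center
  px <- matrix(0, 9, 9); px[3:7, 3:7] <- 1
  f <- px
  expect_equal(weighted_moment(px, f, 1, 0) / weighted_moment(px, f, 0, 0), 5)

  set.seed(20)
  px <- matrix(runif(30 * 40), 30, 40)
  f <- matrix(runif(30 * 40), 30, 40)
  for (pq in list(c(0, 0), c(1, 0), c(0, 1), c(2, 1))) {
    expect_equal(weighted_moment(px, f, pq[1], pq[2]),
                 oracle_moment(px, f, pq[1], pq[2]))
  }
})

test_that("center of gravity follows the weighted moments", {
  px <- matrix(0, 12, 12); f <- matrix(0, 12, 12)
  px[7, 9] <- 0.5; f[7, 9] <- 0.8
  expect_equal(estimate_center(px, f), c(7, 9))

  px2 <- matrix(0, 12, 12); f2 <- matrix(0, 12, 12)
  px2[c(1, 11), 4] <- 1; f2[c(1, 11), 4] <- 1
  expect_equal(estimate_center(px2, f2), c(6, 4))

  expect_error(estimate_center(px * 0, f), class = "epifat_empty_cluster")
})

test_that("center of gravity lands near the generating center on a soft ring", {
  field <- make_ring_field(c(560, 560), c(280, 280), 30 * pi / 180,
                           a = 270, b = 210, wsd = 0.05, seed = 3)
  ones <- matrix(1, 560, 560)
  expect_equal(estimate_center(ones, field), c(280, 280), tolerance = 2 / 280)
})

test_that("PCA orientation recovers axis-aligned and rotated clouds", {
  f <- matrix(0, 50, 50); f[5:45, 25] <- 1      # spread along rows (x-axis)
  expect_equal(as.numeric(estimate_orientation(f)), 0, tolerance = 1e-9)
  f2 <- matrix(0, 50, 50); f2[25, 5:45] <- 1    # spread along columns
  expect_equal(as.numeric(estimate_orientation(f2)), pi / 2, tolerance = 1e-9)

  expect_warning(estimate_orientation(matrix(c(0, 1, 0, 0), 2, 2)),
                 "degenerate")
})

test_that("orientation is invariant to uniform weight scaling", {
  field <- make_ring_field(c(300, 300), c(150, 150), 0.6, a = 110, b = 70,
                           wsd = 0.03, seed = 5)
  for (mode in c("weighted_average", "weighted_coords")) {
    p1 <- as.numeric(estimate_orientation(field, loading = 1e-12, mode = mode))
    p2 <- as.numeric(estimate_orientation(field * 0.37, loading = 1e-12, mode = mode))
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("coordinate transform is the centered rotation and an isometry", {
  ctr <- c(12, 7)
  expect_equal(unname(transform_coords(rbind(ctr), 0.7, ctr)), cbind(0, 0))
  # phi0 = 0: pure translation
  expect_equal(unname(transform_coords(rbind(c(15, 9)), 0, ctr)), cbind(3, 2))
  # phi0 = pi/2 applied to (xc + 1, yc): lands at (0, -1)
  expect_equal(unname(transform_coords(rbind(ctr + c(1, 0)), pi / 2, ctr)),
               cbind(0, -1), tolerance = 1e-12)

  set.seed(21)
  pts <- matrix(rnorm(40, sd = 20), 20, 2)
  tp <- transform_coords(pts, 1.1, c(3, -4))
  expect_equal(as.vector(dist(tp)), as.vector(dist(pts)), tolerance = 1e-9)
  # round trip through the inverse
  back <- epifat:::inverse_transform_coords(tp, 1.1, c(3, -4))
  expect_equal(unname(back), unname(pts), tolerance = 1e-9)
})

test_that("axis fit recovers noise-free elliptical data exactly", {
  phi <- seq(0, 2 * pi, length.out = 721)[-721]
  xt <- 300 * cos(phi); yt <- 250 * sin(phi)
  fit <- fit_axes(xt, yt, bounds = c(200, 450))
  expect_lt(abs(fit$a - 300), 1e-3)
  expect_lt(abs(fit$b - 250), 1e-3)
  expect_lt(fit$objective, 1e-6)

  # circular cloud: both axes equal the radius
  r <- 320
  fitc <- fit_axes(r * cos(phi), r * sin(phi), bounds = c(200, 450))
  expect_lt(abs(fitc$a - r), 1e-4)
  expect_lt(abs(fitc$b - r), 1e-4)

  expect_error(fit_axes(xt, yt, w = rep(0, length(xt))),
               class = "epifat_empty_cluster")
})

test_that("axis fit objective is zero iff points lie on the ellipse", {
  phi <- seq(0.1, 2 * pi, length.out = 100)
  obj <- function(a, b, xt, yt) {
    t <- atan2(yt / b, xt / a)
    sum((a * cos(t) - xt)^2 + (b * sin(t) - yt)^2)
  }
  expect_lt(obj(300, 250, 300 * cos(phi), 250 * sin(phi)), 1e-20)
  expect_gt(obj(300, 250, 305 * cos(phi), 250 * sin(phi)), 1)
})

test_that("axis fit matches a 1-px grid-search oracle on weighted data", {
  set.seed(22)
  phi <- runif(400, 0, 2 * pi)
  xt <- 280 * cos(phi) + rnorm(400, sd = 6)
  yt <- 240 * sin(phi) + rnorm(400, sd = 6)
  w <- runif(400, 0.5, 1)
  fit <- fit_axes(xt, yt, w, bounds = c(200, 450))
  obj <- function(a, b) {
    t <- atan2(yt / b, xt / a)
    sum(w * ((a * cos(t) - xt)^2 + (b * sin(t) - yt)^2))
  }
  grid <- expand.grid(a = 201:449, b = 201:449)
  vals <- mapply(obj, grid$a, grid$b)
  best <- grid[which.min(vals), ]
  expect_lte(abs(fit$a - best$a), 1)
  expect_lte(abs(fit$b - best$b), 1)
  expect_lte(fit$objective, min(vals) + 1e-6)
})

test_that("axis fit stays within 5 px under weight noise", {
  set.seed(23)
  phi <- seq(0, 2 * pi, length.out = 2001)[-2001]
  xt <- 300 * cos(phi); yt <- 250 * sin(phi)
  w <- pmax(1 + rnorm(length(phi), sd = 0.1), 0)
  fit <- fit_axes(xt, yt, w, bounds = c(200, 450))
  expect_lt(abs(fit$a - 300), 5)
  expect_lt(abs(fit$b - 250), 5)
})

test_that("full ellipse recovery from a noisy soft ring is within tolerance", {
  a <- 270; b <- 210; phi0 <- 30 * pi / 180; ctr <- c(280, 280)
  field <- make_ring_field(c(560, 560), ctr, phi0, a, b, wsd = 0.05, seed = 7)
  ones <- matrix(1, 560, 560)
  ell <- fit_referent_ellipse(ones, field, bounds = c(150, 400))
  expect_lt(abs(ell$center[1] - ctr[1]), 2)
  expect_lt(abs(ell$center[2] - ctr[2]), 2)
  expect_lt(abs(ell$phi0 - phi0) * 180 / pi, 3)
  expect_lt(abs(ell$a - a), 5)
  expect_lt(abs(ell$b - b), 5)
  expect_s3_class(ell, "referent_ellipse")
  expect_named(coef(ell), c("x_c", "y_c", "phi0", "a", "b"))
})
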
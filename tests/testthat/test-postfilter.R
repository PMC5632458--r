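test_that("alpha-cut is inclusive at the cut level and antitone in alpha", {
  f <- matrix(c(0.2, 0.7, 0.71, 0.69), 2, 2)
  cut <- alpha_cut(f, 0.7)
  expect_equal(cut, matrix(c(0L, 1L, 1L, 0L), 2, 2))   # mu == alpha retained

  expect_equal(sum(alpha_cut(matrix(0.6, 4, 4), 0.7)), 0L)

  for (s in 1:5) {
    set.seed(s)
    f <- matrix(runif(400), 20, 20)
    hi <- alpha_cut(f, 0.8); lo <- alpha_cut(f, 0.5)
    expect_true(all(hi <= lo))                          # higher cut is a subset
    expect_true(all(hi %in% c(0L, 1L)))
  }
  expect_error(alpha_cut(f, 0), class = "epifat_degenerate_input")
  expect_error(alpha_cut(f, 1), class = "epifat_degenerate_input")
})

test_that("ring distance is the radial gap to the ellipse at the point's angle", {
  a <- 220; b <- 180
  phi <- seq(0, 2 * pi, length.out = 37)[-37]
  rre <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  on_ellipse <- ellipse_ring_distance(rre * cos(phi), rre * sin(phi), a, b)
  expect_true(all(on_ellipse < 1e-9))

  # circle case: distance is just the radial offset
  expect_equal(ellipse_ring_distance(105, 0, 100, 100), 5)
  expect_equal(ellipse_ring_distance(0, -95, 100, 100), 5)

  # dense-parametric-sampling oracle
  set.seed(30)
  xt <- rnorm(50, sd = 150); yt <- rnorm(50, sd = 150)
  expect_equal(ellipse_ring_distance(xt, yt, a, b),
               oracle_ring_distance(xt, yt, a, b), tolerance = 0.1 / 100)

  # center point convention
  expect_equal(ellipse_ring_distance(0, 0, a, b), b)

  # literal printed forms under mode = "as_printed"
  p <- atan2(40, 30)
  expect_equal(ellipse_ring_distance(30, 40, a, b, mode = "as_printed"),
               abs((30^2 * cos(p)^2 + 40^2 * sin(p)^2) -
                   (a^2 * cos(p)^2 + b^2 * sin(p)^2)))
})

test_that("control angles interpolate linearly and clamp outside the range", {
  ctr <- data.frame(slice_index = c(0, 10), phi1 = c(0, pi / 2), phi2 = c(pi, pi))
  expect_equal(interpolate_control_angles(ctr, 5)$phi1, pi / 4)
  expect_equal(interpolate_control_angles(ctr, 0)$phi1, 0)      # exact at control
  expect_equal(interpolate_control_angles(ctr, 10)$phi1, pi / 2)
  expect_equal(interpolate_control_angles(ctr, -3)$phi1, 0)     # clamped below
  expect_equal(interpolate_control_angles(ctr, 25)$phi1, pi / 2)

  # three controls: piecewise-linear between the 2nd and 3rd
  c3 <- data.frame(slice_index = c(1, 5, 9), phi1 = c(0.2, 0.6, 1.0),
                   phi2 = c(1.0, 2.0, 2.4))
  got <- interpolate_control_angles(c3, 7)
  expect_equal(got$phi1, 0.6 + (1.0 - 0.6) * 0.5)
  expect_equal(got$phi2, 2.0 + (2.4 - 2.0) * 0.5)

  expect_error(interpolate_control_angles(data.frame(), 1),
               class = "epifat_missing_controls")
  bad <- data.frame(slice_index = c(3, 1), phi1 = c(0, 0), phi2 = c(1, 1))
  expect_error(interpolate_control_angles(bad, 1),
               class = "epifat_missing_controls")
})

test_that("desirable-part filtering applies the arc and ring predicates exactly", {
  ell <- structure(list(center = c(32, 32), phi0 = 0.4, a = 20, b = 15),
                   class = "referent_ellipse")
  set.seed(31)
  crisp <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  arc <- list(phi1 = 0.5, phi2 = 4.5)
  out <- filter_desirable(crisp, ell, arc, epsilon = 6)

  # brute-force per-pixel oracle
  want <- matrix(0L, 64, 64)
  for (i in 1:64) {
    for (j in 1:64) {
      if (crisp[i, j] == 0) next
      dx <- i - 32; dy <- j - 32
      xt <- cos(0.4) * dx + sin(0.4) * dy
      yt <- -sin(0.4) * dx + cos(0.4) * dy
      phi <- atan2(yt, xt) %% (2 * pi)
      rho <- sqrt(xt^2 + yt^2)
      rre <- 20 * 15 / sqrt((15 * cos(phi))^2 + (20 * sin(phi))^2)
      if (phi >= 0.5 && phi <= 4.5 && abs(rho - rre) <= 6) want[i, j] <- 1L
    }
  }
  expect_equal(out, want)
  expect_true(all(out <= crisp))

  # monotone in epsilon and in arc width
  expect_true(all(out <= filter_desirable(crisp, ell, arc, epsilon = 10)))
  expect_true(all(filter_desirable(crisp, ell, list(phi1 = 1, phi2 = 4), 6) <= out))

  # a pixel exactly on the ellipse at distance epsilon boundary is retained
  pt <- c(32 + 26 * cos(0.4), 32 + 26 * sin(0.4))  # 6 px outside along the a-axis
  one <- matrix(0L, 64, 64); one[round(pt[1]), round(pt[2])] <- 1L
  d <- ellipse_ring_distance(
    transform_coords(rbind(round(pt)), 0.4, c(32, 32))[, 1],
    transform_coords(rbind(round(pt)), 0.4, c(32, 32))[, 2], 20, 15)
  kept <- filter_desirable(one, ell, list(phi1 = 0, phi2 = 2 * pi), epsilon = d)
  expect_equal(sum(kept), 1L)                      # inclusive at d == epsilon
})

test_that("arc predicate supports spans crossing the positive x-axis", {
  ell <- structure(list(center = c(20, 20), phi0 = 0, a = 10, b = 10),
                   class = "referent_ellipse")
  crisp <- matrix(1L, 40, 40)
  # arc from 330 to 390 degrees: points near angle 0 retained, angle 180 not
  arc <- list(phi1 = 330 * pi / 180, phi2 = 390 * pi / 180)
  out <- filter_desirable(crisp, ell, arc, epsilon = 2)
  expect_equal(out[30, 20], 1L)   # angle 0, on the circle
  expect_equal(out[10, 20], 0L)   # angle pi
})

test_that("closure fills small gaps, is idempotent, and keeps empties empty", {
  expect_equal(sum(close_mask(matrix(0L, 20, 20), 5)), 0L)

  m <- matrix(0L, 40, 40)
  m[18:22, 10:16] <- 1L
  m[18:22, 20:26] <- 1L             # 3-px gap, below the SE diameter
  closed <- close_mask(m, 7)
  expect_equal(max(EBImage::bwlabel(closed)), 1)   # merged into one component
  expect_true(all(m <= closed))
  expect_equal(close_mask(closed, 7), closed)      # idempotent
})

test_that("control-angle calibration recovers the reference arc in the fitted frame", {
  # truth: a circular ring sector between angles 1 and 4 rad around (40, 40)
  truth <- matrix(0L, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    dx <- i - 40; dy <- j - 40
    r <- sqrt(dx^2 + dy^2); phi <- atan2(dy, dx) %% (2 * pi)
    if (r >= 18 && r <= 22 && phi >= 1 && phi <= 4) truth[i, j] <- 1L
  }
  fit <- structure(list(
    mask = array(truth, dim = c(80, 80, 1)),
    ellipses = data.frame(slice_index = 1, x_c = 40, y_c = 40, phi0 = 0,
                          a = 20, b = 20)
  ), class = "efseg")
  ctr <- calibrate_control_angles(fit, truth)
  expect_equal(ctr$phi1, 1, tolerance = 0.08)
  expect_equal(ctr$phi2, 4, tolerance = 0.08)
})
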
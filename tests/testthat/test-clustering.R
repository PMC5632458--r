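test_that("patch sampling enumerates exactly the valid stride-grid centers", {
  expect_equal(nrow(sample_patches(matrix(1L, 9, 9), R = 3, stride = 1)$centers), 49L)

  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(sample_patches(one, R = 3, stride = 1)$centers,
               cbind(3L, 3L), ignore_attr = TRUE)
  edge <- matrix(0L, 5, 5); edge[1, 1] <- 1L   # window would leave the image
  expect_error(sample_patches(edge, R = 3, stride = 1), class = "epifat_no_patches")

  # exhaustive-enumeration oracle on a random ROI
  set.seed(4)
  roi <- matrix(rbinom(40 * 50, 1, 0.4), 40, 50)
  got <- sample_patches(roi, R = 5, stride = 2)$centers
  want <- NULL
  for (i in seq(3, 38, by = 2)) {
    for (j in seq(3, 48, by = 2)) {
      if (roi[i, j] == 1L) want <- rbind(want, c(i, j))
    }
  }
  expect_equal(got[order(got[, 1], got[, 2]), ],
               want[order(want[, 1], want[, 2]), ], ignore_attr = TRUE)
})

test_that("patch features are the mean and biased variance", {
  expect_equal(patch_features(matrix(3.7, 5, 5)), c(3.7, 0))
  expect_equal(patch_features(matrix(c(0, 0, 1, 1), 2, 2)), c(0.5, 0.25))
  set.seed(5)
  w <- matrix(rnorm(25), 5, 5)
  expect_equal(patch_features(w), c(mean(w), sum((w - mean(w))^2) / 25))

  # vectorized feature matrix equals the per-patch computation
  px <- matrix(runif(30 * 30), 30, 30)
  ps <- sample_patches(matrix(1L, 30, 30), R = 5, stride = 3)
  fm <- epifat:::patch_feature_matrix(px, ps)
  for (k in seq_len(nrow(ps$centers))) {
    ctr <- ps$centers[k, ]
    expect_equal(unname(fm[k, ]),
                 patch_features(px[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2)]))
  }
})

test_that("fuzzy c-means honours its contracts and matches an independent FCM", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2), matrix(rnorm(200, 6, 0.1), 100, 2))
  cl <- fuzzy_c_means(x, C = 2, seed = 1)

  expect_lte(cl$sum_dev, 1e-9)                     # memberships sum to 1, every iteration
  expect_true(all(diff(cl$objective) <= 1e-9))     # objective non-increasing
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  # two tight well-separated blobs: each point strongly in its own cluster
  expect_true(all(apply(cl$membership, 1, max) >= 0.99))

  # independent cross-check: e1071::cmeans finds the same centers
  skip_if_not_installed("e1071")
  ref <- e1071::cmeans(x, centers = 2, m = 2)
  match_order <- if (sum((cl$centers[1, ] - ref$centers[1, ])^2) <
                     sum((cl$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(cl$centers), unname(ref$centers[match_order, ]),
               tolerance = 1e-3)
})

test_that("fuzzy c-means is bit-reproducible and validates its inputs", {
  set.seed(11)
  x <- matrix(rnorm(600), 300, 2)
  a <- fuzzy_c_means(x, C = 3, seed = 42, n_init = 2)
  b <- fuzzy_c_means(x, C = 3, seed = 42, n_init = 2)
  expect_identical(a$membership, b$membership)
  expect_identical(a$centers, b$centers)

  expect_error(fuzzy_c_means(x[1:2, ], C = 3), class = "epifat_insufficient_data")
  expect_error(fuzzy_c_means(x, C = 1), class = "epifat_insufficient_data")
  expect_error(fuzzy_c_means(x, C = 2, m = 1), class = "epifat_degenerate_input")
})

test_that("a feature point coincident with a cluster center gets membership 1", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(10, 0), c(10, 0))
  cl <- fuzzy_c_means(x, C = 3, seed = 0)
  # converged centers sit on the duplicated points; zero distance => crisp
  for (k in seq_len(nrow(x))) {
    expect_equal(max(cl$membership[k, ]), 1)
    expect_equal(sum(cl$membership[k, ]), 1)
  }
})

test_that("cluster selection minimizes distance to the pondered mean", {
  # two clusters with crisp memberships: pondered (normalized) means are the
  # cluster centroids (0,0) and (1,1); u* = (0.1, 0.1) is nearer the first
  fake <- structure(list(
    membership = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
    features_std = rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  ), class = "fuzzy_clustering")
  sel <- select_cluster(fake, c(0.1, 0.1))
  expect_equal(as.integer(sel), 1L)
  expect_equal(unname(attr(sel, "distances")), c(2 * 0.1^2, 2 * 0.9^2))

  # exact match: distance 0, ties broken to the lowest index
  sel2 <- select_cluster(fake, c(1, 1))
  expect_equal(as.integer(sel2), 2L)
  expect_equal(min(attr(sel2, "distances")), 0)

  # as-printed pondering divides by Q instead of the membership sum
  sel3 <- select_cluster(fake, c(0.5, 0.5), pondered_mean = "as_printed")
  expect_equal(unname(attr(sel3, "distances")),
               c(sum((c(0.5, 0.5) - c(0, 0))^2), sum((c(0.5, 0.5) - c(0.5, 0.5))^2)))
})

test_that("cluster selection and its pixel field are invariant to relabeling", {
  set.seed(12)
  px <- matrix(runif(40 * 40), 40, 40)
  ps <- sample_patches(matrix(1L, 40, 40), R = 5, stride = 2)
  cl <- cluster_patches(px, ps, C = 3, seed = 3, n_init = 1)
  us <- reference_feature(px, c(20, 20), cl)
  sel <- select_cluster(cl, us)
  field <- pixelwise_membership(cl, sel, c(40, 40))

  perm <- c(3, 1, 2)
  cl2 <- cl
  cl2$membership <- cl$membership[, perm]
  cl2$centers <- cl$centers[perm, ]
  sel2 <- select_cluster(cl2, us)
  expect_equal(perm[as.integer(sel2)], as.integer(sel))
  expect_equal(pixelwise_membership(cl2, sel2, c(40, 40)), field)
})

test_that("pixel-wise membership averages exactly over covering patches", {
  # one patch covering a pixel: the pixel inherits its membership
  one <- structure(list(
    membership = matrix(c(0.8, 0.2), 1, 2),
    patches = list(centers = cbind(3L, 3L), R = 3L)
  ), class = "fuzzy_clustering")
  f1 <- pixelwise_membership(one, 1L, c(5, 5))
  expect_equal(f1[3, 3], 0.8)
  expect_equal(f1[4, 4], 0.8)
  expect_equal(f1[1, 1], 0)     # covered by no patch

  # two overlapping patches: mean of 0.2 and 0.6 is 0.4
  two <- structure(list(
    membership = matrix(c(0.2, 0.6, 0.8, 0.4), 2, 2),
    patches = list(centers = rbind(c(3L, 3L), c(4L, 4L)), R = 3L)
  ), class = "fuzzy_clustering")
  f2 <- pixelwise_membership(two, 1L, c(6, 6))
  expect_equal(f2[3, 3], 0.4)
  expect_equal(f2[2, 2], 0.2)
  expect_equal(f2[5, 5], 0.6)

  # brute-force accumulation oracle on a 64x64 instance
  set.seed(13)
  roi <- matrix(1L, 64, 64)
  ps <- sample_patches(roi, R = 5, stride = 2)
  mu <- runif(nrow(ps$centers))
  cl <- structure(list(membership = cbind(mu), patches = ps),
                  class = "fuzzy_clustering")
  field <- pixelwise_membership(cl, 1L, c(64, 64))
  expect_equal(field, oracle_pixel_membership(ps$centers, mu, 5, c(64, 64)))
  # values bounded by the contributing memberships
  expect_gte(min(field[field > 0]), min(mu))
  expect_lte(max(field), max(mu))

  # support restricted to the ROI mask when one is given
  roi2 <- matrix(0L, 64, 64); roi2[20:40, 20:40] <- 1L
  field2 <- pixelwise_membership(cl, 1L, c(64, 64), roi = roi2)
  expect_true(all(field2[roi2 == 0L] == 0))
})
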
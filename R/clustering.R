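#' Sample texture patches inside the region of interest
#'
#' Returns the centers of all `R x R` patches on a regular stride grid whose
#' window lies fully inside the image and whose center pixel belongs to the
#' ROI mask.
#'
#' @param roi binary ROI mask (matrix of 0/1).
#' @param R odd patch side length in pixels.
#' @param stride grid step in pixels (>= 1). Strides smaller than `R`
#'   produce overlapping patches, which is what makes the pixel-wise
#'   membership averaging of [pixelwise_membership()] non-trivial.
#' @return A `patch_set`: list with `centers` (Q x 2 matrix of 1-based
#'   `(row, col)` centers), `R` and `stride`.
#' @examples
#' roi <- matrix(1L, 9, 9)
#' nrow(sample_patches(roi, R = 3, stride = 1)$centers)  # 49
#' @export
sample_patches <- function(roi, R = 5, stride = 2) {
  roi <- as_mask(roi)
  if (R %% 2L != 1L || R < 1L) stop_epifat("R must be odd and positive", "degenerate_input")
  if (stride < 1L) stop_epifat("stride must be >= 1", "degenerate_input")
  h <- (R - 1L) %/% 2L
  M <- nrow(roi); N <- ncol(roi)
  if (M < R || N < R) stop_epifat("image smaller than one patch", "no_patches")
  ci <- seq.int(1L + h, M - h, by = stride)
  cj <- seq.int(1L + h, N - h, by = stride)
  centers <- cbind(rep(ci, times = length(cj)), rep(cj, each = length(ci)))
  keep <- roi[centers] == 1L
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) == 0L) {
    stop_epifat("ROI too small to host any patch", "no_patches")
  }
  structure(list(centers = centers, R = as.integer(R), stride = as.integer(stride)),
            class = "patch_set")
}

#' Mean/variance texture features of one patch
#'
#' The feature vector of an `R x R` luminance window `U` is
#' `u1 = mean(U)` and `u2 = (1/R^2) * sum((U - u1)^2)`, the biased patch
#' variance.
#'
#' @param patch numeric `R x R` matrix.
#' @return Numeric length-2 vector `c(u1, u2)`.
#' @examples
#' patch_features(matrix(c(0, 0, 1, 1), 2, 2))  # c(0.5, 0.25)
#' @export
patch_features <- function(patch) {
  u1 <- mean(patch)
  c(u1, mean((patch - u1)^2))
}

# Feature matrix for a whole patch set, vectorized over the R^2 window
# offsets: one pass accumulating sums and sums of squares at every center.
patch_feature_matrix <- function(pixels, patches) {
  centers <- patches$centers
  h <- (patches$R - 1L) %/% 2L
  n2 <- patches$R^2
  S <- numeric(nrow(centers)); S2 <- numeric(nrow(centers))
  for (di in -h:h) {
    for (dj in -h:h) {
      v <- pixels[cbind(centers[, 1L] + di, centers[, 2L] + dj)]
      S <- S + v
      S2 <- S2 + v * v
    }
  }
  u1 <- S / n2
  u2 <- pmax(S2 / n2 - u1^2, 0)
  cbind(u1 = u1, u2 = u2)
}

#' Fuzzy c-means clustering of patch features
#'
#' Standard fuzzy c-means with fuzzifier `m`: soft memberships
#' `mu[k, c] in [0, 1]` summing to 1 over clusters for every sample, cluster
#' centers updated as membership^m weighted means, iterated until the
#' maximum center displacement falls below `tol` or `max_iter` is reached.
#' Initialization draws `C` distinct feature vectors under a private RNG
#' seed, so a fixed seed makes the whole run bit-reproducible. The
#' per-iteration objective `J = sum(mu^m * d^2)` and the worst per-sample
#' membership-sum deviation are recorded so the algorithm's contracts can
#' be audited.
#'
#' @param x Q x p feature matrix (standardize features beforehand when the
#'   dimensions live on different scales; see [cluster_patches()]).
#' @param C number of clusters (>= 2).
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on the max center displacement.
#' @param max_iter iteration cap.
#' @param seed integer RNG seed for center initialization.
#' @param n_init number of restarts from distinct deterministic
#'   initializations (seeds `seed`, `seed + 1`, ...); the run with the
#'   lowest final objective is kept. Restarting is the standard guard
#'   against the local minima of the c-means objective (e.g. two tissue
#'   groups merged into one cluster).
#' @return A `fuzzy_clustering`: list with `membership` (Q x C), `centers`
#'   (C x p), `objective` (per-iteration trace), `sum_dev` (worst
#'   membership-sum deviation from 1 across all iterations), `iterations`,
#'   `converged`.
#' @export
fuzzy_c_means <- function(x, C, m = 2, tol = 1e-5, max_iter = 300, seed = 0,
                          n_init = 1) {
  if (n_init > 1) {
    runs <- lapply(seq_len(n_init) - 1L, function(k) {
      fuzzy_c_means(x, C, m = m, tol = tol, max_iter = max_iter,
                    seed = seed + k, n_init = 1)
    })
    finals <- vapply(runs, function(r) r$objective[length(r$objective)], numeric(1))
    best <- runs[[which.min(finals)]]
    best$restart_objectives <- finals
    return(best)
  }
  x <- as.matrix(x)
  Q <- nrow(x)
  if (C < 2L) stop_epifat("need at least two clusters", "insufficient_data")
  if (m <= 1) stop_epifat("fuzzifier m must exceed 1", "degenerate_input")
  if (Q < C) stop_epifat(sprintf("%d samples cannot support %d clusters", Q, C),
                         "insufficient_data")

  # private RNG stream so clustering never disturbs the caller's RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  ux <- unique(x)
  if (nrow(ux) < C) {
    stop_epifat("fewer distinct feature vectors than clusters", "insufficient_data")
  }
  centers <- ux[sample.int(nrow(ux), C), , drop = FALSE]

  expo <- 1 / (m - 1)
  objective <- numeric(0)
  sum_dev <- 0
  converged <- FALSE
  it <- 0L
  u <- NULL
  d2 <- matrix(0, Q, C)
  while (it < max_iter) {
    it <- it + 1L
    for (cc in seq_len(C)) {
      d2[, cc] <- rowSums((x - matrix(centers[cc, ], Q, ncol(x), byrow = TRUE))^2)
    }
    w <- d2^(-expo)
    u <- w / rowSums(w)
    # zero-distance samples: crisp membership shared among coincident centers
    zero <- d2 <= .Machine$double.xmin
    hit <- rowSums(zero) > 0L
    if (any(hit)) {
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    sum_dev <- max(sum_dev, max(abs(rowSums(u) - 1)))
    um <- u^m
    objective <- c(objective, sum(um * d2))
    new_centers <- crossprod(um, x) / colSums(um)
    disp <- max(abs(new_centers - centers))
    centers <- new_centers
    if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(membership = u, centers = centers, m = m,
                 objective = objective, sum_dev = sum_dev,
                 iterations = it, converged = converged),
            class = "fuzzy_clustering")
}

#' Cluster the patches of one slice
#'
#' Convenience wrapper: computes mean/variance features for a patch set,
#' z-scores each feature dimension over the patch set (mean and variance
#' live on different scales), and runs [fuzzy_c_means()]. The z-transform
#' is kept so the reference-patch feature can be mapped into the same
#' standardized space.
#'
#' @param pixels enhanced slice matrix.
#' @param patches a `patch_set` from [sample_patches()].
#' @inheritParams fuzzy_c_means
#' @return A `fuzzy_clustering` with extra fields `features` (raw Q x 2),
#'   `features_std`, `scale_center`, `scale_sd`, and the `patches`.
#' @export
cluster_patches <- function(pixels, patches, C = 6, m = 2, tol = 1e-5,
                            max_iter = 300, seed = 0, n_init = 3) {
  pixels <- slice_pixels(pixels)
  feats <- patch_feature_matrix(pixels, patches)
  ctr <- colMeans(feats)
  sds <- apply(feats, 2L, stats::sd)
  sds[!is.finite(sds) | sds <= 0] <- 1
  fstd <- sweep(sweep(feats, 2L, ctr), 2L, sds, "/")
  cl <- fuzzy_c_means(fstd, C = C, m = m, tol = tol, max_iter = max_iter,
                      seed = seed, n_init = n_init)
  cl$features <- feats
  cl$features_std <- fstd
  cl$scale_center <- ctr
  cl$scale_sd <- sds
  cl$patches <- patches
  cl
}

#' Extract and standardize the reference-patch feature
#'
#' Computes the mean/variance feature of the `R x R` reference patch
#' centered at the user's seed point and maps it with the z-transform of a
#' fitted clustering so it is comparable to the standardized patch features.
#'
#' @param pixels enhanced slice matrix holding the seed point.
#' @param seed_point length-2 `(row, col)` center of the reference patch.
#' @param clustering a `fuzzy_clustering` from [cluster_patches()].
#' @return Standardized length-2 feature vector of the reference patch.
#' @export
reference_feature <- function(pixels, seed_point, clustering) {
  pixels <- slice_pixels(pixels)
  R <- clustering$patches$R
  h <- (R - 1L) %/% 2L
  i <- as.integer(seed_point[1]); j <- as.integer(seed_point[2])
  if (i - h < 1L || j - h < 1L || i + h > nrow(pixels) || j + h > ncol(pixels)) {
    stop_epifat("reference patch does not fit inside the image", "degenerate_input")
  }
  u <- patch_features(pixels[(i - h):(i + h), (j - h):(j + h)])
  (u - clustering$scale_center) / clustering$scale_sd
}

#' Select the epicardial-fat cluster from the seed patch
#'
#' For each cluster `c` the membership-pondered mean feature is computed and
#' the cluster minimizing the squared distance to the reference-patch
#' feature is selected; ties break towards the lowest cluster index.
#'
#' Two ponderings are available. `"as_printed"` divides the
#' membership-weighted feature sum by the number of patches `Q`, which
#' shrinks every cluster mean towards the origin by its membership mass
#' fraction. `"normalized"` divides by the membership sum, i.e. the
#' conventional weighted mean in feature space; this is the default because
#' the `1/Q` pondering makes the comparison depend on cluster size rather
#' than cluster location (see the methods vignette for the analysis).
#'
#' @param clustering a `fuzzy_clustering`.
#' @param u_star standardized reference feature ([reference_feature()]).
#' @param pondered_mean `"normalized"` (default) or `"as_printed"`.
#' @return Integer index of the selected cluster, with attribute
#'   `"distances"` holding the per-cluster squared distances.
#' @export
select_cluster <- function(clustering, u_star,
                           pondered_mean = c("normalized", "as_printed")) {
  pondered_mean <- match.arg(pondered_mean)
  u <- clustering$membership
  x <- clustering$features_std
  Q <- nrow(u)
  wsum <- crossprod(u, x)                    # C x p membership-weighted sums
  uhat <- if (pondered_mean == "as_printed") {
    wsum / Q
  } else {
    wsum / colSums(u)
  }
  d <- colSums((t(uhat) - u_star)^2)
  res <- which.min(d)                        # which.min breaks ties low
  attr(res, "distances") <- d
  res
}

#' Pixel-wise membership field of the selected cluster
#'
#' Projects patch-level memberships back to pixels: the membership of a
#' pixel is the mean membership of all patches whose `R x R` window covers
#' it; pixels covered by no patch get 0. Optionally zeroed outside an ROI
#' mask so the field's support stays inside the region of interest.
#'
#' @param clustering a `fuzzy_clustering` carrying its `patches`.
#' @param selected cluster index (e.g. from [select_cluster()]).
#' @param dim image dimensions `c(M, N)`.
#' @param roi optional binary mask; the field is zeroed where `roi == 0`.
#' @return Numeric M x N matrix with values in \[0, 1\].
#' @export
pixelwise_membership <- function(clustering, selected, dim, roi = NULL) {
  centers <- clustering$patches$centers
  h <- (clustering$patches$R - 1L) %/% 2L
  mu <- clustering$membership[, selected]
  num <- matrix(0, dim[1], dim[2])
  den <- matrix(0, dim[1], dim[2])
  for (di in -h:h) {
    for (dj in -h:h) {
      idx <- cbind(centers[, 1L] + di, centers[, 2L] + dj)
      num[idx] <- num[idx] + mu
      den[idx] <- den[idx] + 1
    }
  }
  field <- matrix(0, dim[1], dim[2])
  cov <- den > 0
  field[cov] <- num[cov] / den[cov]
  if (!is.null(roi)) field[as_mask(roi) == 0L] <- 0
  field
}
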
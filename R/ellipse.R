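#' Luminance- and membership-weighted image moment
#'
#' Computes `M(p, q) = sum_i sum_j i^p j^q X(i, j) mu(i, j)` where `X` is
#' the pixel luminance and `mu` the membership field of the selected fuzzy
#' cluster. Coordinates are 1-based; `i` runs along rows (the x-axis of the
#' slice) and `j` along columns (the y-axis).
#'
#' @param pixels enhanced slice matrix (luminance `X`).
#' @param field membership field, same dimensions.
#' @param p,q non-negative integer moment orders.
#' @return The scalar moment value.
#' @export
weighted_moment <- function(pixels, field, p, q) {
  pixels <- slice_pixels(pixels)
  stopifnot(all(dim(pixels) == dim(field)))
  iv <- seq_len(nrow(pixels))^p
  jv <- seq_len(ncol(pixels))^q
  drop(crossprod(iv, (pixels * field) %*% jv))
}

#' Referent-ellipse center by the center-of-gravity approach
#'
#' `(x_c, y_c) = (M(1,0)/M(0,0), M(0,1)/M(0,0))` with the weighted moments
#' of [weighted_moment()].
#'
#' @inheritParams weighted_moment
#' @return Length-2 numeric `(x_c, y_c)` in pixel coordinates (row, col).
#' @export
estimate_center <- function(pixels, field) {
  m00 <- weighted_moment(pixels, field, 0, 0)
  if (!is.finite(m00) || m00 <= 0) {
    stop_epifat("empty cluster: zero total weight, center undefined", "empty_cluster")
  }
  c(weighted_moment(pixels, field, 1, 0) / m00,
    weighted_moment(pixels, field, 0, 1) / m00)
}

#' Orientation of the soft point cloud by PCA
#'
#' Builds the observation cloud of the selected fuzzy cluster, estimates
#' its 2 x 2 covariance matrix (regularized by diagonal loading
#' `epsilon * I`), and returns the angle between the principal eigenvector
#' and the image x-axis (rows), folded into \[0, pi).
#'
#' Two observation models are supported. `"weighted_average"` (default)
#' uses coordinates `c(i, j)` with `mu` as statistical weights in the mean
#' and covariance. `"weighted_coords"` uses `p = mu(i,j) * c(i, j)` —
#' membership scales the coordinates themselves — which collapses
#' low-membership pixels towards the coordinate origin and, for fields
#' with many weak supports, locks the principal axis onto the direction
#' from the origin to the cluster centroid irrespective of the cluster's
#' shape (see the methods vignette); it is kept for comparison.
#'
#' @param field membership field matrix.
#' @param roi optional binary mask restricting the observations.
#' @param loading diagonal loading epsilon; default `1e-6 * trace/2`.
#' @param mode `"weighted_average"` (default) or `"weighted_coords"`.
#' @return Orientation `phi0` in radians in \[0, pi), with attributes
#'   `"eigenvalues"` and `"reliable"` (FALSE for a degenerate cloud).
#' @export
estimate_orientation <- function(field, roi = NULL, loading = NULL,
                                 mode = c("weighted_average", "weighted_coords")) {
  mode <- match.arg(mode)
  sel <- field > 0
  if (!is.null(roi)) sel <- sel & as_mask(roi) == 1L
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) < 1L) stop_epifat("empty cluster: no supported points", "empty_cluster")
  w <- field[sel]
  if (mode == "weighted_coords") {
    pts <- idx * w                       # p_i = mu * [i, j]
    ctr <- colMeans(pts)
    dev <- sweep(pts, 2L, ctr)
    cov <- crossprod(dev) / nrow(dev)
  } else {
    ctr <- colSums(idx * w) / sum(w)
    dev <- sweep(idx, 2L, ctr)
    cov <- crossprod(dev * sqrt(w)) / sum(w)
  }
  if (is.null(loading)) loading <- 1e-6 * sum(diag(cov)) / 2
  if (!is.finite(loading) || loading <= 0) loading <- 1e-12
  cov <- cov + diag(loading, 2L)
  eg <- eigen(cov, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  phi0 <- atan2(v[2L], v[1L]) %% pi
  reliable <- nrow(idx) >= 2L && is.finite(phi0)
  if (!reliable) warning("orientation estimated from a degenerate cloud; unreliable")
  structure(phi0, eigenvalues = eg$values, reliable = reliable)
}

#' Transform coordinates into the ellipse-aligned frame
#'
#' Applies `R(-phi0) %*% (p - center)`: translation to the estimated center
#' followed by rotation by `-phi0`, so the referent ellipse becomes
#' axis-aligned and centered at the origin. The rotation is orthonormal
#' with determinant 1, hence an isometry.
#'
#' @param points n x 2 matrix of `(x, y)` = `(row, col)` coordinates.
#' @param phi0 orientation angle in radians.
#' @param center length-2 `(x_c, y_c)`.
#' @return n x 2 matrix of transformed coordinates `(xt, yt)`.
#' @export
transform_coords <- function(points, phi0, center) {
  points <- matrix(points, ncol = 2L)
  dx <- points[, 1L] - center[1L]
  dy <- points[, 2L] - center[2L]
  cbind(xt = cos(phi0) * dx + sin(phi0) * dy,
        yt = -sin(phi0) * dx + cos(phi0) * dy)
}

# Inverse of transform_coords: back to image coordinates.
inverse_transform_coords <- function(points, phi0, center) {
  points <- matrix(points, ncol = 2L)
  cbind(center[1L] + cos(phi0) * points[, 1L] - sin(phi0) * points[, 2L],
        center[2L] + sin(phi0) * points[, 1L] + cos(phi0) * points[, 2L])
}

#' Constrained least-squares fit of the ellipse axes
#'
#' In the transformed frame the referent ellipse is
#' `(a cos(phi), b sin(phi))`. The axes minimize the weighted objective
#' `sum_k w_k * ((a cos(phi_k) - xt_k)^2 + (b sin(phi_k) - yt_k)^2)` subject
#' to `B_l < a, b < B_u`, where `phi_k = atan2(yt_k / b, xt_k / a)` is the
#' parameter angle of point `k` consistent with the candidate axes (the
#' two-argument arctangent keeps the full angular range). With this
#' parameterization the objective is non-negative and vanishes exactly when
#' every weighted point lies on the ellipse at its own parameter angle, so
#' noise-free elliptical data is recovered exactly. Optimization is a
#' bounded quasi-Newton (`L-BFGS-B`) from the deterministic start given by
#' the clipped second-moment radii of the cloud.
#'
#' @param xt,yt transformed point coordinates.
#' @param w non-negative weights (typically luminance x membership).
#' @param bounds length-2 `(B_l, B_u)` axis bounds in pixels.
#' @param tol optimizer tolerance (passed as `factr`-scaled control).
#' @return List with `a`, `b`, `objective`, `start`, `convergence`.
#' @export
fit_axes <- function(xt, yt, w = NULL, bounds = c(200, 450), tol = 1e-10) {
  if (is.null(w)) w <- rep(1, length(xt))
  keep <- w > 0
  if (!any(keep)) stop_epifat("empty cluster: all weights zero", "empty_cluster")
  xt <- xt[keep]; yt <- yt[keep]; w <- w[keep]
  if (bounds[1] <= 0 || bounds[2] <= bounds[1]) {
    stop_epifat("axis bounds must satisfy 0 < B_l < B_u", "degenerate_input")
  }
  obj <- function(ab) {
    phi <- atan2(yt / ab[2], xt / ab[1])
    sum(w * ((ab[1] * cos(phi) - xt)^2 + (ab[2] * sin(phi) - yt)^2))
  }
  clip <- function(v) min(max(v, bounds[1] + 1e-6), bounds[2] - 1e-6)
  sw <- sum(w)
  start <- c(clip(sqrt(2 * sum(w * xt^2) / sw)),
             clip(sqrt(2 * sum(w * yt^2) / sw)))
  res <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = bounds[1] + 1e-6, upper = bounds[2] - 1e-6,
                      control = list(factr = tol / .Machine$double.eps, maxit = 500))
  if (res$convergence != 0 && res$value > obj(start)) {
    stop_epifat(sprintf("axis optimization failed to converge (code %d: %s)",
                        res$convergence, res$message), "non_convergence")
  }
  list(a = res$par[1L], b = res$par[2L], objective = res$value,
       start = start, convergence = res$convergence)
}

#' Fit the referent ellipse to a fuzzy cluster field
#'
#' Full geometric prior estimation for one slice: center of gravity from
#' luminance-weighted moments, orientation from PCA of the soft point
#' cloud, coordinate transform into the aligned frame, and bounded
#' least-squares estimation of the two axes with weights
#' `X(i,j) * mu(i,j)`.
#'
#' @param pixels enhanced slice matrix.
#' @param field membership field of the selected cluster.
#' @param roi optional binary ROI restricting the orientation/axis cloud.
#' @param bounds axis bounds `(B_l, B_u)` in pixels.
#' @param loading diagonal loading for the orientation covariance.
#' @param orientation_mode observation model for [estimate_orientation()].
#' @return Object of class `referent_ellipse`: list with `center`
#'   `(x_c, y_c)`, `phi0`, `a`, `b`, `objective`, `convergence`.
#' @export
fit_referent_ellipse <- function(pixels, field, roi = NULL,
                                 bounds = c(200, 450), loading = NULL,
                                 orientation_mode = "weighted_average") {
  pixels <- slice_pixels(pixels)
  center <- estimate_center(pixels, field)
  phi0 <- estimate_orientation(field, roi = roi, loading = loading,
                               mode = orientation_mode)
  sel <- field > 0
  if (!is.null(roi)) sel <- sel & as_mask(roi) == 1L
  idx <- which(sel, arr.ind = TRUE)
  w <- pixels[sel] * field[sel]
  tp <- transform_coords(idx, as.numeric(phi0), center)
  ax <- fit_axes(tp[, 1L], tp[, 2L], w = w, bounds = bounds)
  structure(list(center = center, phi0 = as.numeric(phi0),
                 a = ax$a, b = ax$b, objective = ax$objective,
                 convergence = ax$convergence,
                 orientation_reliable = isTRUE(attr(phi0, "reliable"))),
            class = "referent_ellipse")
}

#' @export
print.referent_ellipse <- function(x, ...) {
  cat(sprintf("<referent_ellipse> center (%.1f, %.1f), phi0 %.1f deg, axes a=%.1f b=%.1f px\n",
              x$center[1], x$center[2], x$phi0 * 180 / pi, x$a, x$b))
  invisible(x)
}

#' @export
coef.referent_ellipse <- function(object, ...) {
  c(x_c = object$center[1], y_c = object$center[2], phi0 = object$phi0,
    a = object$a, b = object$b)
}
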
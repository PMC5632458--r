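#' Defuzzify a membership field by alpha-cut
#'
#' The crisp cluster is the set of pixels whose membership is at least
#' `alpha` (inclusive). The cut is antitone in `alpha`: a higher level
#' always yields a subset.
#'
#' @param field membership field matrix in \[0, 1\].
#' @param alpha cut level in (0, 1).
#' @return Integer binary mask.
#' @examples
#' alpha_cut(matrix(c(0.2, 0.7, 0.71, 0.9), 2, 2), 0.7)
#' @export
alpha_cut <- function(field, alpha) {
  if (alpha <= 0 || alpha >= 1) stop_epifat("alpha must lie in (0, 1)", "degenerate_input")
  as_mask(field >= alpha)
}

#' Radial distance from points to the referent ellipse
#'
#' For points expressed in the transformed (ellipse-aligned) frame, the
#' distance is `|rho(point) - rho_RE(phi)|`: the absolute difference
#' between the point's polar radius and the ellipse's polar radius at the
#' same polar angle `phi = atan2(yt, xt)`.
#'
#' `mode = "corrected"` (default) uses the true polar radii
#' `rho = sqrt(xt^2 + yt^2)` and
#' `rho_RE(phi) = a*b / sqrt(b^2 cos^2(phi) + a^2 sin^2(phi))`.
#' `mode = "as_printed"` reproduces the literal squared forms
#' `rho = xt^2 cos^2(phi) + yt^2 sin^2(phi)` and
#' `rho_RE = a^2 cos^2(phi) + b^2 sin^2(phi)`, which are dimensionally
#' inconsistent with a radius and kept only for comparison (see the
#' methods vignette).
#'
#' A point at the exact center has an undefined polar angle; by convention
#' its distance is `min(a, b)`.
#'
#' @param xt,yt transformed point coordinates.
#' @param a,b ellipse axes.
#' @param mode `"corrected"` or `"as_printed"`.
#' @return Numeric vector of distances (px).
#' @export
ellipse_ring_distance <- function(xt, yt, a, b, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  phi <- atan2(yt, xt)
  if (mode == "corrected") {
    rho <- sqrt(xt^2 + yt^2)
    rre <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  } else {
    rho <- xt^2 * cos(phi)^2 + yt^2 * sin(phi)^2
    rre <- a^2 * cos(phi)^2 + b^2 * sin(phi)^2
  }
  d <- abs(rho - rre)
  d[xt == 0 & yt == 0] <- min(a, b)
  d
}

#' Interpolate per-slice arc constraints from control angles
#'
#' Expert control angles `(phi1, phi2)` are set on a few control slices;
#' any other slice gets the linear interpolation between its two nearest
#' controls, clamped to the nearest control outside the covered range.
#'
#' @param controls data frame with columns `slice_index`, `phi1`, `phi2`
#'   (radians), slice indices strictly increasing.
#' @param slice_index slice to query (vectorized).
#' @return Data frame with columns `slice_index`, `phi1`, `phi2`.
#' @examples
#' ctr <- data.frame(slice_index = c(0, 10), phi1 = c(0, pi / 2), phi2 = c(pi, pi))
#' interpolate_control_angles(ctr, 5)$phi1  # pi/4
#' @export
interpolate_control_angles <- function(controls, slice_index) {
  if (is.null(controls) || nrow(controls) == 0L) {
    stop_epifat("no control angles supplied", "missing_controls")
  }
  req <- c("slice_index", "phi1", "phi2")
  if (!all(req %in% names(controls))) {
    stop_epifat("controls need columns slice_index, phi1, phi2", "missing_controls")
  }
  if (is.unsorted(controls$slice_index, strictly = TRUE)) {
    stop_epifat("control slice indices must be strictly increasing", "missing_controls")
  }
  if (any(controls$phi2 < controls$phi1) || any(controls$phi1 < 0) ||
      any(controls$phi2 > controls$phi1 + 2 * pi)) {
    stop_epifat("control angles must satisfy 0 <= phi1 <= phi2 <= phi1 + 2*pi",
                "missing_controls")
  }
  interp <- function(y) {
    if (nrow(controls) == 1L) rep(y, length(slice_index))
    else stats::approx(controls$slice_index, y, xout = slice_index, rule = 2)$y
  }
  data.frame(slice_index = slice_index,
             phi1 = interp(controls$phi1),
             phi2 = interp(controls$phi2))
}

# Angular membership test with wrap-around support: phi in [0, 2*pi),
# phi2 may exceed 2*pi to describe an arc crossing the positive x-axis.
angle_in_arc <- function(phi, phi1, phi2) {
  phi <- phi %% (2 * pi)
  if (phi2 <= 2 * pi) {
    phi >= phi1 & phi <= phi2
  } else {
    phi >= phi1 | phi <= (phi2 - 2 * pi)
  }
}

#' Retain the desirable part of the crisp cluster
#'
#' Keeps only those pixels of the crisp (alpha-cut) mask whose polar angle
#' in the ellipse-aligned frame lies within the arc `[phi1, phi2]` and
#' whose radial distance to the referent ellipse is at most `epsilon`
#' (inclusive). The output is always a subset of the input and is monotone
#' in both `epsilon` and the arc width.
#'
#' @param crisp binary mask from [alpha_cut()].
#' @param ellipse a `referent_ellipse`.
#' @param arc list or one-row data frame with `phi1`, `phi2` (radians).
#' @param epsilon ring half-width in pixels.
#' @param mode distance mode, see [ellipse_ring_distance()].
#' @return Integer binary mask, subset of `crisp`.
#' @export
filter_desirable <- function(crisp, ellipse, arc, epsilon,
                             mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  crisp <- as_mask(crisp)
  out <- matrix(0L, nrow(crisp), ncol(crisp))
  idx <- which(crisp == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  tp <- transform_coords(idx, ellipse$phi0, ellipse$center)
  phi <- atan2(tp[, 2L], tp[, 1L])
  d <- ellipse_ring_distance(tp[, 1L], tp[, 2L], ellipse$a, ellipse$b, mode = mode)
  keep <- angle_in_arc(phi, arc$phi1, arc$phi2) & d <= epsilon
  out[idx[keep, , drop = FALSE]] <- 1L
  out
}

#' Calibrate control angles from a training segmentation
#'
#' Emulates the expert/training protocol for the arc constraint: control
#' angles are not geometric constants of the anatomy but angles *in the
#' transformed frame of the fitted referent ellipse*, which is where the
#' arc predicate operates. Given a fitted run on training data and the
#' corresponding reference (expert) masks, this maps every reference fat
#' pixel into the slice's fitted frame, finds the largest empty angular
#' gap, and returns the complementary arc `(phi1, phi2)` per slice —
#' exactly what an expert marking the fat span on a training slice
#' provides. The returned table feeds [interpolate_control_angles()] for
#' test data of the same kind.
#'
#' @param fit an `efseg` result on the training series.
#' @param truth reference fat masks (matrix or 3D array matching
#'   `fit$mask`).
#' @param pad widen the arc by this many radians on each side (default 0).
#' @return Data frame with `slice_index`, `phi1`, `phi2` (radians;
#'   `phi2` may exceed `2*pi` when the arc crosses the x-axis).
#' @export
calibrate_control_angles <- function(fit, truth, pad = 0) {
  if (length(dim(truth)) == 2L) truth <- array(truth, dim = c(dim(truth), 1L))
  n <- dim(fit$mask)[3]
  rows <- lapply(seq_len(n), function(k) {
    e <- fit$ellipses[k, ]
    if (!is.finite(e$a)) return(NULL)
    idx <- which(truth[, , k] == 1L, arr.ind = TRUE)
    if (nrow(idx) < 2L) return(NULL)
    tp <- transform_coords(idx, e$phi0, c(e$x_c, e$y_c))
    phi <- sort(atan2(tp[, 2L], tp[, 1L]) %% (2 * pi))
    gaps <- diff(c(phi, phi[1L] + 2 * pi))
    g <- which.max(gaps)
    phi1 <- (phi[if (g == length(phi)) 1L else g + 1L] - pad) %% (2 * pi)
    width <- 2 * pi - gaps[g] + 2 * pad
    data.frame(slice_index = k, phi1 = phi1, phi2 = phi1 + width)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop_epifat("no slice with a fitted ellipse and reference fat", "missing_controls")
  }
  out
}

#' Morphological closure of a binary mask
#'
#' Closing (dilation followed by erosion) with a disk structuring element:
#' fills gaps and concavities narrower than the disk without shrinking the
#' mask; idempotent on a second application.
#'
#' @param mask binary mask.
#' @param size disk diameter in pixels.
#' @return Integer binary mask.
#' @export
close_mask <- function(mask, size) {
  mask <- as_mask(mask)
  if (sum(mask) == 0L) return(mask)
  as_mask(EBImage::closing(mask, disc_brush(size)))
}
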
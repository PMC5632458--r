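#' Segment epicardial fat in a CT series
#'
#' End-to-end slice-by-slice segmentation: tone mapping, whole-heart ROI
#' extraction, patch-based fuzzy c-means clustering seeded by a single
#' user-marked fat patch, referent-ellipse fitting of the selected
#' cluster, and arc/ring-constrained post-filtering with morphological
#' closure. The reference patch is extracted once, on the seed slice, and
#' its feature is re-used to select the fat cluster independently on every
#' slice. Slices on which a stage fails (empty ROI, empty cluster, ...)
#' yield an empty mask with a warning instead of aborting the volume.
#'
#' The computation is fully deterministic given the series, the seed
#' point, the control angles and the configuration (all randomness flows
#' from `config$rng_seed`).
#'
#' @param series the CT series: a list of [ct_slice] objects, a 3D array
#'   (`M x N x n`), a single matrix, or a phantom volume as returned by
#'   [generate_volume()].
#' @param seed_point `(slice, row, col)` of the user-marked epicardial-fat
#'   patch center, or `(row, col)` when the series has one slice.
#' @param controls data frame of expert control angles (`slice_index`,
#'   `phi1`, `phi2` in radians) interpolated per slice; `NULL` disables
#'   the angular constraint (full-circle arc).
#' @param config an [efseg_control()] configuration.
#' @param weight optional patient body weight (kg) for the normalized
#'   volume.
#' @param keep_fields keep the per-slice fuzzy membership fields in the
#'   result (memory-heavy for long series).
#' @return Object of class `efseg`: list with `mask` (M x N x n binary
#'   array), `ellipses` (per-slice parameter data frame), `diagnostics`
#'   (per-slice status data frame), `volume` ([fat_volume()] report, with
#'   normalized volume when `weight` is given), `config` (scaled),
#'   `fields` (if kept), plus the inputs needed to reproduce the run.
#' @seealso [efseg_control()], [evaluate_segmentation()], [phantom_spec()]
#' @export
efseg <- function(series, seed_point, controls = NULL,
                  config = efseg_control(), weight = NULL,
                  keep_fields = FALSE) {
  slices <- normalize_series(series)
  n <- length(slices)
  M <- nrow(slices[[1]]$pixels); N <- ncol(slices[[1]]$pixels)
  if (!all(vapply(slices, function(s) all(dim(s$pixels) == c(M, N)), logical(1)))) {
    stop_epifat("all slices must share the same dimensions", "inconsistent_series")
  }
  if (length(seed_point) == 2L) seed_point <- c(1L, seed_point)
  seed_slice <- as.integer(seed_point[1])
  if (seed_slice < 1L || seed_slice > n) {
    stop_epifat("seed slice outside the series", "degenerate_input")
  }
  cfg <- scale_control(config, N)

  # reference patch: extracted once on the seed slice, re-used per slice
  seed_enh <- tone_map(slices[[seed_slice]]$pixels, cfg$clip_percentiles)
  u_star_raw <- {
    h <- (cfg$R - 1L) %/% 2L
    i <- as.integer(seed_point[2]); j <- as.integer(seed_point[3])
    if (i - h < 1L || j - h < 1L || i + h > M || j + h > N) {
      stop_epifat("reference patch does not fit inside the image", "degenerate_input")
    }
    patch_features(seed_enh[(i - h):(i + h), (j - h):(j + h)])
  }

  arcs <- if (is.null(controls)) {
    data.frame(slice_index = seq_len(n), phi1 = 0, phi2 = 2 * pi)
  } else {
    interpolate_control_angles(controls, seq_len(n))
  }

  mask <- array(0L, dim = c(M, N, n))
  fields <- if (keep_fields) vector("list", n) else NULL
  ell_rows <- vector("list", n)
  diag_rows <- vector("list", n)
  for (k in seq_len(n)) {
    res <- tryCatch(
      segment_one_slice(slices[[k]]$pixels, u_star_raw, arcs[k, ], cfg),
      epifat_error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("slice %d: %s (empty mask emitted)", k, conditionMessage(res)))
      ell_rows[[k]] <- data.frame(slice_index = k, x_c = NA_real_, y_c = NA_real_,
                                  phi0 = NA_real_, a = NA_real_, b = NA_real_)
      diag_rows[[k]] <- data.frame(slice_index = k, status = conditionMessage(res),
                                   cluster = NA_integer_, n_patches = NA_integer_,
                                   fcm_iterations = NA_integer_, fat_pixels = 0L)
      next
    }
    mask[, , k] <- res$mask
    if (keep_fields) fields[[k]] <- res$field
    e <- res$ellipse
    ell_rows[[k]] <- data.frame(slice_index = k, x_c = e$center[1], y_c = e$center[2],
                                phi0 = e$phi0, a = e$a, b = e$b)
    diag_rows[[k]] <- data.frame(slice_index = k, status = "ok",
                                 cluster = res$cluster, n_patches = res$n_patches,
                                 fcm_iterations = res$fcm_iterations,
                                 fat_pixels = sum(res$mask))
  }

  sp <- slices[[1]]$pixel_spacing
  vol <- fat_volume(mask, sp, slices[[1]]$slice_thickness)
  if (!is.null(weight)) {
    vol$patient_weight_kg <- weight
    vol$normalized_volume_mm3_kg <- normalized_volume(vol$volume_mm3, weight)
    vol$normalized_volume_voxels_kg <- normalized_volume(vol$voxel_count, weight)
  }

  structure(list(mask = mask,
                 ellipses = do.call(rbind, ell_rows),
                 diagnostics = do.call(rbind, diag_rows),
                 volume = vol,
                 fields = fields,
                 config = cfg,
                 seed_point = seed_point,
                 controls = controls,
                 arcs = arcs,
                 series = slices),
            class = "efseg")
}

# One slice through the whole chain. Internal; raises epifat_error
# conditions that efseg() converts into empty-mask diagnostics.
segment_one_slice <- function(pixels, u_star_raw, arc, cfg) {
  enh <- tone_map(pixels, cfg$clip_percentiles)
  roi <- extract_roi(enh, ms1 = cfg$ms1, ms2 = cfg$ms2)
  patches <- sample_patches(roi, R = cfg$R, stride = cfg$stride)
  cl <- cluster_patches(enh, patches, C = cfg$C, m = cfg$m, tol = cfg$tol,
                        max_iter = cfg$max_iter, seed = cfg$rng_seed,
                        n_init = cfg$n_init)
  u_star <- (u_star_raw - cl$scale_center) / cl$scale_sd
  sel <- select_cluster(cl, u_star, pondered_mean = cfg$pondered_mean)
  field <- pixelwise_membership(cl, sel, dim(enh), roi = roi)
  ellipse <- fit_referent_ellipse(enh, field, roi = roi,
                                  bounds = c(cfg$B_l, cfg$B_u),
                                  loading = cfg$loading,
                                  orientation_mode = cfg$orientation_mode)
  crisp <- alpha_cut(field, cfg$alpha)
  filtered <- filter_desirable(crisp, ellipse, arc, epsilon = cfg$epsilon,
                               mode = cfg$distance_mode)
  final <- close_mask(filtered, cfg$closure_size)
  list(mask = final, field = field, ellipse = ellipse, cluster = as.integer(sel),
       n_patches = nrow(patches$centers), fcm_iterations = cl$iterations)
}

# Coerce the accepted series forms into a list of ct_slice.
normalize_series <- function(series) {
  if (inherits(series, "ct_slice")) return(list(series))
  if (is.matrix(series)) return(list(ct_slice(series)))
  if (is.array(series) && length(dim(series)) == 3L) {
    return(lapply(seq_len(dim(series)[3]), function(k) {
      ct_slice(series[, , k], slice_index = k)
    }))
  }
  if (is.list(series) && !is.null(series$slices)) series <- series$slices
  if (is.list(series) && length(series) > 0 &&
      all(vapply(series, inherits, logical(1), "ct_slice"))) {
    return(series)
  }
  stop_epifat("series must be ct_slice objects, a matrix, or a 3D array",
              "inconsistent_series")
}

#' Evaluate a segmentation against a reference
#'
#' Dice similarity (overall and per slice), volumes, relative volume error
#' and, when a body weight is given, the normalized volume.
#'
#' @param pred,truth binary masks (matrix or 3D array) of identical shape.
#' @param pixel_spacing,slice_thickness voxel geometry in mm.
#' @param weight optional patient body weight (kg).
#' @return List with `dice`, `dice_per_slice`, `pred_volume`,
#'   `truth_volume`, `relative_error_pct`, and `normalized_volume_mm3_kg`
#'   when `weight` is given.
#' @export
evaluate_segmentation <- function(pred, truth, pixel_spacing = c(1, 1),
                                  slice_thickness = 1, weight = NULL) {
  if (!all(dim(pred) == dim(truth))) {
    stop_epifat("prediction and truth must have identical dimensions",
                "degenerate_input")
  }
  if (length(dim(pred)) == 2L) {
    pred <- array(pred, dim = c(dim(pred), 1L))
    truth <- array(truth, dim = c(dim(truth), 1L))
  }
  per_slice <- vapply(seq_len(dim(pred)[3]), function(k) {
    if (sum(pred[, , k]) + sum(truth[, , k]) == 0L) return(NA_real_)
    dice(pred[, , k], truth[, , k])
  }, numeric(1))
  pv <- fat_volume(pred, pixel_spacing, slice_thickness)
  tv <- fat_volume(truth, pixel_spacing, slice_thickness)
  out <- list(dice = dice(pred, truth), dice_per_slice = per_slice,
              pred_volume = pv, truth_volume = tv,
              relative_error_pct = relative_error(pv$volume_mm3, tv$volume_mm3))
  if (!is.null(weight)) {
    out$normalized_volume_mm3_kg <- normalized_volume(pv$volume_mm3, weight)
    out$normalized_volume_voxels_kg <- normalized_volume(pv$voxel_count, weight)
  }
  out
}

#' @export
print.efseg <- function(x, ...) {
  n <- dim(x$mask)[3]
  ok <- sum(x$diagnostics$status == "ok")
  cat(sprintf("Epicardial fat segmentation: %d slice%s (%d ok), %d fat voxels, %.1f mm^3\n",
              n, if (n > 1) "s" else "", ok, x$volume$voxel_count, x$volume$volume_mm3))
  if (!is.null(x$volume$normalized_volume_mm3_kg)) {
    cat(sprintf("Normalized volume: %.3g mm^3/kg (%.3g voxels/kg)\n",
                x$volume$normalized_volume_mm3_kg, x$volume$normalized_volume_voxels_kg))
  }
  invisible(x)
}

#' @export
summary.efseg <- function(object, ...) {
  print(object)
  cat("\nPer-slice referent ellipses:\n")
  print(object$ellipses, row.names = FALSE, digits = 4)
  failed <- object$diagnostics[object$diagnostics$status != "ok", , drop = FALSE]
  if (nrow(failed) > 0) {
    cat("\nFailed slices:\n")
    print(failed[, c("slice_index", "status")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.efseg <- function(object, ...) object$ellipses

#' Plot one slice of a segmentation
#'
#' Grayscale display of the enhanced slice with the final fat mask and the
#' fitted referent ellipse overlaid.
#'
#' @param x an `efseg` object.
#' @param slice slice index to display.
#' @param ... further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.efseg <- function(x, slice = 1, ...) {
  enh <- slice_pixels(tone_map(x$series[[slice]]$pixels,
                               x$config$clip_percentiles))
  M <- nrow(enh); N <- ncol(enh)
  graphics::image(seq_len(N), seq_len(M), t(enh)[, M:1],
                  col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, xlab = "col", ylab = "row", useRaster = TRUE, ...)
  mk <- x$mask[, , slice]
  idx <- which(mk == 1L, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    graphics::points(idx[, 2], M + 1 - idx[, 1], pch = ".", col = "red")
  }
  e <- x$ellipses[slice, ]
  if (is.finite(e$a)) {
    phi <- seq(0, 2 * pi, length.out = 361)
    pts <- inverse_transform_coords(cbind(e$a * cos(phi), e$b * sin(phi)),
                                    e$phi0, c(e$x_c, e$y_c))
    graphics::lines(pts[, 2], M + 1 - pts[, 1], col = "yellow", lwd = 2)
  }
  invisible(x)
}
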
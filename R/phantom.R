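#' Specification of the synthetic cardiac CT phantom
#'
#' Parameters of a synthetic contrast-CT slice generator with known ground
#' truth, used to validate every stage of the segmentation pipeline without
#' patient data. The phantom renders, on a 512 x 512 12-bit grid, a bright
#' elliptical heart (contrast-filled blood pool with papillary-muscle
#' texture inside a myocardial shell), a darker epicardial fat rind hugging
#' the heart boundary over a near-circumferential arc with a posterior gap,
#' a thin pericardial line, patchy paracardial fat of identical luminance
#' outside the pericardium (the confound the arc/ring prior exists to
#' reject), a mediastinal soft-tissue surround, dark lung fields, and
#' bright bone distractors (vertebral body, isolated rib sections).
#'
#' Luminances are approximate shifted Hounsfield units (HU + 1024) and are
#' configuration, not a calibration claim. Geometry drifts linearly across
#' slices of a volume to emulate the through-plane change of the heart
#' silhouette and to exercise control-angle interpolation.
#'
#' @param image_size `(M, N)` grid size in pixels.
#' @param center heart ellipse center `(row, col)`.
#' @param phi0 heart ellipse orientation (radians).
#' @param axes semi-axes `(a, b)` in pixels, `a` along the rotated x-axis.
#' @param fat_arc angular span `(theta1, theta2)` of the epicardial fat
#'   rind in radians, polar angles in the ellipse-aligned frame.
#' @param fat_thickness radial thickness of the fat rind in pixels
#'   (measured along the minor axis).
#' @param pericardium_thickness,paracardial_thickness,mediastinum_thickness
#'   radial thickness (px) of the successive surrounding layers.
#' @param paracardial_sectors list of `(from, to)` angular intervals
#'   (radians) that contain paracardial fat.
#' @param luminance named list of tissue luminances on the 12-bit scale.
#' @param noise_sd additive Gaussian noise standard deviation (12-bit
#'   counts).
#' @param pixel_spacing,slice_thickness voxel geometry in mm.
#' @param n_slices number of slices in a phantom volume.
#' @param center_drift,axes_drift,phi0_drift,arc_drift per-slice-step
#'   linear drift rates of the geometry.
#' @param seed RNG seed for the noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 512L),
                         center = c(256, 256),
                         phi0 = 20 * pi / 180,
                         axes = c(a = 216, b = 200),
                         fat_arc = c(15, 345) * pi / 180,
                         fat_thickness = 16,
                         pericardium_thickness = 2,
                         paracardial_thickness = 10,
                         mediastinum_thickness = 8,
                         paracardial_sectors = list(c(40, 80) * pi / 180,
                                                    c(160, 200) * pi / 180,
                                                    c(270, 310) * pi / 180),
                         luminance = list(lung = 200, fat = 950,
                                          mediastinum = 1040, myocardium = 1070,
                                          pericardium = 1100, blood = 1320,
                                          bone = 1700),
                         noise_sd = 25,
                         pixel_spacing = c(0.35, 0.35),
                         slice_thickness = 2.5,
                         n_slices = 1L,
                         center_drift = c(0, 0),
                         axes_drift = c(0, 0),
                         phi0_drift = 0,
                         arc_drift = c(0, 0),
                         seed = 1L) {
  spec <- structure(
    list(image_size = as.integer(image_size), center = as.numeric(center),
         phi0 = phi0, axes = as.numeric(axes), fat_arc = as.numeric(fat_arc),
         fat_thickness = fat_thickness,
         pericardium_thickness = pericardium_thickness,
         paracardial_thickness = paracardial_thickness,
         mediastinum_thickness = mediastinum_thickness,
         paracardial_sectors = paracardial_sectors,
         luminance = luminance, noise_sd = noise_sd,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = slice_thickness,
         n_slices = as.integer(n_slices),
         center_drift = as.numeric(center_drift),
         axes_drift = as.numeric(axes_drift),
         phi0_drift = phi0_drift, arc_drift = as.numeric(arc_drift),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_geometry(phantom_geometry(spec, 1L), spec)
  spec
}

# Linearly drifted geometry of one slice (drift measured in slice steps
# from the first slice).
phantom_geometry <- function(spec, slice_index) {
  s <- slice_index - 1L
  list(center = spec$center + s * spec$center_drift,
       axes = spec$axes + s * spec$axes_drift,
       phi0 = (spec$phi0 + s * spec$phi0_drift) %% pi,
       fat_arc = spec$fat_arc + s * spec$arc_drift)
}

validate_phantom_geometry <- function(geom, spec) {
  a <- geom$axes[1]; b <- geom$axes[2]
  if (a <= 0 || b <= 0) stop_epifat("phantom axes must be positive", "invalid_spec")
  t1 <- geom$fat_arc[1]; t2 <- geom$fat_arc[2]
  if (t2 <= t1 || t1 < 0 || t2 > t1 + 2 * pi) {
    stop_epifat("phantom fat arc must satisfy 0 <= theta1 < theta2 <= theta1 + 2*pi",
                "invalid_spec")
  }
  s1 <- 1 + spec$fat_thickness / b
  hx <- sqrt((a * s1 * cos(geom$phi0))^2 + (b * s1 * sin(geom$phi0))^2)
  hy <- sqrt((a * s1 * sin(geom$phi0))^2 + (b * s1 * cos(geom$phi0))^2)
  if (geom$center[1] - hx < 1 || geom$center[1] + hx > spec$image_size[1] ||
      geom$center[2] - hy < 1 || geom$center[2] + hy > spec$image_size[2]) {
    stop_epifat("phantom fat ring does not fit inside the image", "invalid_spec")
  }
  invisible(TRUE)
}

# paint a filled disc onto an image matrix
paint_disc <- function(img, center, radius, value) {
  M <- nrow(img); N <- ncol(img)
  ii <- matrix(seq_len(M), M, N)
  jj <- matrix(seq_len(N), M, N, byrow = TRUE)
  img[(ii - center[1])^2 + (jj - center[2])^2 <= radius^2] <- value
  img
}

#' Generate one phantom slice with ground truth
#'
#' Renders a 12-bit phantom slice per its [phantom_spec()] and returns the
#' slice together with the exact ground-truth fat and heart masks and the
#' generating ellipse parameters. Fixed `spec$seed` makes the output
#' bit-reproducible.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index 1-based slice position (drives the geometric drift).
#' @return List with `slice` ([ct_slice]), `fat` and `heart` (binary
#'   masks), and `ellipse` (list: `center`, `phi0`, `axes`, `fat_arc`).
#' @export
generate_slice <- function(spec, slice_index = 1L) {
  geom <- phantom_geometry(spec, slice_index)
  validate_phantom_geometry(geom, spec)
  M <- spec$image_size[1]; N <- spec$image_size[2]
  a <- geom$axes[1]; b <- geom$axes[2]
  lum <- spec$luminance

  pts <- cbind(rep(seq_len(M), times = N), rep(seq_len(N), each = M))
  tp <- transform_coords(pts, geom$phi0, geom$center)
  xt <- matrix(tp[, 1L], M, N); yt <- matrix(tp[, 2L], M, N)
  s <- sqrt((xt / a)^2 + (yt / b)^2)
  phi <- atan2(yt, xt) %% (2 * pi)

  s1 <- 1 + spec$fat_thickness / b
  s2 <- s1 + spec$pericardium_thickness / b
  s3 <- s2 + spec$paracardial_thickness / b
  s4 <- s3 + spec$mediastinum_thickness / b

  in_arc <- angle_in_arc(phi, geom$fat_arc[1] %% (2 * pi),
                         geom$fat_arc[1] %% (2 * pi) +
                           (geom$fat_arc[2] - geom$fat_arc[1]))
  img <- matrix(lum$lung, M, N)
  img[s < s4] <- lum$mediastinum
  para <- Reduce(`|`, lapply(spec$paracardial_sectors, function(iv) {
    angle_in_arc(phi, iv[1] %% (2 * pi), iv[1] %% (2 * pi) + (iv[2] - iv[1]))
  }))
  img[s >= s2 & s < s3 & para] <- lum$fat
  img[s >= s1 & s < s2] <- lum$pericardium
  fat_zone <- s >= 1 & s < s1 & in_arc
  img[s >= 1 & s < s1 & !in_arc] <- lum$mediastinum
  img[fat_zone] <- lum$fat
  img[s < 1] <- lum$myocardium
  img[s < 0.55] <- lum$blood
  # papillary-muscle texture inside the blood pool
  for (off in list(c(60, 0), c(-60, 20))) {
    ctr <- inverse_transform_coords(matrix(off, 1, 2), geom$phi0, geom$center)
    img <- paint_disc(img, ctr, 18, lum$myocardium)
  }
  # vertebral body abutting the posterior mediastinum; isolated rib sections
  img <- paint_disc(img, c(geom$center[1], 18), 14, lum$bone)
  for (ctr in list(c(48, 48), c(48, N - 47), c(M - 47, N - 47), c(M - 47, 48))) {
    img <- paint_disc(img, ctr, 8, lum$bone)
  }

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed + 7919L * (as.integer(slice_index) - 1L))
    img <- img + matrix(stats::rnorm(M * N, sd = spec$noise_sd), M, N)
  }
  img <- round(pmin(pmax(img, 0), 4095))

  list(slice = ct_slice(img, pixel_spacing = spec$pixel_spacing,
                        slice_index = slice_index,
                        slice_thickness = spec$slice_thickness),
       fat = as_mask(fat_zone),
       heart = as_mask(s < 1),
       ellipse = geom)
}

#' Generate a phantom volume
#'
#' Stack of [generate_slice()] outputs with linear per-slice drift of the
#' generating geometry.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of slices (defaults to `spec$n_slices`).
#' @return List with `slices` (list of [ct_slice]), `fat` and `heart`
#'   (M x N x n 3D arrays), `ellipses` (list of per-slice geometry).
#' @export
generate_volume <- function(spec, n_slices = spec$n_slices) {
  if (n_slices < 1L) stop_epifat("need at least one slice", "invalid_spec")
  out <- lapply(seq_len(n_slices), function(k) generate_slice(spec, k))
  M <- spec$image_size[1]; N <- spec$image_size[2]
  list(slices = lapply(out, `[[`, "slice"),
       fat = array(unlist(lapply(out, `[[`, "fat")), dim = c(M, N, n_slices)),
       heart = array(unlist(lapply(out, `[[`, "heart")), dim = c(M, N, n_slices)),
       ellipses = lapply(out, `[[`, "ellipse"))
}

#' Canonical seed point of a phantom
#'
#' A pixel at the middle of the epicardial fat rind (mid-arc angle,
#' mid-thickness radius) of the given slice: the coordinates a user would
#' mark as the reference fat patch.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index slice whose geometry to use.
#' @return Integer `(row, col)` coordinates.
#' @export
phantom_seed_point <- function(spec, slice_index = 1L) {
  geom <- phantom_geometry(spec, slice_index)
  a <- geom$axes[1]; b <- geom$axes[2]
  th <- (geom$fat_arc[1] + geom$fat_arc[2]) / 2
  smid <- 1 + spec$fat_thickness / (2 * b)
  r <- smid * a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  pt <- inverse_transform_coords(matrix(r * c(cos(th), sin(th)), 1, 2),
                                 geom$phi0, geom$center)
  as.integer(round(pt))
}

#' Ground-truth control angles of a phantom volume
#'
#' The exact drifted fat-arc angles at `L` equidistant control slices, in
#' the format [interpolate_control_angles()] expects — the phantom's
#' stand-in for expert-provided control angles.
#'
#' @param spec a [phantom_spec()].
#' @param L number of control slices.
#' @param n_slices volume length (defaults to `spec$n_slices`).
#' @return Data frame with `slice_index`, `phi1`, `phi2` (radians).
#' @export
phantom_controls <- function(spec, L = 5L, n_slices = spec$n_slices) {
  idx <- unique(round(seq(1, n_slices, length.out = min(L, n_slices))))
  arcs <- t(vapply(idx, function(k) phantom_geometry(spec, k)$fat_arc, numeric(2)))
  data.frame(slice_index = idx, phi1 = arcs[, 1], phi2 = arcs[, 2])
}
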
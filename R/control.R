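#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their default
#' values: the morphology sizes, defuzzification level and ring half-width
#' `(ms1, ms2, alpha, epsilon) = (40, 20, 0.7, 20)` and the axis bounds
#' `(B_l, B_u) = (200, 450)` px, which presume a 512-wide acquisition grid.
#' With `scale_to_grid = TRUE` (default) every pixel-dimensioned parameter
#' (`ms1`, `ms2`, `epsilon`, `closure_size`, `B_l`, `B_u`) is multiplied by
#' `image_width / ref_width` at run time so the same physical proportions
#' apply on other grids.
#'
#' @param ms1 disk diameter (px) for opening by reconstruction.
#' @param ms2 disk diameter (px) for the ROI dilation.
#' @param alpha alpha-cut level in (0, 1).
#' @param epsilon ring half-width (px) around the referent ellipse.
#' @param clip_percentiles tone-mapping clip probabilities.
#' @param R odd patch side (px).
#' @param stride patch sampling stride (px).
#' @param C number of fuzzy clusters.
#' @param m fuzzifier (> 1).
#' @param tol fuzzy c-means convergence tolerance.
#' @param max_iter fuzzy c-means iteration cap.
#' @param rng_seed seed for fuzzy c-means initialization.
#' @param n_init fuzzy c-means restarts (best final objective kept).
#' @param pondered_mean cluster-mean pondering for seed matching:
#'   `"normalized"` (conventional weighted mean, default) or
#'   `"as_printed"` (division by the patch count; see the methods
#'   vignette for why this is not the default).
#' @param loading diagonal loading for the orientation covariance
#'   (`NULL` = `1e-6 * trace / 2`).
#' @param orientation_mode observation model for the orientation PCA,
#'   `"weighted_average"` (default) or `"weighted_coords"` (see
#'   [estimate_orientation()]).
#' @param B_l,B_u lower/upper bounds (px) on the ellipse axes.
#' @param optimizer_tol axis-fit optimizer tolerance.
#' @param closure_size disk diameter (px) for the final closure
#'   (`NULL` = `ms2`).
#' @param distance_mode ring-distance formula, `"corrected"` or
#'   `"as_printed"`.
#' @param ref_width reference grid width the pixel parameters presume.
#' @param scale_to_grid rescale pixel parameters to the actual grid width.
#' @return A validated list of class `efseg_control`.
#' @examples
#' cfg <- efseg_control()
#' c(cfg$ms1, cfg$ms2, cfg$alpha, cfg$epsilon)
#' @export
efseg_control <- function(ms1 = 40, ms2 = 20, alpha = 0.7, epsilon = 20,
                          clip_percentiles = c(0.01, 0.99),
                          R = 5, stride = 2, C = 6, m = 2,
                          tol = 1e-5, max_iter = 300, rng_seed = 0, n_init = 3,
                          pondered_mean = c("normalized", "as_printed"),
                          loading = NULL,
                          orientation_mode = c("weighted_average", "weighted_coords"),
                          B_l = 200, B_u = 450, optimizer_tol = 1e-10,
                          closure_size = NULL,
                          distance_mode = c("corrected", "as_printed"),
                          ref_width = 512, scale_to_grid = TRUE) {
  pondered_mean <- match.arg(pondered_mean)
  orientation_mode <- match.arg(orientation_mode)
  distance_mode <- match.arg(distance_mode)
  if (ms1 < 1 || ms2 < 1) stop_epifat("structuring element sizes must be >= 1 px", "degenerate_input")
  if (alpha <= 0 || alpha >= 1) stop_epifat("alpha must lie in (0, 1)", "degenerate_input")
  if (epsilon <= 0) stop_epifat("epsilon must be positive", "degenerate_input")
  if (R %% 2 != 1 || R < 1) stop_epifat("R must be odd and positive", "degenerate_input")
  if (stride < 1) stop_epifat("stride must be >= 1", "degenerate_input")
  if (C < 2) stop_epifat("C must be >= 2", "degenerate_input")
  if (m <= 1) stop_epifat("m must exceed 1", "degenerate_input")
  if (B_l <= 0 || B_u <= B_l) stop_epifat("bounds must satisfy 0 < B_l < B_u", "degenerate_input")
  if (is.null(closure_size)) closure_size <- ms2
  structure(list(ms1 = ms1, ms2 = ms2, alpha = alpha, epsilon = epsilon,
                 clip_percentiles = clip_percentiles,
                 R = as.integer(R), stride = as.integer(stride),
                 C = as.integer(C), m = m, tol = tol,
                 max_iter = as.integer(max_iter), rng_seed = as.integer(rng_seed),
                 n_init = as.integer(n_init),
                 pondered_mean = pondered_mean, loading = loading,
                 orientation_mode = orientation_mode,
                 B_l = B_l, B_u = B_u, optimizer_tol = optimizer_tol,
                 closure_size = closure_size, distance_mode = distance_mode,
                 ref_width = ref_width, scale_to_grid = isTRUE(scale_to_grid)),
            class = "efseg_control")
}

# Pixel-dimensioned parameters rescaled to the actual grid width.
scale_control <- function(config, image_width) {
  f <- if (config$scale_to_grid) image_width / config$ref_width else 1
  config$ms1 <- config$ms1 * f
  config$ms2 <- config$ms2 * f
  config$epsilon <- config$epsilon * f
  config$closure_size <- config$closure_size * f
  config$B_l <- config$B_l * f
  config$B_u <- config$B_u * f
  config$grid_scale <- f
  config
}
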
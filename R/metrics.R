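#' Dice similarity coefficient
#'
#' `D(A, B) = 2 |A  B| / (|A| + |B|)` for two binary masks of identical
#' shape. Symmetric, bounded in \[0, 1\], equal to 1 iff the masks are
#' identical and non-empty. When both masks are empty the coefficient is
#' the undefined form 0/0 and is reported as `NA` with a warning.
#'
#' @param A,B binary masks (matrices or 3D arrays) of identical dimensions.
#' @return Dice coefficient in \[0, 1\], or `NA` if both masks are empty.
#' @examples
#' A <- matrix(c(1, 1, 0, 0), 2, 2); B <- matrix(c(1, 0, 1, 0), 2, 2)
#' dice(A, B)
#' @export
dice <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop_epifat("masks must have identical dimensions",
                                          "degenerate_input")
  a <- A != 0
  b <- B != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks empty: Dice undefined (0/0), reported as NA")
    return(NA_real_)
  }
  2 * sum(a & b) / (na + nb)
}

#' Segmented fat volume
#'
#' Physical volume of a stacked binary segmentation: voxel count times the
#' voxel volume `row_spacing * col_spacing * slice_thickness`.
#'
#' @param mask binary mask, 2D matrix or 3D array of stacked slices.
#' @param pixel_spacing length-2 `(row, col)` spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @return List of class `volume_report` with `voxel_count` and
#'   `volume_mm3`.
#' @export
fat_volume <- function(mask, pixel_spacing, slice_thickness) {
  if (missing(pixel_spacing) || missing(slice_thickness) ||
      is.null(pixel_spacing) || is.null(slice_thickness) ||
      any(!is.finite(c(pixel_spacing, slice_thickness)))) {
    stop_epifat("pixel spacing and slice thickness are required", "metadata")
  }
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0) {
    stop_epifat("spacing and thickness must be positive", "metadata")
  }
  n <- sum(mask != 0)
  structure(list(voxel_count = n,
                 volume_mm3 = n * pixel_spacing[1] * pixel_spacing[2] * slice_thickness),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> %d voxels, %.1f mm^3", x$voxel_count, x$volume_mm3))
  if (!is.null(x$normalized_volume_mm3_kg)) {
    cat(sprintf(", NV %.3g mm^3/kg (%.3g voxels/kg)",
                x$normalized_volume_mm3_kg, x$normalized_volume_voxels_kg))
  }
  cat("\n")
  invisible(x)
}

#' Normalized fat volume
#'
#' Ratio of the segmented epicardial fat volume to patient body weight.
#' Computed in mm^3/kg; when a voxel count is supplied the raw voxels/kg
#' ratio is the same formula on the voxel scale.
#'
#' @param volume fat volume (mm^3, or voxels for the voxel-scale ratio).
#' @param weight patient body weight in kg (> 0).
#' @return Normalized volume, `volume / weight`.
#' @examples
#' normalized_volume(80, 80)  # 1
#' @export
normalized_volume <- function(volume, weight) {
  if (!is.finite(weight) || weight <= 0) {
    stop_epifat("patient weight must be positive", "invalid_weight")
  }
  volume / weight
}

#' Relative volume error
#'
#' `100 * |seg - ref| / ref` in percent, comparing a segmented volume to a
#' reference (e.g. manually annotated) volume.
#'
#' @param seg_volume segmented volume.
#' @param ref_volume reference volume (> 0).
#' @return Relative error in percent (>= 0).
#' @examples
#' relative_error(1.15 * 200, 200)  # 15
#' @export
relative_error <- function(seg_volume, ref_volume) {
  if (!is.finite(ref_volume) || ref_volume <= 0) {
    stop_epifat("reference volume must be positive", "undefined_metric")
  }
  100 * abs(seg_volume - ref_volume) / ref_volume
}
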
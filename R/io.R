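#' Read a CT series
#'
#' Reads a 3D CT volume from a NIfTI file into a list of [ct_slice]
#' objects, slices ordered along the third axis, with pixel spacing and
#' slice thickness taken from the header. DICOM directories are not
#' supported by this reader; convert the series to NIfTI first (e.g. with
#' `dcm2niix`).
#'
#' @param path path to a NIfTI file (`.nii` / `.nii.gz`).
#' @return List of [ct_slice] objects.
#' @export
read_ct_series <- function(path) {
  if (dir.exists(path)) {
    stop_epifat("directory input (DICOM series) is not supported; convert to NIfTI first",
                "metadata")
  }
  if (!file.exists(path)) stop_epifat(sprintf("file not found: %s", path), "metadata")
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop_epifat("expected a 2D or 3D volume", "metadata")
  spacing <- if (length(pd) >= 2) pd[1:2] else c(1, 1)
  thickness <- if (length(pd) >= 3) pd[3] else 1
  lapply(seq_len(dim(arr)[3]), function(k) {
    ct_slice(arr[, , k], pixel_spacing = spacing, slice_index = k,
             slice_thickness = thickness)
  })
}

#' Write a mask or field volume to NIfTI
#'
#' Single-slice volumes are stored as 2D NIfTI images (the format drops
#' trailing singleton dimensions), so their slice-thickness field is not
#' preserved; multi-slice volumes round-trip spacing and thickness.
#'
#' @param x 2D matrix or 3D array (binary mask or membership field).
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param pixel_spacing,slice_thickness voxel geometry in mm.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(x, path, pixel_spacing = c(1, 1),
                               slice_thickness = 1) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  img <- RNifti::asNifti(x * 1)  # force numeric storage
  # RNifti drops trailing singleton dimensions; match pixdim to its rank
  nd <- length(dim(img))
  img <- RNifti::`pixdim<-`(img, c(pixel_spacing, slice_thickness)[seq_len(nd)])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask or membership field as a PNG image
#'
#' Grayscale PNG export for quick-look QC: binary masks map to black/white,
#' membership fields to 8-bit gray levels.
#'
#' @param x 2D matrix (binary mask or membership field in \[0, 1\]).
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_epifat("PNG export needs the 'png' package", "metadata")
  }
  m <- pmin(pmax(as.matrix(x) * 1, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

#' Read expert control angles from CSV
#'
#' Expected columns: `slice_index`, `phi1_deg`, `phi2_deg` (degrees, as an
#' expert would record them) or `phi1`, `phi2` (radians).
#'
#' @param path CSV file path.
#' @return Data frame with `slice_index`, `phi1`, `phi2` in radians.
#' @export
read_control_angles <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("phi1_deg", "phi2_deg") %in% names(df))) {
    df$phi1 <- df$phi1_deg * pi / 180
    df$phi2 <- df$phi2_deg * pi / 180
  }
  if (!all(c("slice_index", "phi1", "phi2") %in% names(df))) {
    stop_epifat("controls CSV needs slice_index and phi1/phi2 (or *_deg) columns",
                "missing_controls")
  }
  df[order(df$slice_index), c("slice_index", "phi1", "phi2")]
}

#' Write per-slice referent-ellipse parameters to CSV
#'
#' @param fit an `efseg` object or its `ellipses` data frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_ellipses_csv <- function(fit, path) {
  df <- if (inherits(fit, "efseg")) fit$ellipses else fit
  names(df)[names(df) == "phi0"] <- "phi0_rad"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
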
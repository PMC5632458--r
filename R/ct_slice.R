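#' CT slice container
#'
#' A lightweight container for one 2D grayscale CT slice. Pixel values are
#' luminance on the native 12-bit scale (0..4095) or on \[0, 1\] after
#' enhancement. Coordinates throughout the package are 1-based `(row, col)`;
#' the row index plays the role of the x-axis and the column index the
#' y-axis of the slice's referent coordinate system.
#'
#' @param pixels numeric matrix of luminance values (finite, non-negative).
#' @param pixel_spacing physical pixel size in mm, length-2 `(row, col)`.
#' @param slice_index integer position of the slice in its 3D stack.
#' @param slice_thickness slice thickness in mm.
#'
#' @return An object of class `ct_slice`: a list with fields `pixels`,
#'   `pixel_spacing`, `slice_index`, `slice_thickness`.
#' @examples
#' sl <- ct_slice(matrix(0:3, 2, 2), pixel_spacing = c(0.35, 0.35))
#' dim(sl$pixels)
#' @export
ct_slice <- function(pixels, pixel_spacing = c(1, 1), slice_index = 1L,
                     slice_thickness = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop_epifat("pixel values must be finite and non-negative",
                "degenerate_input")
  }
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0) {
    stop_epifat("pixel spacing and slice thickness must be positive",
                "metadata")
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         slice_index = as.integer(slice_index),
         slice_thickness = as.numeric(slice_thickness)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3g x %.3g mm, slice %d, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_index,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a ct_slice or a bare matrix wherever a slice is expected.
slice_pixels <- function(x) {
  if (inherits(x, "ct_slice")) x$pixels else as.matrix(x)
}

# Rebuild a result in the same shape as the input slice.
rewrap_slice <- function(template, pixels) {
  if (inherits(template, "ct_slice")) {
    out <- template
    out$pixels <- pixels
    out
  } else {
    pixels
  }
}

# Structured error helper: every condition is an "epifat_error" with a
# specific subclass so callers/tests can discriminate failure modes.
stop_epifat <- function(message, subclass, call. = FALSE, ...) {
  cond <- errorCondition(message,
                         class = c(paste0("epifat_", subclass), "epifat_error"),
                         ...)
  stop(cond)
}

# Binary mask helper: coerce logical/numeric matrices to strict {0,1} integer.
as_mask <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

# EBImage brushes need odd sizes; "size" is a disk diameter in pixels and
# even diameters are rounded up to the next odd integer.
disc_brush <- function(size) {
  size <- max(3L, as.integer(round(size)))
  if (size %% 2L == 0L) size <- size + 1L
  EBImage::makeBrush(size, shape = "disc")
}
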
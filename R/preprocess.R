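#' Histogram-adaptive tone mapping
#'
#' Enhances a raw CT slice with a percentile-based contrast stretch: pixel
#' values are clipped at the given histogram percentiles and rescaled
#' linearly to \[0, 1\]. The mapping is monotonically non-decreasing in the
#' input luminance, so ordering of tissues is preserved while the output
#' occupies the full unit range up to the clipping percentiles.
#'
#' @param x a [ct_slice] or numeric matrix of luminance values.
#' @param clip length-2 numeric, the lower/upper clipping percentiles as
#'   probabilities (default `c(0.01, 0.99)`).
#' @return The enhanced slice (same shape as the input) with values in
#'   \[0, 1\].
#' @examples
#' enh <- tone_map(matrix(c(100, 500, 1500, 3000), 2, 2))
#' range(enh)
#' @export
tone_map <- function(x, clip = c(0.01, 0.99)) {
  px <- slice_pixels(x)
  if (length(clip) != 2L || clip[1] < 0 || clip[2] > 1 || clip[1] >= clip[2]) {
    stop_epifat("clip must be two increasing probabilities in [0, 1]",
                "degenerate_input")
  }
  lo <- min(px); hi <- max(px)
  if (hi <= lo) {
    stop_epifat("constant-valued slice: tone mapping undefined",
                "degenerate_input")
  }
  q <- stats::quantile(px, probs = clip, names = FALSE)
  if (q[2] <= q[1]) q <- c(lo, hi)  # degenerate percentiles: full-range stretch
  out <- (px - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  rewrap_slice(x, out)
}

#' Per-slice threshold from the image histogram
#'
#' Computes a threshold separating bright cardiac/soft tissue from the dark
#' background (lung fields, air) by Otsu's between-class variance criterion
#' on a 256-bin histogram of the enhanced slice. Deterministic for fixed
#' input.
#'
#' @param x an enhanced [ct_slice] or matrix with values in \[0, 1\].
#' @param levels number of histogram bins (default 256).
#' @return A single threshold value in \[0, 1\].
#' @examples
#' set.seed(1)
#' img <- matrix(c(rnorm(100, 0.2, 0.02), rnorm(100, 0.8, 0.02)), 10, 20)
#' compute_slice_threshold(pmin(pmax(img, 0), 1))
#' @export
compute_slice_threshold <- function(x, levels = 256) {
  px <- slice_pixels(x)
  if (max(px) <= min(px)) {
    stop_epifat("constant-valued slice: threshold undefined", "degenerate_input")
  }
  EBImage::otsu(px, range = c(0, 1), levels = levels)
}

#' Grayscale opening by reconstruction
#'
#' Morphological opening by reconstruction with a disk structuring element:
#' the marker is the grayscale erosion of the image by a disk of diameter
#' `size`, which is then reconstructed under the original image — the exact
#' fixed point of the 8-connected unit geodesic dilation, computed by the
#' standard hybrid raster-scan/queue algorithm in compiled code. Bright
#' structures that cannot contain the disk are removed while the shape of
#' surviving structures is preserved exactly.
#'
#' @param x a [ct_slice] or matrix.
#' @param size disk diameter in pixels.
#' @return The reconstructed slice, same shape as the input.
#' @export
open_reconstruct <- function(x, size) {
  px <- slice_pixels(x)
  marker <- pmin(EBImage::erode(px, disc_brush(size)), px)
  rewrap_slice(x, .reconstruct_dilation(marker, px))
}

#' Whole-heart region-of-interest extraction
#'
#' Extracts the binary whole-heart region of interest from an enhanced
#' slice: grayscale opening by reconstruction (disk diameter `ms1`) removes
#' small bright structures such as ribs and sternum fragments; Otsu
#' thresholding of the reconstruction separates soft tissue from the dark
#' lung fields; only the largest connected component (the heart and its
#' immediate mediastinal surround) is retained; and a final dilation by a
#' disk of diameter `ms2` pads the region so the adjacent epicardial fat
#' rim is guaranteed to lie inside the mask.
#'
#' @param x an enhanced [ct_slice] or matrix with values in \[0, 1\].
#' @param ms1 disk diameter (px) for opening by reconstruction (default 40).
#' @param ms2 disk diameter (px) for the final dilation (default 20).
#' @return An integer `BinaryMask` matrix of 0/1 values, same size as the
#'   slice.
#' @export
extract_roi <- function(x, ms1 = 40, ms2 = 20) {
  px <- slice_pixels(x)
  idx <- if (inherits(x, "ct_slice")) x$slice_index else NA_integer_
  if (max(px) <= min(px)) {
    stop_epifat(sprintf("no region of interest found (constant slice %s)", idx),
                "no_roi", slice_index = idx)
  }
  rec <- slice_pixels(open_reconstruct(px, ms1))
  th <- compute_slice_threshold(rec)
  bw <- as_mask(rec > th)
  if (sum(bw) == 0L) {
    stop_epifat(sprintf("no region of interest found in slice %s", idx),
                "no_roi", slice_index = idx)
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  largest <- as_mask(lab == keep)
  as_mask(EBImage::dilate(largest, disc_brush(ms2)))
}
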
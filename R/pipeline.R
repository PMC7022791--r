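#' Image pipeline: crop, grayscale, high-pass filtering and binarization
#'
#' The functions in this file implement the two segmentation paths used to
#' turn an RGB photograph of a tissue slice into a binary fat/muscle mask:
#'
#' * the *unfiltered* path: Rec. 601 grayscale followed by a fixed manual
#'   threshold at 175 (pixels at or above the threshold are labeled fat);
#' * the *high-pass* path: grayscale, Gaussian high-pass at a configurable
#'   radius (25 or 50 px presets), Overlay-blend of the high-pass layer back
#'   onto the grayscale original, then a threshold of 150.
#'
#' Images are plain numeric objects: an RGB image is an \code{H x W x 3}
#' array with values in \code{[0, 255]}, a grayscale image is an
#' \code{H x W} matrix on the same scale, and a tissue mask is a logical
#' matrix with \code{TRUE} = fat, \code{FALSE} = muscle.
#'
#' @name pipeline
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Pipeline configuration
#'
#' Bundles the fixed parameters of the two segmentation paths: the high-pass
#' radius, the two binarization thresholds and the side of the square
#' analysis crop.
#'
#' @param radius_px High-pass filter radius in pixels; the presets compared
#'   in practice are 25 and 50. Must satisfy \code{0 < radius_px <
#'   crop_side / 2}.
#' @param threshold_filtered Threshold applied after high-pass + Overlay
#'   (default 150).
#' @param threshold_unfiltered Threshold applied directly to the grayscale
#'   image in the unfiltered path (default 175).
#' @param crop_side Side of the square crop in pixels (default 512).
#' @return An object of class \code{"filter_config"} (a named list).
#' @export
filter_config <- function(radius_px = 25, threshold_filtered = 150L,
                          threshold_unfiltered = 175L, crop_side = 512L) {
  stopifnot(is.numeric(radius_px), length(radius_px) == 1L)
  crop_side <- as.integer(crop_side)
  if (!(radius_px > 0 && radius_px < crop_side / 2))
    stop("radius_px must lie in (0, crop_side/2); got ", radius_px)
  for (th in c(threshold_filtered, threshold_unfiltered))
    if (th < 0 || th > 255) stop("thresholds must lie in [0, 255]; got ", th)
  structure(list(radius_px = as.numeric(radius_px),
                 threshold_filtered = as.integer(threshold_filtered),
                 threshold_unfiltered = as.integer(threshold_unfiltered),
                 crop_side = crop_side),
            class = "filter_config")
}

assert_rgb <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("expected an H x W x 3 RGB array")
  if (min(image) < 0 || max(image) > 255)
    stop("RGB channel values must lie in [0, 255]")
  invisible(image)
}

assert_gray <- function(image) {
  if (!is.matrix(image)) stop("expected an H x W grayscale matrix")
  invisible(image)
}

assert_mask <- function(mask) {
  if (!(is.matrix(mask) && is.logical(mask)))
    stop("expected a logical H x W mask (TRUE = fat)")
  invisible(mask)
}

#' Crop a square window out of an image
#'
#' @param image An RGB array (\code{H x W x 3}) or grayscale matrix.
#' @param top_left Integer pair \code{c(row, col)} of the window's top-left
#'   pixel (1-based).
#' @param side Window side in pixels.
#' @return The cropped image, pixels copied verbatim.
#' @export
crop_square <- function(image, top_left, side) {
  d <- dim(image)
  side <- as.integer(side)
  r0 <- as.integer(top_left[1]); c0 <- as.integer(top_left[2])
  if (r0 < 1L || c0 < 1L || r0 + side - 1L > d[1] || c0 + side - 1L > d[2])
    stop("crop window [", r0, ":", r0 + side - 1L, ", ", c0, ":",
         c0 + side - 1L, "] exceeds image of size ", d[1], " x ", d[2])
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  if (length(d) == 3L) image[rows, cols, , drop = FALSE] else image[rows, cols, drop = FALSE]
}

#' Convert an RGB image to 8-bit grayscale (Rec. 601 luma)
#'
#' Per-pixel \code{0.299 R + 0.587 G + 0.114 B}, rounded half-up and clipped
#' to \code{[0, 255]}.
#'
#' @param image An \code{H x W x 3} RGB array with values in \code{[0, 255]}.
#' @return An \code{H x W} integer-valued matrix.
#' @export
to_grayscale <- function(image) {
  assert_rgb(image)
  g <- 0.299 * image[, , 1, drop = FALSE] + 0.587 * image[, , 2, drop = FALSE] +
    0.114 * image[, , 3, drop = FALSE]
  dim(g) <- dim(image)[1:2]
  pmin(pmax(round_half_up(g), 0), 255)
}

# One-dimensional Gaussian blur operator as an n x n band matrix with
# clamped (edge-replicated) indices; sigma in pixels, kernel truncated at
# 3*sigma and normalized to unit sum.  Left-multiplication blurs columns.
blur_operator <- function(n, sigma) {
  h <- as.integer(ceiling(3 * sigma))
  off <- -h:h
  k <- exp(-(off^2) / (2 * sigma^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + off, 1L), n)
    for (t in seq_along(off)) B[i, idx[t]] <- B[i, idx[t]] + k[t]
  }
  B
}

#' Gaussian blur of a grayscale image
#'
#' Isotropic Gaussian convolution with standard deviation
#' \code{radius_px / 3}, kernel truncated at three standard deviations,
#' borders handled by edge replication. The result is kept at real (double)
#' precision so it can be subtracted from the original without accumulation
#' of rounding error.
#'
#' @param image Grayscale matrix.
#' @param radius_px Blur radius in pixels (> 0); sigma = radius_px / 3.
#' @return A real-valued matrix of the same size.
#' @export
gaussian_blur <- function(image, radius_px) {
  assert_gray(image)
  stopifnot(radius_px > 0)
  sigma <- radius_px / 3
  Br <- blur_operator(nrow(image), sigma)
  Bc <- if (ncol(image) == nrow(image)) Br else blur_operator(ncol(image), sigma)
  Br %*% image %*% t(Bc)
}

#' Gaussian high-pass filter
#'
#' \code{image - gaussian_blur(image, radius_px) + 128}, rounded half-up and
#' clipped to \code{[0, 255]}: slowly varying illumination maps to mid-gray
#' 128 while local contrast (edges, streaks) is preserved. This reconstructs
#' the classic "High Pass" layer of raster editors.
#'
#' @param image Grayscale matrix.
#' @param radius_px High-pass radius; must be below \code{min(H, W) / 2}.
#' @return Grayscale matrix; a constant input maps to uniform 128.
#' @export
high_pass <- function(image, radius_px) {
  assert_gray(image)
  if (radius_px >= min(dim(image)) / 2)
    stop("radius_px must be below min(H, W)/2")
  hp <- image - gaussian_blur(image, radius_px) + 128
  pmin(pmax(round_half_up(hp), 0), 255)
}

#' Overlay blend of a high-pass layer onto a base image
#'
#' The Overlay operator of raster editors: with \code{a}, \code{b} the base
#' and blend values rescaled to \code{[0, 1]}, the result is \code{2ab}
#' where \code{a < 0.5} and \code{1 - 2(1-a)(1-b)} elsewhere. A uniform
#' mid-gray (128) blend layer is neutral, so superimposing a high-pass layer
#' flattens illumination while keeping local contrast.
#'
#' @param base Grayscale matrix (the original image).
#' @param hp Grayscale matrix (the high-pass layer), same dimensions.
#' @return Grayscale matrix rescaled back to \code{[0, 255]}, rounded.
#' @export
overlay_blend <- function(base, hp) {
  assert_gray(base); assert_gray(hp)
  if (!identical(dim(base), dim(hp)))
    stop("base and blend layers must have identical dimensions")
  a <- base / 255; b <- hp / 255
  out <- ifelse(a < 0.5, 2 * a * b, 1 - 2 * (1 - a) * (1 - b))
  pmin(pmax(round_half_up(255 * out), 0), 255)
}

#' Binarize a grayscale image into a fat/muscle mask
#'
#' Pixels at or above the threshold become fat (\code{TRUE}, rendered
#' white); pixels below become muscle (\code{FALSE}, black). Red lean tissue
#' is dark in luma and falls below the threshold; white/yellow fat lies
#' above it.
#'
#' @param image Grayscale matrix.
#' @param threshold Integer in \code{[0, 255]}.
#' @return Logical matrix, \code{TRUE} = fat.
#' @export
binarize <- function(image, threshold) {
  assert_gray(image)
  stopifnot(threshold >= 0, threshold <= 255)
  image >= threshold
}

assert_crop <- function(image, cfg) {
  d <- dim(image)
  if (d[1] != cfg$crop_side || d[2] != cfg$crop_side)
    stop("expected a ", cfg$crop_side, " x ", cfg$crop_side,
         " crop; got ", d[1], " x ", d[2])
  invisible(image)
}

#' Unfiltered segmentation path
#'
#' Grayscale conversion followed by the manual threshold (default 175); no
#' illumination correction.
#'
#' @param image Square RGB crop of side \code{cfg$crop_side}.
#' @param cfg A [filter_config()].
#' @return Logical fat mask.
#' @export
run_unfiltered <- function(image, cfg = filter_config()) {
  assert_rgb(image); assert_crop(image, cfg)
  binarize(to_grayscale(image), cfg$threshold_unfiltered)
}

#' High-pass segmentation path
#'
#' Grayscale conversion, Gaussian high-pass at \code{cfg$radius_px}, Overlay
#' blend of the high-pass layer onto the grayscale original, then the
#' filtered-path threshold (default 150).
#'
#' @inheritParams run_unfiltered
#' @return Logical fat mask.
#' @export
run_highpass <- function(image, cfg = filter_config()) {
  assert_rgb(image); assert_crop(image, cfg)
  g <- to_grayscale(image)
  binarize(overlay_blend(g, high_pass(g, cfg$radius_px)), cfg$threshold_filtered)
}

#' Export a mask as a three-column coordinate table
#'
#' One row per pixel in row-major scan order (each image row left to right,
#' top to bottom), with 1-based coordinates: horizontal position first, then
#' vertical position, then the tissue code (1 = fat/white, 2 =
#' muscle/black). This is the flat record format consumed by the
#' multifractal stage and written to headerless CSV by [write_pixel_table()].
#'
#' @param mask Logical fat mask.
#' @return A data.frame with integer columns \code{col}, \code{row},
#'   \code{code} and \code{H * W} rows.
#' @export
mask_to_table <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  data.frame(col = rep(seq_len(w), times = h),
             row = rep(seq_len(h), each = w),
             code = ifelse(t(mask), 1L, 2L)[seq_len(h * w)])
}

#' Rebuild a mask from its coordinate table
#'
#' Inverse of [mask_to_table()]; accepts rows in any order.
#'
#' @param table Data.frame with columns \code{col}, \code{row}, \code{code}.
#' @return Logical fat mask.
#' @export
table_to_mask <- function(table) {
  stopifnot(all(c("col", "row", "code") %in% names(table)))
  if (!all(table$code %in% c(1L, 2L))) stop("codes must be 1 (fat) or 2 (muscle)")
  h <- max(table$row); w <- max(table$col)
  if (nrow(table) != h * w) stop("expected one row per pixel (", h * w, ")")
  mask <- matrix(NA, h, w)
  mask[cbind(table$row, table$col)] <- table$code == 1L
  mask
}

#' Fat area fraction of a mask
#'
#' @param mask Logical fat mask.
#' @return Proportion of pixels labeled fat, in \code{[0, 1]}.
#' @export
fat_fraction <- function(mask) {
  assert_mask(mask)
  mean(mask)
}
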
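#' File input/output
#'
#' Rasters travel as PNG (masks as 0/255 grayscale, images as 8-bit RGB),
#' pixel tables as headerless three-column CSV (col,row,code) with LF line
#' endings, and analysis records as JSON. TIFF and JPEG input is supported
#' when the corresponding reader packages are installed.
#'
#' @name io
NULL

#' Read an RGB image from PNG, TIFF or JPEG
#'
#' @param path Image file; format inferred from the extension.
#' @return \code{H x W x 3} numeric array with values in 0-255. Grayscale
#'   files are replicated across channels; an alpha channel is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension: ", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  round_half_up(raw * 255)
}

#' Write an RGB image to PNG
#'
#' @param image \code{H x W x 3} array, values 0-255.
#' @param path Output file.
#' @export
write_image_png <- function(image, path) {
  assert_rgb(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a fat mask to PNG (fat = white 255, muscle = black 0)
#'
#' @param mask Logical fat mask.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a fat mask from a 0/255 PNG
#'
#' Any pixel at or above half intensity is read as fat.
#'
#' @param path PNG file.
#' @return Logical fat mask.
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw >= 0.5
}

#' Write a pixel table as headerless CSV
#'
#' Three columns (col,row,code), no header, LF line endings — the flat
#' format consumed by the multifractal stage.
#'
#' @param table Data.frame from [mask_to_table()].
#' @param path Output file.
#' @export
write_pixel_table <- function(table, path) {
  stopifnot(all(c("col", "row", "code") %in% names(table)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(table$col, table$row, table$code, sep = ","), con,
             sep = "\n")
  invisible(path)
}

#' Read a pixel table from headerless CSV
#'
#' @param path CSV file as written by [write_pixel_table()].
#' @return Data.frame with columns \code{col}, \code{row}, \code{code}.
#' @export
read_pixel_table <- function(path) {
  t <- utils::read.csv(path, header = FALSE,
                       col.names = c("col", "row", "code"),
                       colClasses = "integer")
  t
}

#' Read a mask from either a PNG or a pixel-table CSV
#'
#' @param path File ending in .png or .csv.
#' @return Logical fat mask.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = read_mask_png(path),
    csv = table_to_mask(read_pixel_table(path)),
    stop("unsupported mask format: ", ext))
}

#' Serialize a sandbox analysis to a JSON record
#'
#' @param result An \code{mfa_result} from [analyze_mask()].
#' @param path Output JSON file.
#' @export
write_mfa_json <- function(result, path) {
  stopifnot(inherits(result, "mfa_result"))
  cfg <- result$config
  rec <- list(
    estimates = result$estimates,
    fat_fraction = result$fat_fraction,
    config = list(n_centers = cfg$n_centers, r_min_px = cfg$r_min_px,
                  r_max_px = cfg$r_max_px, n_radii = cfg$n_radii,
                  q_values = cfg$q_values, seed = cfg$seed,
                  min_support_px = cfg$min_support_px))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
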
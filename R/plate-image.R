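#' Construct a TLC plate image
#'
#' A `plate_image` couples an 8-bit RGB raster of a (cropped) thin-layer
#' chromatography plate with the two reference rows that define the
#' development geometry: the origin line where samples were spotted and the
#' solvent front. Migration is upward, so the front row index is smaller
#' than the origin row index. Coordinates are 1-based with row 1 at the top
#' of the image, matching R matrix indexing.
#'
#' @param pixels integer array `H x W x 3` with values in 0..255 (R, G, B).
#' @param origin_row pixel row of the sample-application (origin) line.
#' @param front_row pixel row of the solvent front; must be `< origin_row`.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, origin_row = dim(pixels)[1],
                        front_row = 1L) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    tlc_abort("plate image must be an H x W x 3 RGB array",
              "tlc_format_error")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 32L || w < 32L)
    tlc_abort("plate image must be at least 32 x 32 pixels",
              "tlc_format_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    tlc_abort("channel values must lie in [0, 255]", "tlc_format_error")
  origin_row <- as.numeric(origin_row); front_row <- as.numeric(front_row)
  if (!(front_row < origin_row))
    tlc_abort("front_row must be above (smaller than) origin_row",
              "tlc_geometry_error")
  if (front_row < 1 || origin_row > h)
    tlc_abort("origin and front rows must lie inside the image",
              "tlc_geometry_error")
  structure(list(pixels = pixels, origin_row = origin_row,
                 front_row = front_row),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %d x %d px, origin row %g, front row %g\n",
              d[1], d[2], x$origin_row, x$front_row))
  invisible(x)
}

#' Read a plate photograph from disk
#'
#' Reads an 8-bit RGB image (PNG, JPEG or TIFF), optionally crops it to the
#' development region and records the origin/front rows. By default the crop
#' boundary rows are taken as the reference rows: bottom row = origin line,
#' top row = solvent front.
#'
#' @param path image file path.
#' @param crop optional `c(row1, row2, col1, col2)` crop rectangle
#'   (1-based, inclusive). `NULL` keeps the full frame.
#' @param origin_row,front_row reference rows in the *cropped* frame;
#'   default to the crop's bottom and top rows.
#' @return A [plate_image].
#' @export
read_plate <- function(path, crop = NULL, origin_row = NULL,
                       front_row = NULL) {
  if (!file.exists(path))
    tlc_abort(sprintf("image file not found: %s", path), "tlc_config_error")
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) < 3L || d[3] < 3L)
    tlc_abort("expected a 3-channel RGB image", "tlc_format_error")
  # EBImage stores width x height x channel in [0,1]; convert to row-major.
  px <- array(0L, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) px[, , ch] <- round(t(img[, , ch]) * 255)
  storage.mode(px) <- "integer"
  if (!is.null(crop)) {
    px <- px[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
  }
  h <- dim(px)[1]
  plate_image(px,
              origin_row = if (is.null(origin_row)) h else origin_row,
              front_row  = if (is.null(front_row)) 1L else front_row)
}

#' Write a plate image to disk
#'
#' @param img a [plate_image].
#' @param path output file; format from extension (png/jpg/tiff).
#' @return `path`, invisibly.
#' @export
write_plate <- function(img, path) {
  stopifnot(inherits(img, "plate_image"))
  d <- dim(img$pixels)
  arr <- array(0, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) arr[, , ch] <- t(img$pixels[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}

#' Resample a plate crop to a standard height
#'
#' Calibration AUC units depend on the pixel scale of the crop, so crops are
#' resampled (bilinear) to a fixed number of rows before the pixel pipeline
#' runs; the aspect ratio is preserved and the origin/front rows are scaled
#' with the image.
#'
#' @param img a [plate_image].
#' @param standard_height target number of rows (default 400).
#' @return A resampled [plate_image].
#' @export
resample_plate <- function(img, standard_height = 400L) {
  stopifnot(inherits(img, "plate_image"))
  d <- dim(img$pixels)
  if (d[1] == standard_height) return(img)
  scale <- standard_height / d[1]
  w <- max(32L, round(d[2] * scale))
  arr <- array(0, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) arr[, , ch] <- t(img$pixels[, , ch]) / 255
  res <- EBImage::resize(EBImage::Image(arr, colormode = "Color"),
                         w = w, h = standard_height)
  px <- array(0L, dim = c(standard_height, w, 3L))
  for (ch in 1:3) {
    v <- round(t(res[, , ch]) * 255)
    px[, , ch] <- pmax(0L, pmin(255L, as.integer(v)))
  }
  # map a row through the resize: row r (1-based) sits at centre (r-.5)/h
  map_row <- function(r) min(standard_height, max(1, (r - 0.5) * scale + 0.5))
  plate_image(px, origin_row = map_row(img$origin_row),
              front_row = map_row(img$front_row))
}
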
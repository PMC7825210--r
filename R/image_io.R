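#' Read a raster image
#'
#' Reads a PNG, TIFF, or JPEG file into the pipeline's working representation:
#' a numeric matrix (grayscale) or a height x width x 3 array (RGB), with
#' intensities normalized to `[0, 1]`. An alpha channel, if present, is
#' dropped. Pass RGB output through [to_grayscale()] before segmentation.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return A numeric matrix in `[0, 1]`, or a 3-channel array for RGB input.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64 * 64), 64), f)
#' img <- read_image(f)
#' dim(img)
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    vca_stop("`path` must be a single file path")
  }
  if (!file.exists(path)) {
    vca_io_stop(sprintf("cannot read image: file does not exist: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png  = png::readPNG,
    tif  = ,
    tiff = tiff::readTIFF,
    jpg  = ,
    jpeg = jpeg::readJPEG,
    vca_stop(sprintf(
      "unsupported image format '.%s' for %s (supported: png, tiff, jpeg)",
      ext, path))
  )
  img <- tryCatch(reader(path), error = function(e) {
    vca_io_stop(sprintf("failed to read image %s: %s", path, conditionMessage(e)))
  })
  if (is.list(img)) img <- img[[1L]]  # multi-page TIFF: first page
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) {
    img <- img[, , 1L]
  }
  img <- pmin(pmax(img, 0), 1)
  img
}

#' Convert an RGB raster to grayscale
#'
#' Uses Rec. 601 luma weights (0.299 R + 0.587 G + 0.114 B). Single-channel
#' input is returned unchanged.
#'
#' @param img Numeric matrix (already gray) or height x width x 3 array.
#' @return Numeric grayscale matrix with the same spatial size.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img) && is.numeric(img)) return(img)
  d <- dim(img)
  if (length(d) != 3L || !d[3L] %in% c(1L, 3L)) {
    vca_stop(sprintf(
      "expected 1 or 3 channels, got an array of shape [%s]",
      paste(d, collapse = ", ")))
  }
  if (d[3L] == 1L) return(img[, , 1L])
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based with the origin at the top-left pixel; `top` and
#' `left` are inclusive. All modules share this convention.
#'
#' @param top,left 0-based row/column of the top-left corner.
#' @param height,width Extent in pixels (both `>= 1`).
#' @return A `rect_roi` list.
#' @export
rect_roi <- function(top, left, height, width) {
  vals <- c(top = top, left = left, height = height, width = width)
  if (any(vals != floor(vals))) vca_stop("ROI fields must be integers")
  if (top < 0 || left < 0) vca_stop("ROI `top` and `left` must be >= 0")
  if (height < 1 || width < 1) vca_stop("ROI `height` and `width` must be >= 1")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "rect_roi")
}

#' Crop an image to a region of interest
#'
#' @param img Grayscale matrix or 3-channel array.
#' @param roi A [rect_roi()].
#' @return The cropped image; the source is not modified.
#' @export
crop_roi <- function(img, roi) {
  if (!inherits(roi, "rect_roi")) {
    roi <- do.call(rect_roi, as.list(roi)[c("top", "left", "height", "width")])
  }
  d <- dim(img)
  if (roi$top + roi$height > d[1L] || roi$left + roi$width > d[2L]) {
    vca_stop(sprintf(
      "ROI [top=%d, left=%d, height=%d, width=%d] extends past the %dx%d image",
      roi$top, roi$left, roi$height, roi$width, d[1L], d[2L]))
  }
  rows <- roi$top + seq_len(roi$height)
  cols <- roi$left + seq_len(roi$width)
  if (length(d) == 3L) img[rows, cols, , drop = FALSE] else img[rows, cols, drop = FALSE]
}

#' Write a grayscale image or binary mask as PNG
#'
#' Grayscale PNG is the pipeline's canonical intermediate format; logical
#' masks are written as 0/255.
#'
#' @param img Numeric matrix in `[0, 1]` or a logical matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  if (is.logical(img)) {
    m <- matrix(0, nrow(img), ncol(img))
    m[img] <- 1
    img <- m
  }
  assert_gray(img)
  tryCatch(png::writePNG(img, path), error = function(e) {
    vca_io_stop(sprintf("failed to write %s: %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Read a 0/255 PNG back as a logical mask
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- read_image(path)
  img <- to_grayscale(img)
  img >= 0.5
}
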
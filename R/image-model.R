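#' Construct a scan image
#'
#' The raster unit every pipeline stage consumes: an 8-bit grayscale or
#' 3-channel intensity array with a source identifier. Pixels are stored as an
#' integer array indexed `[row, column]` (grayscale) or `[row, column, channel]`
#' (RGB), values 0--255, origin at the top-left.
#'
#' @param pixels Numeric matrix (H x W) or array (H x W x 3), values 0--255.
#'   Values are rounded and clamped into range.
#' @param source_id Opaque identifier string (file path, or a DICOM
#'   SOPInstanceUID when available).
#' @return A `scan_image` object with fields `pixels`, `height`, `width`,
#'   `channels`, `source_id`.
#' @examples
#' img <- scan_image(matrix(0L, 20, 30))
#' img$height; img$width; img$channels
#' @export
scan_image <- function(pixels, source_id = "<memory>") {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3))) {
    stop("`pixels` must be an HxW matrix or HxWx3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (length(d) == 3 && d[3] == 4L) {          # drop alpha
    pixels <- pixels[, , 1:3, drop = FALSE]
    d <- dim(pixels)
  }
  if (length(d) == 3 && d[3] == 1L) {
    pixels <- pixels[, , 1]
    d <- dim(pixels)
  }
  channels <- if (length(d) == 2) 1L else as.integer(d[3])
  if (!channels %in% c(1L, 3L)) {
    stop("scan images must have 1 or 3 channels, got ", channels, call. = FALSE)
  }
  if (d[1] < 1 || d[2] < 1) stop("image must be at least 1x1", call. = FALSE)
  px <- round(pixels)
  px[px < 0] <- 0
  px[px > 255] <- 255
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, height = as.integer(d[1]), width = as.integer(d[2]),
         channels = channels, source_id = as.character(source_id)),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %dx%d, %d channel%s, source: %s\n",
              x$height, x$width, x$channels,
              if (x$channels > 1) "s" else "", x$source_id))
  invisible(x)
}

#' @export
dim.scan_image <- function(x) {
  if (x$channels == 1L) c(x$height, x$width) else c(x$height, x$width, x$channels)
}

is_scan_image <- function(x) inherits(x, "scan_image")

assert_scan <- function(scan) {
  if (!is_scan_image(scan)) stop("expected a `scan_image` object", call. = FALSE)
  invisible(scan)
}

#' Construct an axis-aligned bounding box
#'
#' Boxes use a 0-based pixel coordinate system with the origin at the topmost,
#' leftmost pixel; they are half-open on the right and bottom, covering columns
#' `[x_left, x_right)` and rows `[y_top, y_bottom)`, so `w = x_right - x_left`
#' and `h = y_bottom - y_top` are the exact pixel extents.
#'
#' @param x_left,y_top,x_right,y_bottom Integer pixel coordinates, 0-based.
#' @return A `bounding_box` object with fields `x_left`, `y_top`, `x_right`,
#'   `y_bottom`, `w`, `h`.
#' @examples
#' bounding_box(0, 0, 10, 5)   # 10 wide, 5 tall
#' @export
bounding_box <- function(x_left, y_top, x_right, y_bottom) {
  x_left <- as.integer(x_left); y_top <- as.integer(y_top)
  x_right <- as.integer(x_right); y_bottom <- as.integer(y_bottom)
  if (x_left < 0 || y_top < 0 || x_right <= x_left || y_bottom <= y_top) {
    stop("invalid bounding box: need 0 <= x_left < x_right and 0 <= y_top < y_bottom",
         call. = FALSE)
  }
  structure(
    list(x_left = x_left, y_top = y_top, x_right = x_right, y_bottom = y_bottom,
         w = x_right - x_left, h = y_bottom - y_top),
    class = "bounding_box"
  )
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> (x_left=%d, y_top=%d, x_right=%d, y_bottom=%d) w=%d h=%d\n",
              x$x_left, x$y_top, x$x_right, x$y_bottom, x$w, x$h))
  invisible(x)
}

is_bounding_box <- function(x) inherits(x, "bounding_box")

# Check that a box fits inside an image (or mask) of the given dims.
check_box_in <- function(box, height, width) {
  if (!is_bounding_box(box)) stop("expected a `bounding_box`", call. = FALSE)
  if (box$x_right > width || box$y_bottom > height) {
    stop("bounding box exceeds image bounds", call. = FALSE)
  }
  invisible(box)
}

# 1-based row/col index ranges covered by a 0-based half-open box.
box_rows <- function(box) (box$y_top + 1L):box$y_bottom
box_cols <- function(box) (box$x_left + 1L):box$x_right

#' Whole-image bounding box of a scan
#' @param scan A `scan_image`.
#' @return A `bounding_box` covering the full frame.
#' @export
full_box <- function(scan) {
  assert_scan(scan)
  bounding_box(0L, 0L, scan$width, scan$height)
}

#' Load a scan image from disk
#'
#' Reads PNG, JPEG, TIFF or uncompressed DICOM into a [scan_image()].
#' Source bit depths other than 8 are linearly rescaled to 0--255 (DICOM
#' frames are min--max rescaled per frame, so thresholds stated on 8-bit
#' values apply uniformly). Multi-frame DICOM returns the first frame; use
#' [load_dicom_frames()] for all frames.
#'
#' @param path Path to the image file.
#' @param format_hint Optional format override: one of `"DICOM"`, `"PNG"`,
#'   `"JPEG"`, `"TIFF"`. Default: guessed from the file extension, falling
#'   back to content sniffing.
#' @return A `scan_image`.
#' @export
load_image <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  fmt <- toupper(format_hint %||% guess_format(path))
  if (fmt == "DICOM") {
    frames <- load_dicom_frames(path)
    return(frames[[1L]])
  }
  px <- switch(fmt,
    PNG  = png::readPNG(path),
    JPEG = jpeg::readJPEG(path),
    TIFF = as.array(EBImage::readImage(path)),
    stop("unsupported image format for ", path, call. = FALSE)
  )
  if (fmt == "TIFF") px <- ebimage_to_pixels(px)
  scan_image(px * 255, source_id = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("PNG")
  if (ext %in% c("jpg", "jpeg")) return("JPEG")
  if (ext %in% c("tif", "tiff")) return("TIFF")
  if (ext %in% c("dcm", "dicom", "")) {
    con <- file(path, "rb"); on.exit(close(con))
    hdr <- readBin(con, "raw", 132L)
    if (length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM") return("DICOM")
    if (ext %in% c("dcm", "dicom")) return("DICOM")  # headerless part-10
  }
  stop("cannot determine image format of ", path, call. = FALSE)
}

# EBImage stores arrays as (x, y[, c]); pipeline convention is (row, col[, c]).
ebimage_to_pixels <- function(a) {
  if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
}

#' Write a scan image as an 8-bit PNG
#'
#' @param scan A `scan_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(scan, path) {
  assert_scan(scan)
  png::writePNG(scan$pixels / 255, target = path)
  invisible(path)
}

#' Convert a scan to grayscale
#'
#' 3-channel input is converted with the standard luma weighting
#' 0.299 R + 0.587 G + 0.114 B, rounded; 1-channel input is returned
#' unchanged (the conversion is idempotent).
#'
#' @param scan A `scan_image`.
#' @return A 1-channel `scan_image`.
#' @export
to_grayscale <- function(scan) {
  assert_scan(scan)
  if (scan$channels == 1L) return(scan)
  p <- scan$pixels
  g <- 0.299 * p[, , 1, drop = TRUE] + 0.587 * p[, , 2, drop = TRUE] +
    0.114 * p[, , 3, drop = TRUE]
  scan_image(matrix(g, scan$height, scan$width), source_id = scan$source_id)
}

#' Test whether a scan is grayscale
#'
#' True iff the scan has a single channel, or the per-pixel channel spread
#' (max channel minus min channel) never exceeds `tol`. The default `tol = 0`
#' demands exact channel equality; a small positive tolerance absorbs JPEG
#' chroma noise on true B-mode frames.
#'
#' @param scan A `scan_image`.
#' @param tol Intensity tolerance, default 0.
#' @return Logical scalar.
#' @export
is_grayscale <- function(scan, tol = 0) {
  assert_scan(scan)
  if (scan$channels == 1L) return(TRUE)
  p <- scan$pixels
  spread <- pmax(p[, , 1], p[, , 2], p[, , 3]) - pmin(p[, , 1], p[, , 2], p[, , 3])
  max(spread) <= tol
}

#' Most frequent pixel intensity
#'
#' The modal intensity of a grayscale scan, over the whole frame or a
#' region; ties are broken toward the lowest value. This is the background
#' estimate the crop stages threshold against.
#'
#' @param scan A 1-channel `scan_image` (convert with [to_grayscale()] first).
#' @param region Optional [bounding_box()] restricting the tally.
#' @return Integer intensity in 0--255.
#' @export
mode_pixel_value <- function(scan, region = NULL) {
  assert_scan(scan)
  if (scan$channels != 1L) stop("mode_pixel_value expects a 1-channel scan", call. = FALSE)
  px <- scan$pixels
  if (!is.null(region)) {
    check_box_in(region, scan$height, scan$width)
    px <- px[box_rows(region), box_cols(region), drop = FALSE]
  }
  if (length(px) == 0) stop("empty region", call. = FALSE)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  which.max(counts) - 1L   # which.max returns the first (lowest) maximum
}
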
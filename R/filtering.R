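#' Filtering parameters
#'
#' Thresholds governing invalid-scan and non-B-mode detection. An invalid scan
#' has more than `black_fraction_cutoff` of its scan area black, where black
#' means a grayscale value strictly below `black_value_cutoff`. A color scan is
#' non-B-mode when blood-flow-palette pixels exceed `flow_fraction_cutoff` of
#' the scan area, or when a green/white indicator rectangle or image-spanning
#' line is present.
#'
#' @param black_value_cutoff Intensity below which a pixel counts as black
#'   (strict; default 5).
#' @param black_fraction_cutoff Fraction of black pixels above which a scan is
#'   invalid (strict; default 0.75).
#' @param flow_fraction_cutoff Fraction of flow-colored pixels above which a
#'   scan is non-B-mode (default 0.005).
#' @param grayscale_tol Channel-equality tolerance for [is_grayscale()]
#'   (default 0).
#' @param span_fraction Fraction of image height/width a line must span to
#'   count as image-spanning (default 0.80).
#' @return A `filter_params` list.
#' @export
filter_params <- function(black_value_cutoff = 5, black_fraction_cutoff = 0.75,
                          flow_fraction_cutoff = 0.005, grayscale_tol = 0,
                          span_fraction = 0.80) {
  stopifnot(black_value_cutoff >= 0, black_value_cutoff <= 255,
            black_fraction_cutoff > 0, black_fraction_cutoff < 1,
            flow_fraction_cutoff > 0, flow_fraction_cutoff < 1)
  structure(list(black_value_cutoff = black_value_cutoff,
                 black_fraction_cutoff = black_fraction_cutoff,
                 flow_fraction_cutoff = flow_fraction_cutoff,
                 grayscale_tol = grayscale_tol,
                 span_fraction = span_fraction),
            class = "filter_params")
}

#' HSV color mask specification
#'
#' An HSV in-range test plus dilation, in OpenCV-style units (hue 0--179,
#' saturation and value 0--255). When `hsv_low[1] > hsv_high[1]` the hue range
#' wraps around 180 (used for red). Vendor palettes vary, so every range is a
#' parameter rather than a constant.
#'
#' @param name Mask name (e.g. `"RED"`, `"GREEN_WHITE_INDICATOR"`).
#' @param hsv_low,hsv_high Length-3 numeric vectors `(h, s, v)`.
#' @param dilation_radius Disc radius (pixels) for post-threshold dilation.
#' @return A `color_mask_spec` list.
#' @export
color_mask_spec <- function(name, hsv_low, hsv_high, dilation_radius = 2) {
  stopifnot(length(hsv_low) == 3, length(hsv_high) == 3,
            all(hsv_low[2:3] <= hsv_high[2:3]))
  structure(list(name = name, hsv_low = as.numeric(hsv_low),
                 hsv_high = as.numeric(hsv_high),
                 dilation_radius = as.integer(dilation_radius)),
            class = "color_mask_spec")
}

#' Default color mask set
#'
#' The blood-flow palette (orange, green, yellow, red, blue) and the
#' green/white indicator mask used for elastography and Doppler overlay
#' boxes. The green/white mask is the union of the green range and a
#' low-saturation bright-white range, handled by `build_color_mask()`
#' through the `extra_white` field.
#'
#' @return Named list of [color_mask_spec()] objects.
#' @export
default_color_masks <- function() {
  masks <- list(
    RED    = color_mask_spec("RED",    c(170, 80, 80), c(10, 255, 255)),
    ORANGE = color_mask_spec("ORANGE", c(11, 80, 80),  c(25, 255, 255)),
    YELLOW = color_mask_spec("YELLOW", c(26, 80, 80),  c(34, 255, 255)),
    GREEN  = color_mask_spec("GREEN",  c(35, 80, 80),  c(85, 255, 255)),
    BLUE   = color_mask_spec("BLUE",   c(100, 80, 80), c(130, 255, 255)),
    GREEN_WHITE_INDICATOR = color_mask_spec("GREEN_WHITE_INDICATOR",
                                            c(35, 80, 80), c(85, 255, 255))
  )
  masks$GREEN_WHITE_INDICATOR$extra_white <- c(s_max = 30, v_min = 220)
  masks
}

flow_mask_names <- c("RED", "ORANGE", "YELLOW", "GREEN", "BLUE")

#' Flag an invalid (predominantly black) scan
#'
#' A scan is invalid when the fraction of black pixels -- grayscale value
#' strictly below `black_value_cutoff` -- within the scan area is strictly
#' greater than `black_fraction_cutoff`.
#'
#' @param scan A `scan_image`.
#' @param params A [filter_params()] object.
#' @param scan_area Optional [bounding_box()]; whole frame when absent.
#' @return Logical scalar.
#' @export
detect_invalid <- function(scan, params = filter_params(), scan_area = NULL) {
  g <- to_grayscale(scan)
  px <- g$pixels
  if (!is.null(scan_area)) {
    check_box_in(scan_area, g$height, g$width)
    px <- px[box_rows(scan_area), box_cols(scan_area), drop = FALSE]
  }
  mean(px < params$black_value_cutoff) > params$black_fraction_cutoff
}

# HSV planes of a 3-channel scan in OpenCV units: hue 0-179, sat/val 0-255.
scan_hsv <- function(scan) {
  p <- scan$pixels
  hsv <- grDevices::rgb2hsv(r = as.vector(p[, , 1]), g = as.vector(p[, , 2]),
                            b = as.vector(p[, , 3]), maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 180, scan$height, scan$width) %% 180,
       s = matrix(hsv[2, ] * 255, scan$height, scan$width),
       v = matrix(hsv[3, ] * 255, scan$height, scan$width))
}

#' Build a dilated HSV color mask
#'
#' Thresholds a 3-channel scan against the HSV range of `spec` (hue wrapping
#' honored), then dilates the binary mask with a disc of the spec's radius.
#' 1-channel input yields an all-`FALSE` mask.
#'
#' @param scan A `scan_image`.
#' @param spec A [color_mask_spec()].
#' @param hsv Optional precomputed HSV planes (internal reuse).
#' @param dilate Apply the spec's dilation (default `TRUE`). The flow-area
#'   fraction test uses the raw in-range mask, since dilation exists to
#'   connect fragments of overlay graphics, not to inflate pixel counts.
#' @return Logical H x W matrix.
#' @export
build_color_mask <- function(scan, spec, hsv = NULL, dilate = TRUE) {
  assert_scan(scan)
  if (scan$channels == 1L) return(matrix(FALSE, scan$height, scan$width))
  if (is.null(hsv)) hsv <- scan_hsv(scan)
  lo <- spec$hsv_low; hi <- spec$hsv_high
  hue_ok <- if (lo[1] <= hi[1]) hsv$h >= lo[1] & hsv$h <= hi[1]
            else hsv$h >= lo[1] | hsv$h <= hi[1]
  m <- hue_ok & hsv$s >= lo[2] & hsv$s <= hi[2] & hsv$v >= lo[3] & hsv$v <= hi[3]
  if (!is.null(spec$extra_white)) {
    m <- m | (hsv$s <= spec$extra_white[["s_max"]] & hsv$v >= spec$extra_white[["v_min"]])
  }
  if (dilate) dilate_mask(m, spec$dilation_radius) else m
}

#' Detect indicator rectangles and image-spanning lines
#'
#' Fires on the green/white threshold image when it contains either (a) a
#' component whose simplified outline has at least three near-right-angle,
#' axis-aligned corners forming a rectangle fragment that covers at least
#' `min_rect_extent` of both dimensions of its bounding box, or (b) a
#' connected run of mask pixels spanning at least `span_fraction` of the
#' image height (vertical line) or width (horizontal line), tolerating gaps
#' up to `max_gap` pixels. Components smaller than `min_rect_px` in either
#' dimension are ignored by the rectangle test so burnt-in text glyphs and
#' text lines (themselves small axis-aligned shapes) cannot fire it;
#' indicator overlays are software-scale graphics, far larger than glyphs.
#'
#' @param mask Logical H x W matrix (green/white threshold image).
#' @param span_fraction Minimum spanned fraction for the line test (default 0.80).
#' @param min_rect_extent Minimum covered fraction of the component box in each
#'   axis for the rectangle test (default 0.5).
#' @param min_rect_px Minimum component bounding-box size for the rectangle
#'   test (default 40).
#' @param max_gap Maximum tolerated gap in a spanning run, pixels (default 5).
#' @return Logical scalar.
#' @export
detect_indicator_shape <- function(mask, span_fraction = 0.80,
                                   min_rect_extent = 0.5, min_rect_px = 40,
                                   max_gap = 5) {
  if (!any(mask)) return(FALSE)
  h <- nrow(mask); w <- ncol(mask)
  if (spanning_run_exists(mask, axis = "col", need = span_fraction * h, max_gap = max_gap) ||
      spanning_run_exists(mask, axis = "row", need = span_fraction * w, max_gap = max_gap)) {
    return(TRUE)
  }
  lab <- label_components(mask)
  boxes <- component_boxes(lab)
  boxes <- boxes[pmin(boxes$w, boxes$h) >= min_rect_px, , drop = FALSE]
  if (nrow(boxes) == 0) return(FALSE)
  contours <- component_contours(lab)
  for (i in seq_len(nrow(boxes))) {
    pts <- contours[[boxes$label[i]]]
    if (is.null(pts) || nrow(pts) < 8) next
    perim <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
    poly <- simplify_polygon(pts, eps = 0.02 * perim)
    if (nrow(poly) < 3) next
    geo <- polygon_vertex_geometry(poly)
    axis_aligned <- function(d) pmin(d, 180 - d) <= 20 | abs(d - 90) <= 20
    corner <- geo$angle >= 80 & geo$angle <= 100 &
      axis_aligned(geo$dir_in) & axis_aligned(geo$dir_out)
    if (sum(corner) < 3) next
    horiz <- pmin(geo$dir_out, 180 - geo$dir_out) <= 20
    vert <- abs(geo$dir_out - 90) <= 20
    if (sum(geo$len_out[horiz]) >= min_rect_extent * boxes$w[i] &&
        sum(geo$len_out[vert]) >= min_rect_extent * boxes$h[i]) {
      return(TRUE)
    }
  }
  FALSE
}

# Longest gap-tolerant run of TRUE down any single column (axis = "col") or
# across any single row (axis = "row"); TRUE if some run reaches `need`.
spanning_run_exists <- function(mask, axis, need, max_gap) {
  m <- if (axis == "col") mask else t(mask)
  for (j in seq_len(ncol(m))) {
    idx <- which(m[, j])
    if (length(idx) < need) next
    if (length(idx) == 0) next
    gaps <- diff(idx)
    breaks <- which(gaps > max_gap + 1)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(idx))
    if (any(idx[ends] - idx[starts] + 1L >= need)) return(TRUE)
  }
  FALSE
}

#' Fraction of flow-mask pixels within the scan area
#'
#' @param flow_mask Logical H x W matrix.
#' @param scan_area A [bounding_box()] within the mask bounds.
#' @return Fraction in `[0, 1]`.
#' @export
flow_fraction <- function(flow_mask, scan_area) {
  check_box_in(scan_area, nrow(flow_mask), ncol(flow_mask))
  sub <- flow_mask[box_rows(scan_area), box_cols(scan_area), drop = FALSE]
  sum(sub) / (scan_area$w * scan_area$h)
}

#' Classify a scan as B-mode or non-B-mode
#'
#' The four-step mode test: (1) grayscale scans are B-mode; (2) HSV masks for
#' the blood-flow palette and for green/white indicator overlays are built and
#' dilated; (3) indicator rectangles or image-spanning lines in the
#' green/white mask mark the scan non-B-mode; (4) the scan is non-B-mode if
#' the union of (undilated) flow-color masks covers more than
#' `flow_fraction_cutoff` of the scan area. The scan area defaults to the stage-1 crop box so the
#' denominator is echo area, not frame area; if cropping degenerates the full
#' frame is used.
#'
#' @param scan A `scan_image`.
#' @param params A [filter_params()].
#' @param specs Named list of [color_mask_spec()]; default [default_color_masks()].
#' @param scan_area Optional [bounding_box()].
#' @return `"B_MODE"` or `"NON_B_MODE"`.
#' @export
classify_scan_mode <- function(scan, params = filter_params(),
                               specs = default_color_masks(), scan_area = NULL) {
  assert_scan(scan)
  if (is_grayscale(scan, tol = params$grayscale_tol)) return("B_MODE")
  hsv <- scan_hsv(scan)
  gw <- build_color_mask(scan, specs$GREEN_WHITE_INDICATOR, hsv = hsv)
  if (detect_indicator_shape(gw, span_fraction = params$span_fraction)) {
    return("NON_B_MODE")
  }
  flow <- matrix(FALSE, scan$height, scan$width)
  for (nm in intersect(flow_mask_names, names(specs))) {
    flow <- flow | build_color_mask(scan, specs[[nm]], hsv = hsv, dilate = FALSE)
  }
  if (is.null(scan_area)) {
    scan_area <- tryCatch(stage1_crop(to_grayscale(scan))$box,
                          buscurate_degenerate_input = function(e) full_box(scan))
  }
  if (flow_fraction(flow, scan_area) > params$flow_fraction_cutoff) {
    return("NON_B_MODE")
  }
  "B_MODE"
}
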
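#' Caliper detection parameters
#'
#' @param border_mask_fraction Fraction of each dimension blacked out per side
#'   before edge detection (default 0.15), suppressing software overlays and
#'   burnt-in text near the frame edges.
#' @param min_box_px,max_box_px Inclusive bounds on contour bounding-box height
#'   and width for a contour to count as a caliper (defaults 10 and 70).
#' @param max_filter_size Square max-filter window applied to the edge image
#'   (default 3).
#' @param dilation_radius Disc radius for the post-filter dilation (default 2).
#' @param edge_threshold Edge-response binarization level (default 120):
#'   speckle texture yields moderate nonzero responses everywhere (a zero
#'   threshold would merge the scan area into one component), while
#'   high-contrast caliper borders saturate the clipped edge response; the
#'   default sits between the two regimes.
#' @param hough_min_line_px Minimum supported segment length for the Hough
#'   extension (default 15).
#' @param hough_max_gap_px Maximum gap bridged along a Hough segment (default
#'   4, chosen to bridge dotted spanning lines).
#' @param hough_parallel_tol_deg Segments within this angle are considered
#'   parallel and never intersect (default 5).
#' @return A `caliper_params` list.
#' @export
caliper_params <- function(border_mask_fraction = 0.15, min_box_px = 10,
                           max_box_px = 70, max_filter_size = 3,
                           dilation_radius = 2, edge_threshold = 120,
                           hough_min_line_px = 15, hough_max_gap_px = 4,
                           hough_parallel_tol_deg = 5) {
  stopifnot(min_box_px > 0, min_box_px < max_box_px,
            border_mask_fraction >= 0, border_mask_fraction < 0.5)
  structure(list(border_mask_fraction = border_mask_fraction,
                 min_box_px = min_box_px, max_box_px = max_box_px,
                 max_filter_size = max_filter_size,
                 dilation_radius = dilation_radius,
                 edge_threshold = edge_threshold,
                 hough_min_line_px = hough_min_line_px,
                 hough_max_gap_px = hough_max_gap_px,
                 hough_parallel_tol_deg = hough_parallel_tol_deg),
            class = "caliper_params")
}

# Shared enhancement for both caliper detectors: black-mask the outer border,
# apply a 3x3 Laplacian edge kernel (high where local intensity changes,
# negatives clipped), max-filter, and binarize. Edge responses within the
# border band plus a small reach margin are zeroed so the artificial frame
# created by the masking never contributes contours or lines.
caliper_edge_mask <- function(gray, params) {
  h <- gray$height; w <- gray$width
  br <- floor(params$border_mask_fraction * h)
  bc <- floor(params$border_mask_fraction * w)
  px <- gray$pixels * 1.0
  if (br > 0) { px[1:br, ] <- 0; px[(h - br + 1):h, ] <- 0 }
  if (bc > 0) { px[, 1:bc] <- 0; px[, (w - bc + 1):w] <- 0 }
  k <- matrix(-1, 3, 3); k[2, 2] <- 8
  edges <- conv2(px, k)
  edges[edges < 0] <- 0
  edges[edges > 255] <- 255
  edges <- max_filter(edges, params$max_filter_size)
  bin <- edges > params$edge_threshold
  margin <- 1L + floor(params$max_filter_size / 2) + params$dilation_radius + 1L
  rb <- min(h, br + margin); cb <- min(w, bc + margin)
  if (rb > 0) { bin[1:rb, ] <- FALSE; bin[(h - rb + 1):h, ] <- FALSE }
  if (cb > 0) { bin[, 1:cb] <- FALSE; bin[, (w - cb + 1):w] <- FALSE }
  bin
}

#' Detect lesion measurement calipers
#'
#' Two-step contour method: the frame is border-masked and edge-enhanced
#' (Laplacian edge kernel, max filter, binarization, dilation), then external
#' contours of the result are measured, and every contour whose bounding box
#' is between `min_box_px` and `max_box_px` (inclusive) in both height and
#' width is returned as a caliper. Dilation decides component membership
#' (fragments of one mark merge); each box is measured on the undilated edge
#' support so the bounds apply to the artifact's own extent. Boxes are in
#' full-image coordinates; removal or cropping is left to the caller.
#'
#' @param scan A `scan_image` (converted to grayscale internally).
#' @param params A [caliper_params()].
#' @return A tibble with one row per detected caliper: `x_left`, `y_top`,
#'   `x_right`, `y_bottom`, `w`, `h` (0-based half-open boxes).
#' @export
detect_calipers <- function(scan, params = caliper_params()) {
  g <- to_grayscale(scan)
  bin <- caliper_edge_mask(g, params)
  # dilation merges fragments of one mark into one component; each component's
  # box is then measured on the undilated edge support so the size test sees
  # the artifact's true extent, not the dilation halo
  lab <- label_components(dilate_mask(bin, params$dilation_radius))
  lab[!bin] <- 0L
  boxes <- component_boxes(lab)
  boxes <- boxes[boxes$w >= params$min_box_px & boxes$w <= params$max_box_px &
                 boxes$h >= params$min_box_px & boxes$h <= params$max_box_px, ,
                 drop = FALSE]
  tibble::as_tibble(boxes[, c("x_left", "y_top", "x_right", "y_bottom", "w", "h")])
}

#' Hough-line caliper detection
#'
#' Extension for annotation styles where calipers are joined by dotted
#' spanning lines, which merge into one over-sized component under the
#' contour method. Line segments are extracted from the edge image by a
#' Hough transform with gap bridging; a caliper is detected when at least two
#' segments are non-parallel (angle difference beyond
#' `hough_parallel_tol_deg`) and their supporting lines intersect within both
#' segments' extents (padded by 3 px).
#'
#' @inheritParams detect_calipers
#' @return Logical scalar.
#' @export
detect_calipers_hough <- function(scan, params = caliper_params()) {
  g <- to_grayscale(scan)
  bin <- caliper_edge_mask(g, params)
  segs <- hough_segments(bin, min_len = params$hough_min_line_px,
                         max_gap = params$hough_max_gap_px)
  n <- nrow(segs)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (segments_cross(segs[i, ], segs[j, ],
                         parallel_tol_deg = params$hough_parallel_tol_deg)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Dual-view detection parameters
#'
#' @param min_aspect Scans with width below `min_aspect` times height are
#'   never dual-view (default 0.75).
#' @param midline_edge_count Minimum Canny edge pixels in the midline column
#'   (default 100).
#' @param neighbor_margin Offset of the comparison columns (default 10).
#' @param neighbor_slack Slack added to the neighbor counts (default 10).
#' @param canny_low,canny_high Canny hysteresis thresholds on 8-bit input
#'   (defaults 50 and 150).
#' @return A `dual_view_params` list.
#' @export
dual_view_params <- function(min_aspect = 0.75, midline_edge_count = 100,
                             neighbor_margin = 10, neighbor_slack = 10,
                             canny_low = 50, canny_high = 150) {
  stopifnot(min_aspect > 0, midline_edge_count > 0,
            neighbor_margin > 0, neighbor_slack > 0)
  structure(list(min_aspect = min_aspect,
                 midline_edge_count = midline_edge_count,
                 neighbor_margin = neighbor_margin,
                 neighbor_slack = neighbor_slack,
                 canny_low = canny_low, canny_high = canny_high),
            class = "dual_view_params")
}

#' Detect dual-view composite scans
#'
#' Four-step test: (1) scans whose teal/green mask covers a non-trivial
#' fraction of the frame are elastography, not dual-view; (2) scans with
#' width below `min_aspect` of their height are excluded; (3) Canny edge
#' detection; (4) the scan is dual-view when the edge-pixel count `c(m)` in
#' the midline column `m = floor(width / 2)` is both greater than
#' `midline_edge_count` and greater than `neighbor_slack` plus the counts at
#' columns `m - neighbor_margin` and `m + neighbor_margin`.
#'
#' @param scan A `scan_image`.
#' @param params A [dual_view_params()].
#' @param specs Color mask set providing the `GREEN` spec (default
#'   [default_color_masks()]).
#' @param green_fraction_cutoff Green-mask fraction above which the scan is
#'   treated as elastography (default 0.005).
#' @return Logical scalar.
#' @export
detect_dual_view <- function(scan, params = dual_view_params(),
                             specs = default_color_masks(),
                             green_fraction_cutoff = 0.005) {
  assert_scan(scan)
  if (scan$width < 2 * params$neighbor_margin + 1) {
    stop("image too narrow for the dual-view midline test", call. = FALSE)
  }
  if (scan$channels == 3L) {
    green <- build_color_mask(scan, specs$GREEN)
    if (mean(green) > green_fraction_cutoff) return(FALSE)
  }
  if (scan$width < params$min_aspect * scan$height) return(FALSE)
  g <- to_grayscale(scan)
  edges <- canny_edges(g$pixels, low = params$canny_low, high = params$canny_high)
  m <- floor(scan$width / 2)                      # 0-based midline column
  cnt <- function(x0) sum(edges[, x0 + 1L])
  cm <- cnt(m)
  cm > params$midline_edge_count &&
    cm > params$neighbor_slack + cnt(m - params$neighbor_margin) &&
    cm > params$neighbor_slack + cnt(m + params$neighbor_margin)
}
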
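degenerate_input_error <- function(msg) {
  stop(structure(class = c("buscurate_degenerate_input", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Stage-1 scan-area crop
#'
#' Thresholds the grayscale frame at mode pixel value + 10, opens the binary
#' mask (erosion then dilation with disc brushes, which strips burnt-in text
#' strokes), isolates the largest 8-connected component, and returns its tight
#' bounding box together with the component mask.
#'
#' @param scan A 1-channel `scan_image`.
#' @param erosion_radius,dilation_radius Disc radii for the opening (default 3).
#' @return List with `box` ([bounding_box()]), `mask` (logical H x W component
#'   mask) and `mode_value` (the background mode used for thresholding).
#' @export
stage1_crop <- function(scan, erosion_radius = 3, dilation_radius = 3) {
  assert_scan(scan)
  if (scan$channels != 1L) stop("stage1_crop expects a 1-channel scan", call. = FALSE)
  mode_val <- mode_pixel_value(scan)
  mask <- scan$pixels > mode_val + 10
  mask <- dilate_mask(erode_mask(mask, erosion_radius), dilation_radius)
  if (!any(mask)) {
    degenerate_input_error("no scan area found: nothing above mode + 10 after opening")
  }
  lab <- label_components(mask)
  boxes <- component_boxes(lab)
  best <- boxes[which.max(boxes$area), ]
  comp <- lab == best$label
  list(box = bounding_box(best$x_left, best$y_top, best$x_right, best$y_bottom),
       mask = comp, mode_value = mode_val)
}

#' Classify the scan-area shape
#'
#' Rectangular scan areas completely fill their stage-1 bounding box; the test
#' is component area over box area at least `rect_fill_cutoff`, with the
#' default 0.95 tolerating anti-aliasing and small text nicks.
#'
#' @param component_mask Logical H x W mask of the stage-1 component.
#' @param box The stage-1 [bounding_box()].
#' @param rect_fill_cutoff Fill-ratio cutoff (default 0.95).
#' @return `"RECTANGULAR"` or `"NON_RECTANGULAR"`.
#' @export
classify_shape <- function(component_mask, box, rect_fill_cutoff = 0.95) {
  fill <- sum(component_mask[box_rows(box), box_cols(box)]) / (box$w * box$h)
  if (fill >= rect_fill_cutoff) "RECTANGULAR" else "NON_RECTANGULAR"
}

#' Stage-2 thirds-slice crop refinement
#'
#' For non-rectangular scan areas: the stage-1 box rows are partitioned into
#' three horizontal bands; within each band the leftmost and rightmost
#' non-mode-valued columns are found, and the refined `x_left`/`x_right` are
#' the medians of the three band extremes. The refined `y_top`/`y_bottom`
#' come from the symmetric rule over three vertical bands. Band edges are
#' integer-floored; a band containing no non-mode pixel contributes the
#' corresponding stage-1 box edge. Width and height are refined independently
#' from the same stage-1 box.
#'
#' @param scan A 1-channel `scan_image`.
#' @param box The stage-1 [bounding_box()].
#' @param mode_value Background mode intensity (global image mode by default
#'   in [crop_scan()]).
#' @return The refined [bounding_box()].
#' @export
stage2_crop <- function(scan, box, mode_value) {
  assert_scan(scan)
  if (scan$channels != 1L) stop("stage2_crop expects a 1-channel scan", call. = FALSE)
  check_box_in(box, scan$height, scan$width)
  nonmode <- scan$pixels != mode_value

  ext <- band_extremes(nonmode, box)
  med <- function(v) sort(v)[2L]   # middle of three, no interpolation
  x_left <- med(ifelse(is.na(ext$h_min), box$x_left, ext$h_min))
  x_right <- med(ifelse(is.na(ext$h_max), box$x_right - 1L, ext$h_max)) + 1L
  y_top <- med(ifelse(is.na(ext$v_min), box$y_top, ext$v_min))
  y_bottom <- med(ifelse(is.na(ext$v_max), box$y_bottom - 1L, ext$v_max)) + 1L
  if (x_right <= x_left || y_bottom <= y_top) return(box)  # fully degenerate bands
  bounding_box(x_left, y_top, x_right, y_bottom)
}

# Per-band extreme non-mode coordinates inside `box` (0-based). Horizontal
# bands give column extremes (h_min/h_max); vertical bands give row extremes.
# NA marks a band with no non-mode pixel. Exposed internally so tests can
# compare against a brute-force scan.
band_extremes <- function(nonmode, box) {
  sub <- nonmode[box_rows(box), box_cols(box), drop = FALSE]
  h <- box$h; w <- box$w
  hb <- c(0L, floor(h / 3), floor(2 * h / 3), h)    # horizontal band row edges
  vb <- c(0L, floor(w / 3), floor(2 * w / 3), w)
  h_min <- h_max <- v_min <- v_max <- rep(NA_integer_, 3)
  for (i in 1:3) {
    if (hb[i + 1] > hb[i]) {
      band <- sub[(hb[i] + 1L):hb[i + 1], , drop = FALSE]
      cols <- which(colSums(band) > 0)
      if (length(cols)) {
        h_min[i] <- box$x_left + min(cols) - 1L
        h_max[i] <- box$x_left + max(cols) - 1L
      }
    }
    if (vb[i + 1] > vb[i]) {
      band <- sub[, (vb[i] + 1L):vb[i + 1], drop = FALSE]
      rows <- which(rowSums(band) > 0)
      if (length(rows)) {
        v_min[i] <- box$y_top + min(rows) - 1L
        v_max[i] <- box$y_top + max(rows) - 1L
      }
    }
  }
  list(h_min = h_min, h_max = h_max, v_min = v_min, v_max = v_max)
}

#' Two-stage scan-area crop
#'
#' Runs [stage1_crop()], classifies the component shape, and applies the
#' [stage2_crop()] thirds-slice refinement when the scan area is not
#' rectangular. The stage-2 non-mode test uses the global grayscale mode
#' (the background value) by default.
#'
#' @param scan A `scan_image` (converted to grayscale internally).
#' @param erosion_radius,dilation_radius Opening radii for stage 1.
#' @param rect_fill_cutoff Rectangularity cutoff for [classify_shape()].
#' @return A `crop_result`: list with `stage1_box`, `stage2_box`,
#'   `shape_class`, `fill_ratio`.
#' @export
crop_scan <- function(scan, erosion_radius = 3, dilation_radius = 3,
                      rect_fill_cutoff = 0.95) {
  g <- to_grayscale(scan)
  s1 <- stage1_crop(g, erosion_radius, dilation_radius)
  fill <- sum(s1$mask[box_rows(s1$box), box_cols(s1$box)]) / (s1$box$w * s1$box$h)
  shape <- classify_shape(s1$mask, s1$box, rect_fill_cutoff)
  s2 <- if (shape == "RECTANGULAR") s1$box else stage2_crop(g, s1$box, s1$mode_value)
  structure(list(stage1_box = s1$box, stage2_box = s2,
                 shape_class = shape, fill_ratio = fill),
            class = "crop_result")
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> %s (fill %.3f)\n", x$shape_class, x$fill_ratio))
  cat("  stage1: "); print(x$stage1_box)
  cat("  stage2: "); print(x$stage2_box)
  invisible(x)
}

#' Extract the cropped sub-image of a crop result
#'
#' @param scan The original `scan_image`.
#' @param box A [bounding_box()] (typically `crop$stage2_box`).
#' @return A `scan_image` restricted to the box.
#' @export
apply_crop <- function(scan, box) {
  assert_scan(scan)
  check_box_in(box, scan$height, scan$width)
  px <- if (scan$channels == 1L) scan$pixels[box_rows(box), box_cols(box), drop = FALSE]
        else scan$pixels[box_rows(box), box_cols(box), , drop = FALSE]
  scan_image(px, source_id = scan$source_id)
}
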
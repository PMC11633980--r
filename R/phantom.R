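# Synthetic BUS-screenshot phantoms with machine-readable ground truth.
# The generator emulates the artifact taxonomy the curation pipeline must
# recognize: speckled scan areas of several shapes on black background,
# burnt-in ACR-style text, measurement calipers (optionally joined by dotted
# spanning lines), Doppler color boxes, green/white indicator overlays,
# side-by-side dual-view composites, and near-black invalid frames.
# Realism is a non-goal: speckle is a smoothed clipped-Gaussian field, which
# reproduces the intensity statistics and spatial smoothness the detectors'
# thresholds are stated against, not ultrasound physics.

#' Declarative phantom specification
#'
#' Describes one synthetic scan; [render_phantom()] turns it into pixels plus
#' ground truth. All coordinates are 0-based image coordinates.
#'
#' @param canvas `c(height, width)` in pixels.
#' @param shape Scan-area shape: `"RECTANGULAR"`, `"TRAPEZOID"`, `"CONVEX"`,
#'   or `"IRREGULAR"`.
#' @param area_margin Fractions `c(top, bottom, left, right)` of the canvas
#'   left black around the scan area.
#' @param speckle `c(mean, sd)` of the clipped-Gaussian speckle field
#'   (default mean 90, sd 30).
#' @param speckle_smooth Gaussian smoothing sigma of the speckle field in
#'   pixels (default 3; echo texture is spatially correlated, with a grain of
#'   a few pixels).
#' @param calipers Tibble or data.frame with columns `cx`, `cy`, `style`
#'   (`"CROSS"`, `"X"`, `"NUMBER"`), `size`; `NULL` for none.
#' @param spanning_line Optional dotted-line annotation joining calipers:
#'   list with `x0`, `y0`, `x1`, `y1`, `dash` (default 4), `gap` (default 3).
#'   A list of such lists draws several lines.
#' @param doppler_box Optional list `(box = bounding_box, fraction, palette)`:
#'   scattered blood-flow-colored pixels inside the box.
#' @param indicator_box Optional list `(box = bounding_box, style)` with style
#'   `"complete"`, `"partial"`, or `"line"`; green overlay graphics.
#' @param text_items Tibble/data.frame with columns `text`, `x`, `y` and
#'   optionally `scale`; `NULL` for none.
#' @param fields Optional named list of the structured field values the text
#'   encodes (recorded in ground truth for extraction tests).
#' @param dual_view Render two independent side-by-side scan areas split at
#'   the midline.
#' @param invalid Render a near-black invalid frame (excludes all other
#'   artifacts).
#' @param color Force a 3-channel canvas; implied by doppler/indicator boxes.
#' @param chroma_jitter Fraction of scan-area pixels given a small random
#'   channel offset (emulates JPEG chroma noise on color-saved B-mode;
#'   default 0).
#' @param seed Integer seed making the rendering deterministic.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(canvas = c(420L, 560L), shape = "RECTANGULAR",
                         area_margin = c(0.08, 0.10, 0.09, 0.09),
                         speckle = c(90, 30), speckle_smooth = 3,
                         calipers = NULL, spanning_line = NULL,
                         doppler_box = NULL, indicator_box = NULL,
                         text_items = NULL, fields = NULL,
                         dual_view = FALSE, invalid = FALSE,
                         color = FALSE, chroma_jitter = 0, seed = 1L) {
  shape <- match.arg(shape, c("RECTANGULAR", "TRAPEZOID", "CONVEX", "IRREGULAR"))
  if (invalid && (dual_view || !is.null(calipers) || !is.null(doppler_box) ||
                  !is.null(indicator_box) || !is.null(spanning_line))) {
    stop("invalid=TRUE excludes all other artifacts", call. = FALSE)
  }
  if (!is.null(calipers)) {
    calipers <- tibble::as_tibble(calipers)
    stopifnot(all(c("cx", "cy", "style", "size") %in% names(calipers)))
    if (any(calipers$size < 4 | calipers$size > 100)) {
      stop("caliper sizes must be in [4, 100] px (field: calipers$size)", call. = FALSE)
    }
    bad <- calipers$cx < 0 | calipers$cx >= canvas[2] |
           calipers$cy < 0 | calipers$cy >= canvas[1]
    if (any(bad)) stop("caliper centers outside canvas (field: calipers)", call. = FALSE)
  }
  if (!is.null(text_items)) {
    text_items <- tibble::as_tibble(text_items)
    if (!"scale" %in% names(text_items)) text_items$scale <- 2L
  }
  if (!is.null(spanning_line) && !is.null(spanning_line$x0)) {
    spanning_line <- list(spanning_line)
  }
  structure(list(canvas = as.integer(canvas), shape = shape,
                 area_margin = area_margin, speckle = speckle,
                 speckle_smooth = speckle_smooth, calipers = calipers,
                 spanning_line = spanning_line, doppler_box = doppler_box,
                 indicator_box = indicator_box, text_items = text_items,
                 fields = fields, dual_view = isTRUE(dual_view),
                 invalid = isTRUE(invalid), color = isTRUE(color),
                 chroma_jitter = chroma_jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Scan-area mask for one view placed at rows r0:r1, cols c0:c1 (1-based).
shape_mask <- function(h, w, r0, r1, c0, c1, shape) {
  mask <- matrix(FALSE, h, w)
  if (shape == "RECTANGULAR") {
    mask[r0:r1, c0:c1] <- TRUE
  } else if (shape == "TRAPEZOID") {
    cx <- (c0 + c1) / 2
    full <- (c1 - c0 + 1)
    for (r in r0:r1) {
      half <- (0.5 + 0.5 * (r - r0) / (r1 - r0)) * full / 2   # top width = half bottom
      cc <- max(c0, ceiling(cx - half)):min(c1, floor(cx + half))
      mask[r, cc] <- TRUE
    }
  } else if (shape == "CONVEX") {
    apex_r <- r0 - 0.9 * (r1 - r0)           # fan apex above the frame
    cx <- (c0 + c1) / 2
    phi <- atan2((c1 - c0) / 2, r1 - apex_r)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    rho <- sqrt((rows - apex_r)^2 + (cols - cx)^2)
    ang <- atan2(cols - cx, rows - apex_r)
    mask <- rho >= (r0 - apex_r) & rho <= (r1 - apex_r) &
            abs(ang) <= phi & rows >= r0
  } else { # IRREGULAR: rectangle with a smooth random lower boundary (shadowing)
    depth <- runif(1, 0.15, 0.35) * (r1 - r0)
    k <- 6
    knots <- runif(k, 0, depth)
    bottom <- stats::spline(seq(c0, c1, length.out = k), knots, xout = c0:c1)$y
    bottom <- pmax(0, pmin(depth, bottom))
    for (j in seq_along(c0:c1)) {
      mask[r0:(r1 - round(bottom[j])), (c0:c1)[j]] <- TRUE
    }
  }
  mask
}

speckle_field <- function(h, w, mean_v, sd_v, smooth_sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (smooth_sigma > 0) {
    size <- 2L * ceiling(2 * smooth_sigma) + 1L
    z <- conv2(z, EBImage::makeBrush(size, "gaussian", sigma = smooth_sigma),
               boundary = "circular")
    z <- z / stats::sd(as.vector(z))    # restore unit marginal sd after smoothing
  }
  pmin(pmax(round(mean_v + sd_v * z), 0), 255)   # matrix first: keep dims
}

draw_cross <- function(px, cx, cy, size, style, value = 255, thick = 3) {
  h <- nrow(px); w <- ncol(px)
  r <- floor(size / 2); t2 <- floor(thick / 2)
  cx <- cx + 1L; cy <- cy + 1L                       # to 1-based
  clip_r <- function(v) pmax(1L, pmin(h, v)); clip_c <- function(v) pmax(1L, pmin(w, v))
  if (style == "CROSS") {
    px[clip_r((cy - r):(cy + r)), clip_c((cx - t2):(cx + t2))] <- value
    px[clip_r((cy - t2):(cy + t2)), clip_c((cx - r):(cx + r))] <- value
  } else if (style == "X") {
    for (d in -r:r) for (o in -t2:t2) {
      px[clip_r(cy + d), clip_c(cx + d + o)] <- value
      px[clip_r(cy + d), clip_c(cx - d + o)] <- value
    }
  } else { # NUMBER: a digit glyph scaled to roughly `size` tall
    scale <- max(1L, round(size / 7))
    digit <- as.character(sample.int(9, 1))
    px <- draw_text(px, digit, row0 = cy - floor(7 * scale / 2),
                    col0 = cx - floor(5 * scale / 2), scale = scale, value = value)
  }
  px
}

draw_dotted_line <- function(px, x0, y0, x1, y1, dash = 4, gap = 3,
                             thick = 2, value = 255) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len < 1) return(px)
  ux <- (x1 - x0) / len; uy <- (y1 - y0) / len
  t <- 0
  h <- nrow(px); w <- ncol(px)
  while (t < len) {
    tt <- seq(t, min(t + dash - 1, len), by = 0.5)
    for (s in tt) {
      x <- round(x0 + s * ux) + 1L; y <- round(y0 + s * uy) + 1L
      rr <- pmax(1L, pmin(h, y:(y + thick - 1L)))
      cc <- pmax(1L, pmin(w, x:(x + thick - 1L)))
      px[rr, cc] <- value
    }
    t <- t + dash + gap
  }
  px
}

#' Render a phantom
#'
#' Deterministic for a fixed spec (including its seed): the same spec renders
#' bit-identical pixels. Ground truth records the flags, scan-area box,
#' caliper boxes, rendered strings and encoded field values that every
#' detector is later scored against.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [scan_image()]) and `truth` (list: flags,
#'   `scan_area` box, `shape_class`, `caliper_boxes` tibble, `text_items`,
#'   `fields`).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  h <- spec$canvas[1]; w <- spec$canvas[2]
  px <- matrix(0, h, w)
  truth <- list(invalid = spec$invalid, non_b_mode = FALSE,
                dual_view = spec$dual_view, has_calipers = FALSE,
                scan_area = NULL, shape_class = spec$shape,
                caliper_boxes = tibble::tibble(x_left = integer(), y_top = integer(),
                                               x_right = integer(), y_bottom = integer()),
                text_items = tibble::tibble(text = character()),
                fields = spec$fields)

  if (spec$invalid) {
    # near-black frame: faint residual patch plus a small burnt-in note
    pr <- sample(round(h * 0.3):round(h * 0.6), 1)
    pc <- sample(round(w * 0.3):round(w * 0.6), 1)
    px[pr:(pr + 20), pc:(pc + 40)] <- 3
    px <- draw_text(px, "CHAPERONE PRESENT", round(h * 0.1), round(w * 0.1),
                    scale = 2, value = 200)
    truth$text_items <- tibble::tibble(text = "CHAPERONE PRESENT")
    img <- scan_image(px, source_id = sprintf("phantom-%08d", spec$seed))
    return(list(image = img, truth = truth))
  }

  m <- spec$area_margin
  r0 <- round(m[1] * h) + 1L; r1 <- h - round(m[2] * h)
  c0 <- round(m[3] * w) + 1L; c1 <- w - round(m[4] * w)

  if (spec$dual_view) {
    mid <- floor(w / 2)                                 # 0-based midline column
    mask <- shape_mask(h, w, r0, r1, c0, mid - 2L, "RECTANGULAR") |
            shape_mask(h, w, r0, r1, mid + 1L, c1, "RECTANGULAR")
    truth$scan_area <- bounding_box(c0 - 1L, r0 - 1L, c1, r1)
  } else {
    mask <- shape_mask(h, w, r0, r1, c0, c1, spec$shape)
    truth$scan_area <- mask_bbox(mask)
  }
  field <- speckle_field(h, w, spec$speckle[1], spec$speckle[2], spec$speckle_smooth)
  px[mask] <- field[mask]

  if (!is.null(spec$calipers)) {
    truth$has_calipers <- TRUE
    boxes <- list()
    for (i in seq_len(nrow(spec$calipers))) {
      cal <- spec$calipers[i, ]
      px <- draw_cross(px, cal$cx, cal$cy, cal$size, cal$style)
      r <- floor(cal$size / 2)
      boxes[[i]] <- tibble::tibble(x_left = cal$cx - r, y_top = cal$cy - r,
                                   x_right = cal$cx + r + 1L, y_bottom = cal$cy + r + 1L)
    }
    truth$caliper_boxes <- dplyr::bind_rows(boxes)
  }
  if (!is.null(spec$spanning_line)) {
    truth$has_calipers <- TRUE
    for (ln in spec$spanning_line) {
      px <- draw_dotted_line(px, ln$x0, ln$y0, ln$x1, ln$y1,
                             dash = ln$dash %||% 4, gap = ln$gap %||% 3)
    }
  }
  if (!is.null(spec$text_items)) {
    for (i in seq_len(nrow(spec$text_items))) {
      ti <- spec$text_items[i, ]
      px <- draw_text(px, ti$text, ti$y + 1L, ti$x + 1L, scale = ti$scale)
    }
    truth$text_items <- tibble::tibble(text = spec$text_items$text)
  }

  needs_color <- spec$color || !is.null(spec$doppler_box) || !is.null(spec$indicator_box)
  if (!needs_color && spec$chroma_jitter <= 0) {
    img <- scan_image(px, source_id = sprintf("phantom-%08d", spec$seed))
    return(list(image = img, truth = truth))
  }

  rgb <- array(rep(px, 3), dim = c(h, w, 3))
  if (!is.null(spec$doppler_box)) {
    truth$non_b_mode <- TRUE
    db <- spec$doppler_box
    palette <- db$palette %||% list(c(220, 30, 30), c(40, 60, 230))
    rows <- box_rows(db$box); cols <- box_cols(db$box)
    n_px <- length(rows) * length(cols)
    pick <- which(stats::runif(n_px) < (db$fraction %||% 0.45))
    pr <- rows[(pick - 1L) %% length(rows) + 1L]
    pc <- cols[(pick - 1L) %/% length(rows) + 1L]
    col_idx <- sample.int(length(palette), length(pick), replace = TRUE)
    for (k in seq_along(pick)) {
      rgb[pr[k], pc[k], ] <- palette[[col_idx[k]]]
    }
  }
  if (!is.null(spec$indicator_box)) {
    truth$non_b_mode <- TRUE
    ib <- spec$indicator_box
    green <- c(30, 220, 60); t <- 3L
    b <- ib$box
    rr <- box_rows(b); cc <- box_cols(b)
    paint <- function(rows, cols) for (ch in 1:3) rgb[rows, cols, ch] <<- green[ch]
    if (ib$style == "line") {
      x <- b$x_left + 1L
      y0 <- max(1L, round(h * 0.07)); y1 <- min(h, round(h * 0.93))
      paint(y0:y1, x:(x + t - 1L))
    } else {
      paint(rr[1:t], cc)                               # top
      paint(rr[(length(rr) - t + 1):length(rr)], cc)   # bottom
      paint(rr, cc[1:t])                               # left
      if (ib$style == "complete") paint(rr, cc[(length(cc) - t + 1):length(cc)])
    }
  }
  if (spec$chroma_jitter > 0) {
    jitter_idx <- which(mask & stats::runif(h * w) < spec$chroma_jitter)
    ch_pick <- sample.int(3, length(jitter_idx), replace = TRUE)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      sel <- jitter_idx[ch_pick == ch]
      plane[sel] <- pmin(255, plane[sel] + sample(1:3, length(sel), replace = TRUE))
      rgb[, , ch] <- plane
    }
  }
  img <- scan_image(rgb, source_id = sprintf("phantom-%08d", spec$seed))
  list(image = img, truth = truth)
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  bounding_box(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
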
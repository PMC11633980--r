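# Stratified synthetic test suite: one stratum per artifact class the
# pipeline recognizes. Every image is reconstructible from (class, seed)
# alone, so the manifest is a complete ground-truth record.

#' Artifact classes of the synthetic suite
#' @return Character vector of class names.
#' @export
suite_classes <- function() {
  c("plain", "calipers", "dotted_calipers", "doppler",
    "indicator_box", "dual_view", "invalid", "text")
}

#' Build the phantom specification for a suite class
#'
#' All within-class variation (canvas, placements, styles, annotation
#' content) derives deterministically from `seed`.
#'
#' @param class One of [suite_classes()].
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
class_phantom_spec <- function(class, seed) {
  class <- match.arg(class, suite_classes())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  wide <- c(420L, 560L); tall <- c(480L, 330L)
  spec <- switch(class,
    plain = phantom_spec(canvas = if (stats::runif(1) < 0.5) wide else tall,
                         seed = seed),
    calipers = {
      cal <- place_calipers(wide, n = sample(2:4, 1))
      phantom_spec(canvas = wide, calipers = cal, seed = seed)
    },
    dotted_calipers = {
      geom <- place_dotted_lines(wide)
      phantom_spec(canvas = wide, calipers = geom$calipers,
                   spanning_line = geom$lines, seed = seed)
    },
    doppler = {
      h <- wide[1]; w <- wide[2]
      bw <- round(w * 0.28); bh <- round(h * 0.30)
      x0 <- sample(round(w * 0.20):round(w * 0.55), 1)
      y0 <- sample(round(h * 0.20):round(h * 0.45), 1)
      phantom_spec(canvas = wide,
                   doppler_box = list(box = bounding_box(x0, y0, x0 + bw, y0 + bh),
                                      fraction = 0.45),
                   seed = seed)
    },
    indicator_box = {
      h <- wide[1]; w <- wide[2]
      style <- sample(c("complete", "partial", "line"), 1)
      box <- if (style == "line") {
        bounding_box(w - 36L, 10L, w - 26L, h - 10L)
      } else {
        x0 <- w - sample(165:185, 1); y0 <- sample(30:60, 1)
        bounding_box(x0, y0, x0 + sample(110:130, 1), y0 + sample(90:120, 1))
      }
      phantom_spec(canvas = wide, indicator_box = list(box = box, style = style),
                   seed = seed)
    },
    dual_view = phantom_spec(canvas = c(420L, 700L), dual_view = TRUE, seed = seed),
    invalid = phantom_spec(canvas = wide, invalid = TRUE, seed = seed),
    text = {
      ann <- sample_annotation()
      phantom_spec(canvas = wide, text_items = ann$items, fields = ann$fields,
                   chroma_jitter = 0.02, color = TRUE, seed = seed)
    }
  )
  spec
}

# Caliper centers in the central (non-border-masked) region, min separation 48 px.
place_calipers <- function(canvas, n, border = 0.15, sep = 48) {
  h <- canvas[1]; w <- canvas[2]
  rr <- c(ceiling(border * h) + 24, floor((1 - border) * h) - 24)
  cc <- c(ceiling(border * w) + 24, floor((1 - border) * w) - 24)
  pts <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(pts) < n && guard < 200) {
    guard <- guard + 1
    p <- c(sample(cc[1]:cc[2], 1), sample(rr[1]:rr[2], 1))
    if (nrow(pts) == 0 || all(sqrt(rowSums(t(t(pts) - p)^2)) >= sep)) {
      pts <- rbind(pts, p)
    }
  }
  tibble::tibble(cx = pts[, 1], cy = pts[, 2],
                 style = sample(c("CROSS", "X", "NUMBER"), nrow(pts),
                                replace = TRUE, prob = c(0.5, 0.35, 0.15)),
                 size = sample(c(17L, 21L, 25L), nrow(pts), replace = TRUE))
}

# Two crossing dotted spanning lines with small marker calipers at their
# endpoints -- the annotation style that merges into one over-sized component
# under the contour method.
place_dotted_lines <- function(canvas, border = 0.15) {
  h <- canvas[1]; w <- canvas[2]
  cx <- sample(round(w * 0.40):round(w * 0.60), 1)
  cy <- sample(round(h * 0.40):round(h * 0.60), 1)
  th1 <- stats::runif(1, 0, pi)
  th2 <- th1 + stats::runif(1, pi / 3, 2 * pi / 3)
  lim_r <- c(ceiling(border * h) + 12, floor((1 - border) * h) - 12)
  lim_c <- c(ceiling(border * w) + 12, floor((1 - border) * w) - 12)
  endpoints <- function(theta) {
    len <- stats::runif(1, 50, 70)
    for (sgn in c(1, -1)) {
      # shrink until the endpoint stays inside the central region
      repeat {
        x <- cx + sgn * len * cos(theta); y <- cy + sgn * len * sin(theta)
        if (x >= lim_c[1] && x <= lim_c[2] && y >= lim_r[1] && y <= lim_r[2]) break
        len <- len - 4
        if (len < 30) break
      }
    }
    list(x0 = round(cx - len * cos(theta)), y0 = round(cy - len * sin(theta)),
         x1 = round(cx + len * cos(theta)), y1 = round(cy + len * sin(theta)))
  }
  e1 <- endpoints(th1); e2 <- endpoints(th2)
  cal <- tibble::tibble(
    cx = c(e1$x0, e1$x1, e2$x0, e2$x1), cy = c(e1$y0, e1$y1, e2$y0, e2$y1),
    style = "X", size = 13L
  )
  list(lines = list(c(e1, dash = 4, gap = 3), c(e2, dash = 4, gap = 3)),
       calipers = cal)
}

# Annotation strings plus the structured field values they encode. Drawn in
# ACR-style dialects (abbreviated laterality/orientation tokens, clock-face
# position, from-nipple distance, optional axilla/measurement/procedure notes).
sample_annotation <- function() {
  side <- sample(c("LEFT", "RIGHT"), 1)
  lat_tok <- if (side == "LEFT") sample(c("LEFT", "LT"), 1) else sample(c("RIGHT", "RT"), 1)
  orient <- sample(c("RAD", "ARAD", "TRANS", "LONG", "SAG", "OBL"), 1)
  orient_tok <- switch(orient,
    ARAD = sample(c("ARAD", "ANTIRAD", "ANTI-RAD"), 1),
    TRANS = sample(c("TRANS", "TRV"), 1),
    orient)
  hour <- sample(1:12, 1); minute <- sample(c(0L, 15L, 30L, 45L), 1)
  clock_tok <- if (minute == 0L && stats::runif(1) < 0.3) {
    sprintf("%d O'CLOCK", hour)
  } else {
    sprintf("%d:%02d", hour, minute)
  }
  dist <- sample(seq(1, 10, by = 0.5), 1)
  dist_tok <- sprintf(sample(c("%g CM FN", "%gCMFN"), 1), dist)
  items <- sprintf("%s BREAST %s %s %s", lat_tok, clock_tok, dist_tok, orient_tok)
  fields <- list(laterality = side, orientation = orient,
                 clock_hour = hour, clock_minute = minute,
                 distance_cm = dist, axilla = FALSE,
                 measurements_cm = numeric(), procedural = FALSE)
  if (stats::runif(1) < 0.4) {
    a <- sample(seq(0.4, 3, by = 0.1), 1)
    if (stats::runif(1) < 0.5) {
      b <- sample(seq(0.4, 3, by = 0.1), 1)
      items <- c(items, sprintf("%g X %g CM", a, b))
      fields$measurements_cm <- c(a, b)
    } else {
      items <- c(items, sprintf("%g CM", a))
      fields$measurements_cm <- a
    }
  }
  if (stats::runif(1) < 0.3) {
    items <- c(items, sample(c("US GUIDED BIOPSY", "CLIP PLACED", "POST BX",
                               "MARKER DEPLOYED"), 1))
    fields$procedural <- TRUE
  }
  if (stats::runif(1) < 0.3) {
    items <- c(items, paste(lat_tok, "AXILLA"))
    fields$axilla <- TRUE
  }
  # annotation block stays inside the top border band (the region the caliper
  # detector masks), as burnt-in labels on clinical scans typically do
  list(items = tibble::tibble(text = items,
                              x = 18L, y = 8L + 18L * (seq_along(items) - 1L),
                              scale = 2L),
       fields = fields)
}

#' Generate the stratified synthetic suite
#'
#' Renders `n_per_class` phantoms for every class in [suite_classes()] and
#' returns a ground-truth manifest with one row per image. With `out_dir`
#' set, images are written as PNGs and the manifest as `manifest.csv`.
#' Two calls with the same seed produce identical manifests (and identical
#' pixels).
#'
#' @param n_per_class Images per class.
#' @param seed Master seed; per-image seeds derive from it.
#' @param out_dir Optional output directory (created if missing).
#' @return Manifest tibble: `source_id`, `class`, `seed`, flag columns,
#'   expected text fields, and the true scan-area box coordinates.
#' @export
generate_suite <- function(n_per_class, seed = 1L, out_dir = NULL) {
  classes <- suite_classes()
  n_total <- n_per_class * length(classes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seeds <- if (n_total > 0) sample.int(.Machine$integer.max - 1L, n_total) else integer()

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- list()
  k <- 0L
  for (cls in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      spec <- class_phantom_spec(cls, seeds[k])
      ph <- render_phantom(spec)
      id <- sprintf("%s_%03d.png", cls, i)
      if (!is.null(out_dir)) save_image(ph$image, file.path(out_dir, id))
      rows[[k]] <- manifest_row(id, cls, seeds[k], ph$truth)
    }
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else manifest_row_empty()
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}

manifest_row <- function(id, cls, seed, truth) {
  f <- truth$fields
  box <- truth$scan_area
  tibble::tibble(
    source_id = id, class = cls, seed = seed,
    invalid = truth$invalid, non_b_mode = truth$non_b_mode,
    dual_view = truth$dual_view, has_calipers = truth$has_calipers,
    n_calipers = nrow(truth$caliper_boxes),
    text_present = nrow(truth$text_items) > 0 && !truth$invalid,
    laterality = f$laterality %||% "NONE",
    orientation = f$orientation %||% "NONE",
    clock_hour = f$clock_hour %||% NA_integer_,
    clock_minute = f$clock_minute %||% NA_integer_,
    distance_cm = f$distance_cm %||% NA_real_,
    axilla = f$axilla %||% FALSE,
    measurements_cm = paste(f$measurements_cm %||% numeric(), collapse = ";"),
    procedural = f$procedural %||% FALSE,
    area_x_left = if (is.null(box)) NA_integer_ else box$x_left,
    area_y_top = if (is.null(box)) NA_integer_ else box$y_top,
    area_x_right = if (is.null(box)) NA_integer_ else box$x_right,
    area_y_bottom = if (is.null(box)) NA_integer_ else box$y_bottom
  )
}

manifest_row_empty <- function() {
  manifest_row("x", "plain", 1L,
               list(invalid = FALSE, non_b_mode = FALSE, dual_view = FALSE,
                    has_calipers = FALSE,
                    caliper_boxes = tibble::tibble(),
                    text_items = tibble::tibble(text = character()),
                    scan_area = NULL, fields = NULL))[0, ]
}
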
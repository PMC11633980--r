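# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / base tabulations so they share no code path with the
# implementations they check.

gray_scan <- function(m) scan_image(m)

rgb_scan <- function(r, g, b) {
  scan_image(array(c(r, g, b), dim = c(nrow(r), ncol(r), 3)))
}

solid_rgb <- function(h, w, rgb) {
  scan_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

# --- brute-force oracles ----------------------------------------------------

oracle_mode <- function(px) {
  counts <- table(factor(as.vector(px), levels = 0:255))
  as.integer(names(counts)[which(counts == max(counts))[1]])
}

oracle_flow_fraction <- function(mask, box) {
  hits <- 0L
  for (r in (box$y_top + 1):box$y_bottom) {
    for (cc in (box$x_left + 1):box$x_right) {
      if (mask[r, cc]) hits <- hits + 1L
    }
  }
  hits / (box$w * box$h)
}

# Thirds-band extremes of non-mode pixels, by direct per-pixel scan.
oracle_band_extremes <- function(px, box, mode_value) {
  nm <- px != mode_value
  h <- box$h; w <- box$w
  hb <- c(0L, floor(h / 3), floor(2 * h / 3), h)
  vb <- c(0L, floor(w / 3), floor(2 * w / 3), w)
  h_min <- h_max <- v_min <- v_max <- rep(NA_integer_, 3)
  for (i in 1:3) {
    for (r in seq.int(box$y_top + hb[i] + 1L, length.out = hb[i + 1] - hb[i])) {
      for (cc in (box$x_left + 1):box$x_right) {
        if (nm[r, cc]) {
          x <- cc - 1L
          if (is.na(h_min[i]) || x < h_min[i]) h_min[i] <- x
          if (is.na(h_max[i]) || x > h_max[i]) h_max[i] <- x
        }
      }
    }
    for (cc in seq.int(box$x_left + vb[i] + 1L, length.out = vb[i + 1] - vb[i])) {
      for (r in (box$y_top + 1):box$y_bottom) {
        if (nm[r, cc]) {
          y <- r - 1L
          if (is.na(v_min[i]) || y < v_min[i]) v_min[i] <- y
          if (is.na(v_max[i]) || y > v_max[i]) v_max[i] <- y
        }
      }
    }
  }
  list(h_min = h_min, h_max = h_max, v_min = v_min, v_max = v_max)
}

# Expected stage-2 box derived from the oracle band extremes.
oracle_stage2 <- function(px, box, mode_value) {
  e <- oracle_band_extremes(px, box, mode_value)
  med <- function(v) sort(v)[2]
  list(
    x_left = med(ifelse(is.na(e$h_min), box$x_left, e$h_min)),
    x_right = med(ifelse(is.na(e$h_max), box$x_right - 1L, e$h_max)) + 1L,
    y_top = med(ifelse(is.na(e$v_min), box$y_top, e$v_min)),
    y_bottom = med(ifelse(is.na(e$v_max), box$y_bottom - 1L, e$v_max)) + 1L
  )
}

mirror_scan <- function(scan) {
  px <- scan$pixels
  px <- if (length(dim(px)) == 2) px[, ncol(px):1] else px[, dim(px)[2]:1, ]
  scan_image(px, source_id = scan$source_id)
}

# --- minimal DICOM writer (synthetic fixtures only) -------------------------

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dicom_elem <- function(group, elem, vr, value) {
  if (length(value) %% 2 == 1) {
    value <- c(value, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  }
  head <- c(le16(group), le16(elem))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)), le32(length(value)), value)
  } else {
    c(head, charToRaw(vr), le16(length(value)), value)
  }
}

dicom_elem_implicit <- function(group, elem, value) {
  if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
  c(le16(group), le16(elem), le32(length(value)), value)
}

# Write a single- or multi-frame synthetic DICOM. `frames` is a list of
# matrices (grayscale) or H x W x 3 arrays (RGB); 16-bit values allowed for
# grayscale when bits = 16.
write_test_dicom <- function(path, frames, photometric = "MONOCHROME2",
                             bits = 8L, explicit = TRUE, preamble = TRUE) {
  f1 <- frames[[1]]
  color <- length(dim(f1)) == 3
  rows <- nrow(f1); cols <- ncol(f1)
  spp <- if (color) 3L else 1L
  pix_vals <- unlist(lapply(frames, function(f) {
    if (color) {
      as.integer(aperm(f, c(3, 2, 1)))       # interleaved RGB, row-major
    } else {
      as.integer(t(f))                       # row-major
    }
  }))
  pix_raw <- if (bits > 8) {
    writeBin(pix_vals, raw(), size = 2, endian = "little")
  } else {
    as.raw(pix_vals)
  }
  us <- function(g, e, v) if (explicit) dicom_elem(g, e, "US", le16(v))
                          else dicom_elem_implicit(g, e, le16(v))
  cs <- function(g, e, v) if (explicit) dicom_elem(g, e, "CS", charToRaw(v))
                          else dicom_elem_implicit(g, e, charToRaw(v))
  is_ <- function(g, e, v) if (explicit) dicom_elem(g, e, "IS", charToRaw(v))
                           else dicom_elem_implicit(g, e, charToRaw(v))
  ds <- c(
    us(0x0028, 0x0002, spp),
    cs(0x0028, 0x0004, photometric),
    if (color) us(0x0028, 0x0006, 0L),
    if (length(frames) > 1) is_(0x0028, 0x0008, as.character(length(frames))),
    us(0x0028, 0x0010, rows),
    us(0x0028, 0x0011, cols),
    us(0x0028, 0x0100, bits),
    us(0x0028, 0x0101, bits),
    us(0x0028, 0x0103, 0L),
    if (explicit) dicom_elem(0x7FE0, 0x0010, if (bits > 8) "OW" else "OB", pix_raw)
    else dicom_elem_implicit(0x7FE0, 0x0010, pix_raw)
  )
  out <- raw(0)
  if (preamble) {
    syntax <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
    meta <- dicom_elem(0x0002, 0x0010, "UI", charToRaw(syntax))
    out <- c(raw(128), charToRaw("DICM"), meta)
  }
  writeBin(c(out, ds), path)
  invisible(path)
}
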
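# Minimal DICOM Part-10 pixel-data reader.
#
# Scope: uncompressed little-endian transfer syntaxes (implicit VR 1.2.840.10008.1.2,
# explicit VR 1.2.840.10008.1.2.1), MONOCHROME1/MONOCHROME2/RGB/YBR_FULL photometric
# interpretations, 8- or 16-bit allocation, multi-frame. Header de-identification,
# sequences with undefined length, and compressed syntaxes are out of scope; the
# latter raise a format error. MONOCHROME1 is inverted so low values mean black
# everywhere downstream; frames stored deeper than 8 bits are min-max rescaled per
# frame to 0-255 so the pipeline's 8-bit thresholds apply uniformly.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
u32 <- function(raw, off) {
  as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
}

# String value with DICOM NUL/space padding stripped.
raw_string <- function(r) trimws(rawToChar(r[r != as.raw(0L)]))

#' Load every frame of a DICOM file
#'
#' @param path Path to an uncompressed little-endian DICOM file.
#' @return A list of [scan_image()] objects, one per frame.
#' @seealso [load_image()] which returns the first frame only.
#' @export
load_dicom_frames <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  off <- 0L
  syntax <- TS_IMPLICIT_LE
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") {
    off <- 132L
    meta <- parse_elements(raw, off, explicit = TRUE, stop_after_group2 = TRUE)
    off <- meta$offset
    ts <- meta$elements[["0002,0010"]]
    if (!is.null(ts)) syntax <- raw_string(ts)
  }
  if (!syntax %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE)) {
    stop("unsupported DICOM transfer syntax: ", syntax,
         " (only uncompressed little endian is supported)", call. = FALSE)
  }
  ds <- parse_elements(raw, off, explicit = (syntax == TS_EXPLICIT_LE))
  el <- ds$elements

  need_u16 <- function(tag, default = NULL) {
    v <- el[[tag]]
    if (is.null(v)) {
      if (!is.null(default)) return(default)
      stop("DICOM file missing required element (", tag, "): ", path, call. = FALSE)
    }
    u16(v, 0L)
  }
  rows <- need_u16("0028,0010")
  cols <- need_u16("0028,0011")
  bits_alloc <- need_u16("0028,0100", 8L)
  spp <- need_u16("0028,0002", 1L)
  photometric <- raw_string(el[["0028,0004"]] %||% charToRaw("MONOCHROME2"))
  nframes <- el[["0028,0008"]]
  nframes <- if (is.null(nframes)) 1L else as.integer(raw_string(nframes))
  planar <- need_u16("0028,0006", 0L)
  pix <- el[["7fe0,0010"]]
  if (is.null(pix)) stop("DICOM file has no pixel data: ", path, call. = FALSE)
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2", "RGB", "YBR_FULL")) {
    stop("unsupported photometric interpretation: ", photometric, call. = FALSE)
  }
  if (spp == 1L && grepl("^MONOCHROME", photometric) == FALSE) {
    stop("inconsistent DICOM: 1 sample/pixel but photometric ", photometric, call. = FALSE)
  }

  bytes_per <- if (bits_alloc > 8L) 2L else 1L
  vals <- if (bytes_per == 2L) {
    readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    as.integer(pix)
  }
  per_frame <- rows * cols * spp
  if (length(vals) < per_frame * nframes) {
    stop("truncated DICOM pixel data: ", path, call. = FALSE)
  }

  lapply(seq_len(nframes), function(f) {
    v <- vals[((f - 1L) * per_frame + 1L):(f * per_frame)]
    if (bits_alloc > 8L) {
      rng <- range(v)
      v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) * 255 else v * 0
    }
    if (spp == 1L) {
      m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
      if (photometric == "MONOCHROME1") m <- 255 - m
      scan_image(m, source_id = paste0(path, "#", f))
    } else {
      a <- array(0, dim = c(rows, cols, 3L))
      if (planar == 0L) {
        for (ch in 1:3) {
          a[, , ch] <- matrix(v[seq(ch, length(v), by = 3L)],
                              nrow = rows, ncol = cols, byrow = TRUE)
        }
      } else {
        plane <- rows * cols
        for (ch in 1:3) {
          a[, , ch] <- matrix(v[((ch - 1L) * plane + 1L):(ch * plane)],
                              nrow = rows, ncol = cols, byrow = TRUE)
        }
      }
      if (photometric == "YBR_FULL") a <- ybr_to_rgb(a)
      scan_image(a, source_id = paste0(path, "#", f))
    }
  })
}

ybr_to_rgb <- function(a) {
  y <- a[, , 1]; cb <- a[, , 2] - 128; cr <- a[, , 3] - 128
  out <- array(0, dim = dim(a))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  out
}

# Walk data elements from `off` (0-based byte offset), returning named raw values
# for the tags the reader needs and the final offset. Sequences with defined
# length are skipped; undefined lengths (compressed/SQ item streams) error out.
parse_elements <- function(raw, off, explicit, stop_after_group2 = FALSE) {
  n <- length(raw)
  keep <- c("0002,0010", "0028,0002", "0028,0004", "0028,0006", "0028,0008",
            "0028,0010", "0028,0011", "0028,0100", "0028,0101", "0028,0103",
            "7fe0,0010")
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8L <= n) {
    group <- u16(raw, off); elem <- u16(raw, off + 2L)
    if (stop_after_group2 && group != 2L) break
    tag <- sprintf("%04x,%04x", group, elem)
    exp_here <- explicit || group == 2L   # file meta is always explicit
    if (exp_here) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (vr %in% long_vrs) {
        len <- u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- u16(raw, off + 6L); hdr <- 8L
      }
    } else {
      len <- u32(raw, off + 4L); hdr <- 8L
      vr <- "UN"
    }
    if (len == 4294967295) {   # undefined length
      stop("unsupported DICOM element with undefined length at tag ", tag,
           " (compressed pixel data or nested sequences are not supported)",
           call. = FALSE)
    }
    start <- off + hdr
    if (start + len > n) stop("corrupt DICOM file: element ", tag, " overruns file",
                              call. = FALSE)
    if (tag %in% keep) out[[tag]] <- raw[seq.int(start + 1L, length.out = len)]
    off <- start + as.integer(len)
    if (tag == "7fe0,0010") break
  }
  list(elements = out, offset = off)
}
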
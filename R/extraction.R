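# Burnt-in annotation parsing: OCR (pluggable backend) followed by
# regular-expression pattern matching into the ACR BI-RADS Section IC
# labeling fields (laterality, clock-face location, transducer orientation,
# distance from the nipple) plus procedural / measurement / axilla flags.
# Every matcher is a pure, case-insensitive function of its input string.

the <- new.env(parent = emptyenv())

#' Load a field-matching vocabulary
#'
#' Reads a YAML file mapping fields to regex lists (see the file shipped at
#' `system.file("extdata", "vocabulary.yaml", package = "buscurate")` for the
#' dialect and capture-group contracts). Users extend recognition to new
#' annotation styles or languages by editing a copy of that file.
#'
#' @param path Path to a vocabulary YAML file; default: the bundled file.
#' @return Nested list of regex strings.
#' @export
read_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vocabulary.yaml", package = "buscurate")
  yaml::read_yaml(path)
}

default_vocab <- function() {
  if (is.null(the$vocab)) the$vocab <- read_vocabulary()
  the$vocab
}

any_match <- function(text, patterns) {
  any(vapply(patterns, function(p) grepl(p, text, perl = TRUE), logical(1)))
}

#' Match breast laterality
#'
#' Word-boundary matching of the laterality vocabulary (LEFT/LT, RIGHT/RT,
#' and bare L/R when followed by BREAST or AX...). When both sides match,
#' the earlier occurrence wins; [extract_fields()] handles the conflict case.
#'
#' @param text Uppercased annotation string.
#' @param vocab Vocabulary list (default: bundled).
#' @return `"LEFT"`, `"RIGHT"`, or `"NONE"`.
#' @export
match_laterality <- function(text, vocab = default_vocab()) {
  pos <- function(patterns) {
    hits <- vapply(patterns, function(p) {
      m <- regexpr(p, text, perl = TRUE)
      if (m[1] == -1) NA_integer_ else as.integer(m[1])
    }, integer(1))
    if (all(is.na(hits))) NA_integer_ else min(hits, na.rm = TRUE)
  }
  pl <- pos(vocab$laterality$LEFT); pr <- pos(vocab$laterality$RIGHT)
  if (is.na(pl) && is.na(pr)) return("NONE")
  if (is.na(pr) || (!is.na(pl) && pl <= pr)) "LEFT" else "RIGHT"
}

laterality_sides <- function(text, vocab = default_vocab()) {
  c(LEFT = any_match(text, vocab$laterality$LEFT),
    RIGHT = any_match(text, vocab$laterality$RIGHT))
}

#' Match transducer orientation
#'
#' Recognizes RAD / ARAD (with ANTI-RAD and ANTIRAD aliases) / TRANS (TRV) /
#' LONG / SAG / OBL tokens at word boundaries; ARAD aliases are tested before
#' RAD so "ANTIRAD" never degrades to RAD.
#'
#' @inheritParams match_laterality
#' @return One of `"RAD"`, `"ARAD"`, `"TRANS"`, `"LONG"`, `"SAG"`, `"OBL"`,
#'   `"NONE"`.
#' @export
match_orientation <- function(text, vocab = default_vocab()) {
  for (nm in c("ARAD", "RAD", "TRANS", "LONG", "SAG", "OBL")) {
    if (any_match(text, vocab$orientation[[nm]])) return(nm)
  }
  "NONE"
}

#' Match a clock-face anatomic location
#'
#' Accepts `H:MM` (hour 1--12, minute 00--59, also `H.MM`) and the
#' `H O'CLOCK` / `H OCLOCK` dialects, embedded anywhere in the string.
#' Hours 0 or above 12 never match. Quadrant notation is deliberately not
#' recognized.
#'
#' @inheritParams match_laterality
#' @return `c(hour, minute)` or `NULL`.
#' @export
match_clock_position <- function(text, vocab = default_vocab()) {
  for (p in vocab$clock$hm) {
    m <- stringr::str_match(text, p)
    if (!is.na(m[1, 1])) return(c(hour = as.integer(m[1, 2]), minute = as.integer(m[1, 3])))
  }
  for (p in vocab$clock$oclock) {
    m <- stringr::str_match(text, p)
    if (!is.na(m[1, 1])) return(c(hour = as.integer(m[1, 2]), minute = 0L))
  }
  NULL
}

#' Match distance from the nipple
#'
#' A number adjacent to CM plus a from-nipple marker (`FN`, `CMFN`,
#' `FROM NIPPLE`) in centimeters. A bare number--CM pair without the marker
#' is a lesion measurement, not a distance (see [match_measurement()]).
#'
#' @inheritParams match_laterality
#' @return Distance in cm (numeric) or `NULL`.
#' @export
match_distance <- function(text, vocab = default_vocab()) {
  for (p in vocab$distance) {
    m <- stringr::str_match(text, p)
    if (!is.na(m[1, 1])) return(as.numeric(m[1, 2]))
  }
  NULL
}

#' Match axillary-imaging tokens
#'
#' @inheritParams match_laterality
#' @return Logical scalar.
#' @export
match_axilla <- function(text, vocab = default_vocab()) {
  any_match(text, vocab$axilla)
}

#' Match lesion measurements
#'
#' Every number--CM group not claimed by [match_distance()] is a lesion
#' measurement; `A x B cm` pairs yield both numbers. Each group is consumed
#' by exactly one of distance or measurement (distance matches are excised
#' before measurement matching), so no number is double-counted.
#'
#' @inheritParams match_laterality
#' @return Numeric vector of measurements in cm (may be empty).
#' @export
match_measurement <- function(text, vocab = default_vocab()) {
  for (p in vocab$distance) text <- stringr::str_replace_all(text, p, " ")
  out <- numeric()
  pair <- vocab$measurement$pair[[1]]
  for (m in stringr::str_match_all(text, pair)[[1]][, 1]) {
    g <- stringr::str_match(m, pair)
    out <- c(out, as.numeric(g[1, 2]), as.numeric(g[1, 3]))
  }
  text <- stringr::str_replace_all(text, pair, " ")
  for (p in vocab$measurement$single) {
    g <- stringr::str_match_all(text, p)[[1]]
    if (nrow(g)) out <- c(out, as.numeric(g[, 2]))
  }
  out
}

#' Match procedural-imaging tokens
#'
#' True for text referring to a surgical procedure (biopsy, FNA, aspiration)
#' or to placement of a clip, marker, coil or wire.
#'
#' @inheritParams match_laterality
#' @return Logical scalar.
#' @export
match_procedural <- function(text, vocab = default_vocab()) {
  any_match(text, vocab$procedural)
}

# ---- OCR backends ----------------------------------------------------------

#' Deterministic stub OCR backend
#'
#' Returns the ground-truth strings of a phantom (or any supplied strings)
#' as perfect detections with confidence 1. Removes the OCR engine from the
#' loop so field-grammar correctness can be tested in isolation.
#'
#' @param truth A phantom ground-truth object (from [render_phantom()]), a
#'   character vector of strings, or a tibble with a `text` column.
#' @return An `ocr_backend` object.
#' @export
ocr_backend_stub <- function(truth = character()) {
  texts <- if (is.character(truth)) truth
           else if (!is.null(truth$text_items)) truth$text_items$text
           else if (!is.null(truth$text)) truth$text
           else character()
  structure(list(texts = as.character(texts)), class = c("ocr_stub", "ocr_backend"))
}

#' Real OCR engine backend handle
#'
#' Placeholder constructor for an external OCR engine. No OCR engine is
#' bundled with the package; calling [extract_text()] with this backend
#' raises a configuration error instructing use of [ocr_backend_stub()]
#' (or of a user-supplied backend implementing `run_ocr()`).
#'
#' @param engine Engine name.
#' @return An `ocr_backend` object.
#' @export
ocr_backend_real <- function(engine = "easyocr") {
  structure(list(engine = engine), class = c("ocr_real", "ocr_backend"))
}

#' Run an OCR backend over a scan
#'
#' Backend contract: given a `scan_image`, return a tibble with columns
#' `text`, `x_left`, `y_top`, `x_right`, `y_bottom`, `confidence`.
#' Implement a method for your own backend class to plug in a real engine.
#'
#' @param backend An `ocr_backend` object.
#' @param scan A `scan_image`.
#' @return Tibble of raw detections.
#' @export
run_ocr <- function(backend, scan) UseMethod("run_ocr")

#' @export
run_ocr.ocr_stub <- function(backend, scan) {
  n <- length(backend$texts)
  tibble::tibble(text = backend$texts,
                 x_left = rep(0L, n), y_top = rep(0L, n),
                 x_right = rep(1L, n), y_bottom = rep(1L, n),
                 confidence = rep(1, n))
}

#' @export
run_ocr.ocr_real <- function(backend, scan) {
  stop("no OCR engine '", backend$engine, "' is available in this installation; ",
       "use ocr_backend_stub() for deterministic testing or supply a backend ",
       "implementing run_ocr()", call. = FALSE)
}

#' Extract text detections from a scan
#'
#' Runs the OCR backend, drops detections below `min_confidence`, uppercases
#' and whitespace-normalizes the strings, and drops detections that are empty
#' after stripping.
#'
#' @param scan A `scan_image`.
#' @param backend An `ocr_backend` (see [ocr_backend_stub()]).
#' @param min_confidence Confidence cutoff (default 0.3; permissive because
#'   the downstream grammars reject garbage anyway).
#' @return Tibble of text detections.
#' @export
extract_text <- function(scan, backend, min_confidence = 0.3) {
  det <- run_ocr(backend, scan)
  det <- det[det$confidence >= min_confidence, , drop = FALSE]
  det$text <- stringr::str_squish(toupper(det$text))
  det[nzchar(det$text), , drop = FALSE]
}

# ---- Field aggregation -----------------------------------------------------

#' Aggregate text detections into BI-RADS fields
#'
#' Applies every field matcher to each detection and combines the results:
#' laterality becomes `"CONFLICT"` when both LEFT and RIGHT matched across
#' detections; orientation, clock position and distance take the first match
#' in detection order; measurements accumulate; every non-NONE field records
#' its source string in `matched_tokens`.
#'
#' @param detections Tibble from [extract_text()] (or any tibble with a
#'   `text` column).
#' @param vocab Vocabulary list (default: bundled).
#' @return An `extracted_fields` object; see [tidy.extracted_fields()] for
#'   the one-row tibble form.
#' @export
extract_fields <- function(detections, vocab = default_vocab()) {
  texts <- if (is.data.frame(detections)) detections$text else as.character(detections)
  texts <- stringr::str_squish(toupper(texts))
  texts <- texts[nzchar(texts)]

  fields <- list(laterality = "NONE", orientation = "NONE",
                 clock_hour = NA_integer_, clock_minute = NA_integer_,
                 distance_cm = NA_real_, axilla = FALSE,
                 measurements_cm = numeric(), procedural = FALSE,
                 text_present = length(texts) > 0)
  tokens <- list()
  note <- function(field, src) tokens[[length(tokens) + 1L]] <<-
    tibble::tibble(field = field, source = src)
  saw_left <- FALSE; saw_right <- FALSE

  for (txt in texts) {
    sides <- laterality_sides(txt, vocab)
    if (sides[["LEFT"]]) { saw_left <- TRUE; note("laterality", txt) }
    if (sides[["RIGHT"]]) { saw_right <- TRUE; note("laterality", txt) }
    o <- match_orientation(txt, vocab)
    if (o != "NONE") {
      if (fields$orientation == "NONE") fields$orientation <- o
      note("orientation", txt)
    }
    ck <- match_clock_position(txt, vocab)
    if (!is.null(ck)) {
      if (is.na(fields$clock_hour)) {
        fields$clock_hour <- ck[["hour"]]; fields$clock_minute <- ck[["minute"]]
      }
      note("clock_position", txt)
    }
    d <- match_distance(txt, vocab)
    if (!is.null(d)) {
      if (is.na(fields$distance_cm)) fields$distance_cm <- d
      note("distance", txt)
    }
    if (match_axilla(txt, vocab)) { fields$axilla <- TRUE; note("axilla", txt) }
    meas <- match_measurement(txt, vocab)
    if (length(meas)) {
      fields$measurements_cm <- c(fields$measurements_cm, meas)
      note("measurement", txt)
    }
    if (match_procedural(txt, vocab)) { fields$procedural <- TRUE; note("procedural", txt) }
  }
  fields$laterality <- if (saw_left && saw_right) "CONFLICT"
                       else if (saw_left) "LEFT"
                       else if (saw_right) "RIGHT" else "NONE"
  fields$matched_tokens <- if (length(tokens)) dplyr::bind_rows(tokens)
                           else tibble::tibble(field = character(), source = character())
  structure(fields, class = "extracted_fields")
}

#' @export
print.extracted_fields <- function(x, ...) {
  cat("<extracted_fields>\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy an extracted-fields object
#'
#' @param x An `extracted_fields` object.
#' @param ... Unused.
#' @return One-row tibble with the structured fields; `measurements_cm` is a
#'   list column.
#' @method tidy extracted_fields
#' @export
tidy.extracted_fields <- function(x, ...) {
  tibble::tibble(
    laterality = x$laterality, orientation = x$orientation,
    clock_hour = x$clock_hour, clock_minute = x$clock_minute,
    distance_cm = x$distance_cm, axilla = x$axilla,
    measurements_cm = list(x$measurements_cm),
    procedural = x$procedural, text_present = x$text_present,
    n_matched_tokens = nrow(x$matched_tokens)
  )
}
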
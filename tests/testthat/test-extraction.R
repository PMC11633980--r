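test_that("laterality matching honors word boundaries and context", {
  expect_equal(match_laterality("LEFT BREAST"), "LEFT")
  expect_equal(match_laterality("RT BREAST 10:00"), "RIGHT")
  expect_equal(match_laterality("HELLO"), "NONE")
  expect_equal(match_laterality("L BREAST"), "LEFT")     # bare L before BREAST
  expect_equal(match_laterality("R AXILLA"), "RIGHT")
  expect_equal(match_laterality("PALPABLE LUMP"), "NONE")  # L inside words ignored
  expect_equal(match_laterality("SALT"), "NONE")           # LT needs a boundary
})

test_that("orientation matching resolves aliases without degrading ARAD", {
  expect_equal(match_orientation("RAD"), "RAD")
  expect_equal(match_orientation("ANTIRAD"), "ARAD")
  expect_equal(match_orientation("ANTI-RAD"), "ARAD")
  expect_equal(match_orientation("ARAD"), "ARAD")
  expect_equal(match_orientation("TRV"), "TRANS")
  expect_equal(match_orientation("LONGITUDINAL"), "LONG")
  expect_equal(match_orientation("SAG"), "SAG")
  expect_equal(match_orientation("OBLIQUE"), "OBL")
  expect_equal(match_orientation(""), "NONE")
  expect_equal(match_orientation("GRADE"), "NONE")
})

test_that("clock positions parse valid hours only", {
  expect_equal(unname(match_clock_position("3:00")), c(3L, 0L))
  expect_equal(unname(match_clock_position("10 O'CLOCK")), c(10L, 0L))
  expect_equal(unname(match_clock_position("12 OCLOCK")), c(12L, 0L))
  expect_equal(unname(match_clock_position("RT BREAST 10:30 RAD")), c(10L, 30L))
  expect_null(match_clock_position("15:00"))   # invalid hour
  expect_null(match_clock_position("0:30"))
  expect_null(match_clock_position("NO CLOCK HERE"))
})

test_that("distance requires a from-nipple marker", {
  expect_equal(match_distance("2 CM FN"), 2)
  expect_equal(match_distance("3CMFN"), 3)
  expect_equal(match_distance("1.5 CM FROM NIPPLE"), 1.5)
  expect_null(match_distance("2 CM"))          # measurement, not distance
  expect_null(match_distance("FN"))
})

test_that("axilla tokens match at word boundaries", {
  expect_true(match_axilla("LT AXILLA"))
  expect_true(match_axilla("AX TAIL"))
  expect_true(match_axilla("AXILLARY NODE"))
  expect_false(match_axilla("MAX"))
  expect_false(match_axilla("RELAX"))
})

test_that("measurements exclude distance groups and expand pairs", {
  expect_equal(match_measurement("1.2 CM"), 1.2)
  expect_equal(match_measurement("0.8 X 1.1 CM"), c(0.8, 1.1))
  expect_equal(match_measurement("2 CM FN"), numeric(0))   # claimed by distance
  expect_equal(match_measurement("3 CM FN 1.2 CM"), 1.2)   # no double counting
  expect_equal(match_measurement("NOTHING"), numeric(0))
})

test_that("procedural tokens match the intervention vocabulary", {
  expect_true(match_procedural("US GUIDED BIOPSY"))
  expect_true(match_procedural("CLIP PLACED"))
  expect_true(match_procedural("POST BX"))
  expect_true(match_procedural("FNA"))
  expect_false(match_procedural("LEFT BREAST 3:00"))
})

test_that("matchers are pure and case-insensitive through extract_text", {
  det <- extract_text(gray_scan(matrix(0, 4, 4)),
                      ocr_backend_stub(c("rt breast 10:00", "  ", "3 cm fn")))
  expect_equal(det$text, c("RT BREAST 10:00", "3 CM FN"))   # normalized, empties dropped
})

test_that("extract_text drops low-confidence detections", {
  backend <- structure(list(), class = c("ocr_fixture", "ocr_backend"))
  registerS3method("run_ocr", "ocr_fixture", function(backend, scan) {
    tibble::tibble(text = c("GOOD", "BAD"), x_left = 0L, y_top = 0L,
                   x_right = 1L, y_bottom = 1L, confidence = c(0.9, 0.1))
  }, envir = asNamespace("buscurate"))
  det <- extract_text(gray_scan(matrix(0, 2, 2)), backend)
  expect_equal(det$text, "GOOD")
})

test_that("the real-OCR backend errors with guidance toward the stub", {
  expect_error(extract_text(gray_scan(matrix(0, 2, 2)), ocr_backend_real()),
               "ocr_backend_stub")
})

test_that("extract_fields composes per-field grammars and flags conflicts", {
  empty <- extract_fields(tibble::tibble(text = character()))
  expect_equal(empty$laterality, "NONE")
  expect_equal(empty$orientation, "NONE")
  expect_false(empty$text_present)
  expect_equal(nrow(empty$matched_tokens), 0)

  f <- extract_fields(c("RT BREAST 10:00 3 CM FN RAD"))
  expect_equal(f$laterality, "RIGHT")
  expect_equal(f$orientation, "RAD")
  expect_equal(c(f$clock_hour, f$clock_minute), c(10L, 0L))
  expect_equal(f$distance_cm, 3)
  expect_true(all(c("laterality", "orientation", "clock_position", "distance")
                  %in% f$matched_tokens$field))

  conflict <- extract_fields(c("LEFT", "RIGHT"))
  expect_equal(conflict$laterality, "CONFLICT")

  td <- tidy(f)
  expect_equal(nrow(td), 1)
  expect_equal(td$laterality, "RIGHT")
})

test_that("stub-backend round-trip recovers every rendered field exactly", {
  set.seed(91)
  for (i in 1:40) {
    seed <- sample.int(1e6, 1)
    ph <- render_phantom(class_phantom_spec("text", seed))
    fx <- extract_fields(extract_text(ph$image, ocr_backend_stub(ph$truth)))
    truth <- ph$truth$fields
    expect_equal(fx$laterality, truth$laterality, info = paste("seed", seed))
    expect_equal(fx$orientation, truth$orientation, info = paste("seed", seed))
    expect_equal(fx$clock_hour, truth$clock_hour, ignore_attr = TRUE)
    expect_equal(fx$clock_minute, truth$clock_minute, ignore_attr = TRUE)
    expect_equal(fx$distance_cm, truth$distance_cm, ignore_attr = TRUE)
    expect_equal(fx$axilla, truth$axilla)
    expect_equal(sort(fx$measurements_cm), sort(truth$measurements_cm))
    expect_equal(fx$procedural, truth$procedural)
  }
})

test_that("a user vocabulary file can extend recognition", {
  vocab <- read_vocabulary()
  vocab$procedural <- c(vocab$procedural, "\\bVACUUM\\b")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(vocab, f)
  v2 <- read_vocabulary(f)
  expect_true(match_procedural("VACUUM ASSISTED", vocab = v2))
  expect_false(match_procedural("VACUUM ASSISTED"))
})
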
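test_that("detect_invalid applies the strict 75%-black rule", {
  expect_true(detect_invalid(gray_scan(matrix(0, 50, 50))))
  expect_false(detect_invalid(gray_scan(matrix(255, 50, 50))))

  # boundary: exactly 75% black is NOT invalid (strictly greater required)
  px <- matrix(200, 100, 100)
  px[seq_len(7500)] <- 0
  expect_false(detect_invalid(gray_scan(px)))

  # 76% of pixels at value 4 (< 5) is invalid
  px2 <- matrix(200, 100, 100)
  px2[seq_len(7600)] <- 4
  expect_true(detect_invalid(gray_scan(px2)))

  # value 5 is not black ("less than five" is strict)
  px3 <- matrix(5, 100, 100)
  expect_false(detect_invalid(gray_scan(px3)))
})

test_that("detect_invalid is monotone under blackening pixels", {
  set.seed(4)
  px <- matrix(sample(0:255, 60 * 60, replace = TRUE), 60, 60)
  for (i in 1:10) {
    before <- detect_invalid(gray_scan(px))
    px[sample(length(px), 300)] <- 0
    after <- detect_invalid(gray_scan(px))
    expect_true(!before || after)    # true never flips back to false
  }
})

test_that("build_color_mask thresholds HSV with wrap and dilates", {
  gray_img <- solid_rgb(20, 20, c(128, 128, 128))
  red_spec <- default_color_masks()$RED
  expect_false(any(build_color_mask(gray_img, red_spec)))

  # single pure-red pixel dilates to a disc
  a <- array(0, dim = c(21, 21, 3)); a[11, 11, 1] <- 255
  m <- build_color_mask(scan_image(a), red_spec)
  expect_true(m[11, 11])
  expect_true(m[9, 11] && m[13, 11] && m[11, 9] && m[11, 13])
  expect_equal(sum(m), sum(buscurate:::disc_brush(2) > 0))

  # hue wrap: dark-magenta-ish red (hue near 179) also matches RED
  a2 <- array(0, dim = c(9, 9, 3)); a2[5, 5, ] <- c(220, 10, 30)
  expect_true(build_color_mask(scan_image(a2), red_spec)[5, 5])

  # 1-channel input yields an all-false mask
  expect_false(any(build_color_mask(gray_scan(matrix(90, 8, 8)), red_spec)))
})

test_that("doppler rectangles are covered by the dilated flow mask", {
  sp <- class_phantom_spec("doppler", 31)
  ph <- render_phantom(sp)
  hsv_masks <- lapply(default_color_masks()[c("RED", "BLUE")],
                      function(s) build_color_mask(ph$image, s))
  flow <- Reduce(`|`, hsv_masks)
  box <- sp$doppler_box$box
  inside <- flow[(box$y_top + 1):box$y_bottom, (box$x_left + 1):box$x_right]
  expect_gt(mean(inside), 0.9)   # dilation must cover at least the colored box
})

test_that("detect_indicator_shape recognizes rectangles and spanning lines", {
  expect_false(detect_indicator_shape(matrix(FALSE, 50, 50)))

  # full border of a 200x300 rectangle
  m <- matrix(FALSE, 300, 400)
  m[50:249, 50:349] <- TRUE
  m[53:246, 53:346] <- FALSE
  expect_true(detect_indicator_shape(m))

  # 1-px vertical line spanning 90% of image height
  v <- matrix(FALSE, 200, 300)
  v[10:190, 150] <- TRUE
  expect_gte(sum(v[, 150]) / 200, 0.9)   # brute-force span check
  expect_true(detect_indicator_shape(v))

  # an isolated small blob fails both criteria
  blob <- matrix(FALSE, 200, 300)
  blob[100:119, 100:119] <- TRUE
  expect_false(detect_indicator_shape(blob))

  # partial (three-sided) rectangle still fires
  u <- matrix(FALSE, 300, 400)
  u[60:200, 80:82] <- TRUE; u[60:200, 300:302] <- TRUE; u[198:200, 80:302] <- TRUE
  expect_true(detect_indicator_shape(u))
})

test_that("flow_fraction equals the brute-force pixel ratio", {
  m <- matrix(FALSE, 100, 100)
  area <- bounding_box(0, 0, 100, 100)
  expect_equal(flow_fraction(m, area), 0)
  expect_equal(flow_fraction(!m, area), 1)
  m[41:50, 31:40] <- TRUE                       # 10x10 block wholly inside
  expect_equal(flow_fraction(m, area), 0.01)

  set.seed(12)
  for (i in 1:20) {
    h <- sample(10:40, 1); w <- sample(10:40, 1)
    mask <- matrix(runif(h * w) < 0.3, h, w)
    x0 <- sample(0:(w - 5), 1); y0 <- sample(0:(h - 5), 1)
    box <- bounding_box(x0, y0, x0 + sample(2:(w - x0), 1), y0 + sample(2:(h - y0), 1))
    expect_equal(flow_fraction(mask, box), oracle_flow_fraction(mask, box))
  }
})

test_that("classify_scan_mode follows the four-step decision", {
  # step 1: any grayscale image is B-mode
  expect_equal(classify_scan_mode(gray_scan(matrix(90, 60, 60))), "B_MODE")
  set.seed(8)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 1600, replace = TRUE), 40, 40)
    expect_equal(classify_scan_mode(gray_scan(px)), "B_MODE")
  }

  # step 3: green indicator rectangle with negligible flow pixels
  ph <- render_phantom(class_phantom_spec("indicator_box", 77))
  expect_equal(classify_scan_mode(ph$image), "NON_B_MODE")

  # step 4: 2% of the scan area pure red, no rectangle
  ph2 <- render_phantom(phantom_spec(seed = 6))
  a <- array(rep(ph2$image$pixels, 3), dim = c(420, 560, 3))
  area <- ph2$truth$scan_area
  n_red <- round(0.02 * area$w * area$h)
  rows <- sample(seq.int(area$y_top + 30, area$y_bottom - 30), n_red, replace = TRUE)
  cols <- sample(seq.int(area$x_left + 30, area$x_right - 30), n_red, replace = TRUE)
  for (k in seq_len(n_red)) a[rows[k], cols[k], ] <- c(230, 20, 20)
  expect_equal(classify_scan_mode(scan_image(a)), "NON_B_MODE")

  # below the 0.5% cutoff: sparse chroma noise stays B-mode
  a2 <- array(rep(ph2$image$pixels, 3), dim = c(420, 560, 3))
  n_few <- round(0.001 * area$w * area$h)
  rows <- sample(seq.int(area$y_top + 30, area$y_bottom - 30), n_few)
  cols <- sample(seq.int(area$x_left + 30, area$x_right - 30), n_few)
  for (k in seq_len(n_few)) a2[rows[k], cols[k], ] <- c(230, 20, 20)
  expect_equal(classify_scan_mode(scan_image(a2)), "B_MODE")
})
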
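library(tibble)

test_that("detect_calipers finds isolated crosses one-to-one", {
  expect_equal(nrow(detect_calipers(gray_scan(matrix(90, 300, 400)))), 0)

  centers <- tibble(cx = c(180, 300, 180, 300), cy = c(140, 140, 280, 280),
                    style = "CROSS", size = 21L)
  ph <- render_phantom(phantom_spec(calipers = centers, seed = 17))
  boxes <- detect_calipers(ph$image)
  expect_equal(nrow(boxes), 4)
  # one-to-one: each detected box center is nearest to a distinct true center
  det_cx <- (boxes$x_left + boxes$x_right) / 2
  det_cy <- (boxes$y_top + boxes$y_bottom) / 2
  assign_idx <- vapply(seq_len(4), function(i) {
    which.min((centers$cx - det_cx[i])^2 + (centers$cy - det_cy[i])^2)
  }, integer(1))
  expect_setequal(assign_idx, 1:4)
  expect_true(all(abs(det_cx - centers$cx[assign_idx]) <= 2))
  expect_true(all(abs(det_cy - centers$cy[assign_idx]) <= 2))
})

test_that("caliper boxes lie strictly inside the central region", {
  ph <- render_phantom(class_phantom_spec("calipers", 55))
  boxes <- detect_calipers(ph$image)
  h <- ph$image$height; w <- ph$image$width
  expect_gt(nrow(boxes), 0)
  expect_true(all(boxes$x_left > 0.15 * w & boxes$x_right < 0.85 * w))
  expect_true(all(boxes$y_top > 0.15 * h & boxes$y_bottom < 0.85 * h))
})

test_that("crosses inside the border mask or below the size bound are ignored", {
  # cross centered in the outer 15% border
  ph <- render_phantom(phantom_spec(
    calipers = tibble(cx = 40, cy = 40, style = "CROSS", size = 21L), seed = 2))
  expect_equal(nrow(detect_calipers(ph$image)), 0)

  # 5-px crosses fall below min_box_px
  ph2 <- render_phantom(phantom_spec(
    calipers = tibble(cx = c(200, 320), cy = c(200, 260), style = "CROSS", size = 5L),
    seed = 2))
  expect_equal(nrow(detect_calipers(ph2$image)), 0)
})

test_that("detect_calipers is translation-equivariant in the central region", {
  base <- tibble(cx = c(190, 310), cy = c(170, 250), style = "CROSS", size = 21L)
  b0 <- detect_calipers(render_phantom(phantom_spec(calipers = base, seed = 5))$image)
  shifted <- dplyr::mutate(base, cx = cx + 13, cy = cy + 9)
  b1 <- detect_calipers(render_phantom(phantom_spec(calipers = shifted, seed = 5))$image)
  expect_equal(nrow(b0), 2); expect_equal(nrow(b1), 2)
  o0 <- order(b0$x_left); o1 <- order(b1$x_left)
  expect_true(all(abs((b1$x_left[o1] - b0$x_left[o0]) - 13) <= 1))
  expect_true(all(abs((b1$y_top[o1] - b0$y_top[o0]) - 9) <= 1))
})

test_that("dotted spanning lines defeat the contour method but not Hough", {
  expect_false(detect_calipers_hough(gray_scan(matrix(0, 300, 400))))

  ph <- render_phantom(class_phantom_spec("dotted_calipers", 23))
  expect_equal(nrow(detect_calipers(ph$image)), 0)     # merged component too large
  expect_true(detect_calipers_hough(ph$image))         # crossing lines intersect
})

test_that("parallel lines never count as Hough calipers", {
  lines <- list(list(x0 = 170, y0 = 170, x1 = 380, y1 = 170, dash = 4, gap = 3),
                list(x0 = 170, y0 = 240, x1 = 380, y1 = 240, dash = 4, gap = 3))
  ph <- render_phantom(phantom_spec(spanning_line = lines, seed = 3))
  expect_false(detect_calipers_hough(ph$image))
})

test_that("detect_dual_view follows the aspect and midline-column rules", {
  # tall narrow scan is excluded by the aspect filter
  tall <- render_phantom(phantom_spec(canvas = c(480L, 240L), seed = 4))
  expect_false(detect_dual_view(tall$image))

  dv <- render_phantom(class_phantom_spec("dual_view", 19))
  expect_true(detect_dual_view(dv$image))
  # column-count oracle: Canny edges at the midline dominate the neighbors
  edges <- buscurate:::canny_edges(to_grayscale(dv$image)$pixels)
  m <- floor(dv$image$width / 2)
  expect_gt(sum(edges[, m + 1]), 100)
  expect_gt(sum(edges[, m + 1]), sum(edges[, m - 9]) + 10)

  # single wide rectangular scan: uniform interior, no midline edges
  single <- render_phantom(phantom_spec(seed = 4))
  expect_false(detect_dual_view(single$image))

  expect_error(detect_dual_view(gray_scan(matrix(0, 30, 15))), "narrow")
})

test_that("green-dominated (elastography-style) scans are never dual-view", {
  ph <- render_phantom(class_phantom_spec("dual_view", 19))
  a <- array(rep(ph$image$pixels, 3), dim = c(dim(ph$image$pixels), 3))
  a[100:300, 100:600, 1] <- 20; a[100:300, 100:600, 2] <- 200; a[100:300, 100:600, 3] <- 60
  expect_false(detect_dual_view(scan_image(a)))
})
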
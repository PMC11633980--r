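test_that("stage1_crop isolates the largest bright component exactly", {
  px <- matrix(0, 200, 300)
  px[41:190, 51:150] <- 120                      # 150x100 block
  s1 <- stage1_crop(gray_scan(px))
  expect_equal(c(s1$box$x_left, s1$box$y_top, s1$box$x_right, s1$box$y_bottom),
               c(50L, 40L, 150L, 190L))
  expect_equal(s1$mode_value, 0L)

  expect_error(stage1_crop(gray_scan(matrix(0, 80, 80))),
               class = "buscurate_degenerate_input")

  # two components: the larger one wins
  px2 <- matrix(0, 100, 100)
  px2[11:40, 11:40] <- 200                        # area 900
  px2[61:75, 61:75] <- 200                        # area 225
  s2 <- stage1_crop(gray_scan(px2))
  expect_equal(c(s2$box$x_left, s2$box$y_top), c(10L, 10L))
  expect_equal(c(s2$box$x_right, s2$box$y_bottom), c(40L, 40L))
})

test_that("classify_shape applies the fill-ratio cutoff", {
  mask <- matrix(FALSE, 100, 100); mask[21:80, 21:80] <- TRUE
  box <- bounding_box(20, 20, 80, 80)
  expect_equal(classify_shape(mask, box), "RECTANGULAR")

  # solid trapezoid, top width half the bottom width: fill (a+b)/2b = 0.75
  trap <- matrix(FALSE, 120, 160)
  for (r in 1:100) {
    half <- (30 + 30 * (r - 1) / 99)
    trap[r + 10, round(80 - half):round(80 + half)] <- TRUE
  }
  tbox <- bounding_box(min(which(colSums(trap) > 0)) - 1, 10,
                       max(which(colSums(trap) > 0)), 110)
  fill <- sum(trap[11:110, (tbox$x_left + 1):tbox$x_right]) / (tbox$w * tbox$h)
  expect_lt(fill, 0.95); expect_gt(fill, 0.70)
  expect_equal(classify_shape(trap, tbox), "NON_RECTANGULAR")

  # 1-px corner nicks stay rectangular
  nick <- mask
  nick[21, 21] <- nick[21, 80] <- nick[80, 21] <- nick[80, 80] <- FALSE
  expect_equal(classify_shape(nick, box), "RECTANGULAR")
})

test_that("stage2_crop matches the thirds-band median rule", {
  # solid rectangle occupying the whole box: stage2 == stage1
  px <- matrix(0, 90, 120); px[31:60, 41:80] <- 150
  box <- bounding_box(40, 30, 80, 60)
  s2 <- stage2_crop(gray_scan(px), box, mode_value = 0)
  expect_equal(unclass(s2)[1:4], unclass(box)[1:4])

  # symmetric trapezoid, h divisible by 3: width = the middle band's width
  h <- 90; top_half <- 30; bot_half <- 60
  px2 <- matrix(0, 140, 200)
  for (r in 1:h) {
    half <- top_half + (bot_half - top_half) * (r - 1) / (h - 1)
    px2[20 + r, round(100 - half):round(100 + half)] <- 140
  }
  s1 <- stage1_crop(gray_scan(px2), erosion_radius = 0, dilation_radius = 0)
  s2b <- stage2_crop(gray_scan(px2), s1$box, mode_value = 0)
  oracle <- oracle_stage2(px2, s1$box, 0)
  expect_equal(s2b$x_left, oracle$x_left)
  expect_equal(s2b$x_right, oracle$x_right)
  expect_equal(s2b$y_top, oracle$y_top)
  expect_equal(s2b$y_bottom, oracle$y_bottom)
  # middle band of a linear taper has the median extremes
  mid_rows <- (s1$box$y_top + floor(h / 3) + 1):(s1$box$y_top + floor(2 * h / 3))
  mid_cols <- which(colSums(px2[mid_rows, ] > 0) > 0)
  expect_equal(s2b$x_left, min(mid_cols) - 1L)
  expect_equal(s2b$x_right, max(mid_cols))
})

test_that("stage2 band extremes agree with a brute-force scan on random masks", {
  set.seed(33)
  for (i in 1:12) {
    px <- matrix(0, 60, 70)
    n <- sample(30:120, 1)
    px[cbind(sample(10:55, n, TRUE), sample(8:62, n, TRUE))] <- sample(50:200, n, TRUE)
    box <- bounding_box(5, 7, 65, 58)
    got <- buscurate:::band_extremes(px != 0, box)
    want <- oracle_band_extremes(px, box, 0)
    expect_equal(got, want)
  }
})

test_that("crop_scan composes the stages with containment and idempotence", {
  for (sh in c("RECTANGULAR", "TRAPEZOID", "CONVEX", "IRREGULAR")) {
    ph <- render_phantom(phantom_spec(shape = sh, seed = 13))
    cr <- crop_scan(ph$image)
    s1 <- cr$stage1_box; s2 <- cr$stage2_box
    expect_true(s2$x_left >= s1$x_left && s2$x_right <= s1$x_right)
    expect_true(s2$y_top >= s1$y_top && s2$y_bottom <= s1$y_bottom)
    if (sh == "RECTANGULAR") {
      expect_equal(cr$shape_class, "RECTANGULAR")
      expect_equal(unclass(s2)[1:4], unclass(s1)[1:4])
    } else {
      expect_equal(cr$shape_class, "NON_RECTANGULAR")
    }
  }

  # trapezoid crops strictly inside stage 1 on left and right
  trap <- render_phantom(phantom_spec(shape = "TRAPEZOID", seed = 13))
  cr <- crop_scan(trap$image)
  expect_gt(cr$stage2_box$x_left, cr$stage1_box$x_left)
  expect_lt(cr$stage2_box$x_right, cr$stage1_box$x_right)

  # idempotence on the cropped trapezoid phantom (its crop retains background
  # corners, so scan-area identification remains well-posed on the sub-image)
  cr1 <- crop_scan(trap$image)
  sub <- apply_crop(trap$image, cr1$stage2_box)
  cr2 <- crop_scan(sub)
  expect_lte(cr2$stage2_box$x_left, 1)
  expect_lte(cr2$stage2_box$y_top, 1)
  expect_gte(cr2$stage2_box$x_right, sub$width - 1)
  expect_gte(cr2$stage2_box$y_bottom, sub$height - 1)

  expect_error(crop_scan(render_phantom(phantom_spec(invalid = TRUE, seed = 1))$image),
               class = "buscurate_degenerate_input")
})

test_that("mirroring the input mirrors the crop boxes", {
  for (seed in c(3, 9)) {
    ph <- render_phantom(phantom_spec(shape = "TRAPEZOID", seed = seed))
    w <- ph$image$width
    cr <- crop_scan(ph$image)
    crm <- crop_scan(mirror_scan(ph$image))
    expect_lte(abs(crm$stage2_box$x_left - (w - cr$stage2_box$x_right)), 1)
    expect_lte(abs(crm$stage2_box$x_right - (w - cr$stage2_box$x_left)), 1)
    expect_lte(abs(crm$stage1_box$x_left - (w - cr$stage1_box$x_right)), 1)
    expect_equal(crm$stage2_box$y_top, cr$stage2_box$y_top)
  }
})
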
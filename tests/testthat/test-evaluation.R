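test_that("confusion counts the four cells by enumeration", {
  cm <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 1, fn = 1, tn = 1))

  same <- confusion(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(same$fp + same$fn, 0)

  allwrong <- confusion(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(allwrong$fn, 5)

  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("undefined ratios are NA, never zero", {
  cm <- confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(sensitivity(cm)))
  expect_equal(specificity(cm), 1)
  cm2 <- confusion_matrix(tp = 3, fp = 0, tn = 0, fn = 0)
  expect_true(is.na(specificity(cm2)))
  expect_equal(sensitivity(cm2), 1)
})

test_that("statistics identities hold on random confusion matrices", {
  set.seed(19)
  for (i in 1:30) {
    cm <- confusion_matrix(tp = sample(0:50, 1) + 1, fp = sample(0:50, 1),
                           tn = sample(0:50, 1), fn = sample(0:50, 1))
    expect_equal(sensitivity(cm) + cm$fn / (cm$tp + cm$fn), 1)
    prec <- cm$tp / (cm$tp + cm$fp)
    rec <- sensitivity(cm)
    expect_equal(f1_score(cm), 2 * prec * rec / (prec + rec))
  }
  # perfect classifier
  p <- confusion_matrix(tp = 7, fp = 0, tn = 9, fn = 0)
  expect_equal(c(sensitivity(p), specificity(p), f1_score(p)), c(1, 1, 1))
})

test_that("round3 rounds halves away from zero", {
  expect_equal(round3(0.0005), 0.001)
  expect_equal(round3(0.9665), 0.967)
  expect_equal(round3(-0.0005), -0.001)
  expect_equal(round3(0.571428), 0.571)
})

test_that("published per-task rows recompute from their own counts", {
  lat <- confusion_matrix(tp = 371, fp = 1, tn = 55, fn = 3)
  expect_equal(round3(sensitivity(lat)), 0.992)
  expect_equal(round3(specificity(lat)), 0.982)
  expect_equal(round3(f1_score(lat)), 0.995)

  enh <- confusion_matrix(tp = 10, fp = 2, tn = 418, fn = 0)
  expect_equal(round3(sensitivity(enh)), 1.000)
  expect_equal(round3(f1_score(enh)), 0.909)

  dual <- confusion_matrix(tp = 4, fp = 6, tn = 420, fn = 0)
  expect_equal(round3(f1_score(dual)), 0.571)
})

test_that("tidy and glance expose counts and statistics as tibbles", {
  cm <- confusion_matrix(tp = 8, fp = 2, tn = 15, fn = 1)
  expect_equal(tidy(cm)$tp, 8)
  g <- glance(cm)
  expect_equal(g$n, 26)
  expect_equal(g$sensitivity, 8 / 9)
})

test_that("score_manifest is exact on perfect predictions and sensitive to flips", {
  man <- generate_suite(2, seed = 55)
  preds <- man    # perfect predictions share the manifest columns
  sc <- score_manifest(preds, man,
                       tasks = c("invalid", "calipers", "laterality", "clock_position"))
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$fp == 0 & sc$fn == 0))
  expect_true(all(sc$sensitivity[!is.na(sc$sensitivity)] == 1))

  expect_equal(nrow(score_manifest(preds, man, tasks = character())), 0)

  flip <- preds
  i <- which(flip$class == "calipers")[1]
  flip$has_calipers[i] <- FALSE
  sc2 <- score_manifest(flip, man, tasks = c("invalid", "calipers"))
  base <- score_manifest(preds, man, tasks = c("invalid", "calipers"))
  expect_equal(sc2$fn[sc2$task == "calipers"], base$fn[base$task == "calipers"] + 1)
  expect_equal(sc2$tp[sc2$task == "calipers"], base$tp[base$task == "calipers"] - 1)
  expect_identical(sc2[sc2$task == "invalid", ], base[base$task == "invalid", ])
})

test_that("field tasks require exact value agreement for a true positive", {
  man <- generate_suite(2, seed = 56)
  wrong <- man
  i <- which(wrong$class == "text")[1]
  wrong$laterality[i] <- if (man$laterality[i] == "LEFT") "RIGHT" else "LEFT"
  sc <- score_manifest(wrong, man, tasks = "laterality")
  expect_equal(sc$fp, 0)   # the wrong value was still on an annotated scan
  expect_equal(sc$fn, 1)   # recognized but misclassified: the truth was missed
  expect_equal(sc$tp + sc$fp + sc$tn + sc$fn, nrow(man))
})

test_that("unmatched source ids are excluded with a warning note", {
  man <- generate_suite(1, seed = 57)
  preds <- man[-1, ]
  sc <- score_manifest(preds, man, tasks = "invalid")
  expect_equal(sc$tp + sc$fp + sc$tn + sc$fn, nrow(man) - 1)
  expect_match(attr(sc, "warnings"), man$source_id[1], fixed = TRUE)
})
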
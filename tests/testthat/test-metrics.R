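test_that("Dice and IoU match brute-force pixel counting", {
  A <- rect_mask(8, 8, 1, 1, 2, 2)  # 4 px
  B <- rect_mask(8, 8, 1, 2, 2, 2)  # 4 px, overlap 2
  expect_equal(dice(A, B), 0.5)
  expect_equal(iou(A, B), 1 / 3)
  expect_equal(dice(A, A), 1)
  expect_equal(iou(A, A), 1)
  D <- rect_mask(8, 8, 5, 5, 2, 2)
  expect_equal(dice(A, D), 0)
  expect_equal(iou(A, D), 0)
  expect_error(dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "undefined")
  expect_error(iou(A, rect_mask(9, 8, 1, 1, 2, 2)), "shape")

  # dice = 2*iou/(1+iou), symmetry, [0,1] on random masks
  withr::with_seed(42, {
    for (k in 1:50) {
      X <- random_ellipse_mask(20, 20); Y <- random_ellipse_mask(20, 20)
      if (!any(X) || !any(Y)) next
      d <- dice(X, Y); u <- iou(X, Y)
      expect_equal(d, naive_dice(X, Y))
      expect_equal(u, naive_iou(X, Y))
      expect_equal(d, 2 * u / (1 + u))
      expect_equal(d, dice(Y, X))
      expect_true(d >= 0 && d <= 1 && u >= 0 && u <= 1)
    }
  })
})

test_that("instance matching follows the greedy best-Dice one-to-one rule", {
  sq <- function(r0, c0, s = 4) rect_mask(20, 20, r0, c0, s, s)

  # no predictions
  mr <- match_instances(list(sq(2, 2), sq(10, 10)), list())
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(0L, 0L, 2L))
  expect_true(all(mr$gt$verdict == "FN"))

  # one perfect prediction per ground truth
  mr <- match_instances(list(sq(2, 2), sq(10, 10)),
                        list(sq(10, 10), sq(2, 2)))
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(2L, 0L, 0L))
  expect_identical(mr$gt$pred, c(2L, 1L))

  # two good predictions contending for one ground truth: 1 TP, 1 FP
  gt <- rect_mask(20, 20, 5, 5, 4, 10)           # 40 px
  p1 <- rect_mask(20, 20, 5, 5, 4, 9)            # IoU 36/40 = 0.9
  p2 <- rect_mask(20, 20, 5, 6, 4, 10)           # IoU 36/44 ~ 0.818
  expect_gt(iou(gt, p1), 0.5); expect_gt(iou(gt, p2), 0.5)
  mr <- match_instances(list(gt), list(p2, p1))
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(1L, 1L, 0L))
  expect_identical(mr$gt$pred, 2L) # the higher-Dice candidate wins

  # FP sub-typing: doublet spanning two somas, boundary miss, background
  g1 <- sq(2, 2); g2 <- sq(2, 8)
  doublet <- rect_mask(20, 20, 2, 2, 4, 10) # covers both
  wrongb <- rect_mask(20, 20, 12, 2, 6, 6)  # overlaps g3 weakly
  g3 <- rect_mask(20, 20, 14, 2, 4, 4)
  bgd <- sq(15, 15)
  mr <- match_instances(list(g1, g2, g3), list(doublet, wrongb, bgd))
  expect_identical(mr$pred$verdict,
                   c("FP_doublet", "FP_wrong_boundary", "FP_background"))

  # counts are internally consistent
  expect_identical(mr$tp, sum(mr$gt$verdict == "TP"))
  expect_identical(mr$fn, sum(mr$gt$verdict == "FN"))
  expect_identical(mr$fp, sum(mr$pred$verdict != "TP"))
})

test_that("matching agrees with the scalar oracle on random instance sets", {
  withr::with_seed(7, {
    for (trial in 1:100) {
      ng <- sample(0:4, 1); np <- sample(0:4, 1)
      gt <- lapply(seq_len(ng), function(i) random_ellipse_mask(16, 16))
      pr <- lapply(seq_len(np), function(i) random_ellipse_mask(16, 16))
      gt <- Filter(any, gt); pr <- Filter(any, pr)
      mr <- match_instances(gt, pr)
      or <- oracle_match(gt, pr)
      expect_identical(mr$gt$pred, or$match_of)
      expect_identical(c(mr$tp, mr$fp, mr$fn),
                       c(or$tp, or$fp, or$fn))
      expect_lte(mr$tp, max_matching_tp(gt, pr))
      expect_lte(mr$tp, min(length(gt), length(pr)))
    }
  })
})

test_that("precision, recall and yield follow their exact ratio contracts", {
  expect_equal(precision(10, 0), 1)
  expect_equal(recall(0, 5), 0)
  expect_equal(yield_rate(0, 7), 0)
  expect_error(precision(0, 0), "undefined")
  expect_error(recall(0, 0), "undefined")
  expect_error(yield_rate(1, 0), "undefined")
  expect_error(yield_rate(5, 3), "exceeds")

  # exactness before rounding: p*(TP+FP) = TP, r*(TP+FN) = TP
  withr::with_seed(1, {
    for (k in 1:20) {
      tp <- sample(0:500, 1) + 1L
      fp <- sample(0:500, 1); fn <- sample(0:500, 1)
      expect_equal(precision(tp, fp) * (tp + fp), tp)
      expect_equal(recall(tp, fn) * (tp + fn), tp)
    }
  })
})

test_that("somatic area and area agreement are exact", {
  m <- rect_mask(20, 20, 3, 3, 10, 10)
  expect_equal(soma_area(m, 1), 100)
  expect_equal(soma_area(m, 0.5), 25)
  expect_equal(soma_area(matrix(FALSE, 4, 4), 1), 0)
  expect_error(soma_area(m, 0), "pixel_size_um")

  man <- c(120, 180, 240, 310, 150, 90)
  # identical pairs
  ag <- area_agreement(cbind(man, man))
  expect_equal(ag$mean_diff, 0)
  expect_equal(ag$slope, 1)
  expect_equal(ag$r_squared, 1)
  # constant shift
  ag <- area_agreement(cbind(man + 10, man))
  expect_equal(ag$mean_diff, 10)
  expect_equal(ag$slope, 1)
  # pure scaling (noise free)
  ag <- area_agreement(cbind(1.1 * man, man))
  expect_equal(ag$slope, 1.1)
  expect_equal(ag$r_squared, 1)
  # constant manual areas: correlation undefined, flagged
  ag <- area_agreement(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_true(ag$constant_manual)
  expect_true(is.na(ag$r_squared))
  expect_error(area_agreement(cbind(1:2, 1:2)), "3")
})

test_that("threshold sweeps partition detections and decline monotonically", {
  sq <- function(r0, c0) rect_mask(24, 24, r0, c0, 4, 4)
  gt <- list(list(sq(2, 2), sq(10, 10), sq(18, 18)))
  mk <- function(mask, s) somaswin:::instance_prediction(mask, s)
  preds <- list(list(mk(sq(2, 2), 0.9), mk(sq(10, 10), 0.3),
                     mk(rect_mask(24, 24, 17, 17, 6, 6), 0.15),
                     mk(sq(2, 18), 0.06)))
  sw <- threshold_sweep(preds, gt, c(0, 0.05, 0.1, 0.2, 0.4, 0.95))
  expect_identical(sw$total_detected[1L], 4L)
  expect_true(all(diff(sw$total_detected) <= 0))
  rowsums <- sw$pct_correct + sw$pct_wrong_boundary +
    sw$pct_background_doublet
  expect_equal(rowsums[!is.na(rowsums)],
               rep(100, sum(!is.na(rowsums))))
  expect_error(threshold_sweep(preds, gt, c(0.4, 0.1)), "ascending")
})
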
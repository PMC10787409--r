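test_that("confusion counts match hand-worked and oracle values", {
  ones <- matrix(1L, 4, 4)
  c1 <- confusion(ones, ones)
  expect_equal(unclass(c1)[c("tp", "fp", "fn", "tn")],
               list(tp = 16, fp = 0, fn = 0, tn = 0))
  c2 <- confusion(matrix(1L, 2, 2), matrix(0L, 2, 2))
  expect_equal(unclass(c2)[c("tp", "fp", "fn", "tn")],
               list(tp = 0, fp = 4, fn = 0, tn = 0))
  pred <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3, byrow = FALSE)
  truth <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 0), 3, 3, byrow = FALSE)
  c3 <- confusion(pred, truth)
  o3 <- confusion_oracle(pred, truth)
  expect_equal(unclass(c3)[c("tp", "fp", "fn", "tn")], o3)
  expect_equal(o3, list(tp = 2, fp = 1, fn = 1, tn = 5))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the three metrics implement the stated formulas", {
  c <- list(tp = 90, fp = 10, fn = 7, tn = 0)
  expect_equal(precision(c), 90)
  expect_equal(iou(list(tp = 1, fp = 1, fn = 2, tn = 0)), 25)
  expect_equal(dice(list(tp = 8, fp = 2, fn = 2, tn = 0)), 80)
  expect_error(precision(list(tp = -1, fp = 0, fn = 0, tn = 0)), "nonnegative")
})

test_that("zero-denominator conventions: warn-and-zero, doubly-empty is 100", {
  empty_both <- list(tp = 0, fp = 0, fn = 0, tn = 16)
  expect_equal(precision(empty_both), 100)
  expect_equal(iou(empty_both), 100)
  expect_equal(dice(empty_both), 100)
  miss <- list(tp = 0, fp = 0, fn = 5, tn = 11)
  expect_warning(p <- precision(miss), "zero denominator")
  expect_equal(p, 0)
  expect_equal(suppressWarnings(iou(miss)), 0)
  expect_equal(suppressWarnings(dice(miss)), 0)
})

test_that("dice_from_iou reproduces printed table rows and fixed points", {
  expect_equal(dice_from_iou(83.38), 90.94)
  expect_equal(dice_from_iou(75.86), 86.27)
  expect_equal(dice_from_iou(0), 0)
  expect_equal(dice_from_iou(100), 100)
  expect_error(dice_from_iou(120), "\\[0, 100\\]")
  expect_error(dice_from_iou(-2), "\\[0, 100\\]")
})

test_that("metric inequalities hold for random counts", {
  set.seed(8)
  for (i in 1:200) {
    c <- list(tp = rpois(1, 20), fp = rpois(1, 5), fn = rpois(1, 5), tn = rpois(1, 50))
    if (c$tp + c$fp + c$fn == 0) next
    i_ <- suppressWarnings(iou(c)); d_ <- suppressWarnings(dice(c))
    p_ <- suppressWarnings(precision(c))
    expect_lte(i_, d_ + 1e-12)
    expect_lte(i_, p_ + 1e-12)
    # shared-count identity before rounding
    expect_equal(d_, 100 * 2 * (i_ / 100) / (1 + i_ / 100), tolerance = 1e-12)
  }
})

test_that("pooled evaluation equals a per-pixel double loop and is order-invariant", {
  set.seed(9)
  samples <- lapply(1:6, function(i) {
    truth <- matrix(rbinom(12 * 12, 1, 0.3), 12, 12)
    list(image = truth, mask = truth)  # image stands in for a stored prediction
  })
  flip_some <- function(img) {
    pred <- img
    pred[1:3, 1:3] <- 1 - pred[1:3, 1:3]
    pred
  }
  ev <- evaluate(flip_some, samples)
  tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (s in samples) {
    o <- confusion_oracle(flip_some(s$image), s$mask)
    for (k in names(tot)) tot[[k]] <- tot[[k]] + o[[k]]
  }
  expect_equal(unclass(ev$counts)[c("tp", "fp", "fn", "tn")], tot)
  expect_equal(ev$precision, 100 * tot$tp / (tot$tp + tot$fp))
  ev_rev <- evaluate(flip_some, rev(samples))
  expect_equal(ev[c("precision", "iou", "dice")],
               ev_rev[c("precision", "iou", "dice")])
  # perfect predictor
  ev_perf <- evaluate(function(img) img, samples)
  expect_equal(c(ev_perf$precision, ev_perf$iou, ev_perf$dice), c(100, 100, 100))
  # all-background predictor
  ev_bg <- suppressWarnings(evaluate(function(img) img * 0, samples))
  expect_equal(c(ev_bg$precision, ev_bg$iou, ev_bg$dice), c(0, 0, 0))
  expect_error(evaluate(function(img) img, list()), "empty")
})

test_that("per-image reporting is available alongside pooled counts", {
  samples <- lapply(1:3, function(i) {
    truth <- matrix(rbinom(8 * 8, 1, 0.4), 8, 8)
    list(image = truth, mask = truth)
  })
  ev <- evaluate(function(img) img, samples, per_image = TRUE)
  expect_identical(nrow(ev$per_image), 3L)
  expect_true(all(ev$per_image$dice == 100))
})
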
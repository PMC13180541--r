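test_that("IoU closed forms and degenerate-box validation", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching follows the one-per-gt, score-order rule", {
  gt <- list(boxes = matrix(c(0, 0, 10, 10), 1), classes = 0L)
  d1 <- list(boxes = matrix(c(0, 0, 10, 10), 1), scores = 0.9, classes = 0L)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(sum(m$tp), 1)
  expect_equal(m$fn, 0)
  # two identical detections on one gt: second is a false positive
  d2 <- list(boxes = rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)),
             scores = c(0.9, 0.8), classes = c(0L, 0L))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  expect_error(match_detections(list(boxes = d2$boxes, scores = c(0.1, 0.9),
                                     classes = c(0L, 0L)), gt, 0.5),
               "sorted")
})

test_that("greedy matching equals an independent reimplementation on random cases", {
  greedy_ref <- function(dets, gts, thr) {
    nb <- nrow(dets$boxes); mg <- nrow(gts$boxes)
    tp <- logical(nb); taken <- logical(mg)
    for (i in seq_len(nb)) {
      best <- 0; bj <- 0L
      for (j in seq_len(mg)) {
        if (taken[j] || gts$classes[j] != dets$classes[i]) next
        iou <- box_iou(dets$boxes[i, ], gts$boxes[j, ])
        if (iou >= thr && iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0L) { tp[i] <- TRUE; taken[bj] <- TRUE }
    }
    list(tp = tp, fn = sum(!taken))
  }
  set.seed(20)
  for (trial in 1:25) {
    mk_box <- function(n) {
      x1 <- runif(n, 0, 50); y1 <- runif(n, 0, 50)
      cbind(x1, y1, x1 + runif(n, 5, 30), y1 + runif(n, 5, 30))
    }
    dets <- list(boxes = mk_box(5), scores = sort(runif(5), decreasing = TRUE),
                 classes = sample(0:1, 5, replace = TRUE))
    gts <- list(boxes = mk_box(3), classes = sample(0:1, 3, replace = TRUE))
    got <- match_detections(dets, gts, 0.3)
    ref <- greedy_ref(dets, gts, 0.3)
    expect_equal(got$tp, ref$tp)
    expect_equal(got$fn, ref$fn)
  }
})

test_that("average precision: boundary cases and exact hand-computed value", {
  expect_equal(average_precision(c(TRUE, TRUE), c(0.9, 0.8), 2), 1)
  expect_equal(average_precision(logical(0), numeric(0), 3), 0)
  expect_true(is.na(average_precision(logical(0), numeric(0), 0)))
  expect_equal(average_precision(c(TRUE), c(0.9), 0), 0)
  # flags (TP, FP, TP), num_gt = 2: PR points are
  #   after det1: rec 0.5, prec 1
  #   after det2: rec 0.5, prec 1/2
  #   after det3: rec 1.0, prec 2/3
  # max-interpolated precision: 1 on recall (0, 0.5], 2/3 on (0.5, 1]
  # 101-point grid: 51 points at 1 (0.00..0.50), 50 points at 2/3
  expected <- (51 * 1 + 50 * 2 / 3) / 101
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2),
               expected)
})

test_that("AP is invariant to monotone score rescaling; zero-IoU FP never raises AP", {
  set.seed(30)
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  sc <- c(0.9, 0.7, 0.6, 0.4, 0.2)
  a1 <- average_precision(flags, sc, 4)
  a2 <- average_precision(flags, sc^3, 4)
  a3 <- average_precision(flags, 100 * sc + 5, 4)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
  a4 <- average_precision(c(flags, FALSE), c(sc, 0.01), 4)
  expect_lte(a4, a1)
})

test_that("evaluate: perfect detector gives all ones; P/R arithmetic is exact", {
  set.seed(40)
  gts <- lapply(1:20, function(i) {
    x1 <- runif(1, 0, 60); y1 <- runif(1, 0, 60)
    list(boxes = matrix(c(x1, y1, x1 + 20, y1 + 20), 1),
         classes = sample(0:3, 1))
  })
  dets <- lapply(gts, function(g) {
    list(boxes = g$boxes, scores = 1, classes = g$classes)
  })
  ev <- evaluate(dets, gts, classes = 0:3)
  expect_equal(ev$mAP50, 1)
  expect_equal(ev$mAP50_95, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # P = 2/3 at TP=2, FP=1; R = 1/2 at TP=2, FN=2
  gt2 <- list(list(boxes = rbind(c(0, 0, 10, 10), c(20, 20, 30, 30),
                                 c(40, 40, 50, 50), c(60, 60, 70, 70)),
                   classes = rep(0L, 4)))
  # detections: two on-target, one far off; two gts never covered
  dt2 <- list(list(boxes = rbind(c(0, 0, 10, 10), c(20, 20, 30, 30),
                                 c(80, 80, 90, 90)),
                   scores = c(0.9, 0.8, 0.7), classes = rep(0L, 3)))
  ev2 <- evaluate(dt2, gt2, classes = 0L)
  expect_equal(ev2$tp, 2)
  expect_equal(ev2$fp, 1)
  expect_equal(ev2$fn, 2)
  expect_equal(ev2$precision, 2 / 3)
  expect_equal(ev2$recall, 1 / 2)
  expect_error(evaluate(dt2, gt2, classes = 5L), "class id")
})

test_that("constructed jitter fixture: IoU 0.62 boxes give mAP@50-95 = 0.3", {
  # shift t chosen so IoU = (100 - t) / (100 + t) = 0.62 exactly
  t <- 100 * (1 - 0.62) / (1 + 0.62)
  gts <- lapply(1:10, function(i) {
    list(boxes = matrix(c(0, 0, 100, 100), 1), classes = 0L)
  })
  dets <- lapply(gts, function(g) {
    list(boxes = matrix(c(t, 0, 100 + t, 100), 1), scores = 0.9,
         classes = 0L)
  })
  expect_equal(box_iou(c(t, 0, 100 + t, 100), c(0, 0, 100, 100)), 0.62,
               tolerance = 1e-12)
  ev <- evaluate(dets, gts, classes = 0L)
  # passes thresholds 0.50, 0.55, 0.60; fails 0.65+ -> mean = 3/10
  expect_equal(ev$mAP50, 1)
  expect_equal(ev$mAP50_95, 0.3)
})
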
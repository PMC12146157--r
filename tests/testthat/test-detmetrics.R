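test_that("greedy matching yields one-to-one TP/FP/FN counts", {
  gts <- list(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30))
  perfect <- lapply(gts, function(b)
    bbox(b$x1, b$y1, b$x2, b$y2, confidence = 0.9))
  m <- match_detections(perfect, gts, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 0))
  m0 <- match_detections(list(), gts, 0.5)
  expect_equal(c(m0$tp, m0$fn), c(0, 2))
  # two preds over one gt: exactly one TP, one FP
  two <- list(bbox(0, 0, 10, 10, confidence = 0.9),
              bbox(0.5, 0.5, 10, 10, confidence = 0.8))
  m2 <- match_detections(two, gts[1], 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  # higher-confidence pred claims the gt
  expect_equal(m2$pairs$pred, 1L)
  # invariant: TP + FN = number of gt
  set.seed(31)
  for (i in 1:20) {
    inst <- random_instance()
    mm <- match_detections(inst$preds, inst$gts, runif(1, 0.1, 0.9))
    expect_equal(mm$tp + mm$fn, length(inst$gts))
    expect_equal(mm$tp + mm$fp, length(inst$preds))
    expect_true(all(!duplicated(mm$pairs$gt)))
    expect_true(all(!duplicated(mm$pairs$pred)))
  }
})

test_that("precision and recall follow the counting definitions", {
  expect_equal(precision_recall(list(tp = 3, fp = 1, fn = 2)),
               c(precision = 0.75, recall = 0.6))
  expect_equal(precision_recall(list(tp = 0, fp = 0, fn = 5)),
               c(precision = 0, recall = 0))
  expect_equal(precision_recall(list(tp = 8, fp = 2, fn = 0))[["precision"]],
               0.8)
})

test_that("average precision equals the exhaustive staircase oracle", {
  # all preds correct -> AP = 1 regardless of confidences
  gts <- list(bbox(0, 0, 10, 10), bbox(20, 20, 30, 30))
  preds <- list(bbox(0, 0, 10, 10, confidence = 0.3),
                bbox(20, 20, 30, 30, confidence = 0.8))
  expect_equal(average_precision(preds, gts, 0.5, "exact"), 1.0)
  expect_equal(average_precision(preds, gts, 0.5, "101point"), 1.0)
  # single miss -> AP = 0
  expect_equal(average_precision(list(bbox(50, 50, 60, 60, confidence = 0.9)),
                                 gts[1], 0.5), 0.0)
  # 200 random small instances, single class at a time
  set.seed(32)
  for (i in 1:200) {
    inst <- random_instance(n_classes = 1)
    th <- sample(c(0.3, 0.5, 0.75), 1)
    expect_equal(average_precision(inst$preds, inst$gts, th, "exact"),
                 ap_staircase_oracle(inst$preds, inst$gts, th))
  }
  expect_warning(ap <- average_precision(list(), list(), 0.5), "undefined")
  expect_true(is.na(ap))
})

test_that("AP is invariant to monotone transformation of confidences", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instance(n_classes = 1)
    if (!length(inst$preds)) next
    ap1 <- average_precision(inst$preds, inst$gts, 0.5, "exact")
    warped <- lapply(inst$preds, function(b) {
      b$confidence <- plogis(3 * b$confidence - 1); b
    })
    expect_equal(average_precision(warped, inst$gts, 0.5, "exact"), ap1)
  }
})

test_that("mAP averages classes and decreases with stricter thresholds", {
  gts <- list(bbox(0, 0, 10, 10, class_id = "small"),
              bbox(20, 20, 30, 30, class_id = "big"))
  # small detected perfectly, big missed entirely
  preds <- list(bbox(0, 0, 10, 10, class_id = "small", confidence = 0.9),
                bbox(60, 60, 70, 70, class_id = "big", confidence = 0.8))
  expect_equal(mean_ap(preds, gts, 0.5), 0.5)
  perfect <- lapply(gts, function(b)
    bbox(b$x1, b$y1, b$x2, b$y2, class_id = b$class_id, confidence = 0.9))
  expect_equal(mean_ap(perfect, gts, 0.5), 1.0)
  expect_equal(mean_ap(perfect, gts, seq(0.5, 0.95, 0.05)), 1.0)
  # monotone in the threshold set on random instances
  set.seed(34)
  for (i in 1:20) {
    inst <- random_instance()
    m50 <- mean_ap(inst$preds, inst$gts, 0.5)
    m5095 <- mean_ap(inst$preds, inst$gts, seq(0.5, 0.95, 0.05))
    expect_gte(m50 + 1e-12, m5095)
    ths <- seq(0.3, 0.9, 0.15)
    vals <- vapply(ths, function(t) mean_ap(inst$preds, inst$gts, t),
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
  expect_warning(mean_ap(preds, gts[1], 0.5, classes = c("small", "big")),
                 "no ground truth")
})

test_that("MAPE and RMSE match direct arithmetic", {
  expect_equal(regression_errors(c(100, 200), c(110, 180)),
               c(mape = 10, rmse = sqrt((100 + 400) / 2)))
  y <- c(3, 7, 2)
  expect_equal(regression_errors(y, y), c(mape = 0, rmse = 0))
  expect_equal(regression_errors(c(1, 1), c(3, 4))[["rmse"]], sqrt(6.5))
  expect_warning(r <- regression_errors(c(0, 2), c(1, 2)), "zero-valued")
  expect_equal(r[["mape"]], 0)
  expect_error(regression_errors(numeric(0), numeric(0)), "empty")
})

test_that("region overlap scores follow mask arithmetic and the Dice-IoU identity", {
  a <- list(bbox(0, 0, 2, 2))
  expect_equal(overlap_scores(a, a, c(10, 10)), c(dice = 1, iou = 1))
  got <- overlap_scores(list(bbox(0, 0, 2, 2)), list(bbox(1, 1, 3, 3)),
                        c(10, 10))
  expect_equal(got, c(dice = 0.25, iou = 1 / 7))
  expect_equal(overlap_scores(list(bbox(0, 0, 2, 2)), list(bbox(5, 5, 8, 8)),
                              c(10, 10)), c(dice = 0, iou = 0))
  # Dice = 2 IoU / (1 + IoU) on random mask pairs
  set.seed(35)
  for (i in 1:30) {
    p <- lapply(1:3, function(j) random_box(40, 40))
    g <- lapply(1:3, function(j) random_box(40, 40))
    sc <- overlap_scores(p, g, c(40, 40))
    expect_equal(sc[["dice"]], 2 * sc[["iou"]] / (1 + sc[["iou"]]),
                 tolerance = 1e-12)
    expect_gte(sc[["dice"]], sc[["iou"]])
  }
})

test_that("eval report aggregates per-class metrics and serializes", {
  gts <- list(list(bbox(0, 0, 10, 10, class_id = "small"),
                   bbox(30, 30, 50, 50, class_id = "big")),
              list(bbox(5, 5, 15, 15, class_id = "small")))
  preds <- lapply(gts, function(g) lapply(g, function(b)
    bbox(b$x1, b$y1, b$x2, b$y2, class_id = b$class_id, confidence = 0.9)))
  rep <- eval_report(preds, gts, c(64, 64))
  expect_equal(rep$map50, 1.0)
  expect_equal(rep$map5095, 1.0)
  expect_equal(rep$dice, 1.0)
  expect_equal(rep$count_mape, 0)
  expect_equal(rep$count_rmse, 0)
  expect_setequal(names(rep$per_class), c("small", "big"))
  txt <- capture.output(print(rep))
  expect_true(any(grepl("mAP@.5", txt)))
  js <- jsonlite::fromJSON(eval_report_json(rep))
  expect_equal(js$map50, 1.0)
})
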
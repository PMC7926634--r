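box <- function(x0, y0, x1, y1, label = "chest", conf = NA_real_)
  bounding_box(label, x0, y0, x1, y1, confidence = conf)

test_that("iou: closed form, symmetry and rasterization oracle", {
  a <- box(0, 0, 10, 10); b <- box(5, 5, 15, 15)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box(20, 20, 30, 30)), 0)
  expect_equal(iou(a, b), 25 / 175)
  expect_equal(iou(a, b), iou(b, a))

  set.seed(99)
  for (i in 1:25) {
    u <- random_box(); v <- random_box()
    expect_lt(abs(iou(u, v) - oracle_iou_raster(u, v)), 1e-3)
  }
})

test_that("greedy matching at threshold 0.5", {
  t1 <- box(0, 0, 10, 10)
  # IoU 0.8 prediction: overlap area/(union) -> shrink one edge slightly
  p_hi <- box(0, 0, 10, 8 / 0.9, conf = 0.9)   # iou > 0.5 for sure
  m <- match_detections(p_hi, t1)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))

  p_lo <- box(6, 6, 16, 16, conf = 0.9)        # iou 16/184 < 0.5
  m <- match_detections(p_lo, t1)
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 1L, 1L))

  # two predictions on one truth: the higher-confidence one claims it
  p1 <- box(0, 0, 10, 12, conf = 0.9)          # iou 100/120
  p2 <- box(0, 0, 10, 11, conf = 0.8)          # iou 100/110 (higher IoU!)
  m <- match_detections(rbind(p1, p2), t1)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 1L, 0L))
  # and the matched IoU is that of the higher-confidence prediction
  expect_equal(m$per_class$mean_iou, 100 / 120)

  # TP + FN equals the number of truths, per class
  set.seed(7)
  truths <- do.call(rbind, lapply(1:6, function(i)
    box(i * 5, i * 4, i * 5 + 6, i * 4 + 5,
        label = sample(BOX_LABELS, 1))))
  preds <- do.call(rbind, lapply(1:8, function(i)
    box(runif(1, 0, 40), runif(1, 0, 30), runif(1, 41, 50), runif(1, 31, 40),
        label = sample(BOX_LABELS, 1), conf = runif(1))))
  m <- match_detections(preds, truths)
  agg <- merge(m$per_class,
               as.data.frame(table(label = truths$label),
                             stringsAsFactors = FALSE),
               by = "label", all.x = TRUE)
  agg$Freq[is.na(agg$Freq)] <- 0L
  expect_true(all(agg$tp + agg$fn == agg$Freq))
})

test_that("average precision matches PR-point enumeration", {
  t2 <- rbind(box(0, 0, 10, 10), box(100, 100, 110, 110))
  preds <- rbind(box(0, 0, 10, 10.5, conf = 0.9),       # TP
                 box(50, 50, 60, 60, conf = 0.8),       # FP
                 box(100, 100, 110, 111, conf = 0.7))   # TP
  ap <- average_precision(preds, t2, "chest")
  expect_equal(ap, oracle_ap(c(TRUE, FALSE, TRUE), 2))
  expect_equal(ap, 0.5 * 1 + 0.5 * (2 / 3))

  # single correct detection / all-FP boundary cases
  expect_equal(average_precision(box(0, 0, 10, 10, conf = 0.9), t2[1, ],
                                 "chest"), 1)
  expect_equal(average_precision(box(50, 50, 60, 60, conf = 0.9), t2[1, ],
                                 "chest"), 0)
  # no ground truth of the class -> NA, excluded from mAP
  expect_true(is.na(average_precision(preds, t2, "head")))

  # removing an FP cannot decrease AP
  ap_with <- average_precision(preds, t2, "chest")
  ap_without <- average_precision(preds[-2, ], t2, "chest")
  expect_gte(ap_without, ap_with)
})

test_that("f1 score and degenerate cases", {
  expect_equal(f1_score(list(tp = 10, fp = 0, fn = 0)), 1)
  expect_equal(f1_score(list(tp = 0, fp = 3, fn = 2)), 0)
  expect_equal(f1_score(list(tp = 8, fp = 2, fn = 4)), 8 / 11)
  expect_true(is.na(f1_score(list(tp = 0, fp = 0, fn = 0))))
})

test_that("detection coverage counts frames with the class", {
  sc <- tiny_scene(seed = 2, duration = 5)   # 20 frames, all classes present
  expect_equal(detection_coverage(sc$truth$boxes, "chest"), 100)
  expect_equal(detection_coverage(roi_track(list(), 10), "chest"), 0)
  # drop chest in 3 of 20 frames
  tr <- sc$truth$boxes
  for (i in c(2, 5, 9))
    tr[[i]] <- tr[[i]][tr[[i]]$label != "chest", ]
  expect_equal(detection_coverage(tr, "chest"), 100 * 17 / 20)
  expect_equal(detection_coverage(tr, "head"), 100)
})

test_that("perfect fixture gives mAP 1 and F1 1; garbage gives 0", {
  sc <- tiny_scene(seed = 4, duration = 5)
  perfect <- generate_detection_fixture(sc$truth$boxes, jitter_px = 0,
                                        drop_rate = 0, seed = 1)
  m <- detection_metrics(perfect, sc$truth$boxes)
  expect_equal(m$map, 1)
  expect_equal(m$f1, 1)
  expect_true(all(abs(m$per_class$mean_iou - 1) < 1e-12))

  wild <- generate_detection_fixture(sc$truth$boxes, jitter_px = 60, seed = 2)
  m2 <- detection_metrics(wild, sc$truth$boxes)
  expect_lt(m2$map, 0.3)
})
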
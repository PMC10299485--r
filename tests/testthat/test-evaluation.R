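test_that("IoU follows the area-of-overlap over area-of-union definition", {
  a <- tibble::tibble(x = 0, y = 0, w = 2, h = 2)
  expect_equal(bbox_iou(a, a), 1)
  expect_equal(bbox_iou(a, tibble::tibble(x = 5, y = 5, w = 2, h = 2)), 0)
  b <- tibble::tibble(x = 1, y = 1, w = 2, h = 2)
  expect_equal(bbox_iou(a, b), 1 / 7) # intersection 1, union 7
  expect_equal(bbox_iou(a, b), bbox_iou(b, a)) # symmetric
  z <- tibble::tibble(x = 0, y = 0, w = 0, h = 0)
  expect_equal(bbox_iou(z, z), 0) # degenerate boxes
  expect_equal(bbox_iou(z, a), 0)
})

test_that("greedy matching is confidence-ordered, one-to-one, and argmax over IoU", {
  truths <- tibble::tibble(x = c(0, 100), y = 0, w = 10, h = 10,
    class = c("SD", "OT"))
  perfect <- dplyr::mutate(truths, confidence = 1)
  m <- match_detections(perfect, truths)
  expect_equal(nrow(m$pairs), 2L)
  expect_length(m$unmatched_pred, 0L)
  expect_length(m$unmatched_truth, 0L)

  # one prediction overlapping two truths at IoU 0.9 and 0.75 takes the 0.9
  t2 <- tibble::tibble(x = 0, y = c(0, 2.5), w = 10, h = c(9, 7.5),
    class = "SD")
  p <- tibble::tibble(x = 0, y = 0, w = 10, h = 10, class = "SD",
    confidence = .9)
  iou_each <- c(bbox_iou(p, t2[1, ]), bbox_iou(p, t2[2, ]))
  expect_true(iou_each[1] > iou_each[2] && all(iou_each > 0.5))
  m2 <- match_detections(p, t2)
  expect_equal(m2$pairs$truth, 1L)
})

test_that("greedy matching agrees with a brute-force replay of the protocol", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      truths <- random_boxes(25, extent = 300, wmax = 40)
      truths$class <- sample(trap_classes(), 25, replace = TRUE)
      preds <- random_boxes(50, extent = 300, wmax = 40)
      preds$class <- sample(trap_classes(), 50, replace = TRUE)
      preds$confidence <- runif(50)
      got <- match_detections(preds, truths, 0.3)
      # literal replay: walk predictions by confidence, scan truths
      taken <- logical(nrow(truths))
      pairs <- list()
      for (pi in order(-preds$confidence)) {
        best <- 0; best_iou <- 0
        for (ti in seq_len(nrow(truths))) {
          if (taken[ti]) next
          v <- bbox_iou(preds[pi, ], truths[ti, ])
          if (v >= 0.3 && v > best_iou) { best <- ti; best_iou <- v }
        }
        if (best > 0) {
          taken[best] <- TRUE
          pairs[[length(pairs) + 1]] <- c(pi, best)
        }
      }
      want <- do.call(rbind, pairs)
      expect_equal(nrow(got$pairs), NROW(want))
      if (NROW(want)) {
        expect_setequal(paste(got$pairs$pred, got$pairs$truth),
          paste(want[, 1], want[, 2]))
      }
    }
  })
})

test_that("precision and recall reproduce the published per-class arithmetic", {
  expect_equal(recall_score(2103, 141), 0.93717, tolerance = 1e-5) # 93.7%
  expect_equal(recall_score(2179, 65), 0.97103, tolerance = 1e-5) # 97.1%
  expect_equal(precision_score(0, 0), 0) # empty-denominator convention
  expect_equal(recall_score(0, 0), 0)
  expect_equal(precision_score(8, 2), 0.8)
})

test_that("average precision integrates the interpolated precision envelope", {
  truths <- tibble::tibble(x = c(0, 100), y = 0, w = 10, h = 10, class = "SD")
  perfect <- dplyr::mutate(truths, confidence = c(.9, .8))
  expect_equal(average_precision(perfect, truths, "SD"), 1)

  wrong <- tibble::tibble(x = 500, y = 500, w = 10, h = 10, class = "SD",
    confidence = .9)
  expect_equal(average_precision(wrong, truths, "SD"), 0)

  # hand-worked: conf .9 TP, .8 FP, .7 TP over 2 truths -> AP = 5/6
  preds <- tibble::tibble(
    x = c(0, 500, 100), y = c(0, 500, 0), w = 10, h = 10,
    class = "SD", confidence = c(.9, .8, .7)
  )
  expect_equal(average_precision(preds, truths, "SD"), 5 / 6)

  # invariance under monotone confidence rescaling
  resc <- dplyr::mutate(preds, confidence = confidence^3 / 2)
  expect_equal(average_precision(resc, truths, "SD"), 5 / 6)

  # undefined AP (no OT ground truth) is distinct from 0
  expect_true(is.na(average_precision(preds, truths, "OT")))
})

test_that("mAP is the arithmetic mean of defined per-class APs", {
  expect_equal(mean_ap(c(0.907, 0.913)), 0.910)
  expect_equal(mean_ap(c(0.875, 0.882)), 0.8785) # rounds to 87.9%
  expect_equal(mean_ap(0.42), 0.42)
  expect_equal(mean_ap(c(0.8, NA)), 0.8)
  expect_error(mean_ap(c(NA_real_, NA_real_)), class = "trapscan_no_ap")
})

test_that("confusion compilation tallies matched pairs by both class labels", {
  truths <- tibble::tibble(x = c(0, 100, 200), y = 0, w = 10, h = 10,
    class = "SD")
  preds <- dplyr::mutate(truths, class = c("SD", "SD", "OT"), confidence = 1)
  cm <- compile_confusion(match_detections(preds, truths))
  expect_equal(unname(cm), rbind(c(2L, 1L), c(0L, 0L)), ignore_attr = TRUE)
  expect_equal(attr(cm, "unmatched_pred"), 0L)
  # row sums count localised ground truths per actual class
  expect_equal(unname(rowSums(cm)), c(3, 0))
})

test_that("published confusion tables yield their printed recall percentages", {
  rec <- confusion_recall(validation_confusion())
  pick <- function(ds, mod, act) {
    rec$recall_pct[rec$dataset == ds & rec$model == mod & rec$actual == act]
  }
  expect_equal(round(pick("transmittance", "yolov5", "SD"), 1), 97.1)
  expect_equal(round(pick("reflectance", "yolov5", "SD"), 1), 90.7)
  expect_equal(round(pick("reflectance", "efficientdet_d0", "SD"), 1), 87.5)
  expect_equal(round(pick("reflectance", "efficientdet_d0", "OT"), 1), 88.2)
  # row sums are constant across models within a dataset
  sums <- rec %>% dplyr::group_by(dataset, actual) %>%
    dplyr::summarise(n = dplyr::n_distinct(n_actual), .groups = "drop")
  expect_true(all(sums$n == 1))
})

test_that("a known class-flip rate shows up in the confusion off-diagonal", {
  # 10,000+ aligned boxes, flip probability 0.2, no misses or jitter:
  # matched pairs disagree in class exactly when flipped
  n <- 10000
  block <- 100 # match tile by tile, as tiled evaluation does
  cm <- matrix(0L, 2, 2, dimnames = list(trap_classes(), trap_classes()))
  withr::with_seed(57, {
    for (b in seq_len(n / block)) {
      truths <- tibble::tibble(
        x = (seq_len(block) - 1) %% 10 * 20, y = (seq_len(block) - 1) %/% 10 * 20,
        w = 10, h = 10, class = sample(trap_classes(), block, replace = TRUE)
      )
      flip <- runif(block) < 0.2
      preds <- dplyr::mutate(truths,
        class = ifelse(flip, ifelse(class == "SD", "OT", "SD"), class),
        confidence = 1)
      cm <- cm + compile_confusion(match_detections(preds, truths))
    }
  })
  off <- (cm["SD", "OT"] + cm["OT", "SD"]) / sum(cm)
  expect_lt(abs(off - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("recall declines monotonically with the detector miss rate", {
  truth <- tibble::tibble(
    trap_id = "t", col = 0L, row = 0L,
    tile_i = rep(0:6, length.out = 10000) %% 7L,
    tile_j = rep(0:6, each = 7, length.out = 10000) %% 7L,
    class_id = 0L,
    cx = rep((1:10 - .5) / 10, length.out = 10000),
    cy = rep((1:25 - .5) / 25, each = 10, length.out = 10000),
    w = .04, h = .02
  )
  recalls <- vapply(c(0, .1, .3, .5), function(pm) {
    det <- stub_detect(truth, noise_spec(p_miss = pm, seed = 77))
    nrow(det) / nrow(truth) # no FPs/jitter: survivors are the recall
  }, double(1))
  expect_true(all(diff(recalls) < 0))
  expect_equal(recalls[1], 1)
})

test_that("evaluate_detections summarises AP, confusion and operating point tidily", {
  truths <- tibble::tibble(x = c(0, 100, 200), y = 0, w = 10, h = 10,
    class = c("SD", "SD", "OT"))
  preds <- dplyr::bind_rows(
    dplyr::mutate(truths, confidence = c(.95, .9, .85)),
    tibble::tibble(x = 500, y = 0, w = 10, h = 10, class = "SD",
      confidence = .1) # low-confidence FP
  )
  ev <- evaluate_detections(preds, truths, conf_thresh = 0.25)
  expect_equal(ev$map, 1) # FP arrives after full recall; envelope unaffected
  expect_equal(unname(ev$ap), c(1, 1))
  td <- tidy(ev)
  expect_equal(td$recall, c(1, 1))
  expect_equal(td$tp, c(2, 1))
  gl <- glance(ev)
  expect_equal(gl$n_pred, 4L)
  expect_s3_class(autoplot(ev), "ggplot")
})
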
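test_that("matching is one-to-one, greedy by score, at the IOU threshold", {
  gts <- data.frame(frame = 0L, class_name = "fish", track_id = 1L,
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  one <- detection_records(0L, 3L, 0.8, 0, 0, 10, 13)  # IOU ~ 0.77
  expect_true(match_detections_to_gt(one, gts)$is_tp)

  two <- detection_records(c(0L, 0L), c(3L, 3L), c(0.9, 0.7),
                           c(0, 1), c(0, 1), c(10, 11), c(10, 11))
  lab <- match_detections_to_gt(two, gts)
  expect_equal(lab$is_tp, c(TRUE, FALSE))
})

test_that("matching equals an independent per-scene oracle", {
  oracle_match <- function(dets, gts, thr) {
    tp <- rep(FALSE, nrow(dets))
    used <- rep(FALSE, nrow(gts))
    for (d in order(-dets$score)) {
      best <- 0
      bj <- 0L
      for (j in seq_len(nrow(gts))) {
        if (used[j]) next
        if (gts$frame[j] != dets$frame[d] ||
            gts$class_id[j] != dets$class_id[d]) next
        i <- box_iou(c(dets$x1[d], dets$y1[d], dets$x2[d], dets$y2[d]),
                     c(gts$x1[j], gts$y1[j], gts$x2[j], gts$y2[j]))
        if (i > best) {
          best <- i
          bj <- j
        }
      }
      if (bj > 0L && best >= thr) {
        tp[d] <- TRUE
        used[bj] <- TRUE
      }
    }
    tp
  }
  set.seed(404)
  for (rep in 1:10) {
    ng <- sample(2:5, 1L)
    gx <- runif(ng, 0, 80)
    gy <- runif(ng, 0, 80)
    gts <- data.frame(frame = sample(0:1, ng, TRUE),
                      class_id = sample(0:1, ng, TRUE),
                      x1 = gx, y1 = gy, x2 = gx + runif(ng, 10, 30),
                      y2 = gy + runif(ng, 10, 30))
    nd <- sample(3:7, 1L)
    pick <- sample(ng, nd, TRUE)
    dets <- detection_records(
      frame = gts$frame[pick], class_id = sample(0:1, nd, TRUE),
      score = runif(nd),
      x1 = pmax(gts$x1[pick] + rnorm(nd, 0, 4), 0),
      y1 = pmax(gts$y1[pick] + rnorm(nd, 0, 4), 0),
      x2 = gts$x2[pick] + rnorm(nd, 0, 4),
      y2 = gts$y2[pick] + rnorm(nd, 0, 4))
    dets$x2 <- pmax(dets$x2, dets$x1 + 1)
    dets$y2 <- pmax(dets$y2, dets$y1 + 1)
    got <- match_detections_to_gt(dets, gts)$is_tp
    expect_equal(got, oracle_match(dets, gts, 0.5))
  }
})

test_that("average precision integrates the monotone step curve", {
  # 2 gts; one TP at 0.9, one FP at 0.8: P/R (1.0, 0.5) then (0.5, 0.5)
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, FALSE), 2L), 0.5)
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2L), 1)
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, FALSE), 2L), 0)
  expect_true(is.na(average_precision(numeric(), logical(), 0L)))
  expect_equal(average_precision(c(0.5), c(FALSE), 0L), 0)
  # 11-point variant for the same toy
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, FALSE), 2L,
                                 interpolation = "11point"), 6 / 11)
})

test_that("monotone AP properties hold when adding detections", {
  set.seed(31)
  sc <- runif(8, 0.3, 1)
  tp <- runif(8) > 0.4
  base <- average_precision(sc, tp, 6L)
  # a zero-score FP appended at the end of the ranking cannot increase AP
  expect_lte(average_precision(c(sc, 1e-9), c(tp, FALSE), 6L), base + 1e-12)
  # a TP for a previously unmatched gt cannot decrease AP
  expect_gte(average_precision(c(sc, 0.99), c(tp, TRUE), 6L), base - 1e-12)
})

test_that("mAP averages defined classes and composes from per-class APs", {
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(c(0.7, NA)), 0.7)
  expect_error(mean_ap(c(NA_real_, NA_real_)), "defined")

  sc <- std_scene()
  dets <- std_corrupted(sc)
  res <- evaluate_detections(dets, sc$annotations)
  aps <- vapply(which(res$per_class$n_gt > 0) - 1L, function(cl) {
    lab <- match_detections_to_gt(dets[dets$class_id == cl, ],
                                  sc$annotations)
    average_precision(lab$score, lab$is_tp,
                      sum(match(sc$annotations$class_name,
                                uwv_classes()) - 1L == cl))
  }, 0)
  expect_equal(res$map, mean(aps), tolerance = 1e-12)
})

test_that("noiseless oracle detections evaluate to perfect mAP", {
  sc <- std_scene()
  clean <- corrupt_detections(sc$annotations,
                              noise_config(box_sigma = 0, score_sd = 0,
                                           p_dip = 0, p_miss = 0,
                                           fp_rate = 0),
                              image_size = c(128, 128), seed = 1L)
  expect_equal(evaluate_detections(clean, sc$annotations)$map, 1)
  # and the optimizer leaves perfect detections perfect
  opt <- optimize_detections(clean, image_size = c(128, 128))
  expect_equal(evaluate_detections(opt, sc$annotations)$map, 1)
})
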
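test_that("pair similarity rewards overlap and gates on confidence", {
  m <- similarity_model()
  sz <- c(128, 128)
  a <- list(score = 1, x1 = 10, y1 = 10, x2 = 30, y2 = 30)
  # identical geometry at full confidence: X(iou=1, d=0, logs=0)
  expect_equal(pair_similarity(a, a, m, sz),
               plogis(m$w_iou + m$bias), tolerance = 1e-12)
  a0 <- a
  a0$score <- 0
  expect_equal(pair_similarity(a0, a, m, sz), 0)
  # far-apart small boxes fall below any sensible link threshold
  b <- list(score = 1, x1 = 110, y1 = 110, x2 = 118, y2 = 118)
  expect_lt(pair_similarity(a, b, m, sz), 0.3)
  # degenerate box
  z <- list(score = 1, x1 = 5, y1 = 5, x2 = 5, y2 = 9)
  expect_equal(pair_similarity(z, a, m, sz), 0)
})

test_that("greedy matching follows the zero-out procedure", {
  expect_equal(greedy_match(matrix(c(0.9, 0.8, 0.4, 0.7), 2L, 2L), 0),
               cbind(row = c(1L, 2L), col = c(1L, 2L)))
  # greedy is not the optimal assignment
  m <- matrix(c(0.9, 0.86, 0.85, 0.1), 2L, 2L)
  got <- greedy_match(m, 0)
  expect_equal(got, cbind(row = c(1L, 2L), col = c(1L, 2L)))
  expect_lt(m[1, 1] + m[2, 2], m[1, 2] + m[2, 1])
  # below-threshold matrix gives no pairs
  expect_equal(nrow(greedy_match(matrix(0.1, 3L, 3L), 0.5)), 0L)
  # ties break toward the lowest (row, col)
  expect_equal(greedy_match(matrix(0.7, 2L, 2L), 0)[1L, ],
               c(row = 1L, col = 1L))
})

test_that("greedy matching equals a step-by-step simulation oracle", {
  oracle <- function(m, tau) {
    pairs <- matrix(integer(), 0L, 2L)
    repeat {
      best <- -Inf
      bi <- 0L
      bj <- 0L
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(ncol(m))) {
          if (m[i, j] > best) {
            best <- m[i, j]
            bi <- i
            bj <- j
          }
        }
      }
      if (best < tau) break
      pairs <- rbind(pairs, c(bi, bj))
      m[bi, ] <- -Inf
      m[, bj] <- -Inf
    }
    pairs
  }
  set.seed(606)
  for (rep in 1:50) {
    m <- matrix(runif(36), 6L, 6L)
    got <- greedy_match(m, 0.25)
    exp <- oracle(m, 0.25)
    expect_equal(unname(got), unname(exp))
  }
})

test_that("tubelet linking partitions detections into contiguous chains", {
  sc <- std_scene()
  dets <- std_corrupted(sc)
  tubes <- link_tubelets(dets, image_size = c(128, 128))
  idx <- sort(unlist(lapply(tubes, `[[`, "det_idx")))
  expect_equal(idx, seq_len(nrow(dets)))  # partition: each det exactly once
  for (tb in tubes) {
    expect_true(all(diff(tb$frames) == 1L))            # contiguity
    expect_equal(length(unique(dets$class_id[tb$det_idx])), 1L)  # purity
  }
  # the well-separated objects yield a few long chains, not per-frame
  # fragments (consecutive confidence dips may split a track where the
  # similarity product falls under the link threshold)
  long <- Filter(function(tb) length(tb$frames) >= 10L, tubes)
  expect_gte(length(long), 2L)
  expect_lte(length(tubes), 10L)
})

test_that("single-object clean track links into one tubelet", {
  n <- 5L
  dets <- detection_records(frame = 0:4, class_id = rep(2L, n),
                            score = rep(0.9, n),
                            x1 = 10 + (0:4), y1 = 20 + (0:4),
                            x2 = 30 + (0:4), y2 = 40 + (0:4))
  tubes <- link_tubelets(dets, image_size = c(64, 64))
  expect_length(tubes, 1L)
  expect_equal(tubes[[1L]]$frames, 0:4)

  # two crossing objects of different classes never merge
  dets2 <- rbind(dets, transform(dets, class_id = 4L))
  tubes2 <- link_tubelets(detection_records(dets2$frame, dets2$class_id,
                                            dets2$score, dets2$x1, dets2$y1,
                                            dets2$x2, dets2$y2),
                          image_size = c(64, 64))
  expect_length(tubes2, 2L)

  # a missing frame splits the chain; gaps are not bridged
  dets3 <- dets[dets$frame != 2L, ]
  tubes3 <- link_tubelets(dets3, image_size = c(64, 64))
  expect_length(tubes3, 2L)
  expect_equal(sort(vapply(tubes3, function(tb) length(tb$frames), 0L)),
               c(2L, 2L))
})

test_that("re-scoring averages and conserves the tubelet score mean", {
  tb <- list(class_id = 0L, det_idx = 1:3, frames = 0:2,
             scores = c(0.9, 0.5, 0.7),
             boxes = matrix(1:12, 3L, 4L))
  out <- rescore_tubelet(tb)
  expect_equal(out$scores, rep(0.7, 3L))
  expect_equal(mean(out$scores), mean(tb$scores))
  expect_equal(out$boxes, tb$boxes)
  one <- list(class_id = 0L, det_idx = 1L, frames = 0L, scores = 0.4,
              boxes = matrix(1:4, 1L))
  expect_equal(rescore_tubelet(one)$scores, 0.4)
})

test_that("re-coordinating matches a direct-summation Gaussian oracle", {
  gp <- gaussian_params(sigma = 1, radius = 3L)
  one <- list(class_id = 0L, det_idx = 1L, frames = 0L, scores = 0.4,
              boxes = matrix(c(3, 4, 5, 6), 1L))
  expect_equal(recoordinate_tubelet(one, gp)$boxes, one$boxes)

  const <- list(class_id = 0L, det_idx = 1:5, frames = 0:4,
                scores = rep(0.5, 5L),
                boxes = matrix(rep(c(2, 3, 12, 13), each = 5L), 5L, 4L))
  expect_equal(recoordinate_tubelet(const, gp)$boxes, const$boxes,
               tolerance = 1e-12)

  imp <- const
  imp$boxes[, 1L] <- c(0, 0, 10, 0, 0)
  out <- recoordinate_tubelet(imp, gp)
  # direct summation of the renormalized truncated Gaussian
  g <- exp(-((-3):3)^2 / 2)
  oracle <- vapply(1:5, function(i) {
    j <- max(1L, i - 3L):min(5L, i + 3L)
    w <- g[j - i + 4L]
    sum(imp$boxes[j, 1L] * w / sum(w))
  }, 0)
  expect_equal(out$boxes[, 1L], oracle, tolerance = 1e-12)
  expect_lt(out$boxes[3L, 1L], 10)
  expect_gt(out$boxes[2L, 1L], 0)
  expect_equal(out$scores, imp$scores)
  expect_error(gaussian_params(sigma = 0), "sigma")
})

test_that("optimization smooths tracks without changing counts or classes", {
  sc <- std_scene()
  dets <- std_corrupted(sc)
  opt <- optimize_detections(dets, image_size = c(128, 128))
  expect_equal(nrow(opt), nrow(dets))
  expect_equal(table(opt$class_id), table(dets$class_id))
  expect_equal(table(opt$frame), table(dets$frame))

  before <- center_jitter_stat(dets, sc$annotations, c(128, 128))
  after <- center_jitter_stat(opt, sc$annotations, c(128, 128))
  expect_lt(after, before)

  # after re-scoring, scores within every tubelet are constant (track rows
  # through the per-frame reordering with an id column, which is preserved)
  dets$.id <- seq_len(nrow(dets))
  opt2 <- optimize_detections(dets, image_size = c(128, 128))
  tubes <- link_tubelets(dets, image_size = c(128, 128))
  for (tb in tubes) {
    s <- opt2$score[match(dets$.id[tb$det_idx], opt2$.id)]
    expect_lt(max(s) - min(s), 1e-12)
  }

  expect_equal(nrow(optimize_detections(detection_records(),
                                        image_size = c(128, 128))), 0L)
})
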
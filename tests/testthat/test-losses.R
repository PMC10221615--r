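test_that("binary cross-entropy has its closed-form values and symmetry", {
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_lt(bce_loss(0, 0), 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  set.seed(4)
  p <- runif(50)
  y <- runif(50)
  expect_equal(bce_loss(p, y), bce_loss(1 - p, 1 - y), tolerance = 1e-12)
})

test_that("IOU and the squared-IOU loss match area arithmetic", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15)), 25 / 175,
               tolerance = 1e-12)
  expect_equal(iou_squared_loss(c(0, 0, 10, 10), c(0, 0, 10, 10)), 0)
  expect_equal(iou_squared_loss(c(0, 0, 10, 10), c(20, 20, 30, 30)), 1)
  expect_equal(iou_squared_loss(c(0, 0, 10, 10), c(5, 5, 15, 15)),
               1 - (25 / 175)^2, tolerance = 1e-12)
})

test_that("log-area IOU matches direct evaluation and exceeds plain IOU", {
  a <- c(0, 0, 10, 10)
  b <- c(5, 5, 15, 15)
  # step-by-step: intersection 5x5, sides padded by lambda=1
  num <- log((5 + 1) * (5 + 1))
  den <- 2 * log((10 + 1) * (10 + 1)) - num
  expect_equal(iou_log(a, b), num / den, tolerance = 1e-12)
  expect_gt(iou_log(a, b), box_iou(a, b))
  expect_equal(iou_log(a, a), 1)
  expect_equal(iou_log(c(0, 0, 2, 2), c(10, 10, 12, 12)), 0)
  expect_error(iou_log(a, b, lambda = 0), "lambda")
})

test_that("log-area IOU is base-invariant and bounded on random pairs", {
  set.seed(99)
  n <- 10000L
  x1 <- runif(n, 0, 100)
  y1 <- runif(n, 0, 100)
  a <- cbind(x1, y1, x1 + runif(n, 0, 60), y1 + runif(n, 0, 60))
  u1 <- runif(n, 0, 100)
  v1 <- runif(n, 0, 100)
  b <- cbind(u1, v1, u1 + runif(n, 0, 60), v1 + runif(n, 0, 60))
  nat <- iou_log(a, b)
  expect_true(all(nat >= 0 & nat <= 1))
  expect_lt(max(abs(nat - iou_log(a, b, base = 10))), 1e-12)
})

test_that("CIOUlog combines overlap, position and shape as specified", {
  a <- c(0, 0, 10, 10)
  expect_equal(ciou_log(a, a), 1)
  # same center, same aspect ratio, different scale: only overlap term left
  b <- c(-5, -5, 15, 15)
  expect_equal(ciou_log(a, b), iou_log(a, b), tolerance = 1e-8)
  # independent step-by-step evaluation for a shape mismatch
  p <- c(0, 0, 10, 10)
  g <- c(0, 0, 10, 20)
  il <- iou_log(p, g)
  rho2 <- (5 - 5)^2 + (5 - 10)^2
  c2 <- 10^2 + 20^2
  v <- 4 / pi^2 * (atan(10 / 10) - atan(10 / 20))^2
  alpha <- v / (1 - il + v)
  expect_equal(ciou_log(p, g), il - rho2 / c2 - alpha * v,
               tolerance = 1e-8)
  expect_equal(ciou_log(p, g, shape_sign = 1), il - rho2 / c2 + alpha * v,
               tolerance = 1e-8)
})

test_that("regression loss is zero at identity and monotone in translation", {
  a <- c(10, 10, 30, 30)
  expect_equal(regression_loss(a, a, mode = "ciou_log"), 0, tolerance = 1e-9)
  expect_equal(regression_loss(a, a, mode = "iou_sq"), 0)
  shifts <- seq(0, 18, by = 2)  # keep some overlap: IOU plateaus at 0 beyond
  for (mode in c("ciou_log", "iou_sq")) {
    losses <- vapply(shifts, function(s) {
      regression_loss(a + c(s, 0, s, 0), a, mode = mode)
    }, 0)
    expect_true(all(diff(losses) > 0))
  }
  expect_equal(regression_loss(a, a + 5, mode = "iou_sq"),
               iou_squared_loss(a, a + 5))
  expect_error(regression_loss(a, a, mode = "giou"))
})

test_that("jitter loss evaluates second differences as specified", {
  # exact predictions
  y <- cbind(1:6, 2 * (1:6), 1:6 + 10, 2 * (1:6) + 8)
  expect_equal(jitter_loss(y, y), 0)
  # linear motion with a different constant velocity: accelerations vanish
  g <- cbind(1:6, 1:6, 1:6 + 4, 1:6 + 4)
  p <- sweep(cbind(3 * (1:6), 3 * (1:6), 3 * (1:6) + 4, 3 * (1:6) + 4),
             2, c(7, -2, 7, -2), `+`)
  expect_equal(jitter_loss(p, g), 0)
  # scalar toy, T = 4
  expect_equal(jitter_loss(c(0, 1, 3, 3), c(0, 1, 2, 3)), 1.5)
  # T < 3 contributes nothing
  expect_equal(jitter_loss(c(0, 5), c(0, 1)), 0)
  expect_error(jitter_loss(cbind(1:4), cbind(1:5)), "align")
})

test_that("jitter loss is translation-invariant and scales linearly", {
  set.seed(12)
  g <- matrix(cumsum(rnorm(40)), 10L, 4L)
  p <- g + matrix(rnorm(40, 0, 2), 10L, 4L)
  base <- jitter_loss(p, g)
  expect_gt(base, 0)
  expect_equal(jitter_loss(p + 17.3, g + 17.3), base, tolerance = 1e-9)
  expect_equal(jitter_loss(3 * p, 3 * g), 3 * base, tolerance = 1e-9)
})

test_that("the composite loss is the weighted sum of its terms", {
  a <- c(0, 0, 10, 10)
  perfect <- total_loss(cls_terms = list(p = c(1, 0), y = c(1, 0)),
                        reg_pairs = list(pred = rbind(a), gt = rbind(a)),
                        conf_terms = list(p = 1, y = 1),
                        track_batch = list(pred = cbind(1:4), gt = cbind(1:4)))
  expect_lt(perfect$total, 1e-5)

  set.seed(55)
  cls <- list(p = runif(6), y = rep(c(0, 1), 3))
  x1 <- runif(4, 0, 20)
  pred <- cbind(x1, x1, x1 + 10, x1 + 12)
  gt <- pred + matrix(rnorm(16), 4L, 4L)
  gt[, 3:4] <- pmax(gt[, 3:4], gt[, 1:2] + 1)
  conf <- list(p = runif(5), y = c(1, 0, 0, 1, 0))
  tb <- list(pred = cbind(c(0, 1, 3, 3)), gt = cbind(c(0, 1, 2, 3)))
  w <- loss_weights(1, 5, 1, 0.05)
  res <- total_loss(cls, list(pred = pred, gt = gt), conf, tb, weights = w)
  by_hand <- 1 * mean(bce_loss(cls$p, cls$y)) +
    5 * mean(1 - ciou_log(pred, gt)) +
    1 * mean(bce_loss(conf$p, conf$y)) +
    0.05 * jitter_loss(tb$pred, tb$gt)
  expect_equal(res$total, by_hand, tolerance = 1e-10)
  expect_equal(res$jitter, 1.5)

  no_jit <- total_loss(cls, list(pred = pred, gt = gt), conf, tb,
                       weights = loss_weights(jitter = 0))
  expect_equal(no_jit$total,
               res$total - 0.05 * res$jitter, tolerance = 1e-10)
  expect_error(loss_weights(cls = -1), "nonnegative")
})
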
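ns <- asNamespace("uwvdetect")

test_that("parameter counts match independent layer-by-layer arithmetic", {
  # single 1x1 prediction conv 64 -> 5 with bias
  shp <- ns$spec_shapes(ns$spec_pred(64L, 5L), "p")
  expect_equal(sum(vapply(shp, prod, 0)), 64 * 5 + 5)

  # coordinate attention block, C = 64, r = 32 -> mid = max(8, 2) = 8:
  # shared conv 64*8+8, norm 2*8, two direction convs (8*64+64) each
  ca <- ns$spec_shapes(ns$spec_ca(64L, 32L, 8L), "ca")
  expect_equal(sum(vapply(ca, prod, 0)),
               (64 * 8 + 8) + 16 + 2 * (8 * 64 + 64))

  # CSP block with one residual unit at C = 64 (hidden 32):
  # three 1x1 convs + unit (1x1 conv + 3x3 conv), each conv with 2C norm
  csp <- ns$spec_shapes(ns$spec_csp(64L, 64L, 1L, TRUE), "c")
  hand <- (64 * 32 + 64) * 2 +        # conv1, conv2: 64->32 1x1 + bn
    (64 * 64 + 128) +                 # conv3: 64->64 1x1 + bn
    (32 * 32 + 64) + (32 * 32 * 9 + 64)  # unit convs + bn
  expect_equal(sum(vapply(csp, prod, 0)), hand)

  # CSP_CA1 = CSP + CA on the hidden width
  ca_opts <- list(reduction = 32L, mid_min = 8L)
  csp1 <- ns$spec_shapes(ns$spec_csp(64L, 64L, 1L, TRUE, "ca1", ca_opts), "c")
  ca32 <- ns$spec_shapes(ns$spec_ca(32L, 32L, 8L), "x")
  expect_equal(sum(vapply(csp1, prod, 0)),
               hand + sum(vapply(ca32, prod, 0)))

  # CSP_CA2 drops the residual units: fewer parameters than any CSP with
  # n >= 1 units at equal channels
  csp2 <- ns$spec_shapes(ns$spec_csp(128L, 128L, 3L, FALSE, "ca2", ca_opts), "c")
  base2 <- ns$spec_shapes(ns$spec_csp(128L, 128L, 3L, FALSE), "c")
  expect_lt(sum(vapply(csp2, prod, 0)), sum(vapply(base2, prod, 0)))
})

test_that("counts are pure functions of config and the CA switch works", {
  cfg_off <- detector_config(depth_mult = 0.33, width_mult = 0.125,
                             use_ca = FALSE, test_size = 64L)
  cfg_on <- detector_config(depth_mult = 0.33, width_mult = 0.125,
                            use_ca = TRUE, test_size = 64L)
  d_off <- build_detector(cfg_off)
  d_on <- build_detector(cfg_on)
  expect_identical(count_parameters(d_off),
                   count_parameters(build_detector(cfg_off)))
  # baseline has no CA parameters anywhere
  expect_false(any(grepl("\\.ca\\.", names(d_off$shapes))))
  expect_true(any(grepl("\\.ca\\.", names(d_on$shapes))))
  # backbone-only default placement: neck blocks stay plain
  expect_false(any(grepl("^neck.*\\.ca\\.", names(d_on$shapes))))
  both <- build_detector(detector_config(depth_mult = 0.33,
                                         width_mult = 0.125, use_ca = TRUE,
                                         ca_placement = "backbone_neck",
                                         test_size = 64L))
  expect_true(any(grepl("^neck.*\\.ca\\.", names(both$shapes))))
  expect_error(detector_config(num_classes = 0L), "num_classes")
  expect_error(detector_config(depth_mult = -1), "multipliers")
})

test_that("coordinate attention preserves shape and gates multiplicatively", {
  set.seed(3)
  sp <- ns$spec_ca(16L, 32L, 8L)
  shapes <- ns$spec_shapes(sp, "ca")
  P <- lapply(shapes, function(s) {
    if (length(s) == 2L) matrix(rnorm(prod(s), 0, 0.5), s[1L], s[2L])
    else rnorm(s)
  })
  P[["ca.bn_g"]] <- rep(1, 8)
  x <- array(abs(rnorm(16 * 8 * 12)), c(8L, 12L, 16L))
  y <- ns$fwd_spec(sp, x, P, "ca")
  expect_equal(dim(y), dim(x))
  # sigmoid gates lie in (0,1): magnitudes cannot grow on nonnegative input
  expect_true(all(y >= 0 & y <= x + 1e-12))
})

test_that("CSP blocks preserve spatial dimensions", {
  set.seed(4)
  for (variant in c("plain", "ca1", "ca2")) {
    sp <- ns$spec_csp(16L, 16L, 1L, variant != "ca2", variant,
                      list(reduction = 32L, mid_min = 4L))
    shapes <- ns$spec_shapes(sp, "b")
    P <- lapply(shapes, function(s) {
      if (length(s) == 2L) matrix(rnorm(prod(s), 0, 0.3), s[1L], s[2L])
      else rnorm(s)
    })
    x <- array(rnorm(16 * 16 * 16), c(16L, 16L, 16L))
    expect_equal(dim(ns$fwd_spec(sp, x, P, "b")), c(16L, 16L, 16L))
  }
})

test_that("the head emits one channel per class at every level", {
  det <- smoke_detector(use_ca = FALSE)
  x <- array(runif(64 * 64 * 3), c(64L, 64L, 3L))
  out <- ns$forward_detector(det, x)
  expect_length(out, 3L)
  expect_equal(vapply(out, function(o) dim(o$cls)[3L], 0L), rep(5L, 3L))
  expect_equal(vapply(out, function(o) dim(o$reg)[3L], 0L), rep(4L, 3L))
  expect_equal(lapply(out, function(o) dim(o$obj)[1:2]),
               list(c(8L, 8L), c(4L, 4L), c(2L, 2L)))
})

test_that("greedy NMS matches a brute-force oracle", {
  boxes <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(boxes, c(0.9, 0.8), 0.5), 1L)

  brute_nms <- function(boxes, scores, thr) {
    o <- order(-scores)
    kept <- integer()
    for (i in o) {
      ok <- TRUE
      for (j in kept) {
        if (box_iou(boxes[i, ], boxes[j, ]) > thr) ok <- FALSE
      }
      if (ok) kept <- c(kept, i)
    }
    kept
  }
  set.seed(17)
  for (rep in 1:20) {
    n <- 12L
    x1 <- runif(n, 0, 40)
    y1 <- runif(n, 0, 40)
    boxes <- cbind(x1, y1, x1 + runif(n, 5, 25), y1 + runif(n, 5, 25))
    sc <- runif(n)
    expect_identical(nms(boxes, sc, 0.5), brute_nms(boxes, sc, 0.5))
  }
})

test_that("suppressed objectness yields no detections", {
  det <- smoke_detector(use_ca = TRUE)
  for (nm in grep("obj_pred\\.b$", names(det$params), value = TRUE)) {
    det$params[[nm]][] <- -30
  }
  sc <- generate_scene(scene_config(width = 64L, height = 64L,
                                    n_frames = 3L), seed = 5L)
  out <- detect_frames(det, sc$clip, score_thr = 0.01)
  expect_equal(nrow(out), 0L)
})
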
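test_that("histogram equalization matches the hand-derived remap", {
  # 4 pixels [0,0,100,200]: cdf 0.5/0.75/1.0, cdf_min 0.5
  out <- histogram_equalize(matrix(c(0L, 0L, 100L, 200L), 2L, 2L))
  expect_equal(sort(unique(as.vector(out))), c(0L, 128L, 255L))
  expect_equal(as.vector(out), c(0, 0, 128, 255))

  expect_equal(histogram_equalize(matrix(77L, 5L, 5L)),
               matrix(77L, 5L, 5L))
  expect_error(histogram_equalize(integer(0)), "empty")
})

test_that("equalization moves the cumulative histogram toward linear", {
  cdf_dist <- function(ch) {
    cdf <- cumsum(tabulate(as.integer(ch) + 1L, 256L)) / length(ch)
    sqrt(mean((cdf - (1:256) / 256)^2))
  }
  set.seed(5)
  for (k in 1:5) {
    lo <- sample(0:120, 1L)
    ch <- matrix(as.integer(pmin(pmax(round(rnorm(32 * 32, lo + 40, 15)),
                                      lo), lo + 80)), 32L, 32L)
    expect_lte(cdf_dist(histogram_equalize(ch)), cdf_dist(ch) + 1e-12)
  }
})

test_that("clip-redistribution conserves mass and obeys the ceiling", {
  expect_equal(clip_redistribute(c(10, 0, 0, 2), 4, iters = 1L),
               c(5.5, 1.5, 1.5, 3.5))
  h <- c(1, 2, 3, 1)
  expect_equal(clip_redistribute(h, 4), h)
  set.seed(8)
  for (k in 1:20) {
    h <- rpois(256L, 5) * sample(1:4, 256L, TRUE)
    out <- clip_redistribute(h, 8, iters = 5L)
    expect_equal(sum(out), sum(h), tolerance = 1e-9)
    # residual overshoot after the capped passes is at most one spread unit
    expect_lte(max(out), 8 + sum(pmax(h - 8, 0)) / 256)
  }
  expect_error(clip_redistribute(c(1, 2), 0), "ceiling")
  expect_error(clip_redistribute(c(-1, 2), 4), "nonnegative")
})

test_that("degenerate CLAHE (one tile, no clipping) is plain equalization", {
  set.seed(13)
  ch <- matrix(as.integer(sample(40:200, 48 * 40, TRUE)), 48L, 40L)
  out <- clahe_channel(ch, clahe_params(tile_grid = c(1L, 1L),
                                        clip_limit = Inf))
  expect_identical(out, histogram_equalize(ch))
})

test_that("CLAHE keeps constant images fixed and expands low contrast", {
  const <- matrix(77L, 32L, 32L)
  expect_identical(clahe_channel(const, clahe_params()), const)

  set.seed(21)
  lowc <- matrix(as.integer(sample(100:130, 64 * 64, TRUE)), 64L, 64L)
  out <- clahe_channel(lowc, clahe_params())
  expect_gt(diff(range(out)), diff(range(lowc)))
  expect_error(clahe_channel(matrix(0L, 4L, 4L),
                             clahe_params(tile_grid = c(8L, 8L))),
               "tile grid")
})

test_that("video enhancement is per-channel, shape- and order-preserving", {
  const_clip <- video_clip(lapply(1:3, function(i) array(90L, c(16L, 16L, 3L))))
  out <- enhance_video(const_clip, clahe_params(tile_grid = c(2L, 2L)))
  expect_identical(out$frames, const_clip$frames)

  set.seed(31)
  gray <- matrix(as.integer(sample(60:180, 32 * 32, TRUE)), 32L, 32L)
  clip <- video_clip(list(array(c(gray, gray, gray), c(32L, 32L, 3L))))
  out <- enhance_video(clip, clahe_params(tile_grid = c(4L, 4L)))
  expect_equal(dim(out$frames[[1L]]), c(32L, 32L, 3L))
  # identical channels get identical per-channel mappings
  expect_identical(out$frames[[1L]][, , 1L], out$frames[[1L]][, , 2L])
  expect_identical(out$frames[[1L]][, , 1L], out$frames[[1L]][, , 3L])

  sc <- generate_scene(scene_config(width = 64L, height = 64L,
                                    n_frames = 4L), seed = 2L)
  enh <- enhance_video(sc$clip, clahe_params())
  expect_equal(n_frames(enh), 4L)
  expect_equal(enh$frame_indices, sc$clip$frame_indices)
  # determinism: identical input and params give identical bytes
  expect_identical(enh$frames, enhance_video(sc$clip, clahe_params())$frames)
})
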
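# Shared seeded fixtures and oracle statistics.

withr_like_tempdir <- function() {
  d <- tempfile("uwv")
  dir.create(d)
  d
}

# standard corrupted-track fixture: 3 objects over 20 frames, 3 px box
# jitter, occasional confidence dips
std_scene <- function() {
  generate_scene(scene_config(width = 128L, height = 128L, n_frames = 20L,
                              n_objects = 3L), seed = 42L)
}

std_corrupted <- function(scene = std_scene()) {
  corrupt_detections(scene$annotations,
                     noise_config(box_sigma = 3, p_dip = 0.2),
                     image_size = c(128, 128), seed = 43L)
}

# width-reduced detector for desk-scale runs
smoke_detector <- function(use_ca = TRUE, seed = 3L, num_classes = 5L) {
  cfg <- detector_config(depth_mult = 0.33, width_mult = 0.125,
                         num_classes = num_classes, use_ca = use_ca,
                         test_size = 64L)
  init_detector_weights(build_detector(cfg), seed = seed)
}

# two square 64 px frames with ground truth, for smoke training
smoke_frames <- function(seed = 11L) {
  sc <- generate_scene(scene_config(width = 64L, height = 64L,
                                    n_frames = 3L, n_objects = 2L,
                                    size_range = c(6, 12)), seed = seed)
  list(clip = video_clip(sc$clip$frames[1:2]),
       annotations = sc$annotations[sc$annotations$frame < 2L, ])
}

# jitter statistic: mean absolute second difference of tubelet box centers
# (computed from ground-truth track identity, independent of the linker)
center_jitter_stat <- function(dets, gt_tracks, image_size,
                               iou_match = 0.25) {
  # associate each detection with the gt track whose box it overlaps most
  stats <- c()
  for (tid in unique(gt_tracks$track_id)) {
    sub <- gt_tracks[gt_tracks$track_id == tid, , drop = FALSE]
    cx <- rep(NA_real_, nrow(sub))
    cy <- rep(NA_real_, nrow(sub))
    for (k in seq_len(nrow(sub))) {
      cand <- dets[dets$frame == sub$frame[k], , drop = FALSE]
      if (nrow(cand) == 0L) next
      ious <- box_iou(as.matrix(cand[, c("x1", "y1", "x2", "y2")]),
                      matrix(as.numeric(sub[k, c("x1", "y1", "x2", "y2")]),
                             nrow(cand), 4L, byrow = TRUE))
      j <- which.max(ious)
      if (ious[j] >= iou_match) {
        cx[k] <- (cand$x1[j] + cand$x2[j]) / 2
        cy[k] <- (cand$y1[j] + cand$y2[j]) / 2
      }
    }
    if (sum(!is.na(cx)) >= 3L) {
      ax <- diff(diff(cx))
      ay <- diff(diff(cy))
      stats <- c(stats, abs(ax[!is.na(ax)]), abs(ay[!is.na(ay)]))
    }
  }
  mean(stats)
}
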
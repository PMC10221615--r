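# Seeded synthetic underwater scenes and detector-like corrupted
# detections.  The generator emulates the two properties that matter for
# exercising the pipeline on low-quality underwater footage: global
# contrast compression (light absorption) and Gaussian blur (scatter),
# over a noisy background with a few moving benthic objects whose
# ground-truth boxes and track identities are known exactly.

#' Synthetic scene configuration
#'
#' Objects are filled ellipses or rectangles with class-keyed colors moving
#' on linear or sinusoidal trajectories.  After rendering, the frame is
#' degraded: intensities are compressed around mid-gray by `gamma` and
#' blurred with a Gaussian kernel.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames T (>= 3).
#' @param n_objects Number of moving objects.
#' @param classes Class names to cycle through for the objects.
#' @param size_range Range of object half-sizes in pixels.
#' @param speed_range Range of speeds in px/frame.
#' @param sinus_amplitude Amplitude (px) of the sinusoidal component added
#'   to half of the trajectories.
#' @param base_gray Background intensity.
#' @param noise_sd Per-pixel Gaussian background noise sd.
#' @param gamma Contrast compression factor in (0, 1]; output range is
#'   about `gamma * 255` around mid-gray.
#' @param blur_sigma Gaussian blur sd in pixels (0 disables).
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 128L, height = 128L, n_frames = 20L,
                         n_objects = 3L, classes = uwv_classes(),
                         size_range = c(8, 16), speed_range = c(1, 3),
                         sinus_amplitude = 3, base_gray = 120,
                         noise_sd = 6, gamma = 0.45, blur_sigma = 1) {
  if (n_frames < 3L) stop_uwv("n_frames must be >= 3")
  if (gamma <= 0 || gamma > 1) stop_uwv("gamma must be in (0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 n_objects = as.integer(n_objects), classes = classes,
                 size_range = size_range, speed_range = speed_range,
                 sinus_amplitude = sinus_amplitude, base_gray = base_gray,
                 noise_sd = noise_sd, gamma = gamma,
                 blur_sigma = blur_sigma),
            class = "scene_config")
}

# class-keyed fill colors (R,G,B) so a small detector can separate classes
class_colors <- function() {
  matrix(c(40, 40, 40,     # echinus: dark
           150, 110, 60,   # holothurian: brown
           230, 120, 60,   # starfish: orange
           200, 200, 220,  # fish: silvery
           220, 200, 240), # jellyfish: pale violet
         ncol = 3L, byrow = TRUE)
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate padding
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  H <- nrow(m)
  W <- ncol(m)
  pad_rows <- m[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (t in seq_along(k)) {
    tmp <- tmp + k[t] * pad_rows[(t - 1L) + seq_len(H), , drop = FALSE]
  }
  pad_cols <- tmp[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) {
    out <- out + k[t] * pad_cols[, (t - 1L) + seq_len(W), drop = FALSE]
  }
  out
}

#' Generate a synthetic underwater clip with ground-truth tracks
#'
#' Deterministic for a fixed seed.  Ground-truth boxes are tight to the
#' rendered shapes (before degradation) and clipped to the frame; object
#' trajectories are constructed so centers stay inside the frame, keeping
#' at least half of each object visible.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed.
#' @return `list(clip = video_clip, annotations = data.frame)` where the
#'   annotations carry `frame`, `class_name`, `track_id` and box corners.
#' @export
generate_scene <- function(cfg = scene_config(), seed = 1L) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    W <- cfg$width
    H <- cfg$height
    TT <- cfg$n_frames
    cols <- class_colors()
    objs <- lapply(seq_len(cfg$n_objects), function(i) {
      cls_i <- ((i - 1L) %% length(cfg$classes)) + 1L
      rx <- stats::runif(1, cfg$size_range[1L], cfg$size_range[2L])
      ry <- stats::runif(1, cfg$size_range[1L], cfg$size_range[2L])
      speed <- stats::runif(1, cfg$speed_range[1L], cfg$speed_range[2L])
      theta <- stats::runif(1, 0, 2 * pi)
      vx <- speed * cos(theta)
      vy <- speed * sin(theta)
      margin_x <- min(rx + 2, W / 4)
      margin_y <- min(ry + 2, H / 4)
      cx0 <- stats::runif(1, margin_x, W - margin_x)
      cy0 <- stats::runif(1, margin_y, H - margin_y)
      sinus <- i %% 2L == 0L
      phase <- stats::runif(1, 0, 2 * pi)
      list(class_i = cls_i, rx = rx, ry = ry, vx = vx, vy = vy,
           cx0 = cx0, cy0 = cy0, sinus = sinus, phase = phase,
           shape = if (cls_i %in% c(1L, 5L)) "ellipse" else "rect")
    })
    # reflect trajectories at the walls so centers stay in frame
    centers <- lapply(objs, function(o) {
      cx <- numeric(TT)
      cy <- numeric(TT)
      x <- o$cx0
      y <- o$cy0
      vx <- o$vx
      vy <- o$vy
      for (t in seq_len(TT)) {
        amp <- if (o$sinus) cfg$sinus_amplitude * sin(0.6 * t + o$phase) else 0
        cx[t] <- x
        cy[t] <- min(max(y + amp, 1), H - 1)
        x <- x + vx
        y <- y + vy
        if (x < 2 || x > W - 2) vx <- -vx
        if (y < 2 || y > H - 2) vy <- -vy
        x <- min(max(x, 2), W - 2)
        y <- min(max(y, 2), H - 2)
      }
      if (any(cx < 0 | cx > W | cy < 0 | cy > H)) {
        stop_uwv("infeasible object placement")
      }
      cbind(cx, cy)
    })
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
    frames <- vector("list", TT)
    ann <- vector("list", TT)
    for (t in seq_len(TT)) {
      frame <- array(0, c(H, W, 3L))
      for (ch in 1:3) {
        frame[, , ch] <- cfg$base_gray +
          stats::rnorm(H * W, 0, cfg$noise_sd)
      }
      rows <- NULL
      for (i in seq_along(objs)) {
        o <- objs[[i]]
        cx <- centers[[i]][t, 1L]
        cy <- centers[[i]][t, 2L]
        mask <- if (o$shape == "ellipse") {
          ((xs - cx) / o$rx)^2 + ((ys - cy) / o$ry)^2 <= 1
        } else {
          abs(xs - cx) <= o$rx & abs(ys - cy) <= o$ry
        }
        if (any(mask)) {
          for (ch in 1:3) {
            pl <- frame[, , ch]
            pl[mask] <- cols[o$class_i, ch] + stats::rnorm(sum(mask), 0, 4)
            frame[, , ch] <- pl
          }
        }
        rows <- rbind(rows, data.frame(
          frame = t - 1L, class_name = cfg$classes[o$class_i],
          track_id = i,
          x1 = max(cx - o$rx, 0), y1 = max(cy - o$ry, 0),
          x2 = min(cx + o$rx, W), y2 = min(cy + o$ry, H)
        ))
      }
      # degradation: contrast compression around mid-gray, then blur
      frame <- cfg$gamma * (frame - 128) + 128
      if (cfg$blur_sigma > 0) {
        for (ch in 1:3) {
          frame[, , ch] <- blur_matrix(frame[, , ch], cfg$blur_sigma)
        }
      }
      frame <- round(pmin(pmax(frame, 0), 255))
      storage.mode(frame) <- "integer"
      frames[[t]] <- frame
      ann[[t]] <- rows
    }
    list(clip = video_clip(frames), annotations = do.call(rbind, ann))
  })
}

#' Detection-noise configuration
#'
#' Emulates a detector's failure modes on top of ground-truth tracks:
#' i.i.d. coordinate jitter, score noise with occasional confidence dips,
#' missed detections and Poisson false positives.
#'
#' @param box_sigma Coordinate jitter sd in pixels (per corner coordinate,
#'   per frame).
#' @param score_base Base detection score.
#' @param score_sd Half-normal score noise sd.
#' @param p_dip Probability of a confidence dip in a frame.
#' @param dip_depth Score drop of a dip.
#' @param p_miss Probability a ground-truth object is missed in a frame.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @return A `noise_config` list.
#' @export
noise_config <- function(box_sigma = 3, score_base = 0.9, score_sd = 0.05,
                         p_dip = 0.1, dip_depth = 0.4, p_miss = 0,
                         fp_rate = 0) {
  probs <- c(p_dip, p_miss)
  if (any(probs < 0 | probs > 1)) stop_uwv("probabilities must be in [0, 1]")
  structure(list(box_sigma = box_sigma, score_base = score_base,
                 score_sd = score_sd, p_dip = p_dip, dip_depth = dip_depth,
                 p_miss = p_miss, fp_rate = fp_rate),
            class = "noise_config")
}

#' Corrupt ground-truth tracks into detector-like detections
#'
#' Deterministic for a fixed seed.  Each ground-truth box is emitted with
#' probability `1 - p_miss`, with jittered corners and a noised score;
#' additionally `Poisson(fp_rate)` false positives with random boxes and
#' low scores are added per frame.
#'
#' @param annotations Ground-truth annotation data frame (see
#'   [generate_scene()]).
#' @param cfg A [noise_config()].
#' @param image_size `c(width, height)` used to clip boxes and to place
#'   false positives.
#' @param classes Class vocabulary mapping `class_name` to 0-based ids.
#' @param seed Integer seed.
#' @return Detection data frame sorted by frame and descending score.
#' @export
corrupt_detections <- function(annotations, cfg = noise_config(),
                               image_size, classes = uwv_classes(),
                               seed = 1L) {
  stopifnot(inherits(cfg, "noise_config"))
  W <- image_size[1L]
  H <- image_size[2L]
  with_seed(seed, {
    keep <- stats::runif(nrow(annotations)) >= cfg$p_miss
    sub <- annotations[keep, , drop = FALSE]
    n <- nrow(sub)
    if (n > 0L) {
      jit <- matrix(stats::rnorm(4L * n, 0, cfg$box_sigma), n, 4L)
      x1 <- sub$x1 + jit[, 1L]
      y1 <- sub$y1 + jit[, 2L]
      x2 <- sub$x2 + jit[, 3L]
      y2 <- sub$y2 + jit[, 4L]
      x1 <- pmin(pmax(x1, 0), W - 1)
      y1 <- pmin(pmax(y1, 0), H - 1)
      x2 <- pmin(pmax(pmax(x2, x1 + 1), 1), W)
      y2 <- pmin(pmax(pmax(y2, y1 + 1), 1), H)
      dip <- stats::runif(n) < cfg$p_dip
      score <- cfg$score_base - abs(stats::rnorm(n, 0, cfg$score_sd)) -
        dip * cfg$dip_depth
      score <- pmin(pmax(score, 0.01), 1)
      det <- data.frame(frame = sub$frame,
                        class_id = match(sub$class_name, classes) - 1L,
                        score = score, x1 = x1, y1 = y1, x2 = x2, y2 = y2)
    } else {
      det <- detection_records()
    }
    sizes <- cbind(annotations$x2 - annotations$x1,
                   annotations$y2 - annotations$y1)
    for (f in sort(unique(annotations$frame))) {
      nfp <- stats::rpois(1L, cfg$fp_rate)
      if (nfp > 0L) {
        for (k in seq_len(nfp)) {
          i <- sample.int(nrow(sizes), 1L)
          w <- sizes[i, 1L]
          h <- sizes[i, 2L]
          x1 <- stats::runif(1, 0, max(W - w, 1))
          y1 <- stats::runif(1, 0, max(H - h, 1))
          det <- rbind(det, data.frame(
            frame = f,
            class_id = sample.int(length(classes), 1L) - 1L,
            score = stats::runif(1, 0.05, 0.3),
            x1 = x1, y1 = y1,
            x2 = min(x1 + w, W), y2 = min(y1 + h, H)
          ))
        }
      }
    }
    det <- det[order(det$frame, -det$score), , drop = FALSE]
    rownames(det) <- NULL
    validate_detections(det)
    det
  })
}
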
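# Desk-scale training machinery: a simplified center-radius assigner (a
# documented stand-in for the full optimal-transport assignment of the
# baseline detector, sufficient for smoke training on synthetic scenes),
# the composite loss evaluated on the autodiff tape, and plain SGD with
# momentum.

# Positive anchors for one frame: an anchor is positive for a ground-truth
# box if its center lies inside the box and within `radius` strides of the
# box center; anchors matching several boxes take the nearest center.
# Returns one row per positive: level, linear anchor index (column-major
# over the level grid), and the gt row index.
assign_targets <- function(gt_boxes, level_dims, strides, radius = 2.5) {
  ng <- nrow(gt_boxes)
  if (ng == 0L) return(NULL)
  rows <- NULL
  gcx <- (gt_boxes[, 1L] + gt_boxes[, 3L]) / 2
  gcy <- (gt_boxes[, 2L] + gt_boxes[, 4L]) / 2
  for (l in seq_along(strides)) {
    s <- strides[l]
    Ho <- level_dims[[l]][1L]
    Wo <- level_dims[[l]][2L]
    gx <- rep(seq_len(Wo) - 1L, each = Ho)
    gy <- rep(seq_len(Ho) - 1L, times = Wo)
    ax <- (gx + 0.5) * s
    ay <- (gy + 0.5) * s
    best_gt <- rep(NA_integer_, Ho * Wo)
    best_d <- rep(Inf, Ho * Wo)
    for (g in seq_len(ng)) {
      inside <- ax >= gt_boxes[g, 1L] & ax <= gt_boxes[g, 3L] &
        ay >= gt_boxes[g, 2L] & ay <= gt_boxes[g, 4L]
      near <- abs(ax - gcx[g]) <= radius * s & abs(ay - gcy[g]) <= radius * s
      d <- (ax - gcx[g])^2 + (ay - gcy[g])^2
      hit <- inside & near & d < best_d
      best_gt[hit] <- g
      best_d[hit] <- d[hit]
    }
    pos <- which(!is.na(best_gt))
    if (length(pos) > 0L) {
      rows <- rbind(rows, data.frame(level = l, anchor = pos,
                                     gt = best_gt[pos]))
    }
  }
  rows
}

# 1 - CIOUlog on tracked (or plain) coordinate vectors; the degenerate-box
# guards of the public API are unnecessary here because decoded predictions
# always have positive sizes.
reg_loss_nodes <- function(px1, py1, px2, py2, gx1, gy1, gx2, gy2,
                           lambda = 1, shape_sign = -1, mode = "ciou_log") {
  if (mode == "iou_sq") {
    wi <- nv_max(0, nv_min(px2, gx2) - nv_max(px1, gx1))
    hi <- nv_max(0, nv_min(py2, gy2) - nv_max(py1, gy1))
    inter <- wi * hi
    uni <- (px2 - px1) * (py2 - py1) + (gx2 - gx1) * (gy2 - gy1) - inter
    iou <- inter / nv_max(uni, 1e-9)
    return(1 - iou^2)
  }
  parts <- ciou_log_core(px1, py1, px2, py2, gx1, gy1, gx2, gy2,
                         lambda = lambda)
  il <- parts$iou_log
  alpha <- parts$v / (1 - il + parts$v + 1e-12)
  1 - (il - parts$rho2 / nv_max(parts$c2, 1e-9) +
         shape_sign * alpha * parts$v)
}

# Per-frame loss terms on the tape.  `outputs` are the raw head outputs
# (adnodes), `assign` the assignment table, `gt_boxes`/`gt_cls` the frame's
# ground truth.  Returns nodes (or plain zeros) per term plus bookkeeping
# for the jitter pass.
frame_loss_terms <- function(outputs, assign, gt_boxes, gt_cls, ncls,
                             strides, reg_mode = "ciou_log",
                             shape_sign = -1) {
  conf_sum <- 0
  n_anchor <- 0L
  # flatten per level once
  flat <- lapply(outputs, function(o) {
    list(reg = ad_flatten(o$reg), obj = ad_flatten(o$obj),
         cls = ad_flatten(o$cls), dims = dim(vof(o$reg))[1:2])
  })
  for (l in seq_along(flat)) {
    hw <- prod(flat[[l]]$dims)
    y <- numeric(hw)
    if (!is.null(assign)) {
      al <- assign[assign$level == l, , drop = FALSE]
      y[al$anchor] <- 1
    }
    conf_sum <- conf_sum + ad_sum(bce_loss(ad_sigmoid(flat[[l]]$obj), y))
    n_anchor <- n_anchor + hw
  }
  conf <- conf_sum / n_anchor
  if (is.null(assign) || nrow(assign) == 0L) {
    return(list(cls = 0, reg = 0, conf = conf, pred_boxes = NULL))
  }
  cls_sum <- 0
  reg_sum <- 0
  npos <- nrow(assign)
  pred_boxes <- vector("list", npos)
  k <- 0L
  for (l in seq_along(flat)) {
    al <- assign[assign$level == l, , drop = FALSE]
    if (nrow(al) == 0L) next
    hw <- prod(flat[[l]]$dims)
    Ho <- flat[[l]]$dims[1L]
    s <- strides[l]
    a <- al$anchor
    gx <- (a - 1L) %/% Ho          # column index, 0-based
    gy <- (a - 1L) %% Ho           # row index, 0-based
    tx <- ad_gather(flat[[l]]$reg, a)
    ty <- ad_gather(flat[[l]]$reg, hw + a)
    tw <- ad_gather(flat[[l]]$reg, 2L * hw + a)
    th <- ad_gather(flat[[l]]$reg, 3L * hw + a)
    cx <- (gx + tx) * s
    cy <- (gy + ty) * s
    w <- exp(tw) * s
    h <- exp(th) * s
    px1 <- cx - w / 2
    py1 <- cy - h / 2
    px2 <- cx + w / 2
    py2 <- cy + h / 2
    gb <- gt_boxes[al$gt, , drop = FALSE]
    reg_sum <- reg_sum + ad_sum(reg_loss_nodes(
      px1, py1, px2, py2, gb[, 1L], gb[, 2L], gb[, 3L], gb[, 4L],
      shape_sign = shape_sign, mode = reg_mode))
    # classification: BCE over all classes at the positive anchors
    cls_idx <- as.vector(outer(a, (seq_len(ncls) - 1L) * hw, `+`))
    ycls <- as.vector(outer(al$gt, seq_len(ncls) - 1L,
                            function(g, c) as.numeric(gt_cls[g] == c)))
    cls_sum <- cls_sum + ad_sum(bce_loss(
      ad_sigmoid(ad_gather(flat[[l]]$cls, cls_idx)), ycls))
    for (j in seq_len(nrow(al))) {
      k <- k + 1L
      pred_boxes[[k]] <- list(
        gt = al$gt[j], level = l, anchor = al$anchor[j],
        box = list(ad_gather(px1, j), ad_gather(py1, j),
                   ad_gather(px2, j), ad_gather(py2, j)),
        score = stats::plogis(vof(flat[[l]]$obj)[al$anchor[j]]))
    }
  }
  list(cls = cls_sum / (npos * ncls), reg = reg_sum / npos, conf = conf,
       pred_boxes = pred_boxes[seq_len(k)])
}

# Tracked jitter loss over the matched positives of T consecutive frames.
# For each track and frame, the assigned positive with the highest
# objectness represents the prediction; tracks with fewer than 3 matched
# consecutive frames contribute 0.
jitter_loss_nodes <- function(track_preds, track_gts, n_frames) {
  if (n_frames < 3L || length(track_preds) == 0L) return(0)
  total <- 0
  n_obj <- 0L
  for (tid in names(track_preds)) {
    pseq <- track_preds[[tid]]
    gseq <- track_gts[[tid]]
    contrib <- 0
    any_valid <- FALSE
    for (i in 2:(n_frames - 1L)) {
      trip <- list(pseq[[i - 1L]], pseq[[i]], pseq[[i + 1L]])
      if (any(vapply(trip, is.null, TRUE))) next
      any_valid <- TRUE
      acc <- 0
      for (c in 1:4) {
        ap <- trip[[3L]]$box[[c]] - 2 * trip[[2L]]$box[[c]] +
          trip[[1L]]$box[[c]]
        ag <- gseq[[i + 1L]][c] - 2 * gseq[[i]][c] + gseq[[i - 1L]][c]
        acc <- acc + abs(ag - ap)
      }
      contrib <- contrib + acc / 4
    }
    if (any_valid || n_frames >= 3L) {
      total <- total + contrib / (n_frames - 2L)
      n_obj <- n_obj + 1L
    }
  }
  if (n_obj == 0L) 0 else total / n_obj
}

#' Smoke-train a detector on a synthetic clip
#'
#' Runs the composite loss (classification, log-area CIoU regression,
#' confidence and jitter terms) with the simplified center-radius assigner
#' for a number of SGD steps, at the standard settings (momentum 0.9,
#' learning rate 0.005, weight decay 5e-4 by default).  Intended for
#' desk-scale verification that the full computational graph trains, not
#' for producing a usable model.
#'
#' @param detector An initialized `uwv_detector` (see
#'   [init_detector_weights()]).
#' @param clip A [video_clip()] whose frames are square and divisible
#'   by 32.
#' @param annotations Ground-truth annotation data frame with `frame`,
#'   `class_name`, `track_id` and box corners.
#' @param steps Number of SGD steps.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param weights A [loss_weights()] object.
#' @param reg_mode `"ciou_log"` or `"iou_sq"`.
#' @param classes Class vocabulary.
#' @return `list(detector = updated detector, trace = data.frame)` with
#'   per-step total and per-term loss values.
#' @export
smoke_train <- function(detector, clip, annotations, steps = 50L,
                        lr = 0.005, momentum = 0.9, weight_decay = 5e-4,
                        weights = loss_weights(), reg_mode = "ciou_log",
                        classes = uwv_classes()) {
  stopifnot(inherits(detector, "uwv_detector"))
  if (is.null(detector$params)) stop_uwv("initialize weights first")
  if (steps == 0L) {
    return(list(detector = detector,
                trace = data.frame(step = integer(), total = numeric(),
                                   cls = numeric(), reg = numeric(),
                                   conf = numeric(), jitter = numeric())))
  }
  ncls <- detector$cfg$num_classes
  strides <- detector$cfg$strides
  TT <- n_frames(clip)
  frames01 <- lapply(clip$frames, function(f) f / 255)
  per_frame <- lapply(seq_len(TT), function(i) {
    sub <- annotations[annotations$frame == clip$frame_indices[i], ,
                       drop = FALSE]
    list(boxes = as.matrix(sub[, c("x1", "y1", "x2", "y2")]),
         cls = match(sub$class_name, classes) - 1L,
         track = sub$track_id)
  })
  vel <- lapply(detector$params, function(p) p * 0)
  trace <- data.frame(step = seq_len(steps), total = NA_real_,
                      cls = NA_real_, reg = NA_real_, conf = NA_real_,
                      jitter = NA_real_)
  for (step in seq_len(steps)) {
    ad_tape_begin()
    nodes <- lapply(detector$params, ad_param)
    t_cls <- 0
    t_reg <- 0
    t_conf <- 0
    track_preds <- list()
    track_gts <- list()
    n_pos_frames <- 0L
    for (i in seq_len(TT)) {
      outputs <- forward_detector(detector, frames01[[i]], nodes)
      level_dims <- lapply(outputs, function(o) dim(vof(o$reg))[1:2])
      asg <- assign_targets(per_frame[[i]]$boxes, level_dims, strides)
      terms <- frame_loss_terms(outputs, asg, per_frame[[i]]$boxes,
                                per_frame[[i]]$cls, ncls, strides,
                                reg_mode = reg_mode)
      t_conf <- t_conf + terms$conf
      if (!is.null(asg)) {
        t_cls <- t_cls + terms$cls
        t_reg <- t_reg + terms$reg
        n_pos_frames <- n_pos_frames + 1L
      }
      # best positive per track for the jitter term
      if (!is.null(terms$pred_boxes)) {
        for (pb in terms$pred_boxes) {
          tid <- as.character(per_frame[[i]]$track[pb$gt])
          if (is.na(tid)) next
          if (is.null(track_preds[[tid]])) {
            track_preds[[tid]] <- vector("list", TT)
            track_gts[[tid]] <- vector("list", TT)
          }
          cur <- track_preds[[tid]][[i]]
          if (is.null(cur) || pb$score > cur$score) {
            track_preds[[tid]][[i]] <- pb
            track_gts[[tid]][[i]] <- per_frame[[i]]$boxes[pb$gt, ]
          }
        }
      }
    }
    t_conf <- t_conf / TT
    if (n_pos_frames > 0L) {
      t_cls <- t_cls / n_pos_frames
      t_reg <- t_reg / n_pos_frames
    }
    t_jit <- jitter_loss_nodes(track_preds, track_gts, TT)
    total <- weights$cls * t_cls + weights$reg * t_reg +
      weights$conf * t_conf + weights$jitter * t_jit
    tv <- vof(total)
    if (!is.finite(tv)) {
      bad <- c(cls = vof(t_cls), reg = vof(t_reg), conf = vof(t_conf),
               jitter = vof(t_jit))
      ad_tape_end()
      stop_uwv("training diverged (non-finite ",
               paste(names(bad)[!is.finite(bad)], collapse = ", "),
               " term) at step ", step)
    }
    trace[step, 2:6] <- c(tv, vof(t_cls), vof(t_reg), vof(t_conf),
                          vof(t_jit))
    ad_backward(total)
    for (nm in names(detector$params)) {
      g <- nodes[[nm]]$grad
      if (is.null(g)) next
      if (is.matrix(detector$params[[nm]])) {
        g <- g + weight_decay * detector$params[[nm]]
      }
      vel[[nm]] <- momentum * vel[[nm]] + g
      detector$params[[nm]] <- detector$params[[nm]] - lr * vel[[nm]]
    }
    ad_tape_end()
  }
  list(detector = detector, trace = trace)
}
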
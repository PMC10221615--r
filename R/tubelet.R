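# Frame-level optimization: detections in adjacent frames are paired by a
# logistic similarity over geometric features, pairs are chained into
# tubelets (contiguous-frame, class-pure chains of one physical object),
# and each tubelet is re-scored (confidence averaging) and re-coordinated
# (Gaussian smoothing of the four corner-coordinate time series).

#' Logistic pair-similarity model
#'
#' Similarity between two detections A, B in adjacent frames is
#' `X(features) * scoreA * scoreB` with
#' `X = sigmoid(w_iou*IOU + w_dcenter*dcenter + w_logw*|log ratio_w| +
#' w_logh*|log ratio_h| + bias)`, `dcenter` the center distance normalized
#' by the image diagonal and `ratio_w`, `ratio_h` the side-length ratios.
#' Default weights make X increase with overlap and decrease with distance
#' and shape mismatch.
#'
#' @param w_iou,w_dcenter,w_logw,w_logh,bias Logistic weights.
#' @return A `similarity_model` list.
#' @export
similarity_model <- function(w_iou = 4, w_dcenter = -8, w_logw = -2,
                             w_logh = -2, bias = 1) {
  structure(list(w_iou = w_iou, w_dcenter = w_dcenter, w_logw = w_logw,
                 w_logh = w_logh, bias = bias), class = "similarity_model")
}

#' Gaussian re-coordinating parameters
#'
#' @param sigma Standard deviation of the temporal Gaussian, in frames.
#' @param radius Truncation radius in frames; defaults to `ceiling(3*sigma)`.
#' @return A `gaussian_params` list.
#' @export
gaussian_params <- function(sigma = 1, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) stop_uwv("sigma must be > 0")
  if (radius < 1) stop_uwv("radius must be >= 1")
  structure(list(sigma = sigma, radius = as.integer(radius)),
            class = "gaussian_params")
}

#' Similarity between two detections in adjacent frames
#'
#' @param det_a,det_b Single-row detection data frames (or lists) with
#'   `score`, `x1`, `y1`, `x2`, `y2`.
#' @param model A [similarity_model()].
#' @param image_size `c(width, height)` for the diagonal normalization.
#' @return Similarity in `[0, 1]`; 0 for degenerate (zero-size) boxes.
#' @export
pair_similarity <- function(det_a, det_b, model = similarity_model(),
                            image_size) {
  a <- c(det_a$x1, det_a$y1, det_a$x2, det_a$y2)
  b <- c(det_b$x1, det_b$y1, det_b$x2, det_b$y2)
  wa <- a[3L] - a[1L]
  ha <- a[4L] - a[2L]
  wb <- b[3L] - b[1L]
  hb <- b[4L] - b[2L]
  if (wa <= 0 || ha <= 0 || wb <= 0 || hb <= 0) return(0)
  diag <- sqrt(sum(image_size^2))
  dc <- sqrt(((a[1L] + a[3L]) / 2 - (b[1L] + b[3L]) / 2)^2 +
             ((a[2L] + a[4L]) / 2 - (b[2L] + b[4L]) / 2)^2) / diag
  z <- model$w_iou * box_iou(a, b) + model$w_dcenter * dc +
    model$w_logw * abs(log(wa / wb)) + model$w_logh * abs(log(ha / hb)) +
    model$bias
  unname(stats::plogis(z) * det_a$score * det_b$score)
}

#' Greedy matching on a similarity matrix
#'
#' Repeatedly selects the globally largest entry `>= tau`, records the
#' pair, and removes its row and column; this is the greedy scheme, not an
#' optimal assignment.  Ties at the maximum are broken toward the lowest
#' (row, col) lexicographic index.
#'
#' @param m Finite nonnegative similarity matrix (rows: earlier frame,
#'   cols: later frame).
#' @param tau Link threshold.
#' @return Integer matrix with columns `row`, `col` (1-based), possibly
#'   zero rows.
#' @export
greedy_match <- function(m, tau = 0.3) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  pairs <- NULL
  row_free <- rep(TRUE, nrow(m))
  col_free <- rep(TRUE, ncol(m))
  mw <- m
  repeat {
    mw2 <- mw
    mw2[!row_free, ] <- -Inf
    mw2[, !col_free] <- -Inf
    best <- suppressWarnings(max(mw2))
    if (!is.finite(best) || best < tau) break
    hits <- which(mw2 == best, arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], , drop = FALSE]
    pairs <- rbind(pairs, hit)
    row_free[hit[1L]] <- FALSE
    col_free[hit[2L]] <- FALSE
    if (!any(row_free) || !any(col_free)) break
  }
  if (is.null(pairs)) {
    pairs <- matrix(integer(), 0L, 2L)
  }
  colnames(pairs) <- c("row", "col")
  rownames(pairs) <- NULL
  pairs
}

#' Link detections into tubelets
#'
#' For each adjacent frame pair and each class, a similarity matrix is
#' built with [pair_similarity()] and matched with [greedy_match()]; a
#' matched pair extends the tubelet ending at the earlier detection or
#' starts a new two-member tubelet.  Unpaired detections become singleton
#' tubelets.  Every detection belongs to exactly one tubelet; tubelets are
#' frame-contiguous (no gap bridging) and class-pure.
#'
#' @param dets Detection data frame.
#' @param model A [similarity_model()].
#' @param tau Link threshold.
#' @param image_size `c(width, height)`.
#' @return List of tubelets, each
#'   `list(class_id, det_idx, frames, scores, boxes)` with `det_idx`
#'   row indices into `dets` ordered by frame.
#' @export
link_tubelets <- function(dets, model = similarity_model(), tau = 0.3,
                          image_size) {
  validate_detections(dets)
  n <- nrow(dets)
  tube_of <- rep(NA_integer_, n)
  tubes <- list()
  if (n > 0L) {
    frames <- sort(unique(dets$frame))
    for (f in frames) {
      if (!(f + 1L) %in% frames) next
      for (cl in unique(dets$class_id[dets$frame == f])) {
        ia <- which(dets$frame == f & dets$class_id == cl)
        ib <- which(dets$frame == f + 1L & dets$class_id == cl)
        if (length(ia) == 0L || length(ib) == 0L) next
        m <- matrix(0, length(ia), length(ib))
        for (r in seq_along(ia)) {
          for (s in seq_along(ib)) {
            m[r, s] <- pair_similarity(dets[ia[r], ], dets[ib[s], ],
                                       model, image_size)
          }
        }
        pr <- greedy_match(m, tau)
        for (k in seq_len(nrow(pr))) {
          a <- ia[pr[k, 1L]]
          b <- ib[pr[k, 2L]]
          ta <- tube_of[a]
          if (!is.na(ta)) {
            tubes[[ta]] <- c(tubes[[ta]], b)
            tube_of[b] <- ta
          } else {
            tubes[[length(tubes) + 1L]] <- c(a, b)
            tube_of[a] <- length(tubes)
            tube_of[b] <- length(tubes)
          }
        }
      }
    }
    for (i in which(is.na(tube_of))) {
      tubes[[length(tubes) + 1L]] <- i
      tube_of[i] <- length(tubes)
    }
  }
  lapply(tubes, function(idx) {
    idx <- idx[order(dets$frame[idx])]
    list(class_id = dets$class_id[idx[1L]],
         det_idx = idx,
         frames = dets$frame[idx],
         scores = dets$score[idx],
         boxes = as.matrix(dets[idx, c("x1", "y1", "x2", "y2")]))
  })
}

#' Re-score a tubelet
#'
#' Every member's score is replaced by the tubelet mean score; boxes are
#' untouched, so the tubelet's score mean is conserved.
#'
#' @param tubelet A tubelet from [link_tubelets()].
#' @return The re-scored tubelet.
#' @export
rescore_tubelet <- function(tubelet) {
  tubelet$scores <- rep(mean(tubelet$scores), length(tubelet$scores))
  tubelet
}

#' Re-coordinate a tubelet by temporal Gaussian smoothing
#'
#' Each of the four corner-coordinate series is convolved with a truncated
#' Gaussian whose window is intersected with the tubelet extent and whose
#' weights are renormalized to sum to one over the valid window (so
#' boundary members are not shrunk toward zero).  Scores are untouched;
#' member count and frame span are conserved.
#'
#' @param tubelet A tubelet from [link_tubelets()].
#' @param params A [gaussian_params()].
#' @return The smoothed tubelet.
#' @export
recoordinate_tubelet <- function(tubelet, params = gaussian_params()) {
  n <- length(tubelet$frames)
  if (n <= 1L) return(tubelet)
  r <- params$radius
  w <- exp(-((-r):r)^2 / (2 * params$sigma^2))
  sm <- matrix(0, n, 4L)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    wi <- w[j - i + r + 1L]
    wi <- wi / sum(wi)
    sm[i, ] <- colSums(tubelet$boxes[j, , drop = FALSE] * wi)
  }
  colnames(sm) <- colnames(tubelet$boxes)
  tubelet$boxes <- sm
  tubelet
}

#' Frame-level optimization of detections
#'
#' [link_tubelets()], then [rescore_tubelet()] and
#' [recoordinate_tubelet()] on every tubelet, flattened back to a
#' detection table.  The detection count, classes and frame assignment are
#' preserved; per-frame ordering by descending score is re-established.
#'
#' @inheritParams link_tubelets
#' @param gparams A [gaussian_params()].
#' @return The optimized detection data frame.
#' @export
optimize_detections <- function(dets, model = similarity_model(),
                                tau = 0.3, gparams = gaussian_params(),
                                image_size) {
  validate_detections(dets)
  if (nrow(dets) == 0L) return(dets)
  tubes <- link_tubelets(dets, model, tau, image_size)
  out <- dets
  for (tb in tubes) {
    tb <- recoordinate_tubelet(rescore_tubelet(tb), gparams)
    out$score[tb$det_idx] <- tb$scores
    out[tb$det_idx, c("x1", "y1", "x2", "y2")] <- tb$boxes
  }
  out <- out[order(out$frame, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
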
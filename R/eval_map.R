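# VOC-style detection evaluation: greedy-by-score matching at an IOU
# threshold, per-class precision/recall curves, average precision as the
# exact area under the monotone step curve, and mAP@0.5.

#' Match detections to ground truth
#'
#' Per class and per frame, detections are processed in descending score
#' order; each matches the unmatched ground-truth box of the same class
#' with the highest IOU if that IOU reaches `iou_thr` (one-to-one),
#' otherwise it is a false positive.  Unmatched ground truths are false
#' negatives.
#'
#' @param dets Detection data frame.
#' @param gts Ground-truth data frame (`frame`, `class_name` or
#'   `class_id`, box corners).
#' @param iou_thr IOU threshold for a true positive (default 0.5).
#' @param classes Class vocabulary for mapping `class_name` to ids.
#' @return `dets` with a logical `is_tp` column, rows ordered as input.
#' @export
match_detections_to_gt <- function(dets, gts, iou_thr = 0.5,
                                   classes = uwv_classes()) {
  validate_detections(dets)
  if (!"class_id" %in% names(gts)) {
    gts$class_id <- match(gts$class_name, classes) - 1L
  }
  is_tp <- rep(FALSE, nrow(dets))
  gt_used <- rep(FALSE, nrow(gts))
  for (cl in unique(dets$class_id)) {
    for (f in unique(dets$frame[dets$class_id == cl])) {
      di <- which(dets$class_id == cl & dets$frame == f)
      di <- di[order(-dets$score[di])]
      gi <- which(gts$class_id == cl & gts$frame == f)
      if (length(gi) == 0L) next
      gboxes <- as.matrix(gts[gi, c("x1", "y1", "x2", "y2")])
      for (d in di) {
        db <- c(dets$x1[d], dets$y1[d], dets$x2[d], dets$y2[d])
        ious <- box_iou(matrix(db, length(gi), 4L, byrow = TRUE), gboxes)
        ious[gt_used[gi]] <- -1
        j <- which.max(ious)
        if (length(j) > 0L && ious[j] >= iou_thr) {
          is_tp[d] <- TRUE
          gt_used[gi[j]] <- TRUE
        }
      }
    }
  }
  dets$is_tp <- is_tp
  dets
}

#' Average precision from labeled detections
#'
#' Detections (already TP/FP labeled) are sorted by descending score; the
#' precision envelope is made monotone from the high-recall side and AP is
#' the exact area under the resulting step curve (the integral form).  An
#' 11-point interpolation is available for comparison.
#'
#' @param scores Detection scores.
#' @param is_tp Logical TP labels aligned with `scores`.
#' @param n_gt Number of ground-truth boxes of the class.
#' @param interpolation `"area"` (default) or `"11point"`.
#' @return AP in `[0, 1]`; `NA` if the class has neither ground truth nor
#'   detections.
#' @export
average_precision <- function(scores, is_tp, n_gt,
                              interpolation = c("area", "11point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L && length(scores) == 0L) return(NA_real_)
  if (n_gt == 0L || length(scores) == 0L) return(0)
  o <- order(-scores)
  tp <- cumsum(is_tp[o])
  fp <- cumsum(!is_tp[o])
  prec <- tp / (tp + fp)
  rec <- tp / n_gt
  if (interpolation == "11point") {
    ap <- mean(vapply(seq(0, 1, 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p) == 0L) 0 else max(p)
    }, 0))
    return(ap)
  }
  # monotone envelope over recall grid 0, r_1, ..., r_k
  mrec <- c(0, rec)
  mpre <- c(0, prec)
  for (i in rev(seq_len(length(mpre) - 1L))) {
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  }
  sum(diff(mrec) * mpre[-1L])
}

#' Mean average precision over classes
#'
#' Arithmetic mean of the defined per-class APs; classes with neither
#' ground truth nor detections (undefined AP) are excluded.
#'
#' @param aps Numeric vector of per-class APs, possibly with `NA`.
#' @return Scalar mAP.
#' @export
mean_ap <- function(aps) {
  ok <- !is.na(aps)
  if (!any(ok)) stop_uwv("no class has a defined AP")
  mean(aps[ok])
}

#' Evaluate detections against ground truth
#'
#' Full VOC-style evaluation: matching at `iou_thr`, per-class AP, and
#' mAP.
#'
#' @inheritParams match_detections_to_gt
#' @param interpolation Passed to [average_precision()].
#' @return `list(per_class = data.frame(class_name, n_gt, n_det, ap),
#'   map = scalar)`.
#' @export
evaluate_detections <- function(dets, gts, iou_thr = 0.5,
                                classes = uwv_classes(),
                                interpolation = "area") {
  if (!"class_id" %in% names(gts)) {
    gts$class_id <- match(gts$class_name, classes) - 1L
  }
  labeled <- match_detections_to_gt(dets, gts, iou_thr, classes)
  aps <- vapply(seq_along(classes) - 1L, function(cl) {
    sel <- labeled$class_id == cl
    average_precision(labeled$score[sel], labeled$is_tp[sel],
                      sum(gts$class_id == cl), interpolation)
  }, 0)
  list(
    per_class = data.frame(
      class_name = classes,
      n_gt = vapply(seq_along(classes) - 1L,
                    function(cl) sum(gts$class_id == cl), 0L),
      n_det = vapply(seq_along(classes) - 1L,
                     function(cl) sum(labeled$class_id == cl), 0L),
      ap = aps
    ),
    map = mean_ap(aps)
  )
}
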
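# Composite detection loss: binary cross-entropy classification/confidence
# terms, a log-area CIoU regression term, and an inter-frame jitter
# (acceleration) term.
#
# Boxes are corner-format numeric vectors c(x1, y1, x2, y2) in continuous
# 0-based half-open pixel coordinates; vectorized entry points take n x 4
# matrices.  The geometric cores are written against the nv_* helpers from
# autodiff.R so the training path can reuse them on tracked values.

as_box_matrix <- function(b) {
  if (is.matrix(b)) {
    if (ncol(b) != 4L) stop_uwv("box matrix must have 4 columns")
    m <- b
  } else {
    if (length(b) != 4L) stop_uwv("a box is c(x1, y1, x2, y2)")
    m <- matrix(as.numeric(b), 1L, 4L)
  }
  if (any(m[, 3L] < m[, 1L]) || any(m[, 4L] < m[, 2L])) {
    stop_uwv("invalid box: x2 must be >= x1 and y2 >= y1")
  }
  m
}

#' Intersection over union of two boxes
#'
#' Boxes are corner-format `c(x1, y1, x2, y2)` (0-based, half-open).  Both
#' arguments may be n x 4 matrices for a vectorized row-wise computation.
#' Two empty boxes have IOU 0.
#'
#' @param a,b Boxes or n x 4 box matrices.
#' @return Numeric vector of IOU values in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15)) # 25 / 175
box_iou <- function(a, b) {
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  wi <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  hi <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  inter <- wi * hi
  areas <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L]) +
    (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L]) - inter
  ifelse(areas > 0, inter / areas, 0)
}

#' Squared-IOU regression loss
#'
#' The baseline regression loss `1 - IOU^2`.
#'
#' @inheritParams box_iou
#' @return Numeric vector of losses.
#' @export
iou_squared_loss <- function(a, b) {
  1 - box_iou(a, b)^2
}

# Shared geometric core; coordinates may be plain numerics or adnodes.
# Returns the components needed by iou_log / ciou_log.
ciou_log_core <- function(x1a, y1a, x2a, y2a, x1b, y1b, x2b, y2b,
                          lambda = 1, base = exp(1)) {
  w1 <- x2a - x1a
  h1 <- y2a - y1a
  w2 <- x2b - x1b
  h2 <- y2b - y1b
  wi <- nv_max(0, nv_min(x2a, x2b) - nv_max(x1a, x1b))
  hi <- nv_max(0, nv_min(y2a, y2b) - nv_max(y1a, y1b))
  num <- log((wi + lambda) * (hi + lambda), base)
  den <- log((w1 + lambda) * (h1 + lambda), base) +
    log((w2 + lambda) * (h2 + lambda), base) - num
  iou_log <- num / nv_max(den, 1e-300)
  cxa <- (x1a + x2a) / 2
  cya <- (y1a + y2a) / 2
  cxb <- (x1b + x2b) / 2
  cyb <- (y1b + y2b) / 2
  rho2 <- (cxa - cxb)^2 + (cya - cyb)^2
  c2 <- (nv_max(x2a, x2b) - nv_min(x1a, x1b))^2 +
    (nv_max(y2a, y2b) - nv_min(y1a, y1b))^2
  # tiny additive guard keeps 0/0 aspect ratios finite without moving
  # non-degenerate values beyond ~1e-13
  v <- (4 / pi^2) * (atan(w1 / (h1 + 1e-12)) - atan(w2 / (h2 + 1e-12)))^2
  list(iou_log = iou_log, den = den, rho2 = rho2, c2 = c2, v = v)
}

#' Log-area intersection over union
#'
#' IOU computed on logarithms of lambda-padded box side products:
#' `log((wi+l)(hi+l)) / (log((w1+l)(h1+l)) + log((w2+l)(h2+l)) -
#' log((wi+l)(hi+l)))`.  With `lambda = 1` disjoint boxes give 0 and
#' identical boxes give 1; the value does not depend on the logarithm base.
#'
#' @inheritParams box_iou
#' @param lambda Positive padding added to each side length before the
#'   logarithm (default 1).
#' @param base Logarithm base; the result is base-invariant, the argument
#'   exists to demonstrate that.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' iou_log(c(0, 0, 10, 10), c(5, 5, 15, 15)) # ~0.596
iou_log <- function(a, b, lambda = 1, base = exp(1)) {
  if (lambda <= 0) stop_uwv("lambda must be > 0")
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  parts <- ciou_log_core(a[, 1L], a[, 2L], a[, 3L], a[, 4L],
                         b[, 1L], b[, 2L], b[, 3L], b[, 4L],
                         lambda = lambda, base = base)
  out <- parts$iou_log
  deg <- abs(parts$den) < 1e-12
  if (any(deg)) {
    same <- rowSums(abs(a - b)) < 1e-12
    out[deg] <- ifelse(same[deg], 1, 0)
  }
  out
}

#' Log-area complete IOU
#'
#' Combines the log-area overlap term with a normalized center-distance
#' penalty and an aspect-ratio shape term:
#' `IOUlog - rho^2/c^2 + shape_sign * alpha * v` with
#' `alpha = v / (1 - IOUlog + v)`.  `rho^2` is the squared center distance
#' and `c^2` the squared diagonal of the smallest enclosing rectangle.  The
#' default `shape_sign = -1` penalizes aspect-ratio mismatch so that the
#' derived loss `1 - CIOUlog` is monotone in shape agreement.
#'
#' @inheritParams iou_log
#' @param shape_sign Sign applied to the `alpha * v` shape term (-1 or +1).
#' @return Numeric vector of CIOUlog values.
#' @export
ciou_log <- function(a, b, lambda = 1, shape_sign = -1, base = exp(1)) {
  if (lambda <= 0) stop_uwv("lambda must be > 0")
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  il <- iou_log(a, b, lambda = lambda, base = base)
  parts <- ciou_log_core(a[, 1L], a[, 2L], a[, 3L], a[, 4L],
                         b[, 1L], b[, 2L], b[, 3L], b[, 4L],
                         lambda = lambda, base = base)
  pos <- ifelse(parts$c2 < 1e-12, 0, parts$rho2 / pmax(parts$c2, 1e-300))
  alpha <- parts$v / (1 - il + parts$v + 1e-300)
  il - pos + shape_sign * alpha * parts$v
}

#' Box regression loss
#'
#' `1 - metric` where the metric is either the squared IOU
#' (`mode = "iou_sq"`) or the log-area complete IOU (`mode = "ciou_log"`,
#' default).
#'
#' @inheritParams ciou_log
#' @param mode `"ciou_log"` or `"iou_sq"`.
#' @return Numeric vector of nonnegative losses (0 for identical boxes).
#' @export
regression_loss <- function(a, b, mode = c("ciou_log", "iou_sq"),
                            lambda = 1, shape_sign = -1) {
  mode <- match.arg(mode)
  switch(mode,
    iou_sq = iou_squared_loss(a, b),
    ciou_log = 1 - ciou_log(a, b, lambda = lambda, shape_sign = shape_sign)
  )
}

#' Binary cross-entropy
#'
#' `-(y log p + (1 - y) log(1 - p))` with `p` clamped to
#' `[1e-7, 1 - 1e-7]`.  Vectorized; `y` may be soft targets in `[0, 1]`.
#'
#' @param p Predicted probabilities.
#' @param y Targets in `[0, 1]`.
#' @return Nonnegative numeric vector of per-element losses.
#' @export
bce_loss <- function(p, y) {
  p <- nv_clamp(p, 1e-7, 1 - 1e-7)
  -(y * log(p) + (1 - y) * log(1 - p))
}

as_track_list <- function(x) {
  if (is.null(x)) return(list())
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, as_track_matrix))
  list(as_track_matrix(x))
}

as_track_matrix <- function(m) {
  if (is.matrix(m)) m else matrix(as.numeric(m), ncol = 1L)
}

#' Inter-frame jitter loss
#'
#' Coordinate sequences over T consecutive frames are differenced twice to
#' obtain per-frame accelerations; the loss is the mean absolute difference
#' between predicted and ground-truth accelerations, averaged over
#' coordinates, summed over the T - 2 acceleration indices, divided by
#' T - 2, and averaged over objects.  Rows with missing values (frames in
#' which an object was not matched) only contribute complete triplets, but
#' the divisor stays T - 2.  Sequences shorter than 3 frames contribute 0.
#'
#' @param pred,gt Aligned coordinate sequences: a T x d matrix (d = 4 for
#'   boxes, d = 1 for scalar series), a length-T vector, or a list of such
#'   matrices (one per object).
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' jitter_loss(c(0, 1, 3, 3), c(0, 1, 2, 3)) # 1.5
jitter_loss <- function(pred, gt) {
  ps <- as_track_list(pred)
  gs <- as_track_list(gt)
  if (length(ps) != length(gs)) stop_uwv("pred and gt must align object-wise")
  if (length(ps) == 0L) return(0)
  per_obj <- mapply(function(p, g) {
    if (!all(dim(p) == dim(g))) stop_uwv("pred and gt sequences must align")
    tt <- nrow(p)
    if (tt < 3L) return(0)
    ap <- diff(diff(p))
    ag <- diff(diff(g))
    rows <- rowMeans(abs(ag - ap))
    sum(rows, na.rm = TRUE) / (tt - 2L)
  }, ps, gs)
  mean(per_obj)
}

#' Loss term weights
#'
#' Weights of the composite loss.  Only the jitter weight is model-specific
#' (0.05); the classification/confidence weights default to 1 and the
#' regression weight to 5, the usual anchor-free detector convention.
#'
#' @param cls,reg,conf,jitter Nonnegative weights.
#' @return A named list of class `loss_weights`.
#' @export
loss_weights <- function(cls = 1, reg = 5, conf = 1, jitter = 0.05) {
  w <- list(cls = cls, reg = reg, conf = conf, jitter = jitter)
  if (any(unlist(w) < 0)) stop_uwv("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

#' Composite detection loss
#'
#' Weighted sum of classification, regression, confidence and jitter terms
#' with a per-term breakdown.  Classification and confidence terms are mean
#' binary cross-entropies; the regression term is the mean
#' [regression_loss()] over matched box pairs; the jitter term is
#' [jitter_loss()] over the track batch.  With no positive samples the
#' classification and regression terms are 0.
#'
#' @param cls_terms,conf_terms `list(p = , y = )` of probabilities and
#'   targets, or `NULL`.
#' @param reg_pairs `list(pred = , gt = )` of n x 4 box matrices, or `NULL`.
#' @param track_batch `list(pred = , gt = )` of aligned coordinate
#'   sequences as accepted by [jitter_loss()], or `NULL`.
#' @param weights A [loss_weights()] object.
#' @param reg_mode Regression metric passed to [regression_loss()].
#' @param lambda,shape_sign Passed to [regression_loss()].
#' @return List with `total` and the unweighted per-term values `cls`,
#'   `reg`, `conf`, `jitter`.
#' @export
total_loss <- function(cls_terms = NULL, reg_pairs = NULL, conf_terms = NULL,
                       track_batch = NULL, weights = loss_weights(),
                       reg_mode = "ciou_log", lambda = 1, shape_sign = -1) {
  l_cls <- if (is.null(cls_terms) || length(cls_terms$p) == 0L) 0 else {
    mean(bce_loss(cls_terms$p, cls_terms$y))
  }
  l_reg <- if (is.null(reg_pairs) || NROW(reg_pairs$pred) == 0L) 0 else {
    mean(regression_loss(reg_pairs$pred, reg_pairs$gt, mode = reg_mode,
                         lambda = lambda, shape_sign = shape_sign))
  }
  l_conf <- if (is.null(conf_terms) || length(conf_terms$p) == 0L) 0 else {
    mean(bce_loss(conf_terms$p, conf_terms$y))
  }
  l_jit <- if (is.null(track_batch)) 0 else {
    jitter_loss(track_batch$pred, track_batch$gt)
  }
  list(
    total = weights$cls * l_cls + weights$reg * l_reg +
      weights$conf * l_conf + weights$jitter * l_jit,
    cls = l_cls, reg = l_reg, conf = l_conf, jitter = l_jit
  )
}
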
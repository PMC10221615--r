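# Anchor-free one-stage detector: CSPDarknet backbone, PAFPN neck and a
# decoupled head at strides 8/16/32, optionally with coordinate-attention
# CSP blocks (CSP_CA1 keeps the residual units and inserts a CA module
# after the trunk's 1x1 convolution; CSP_CA2 replaces the residual units
# with a single CA module).
#
# The architecture is held as a declarative spec tree; parameter shapes
# and counts are derived from the tree without materializing weights, so
# full-scale (~1e8 parameter) configurations can be counted cheaply while
# desk-scale configurations are actually run through the autodiff ops.

#' Detector configuration
#'
#' The default multipliers (depth 1.33, width 1.25) give the X-scale model
#' whose baseline parameter count is 99.00 M at 5 classes; `use_ca = TRUE`
#' swaps the backbone's CSP blocks for the coordinate-attention variants
#' (residual-type blocks become CSP_CA1, the non-residual block CSP_CA2),
#' giving 82.66 M.
#'
#' @param depth_mult,width_mult Depth/width scaling factors.
#' @param num_classes Number of object classes.
#' @param use_ca Use coordinate-attention CSP blocks.
#' @param ca_reduction Channel reduction ratio r of the CA module.
#' @param ca_mid_min Floor on the CA intermediate channel count.
#' @param ca_placement `"backbone"` (default; the residual-type backbone
#'   blocks become CSP_CA1 and the last, non-residual backbone block
#'   CSP_CA2) or `"backbone_neck"` (additionally converts the neck's
#'   non-residual blocks to CSP_CA2).
#' @param strides Detection strides.
#' @param score_thr Inference score threshold.
#' @param nms_thr Per-class NMS IOU threshold.
#' @param test_size Inference resolution (square letterbox).
#' @return A `detector_config` list.
#' @export
detector_config <- function(depth_mult = 1.33, width_mult = 1.25,
                            num_classes = 5L, use_ca = FALSE,
                            ca_reduction = 32L, ca_mid_min = 8L,
                            ca_placement = c("backbone", "backbone_neck"),
                            strides = c(8L, 16L, 32L), score_thr = 0.25,
                            nms_thr = 0.5, test_size = 576L) {
  ca_placement <- match.arg(ca_placement)
  if (num_classes < 1L) stop_uwv("num_classes must be >= 1")
  if (nms_thr <= 0 || nms_thr > 1) stop_uwv("nms_thr must be in (0, 1]")
  if (depth_mult <= 0 || width_mult <= 0) {
    stop_uwv("depth/width multipliers must be > 0")
  }
  structure(list(depth_mult = depth_mult, width_mult = width_mult,
                 num_classes = as.integer(num_classes), use_ca = use_ca,
                 ca_reduction = as.integer(ca_reduction),
                 ca_mid_min = as.integer(ca_mid_min),
                 ca_placement = ca_placement,
                 strides = as.integer(strides),
                 score_thr = score_thr, nms_thr = nms_thr,
                 test_size = as.integer(test_size)),
            class = "detector_config")
}

# -- architecture spec constructors -----------------------------------------

spec_cbs <- function(cin, cout, k, stride, act = "silu") {
  list(type = "cbs", cin = cin, cout = cout, k = k, stride = stride,
       act = act)
}

spec_pred <- function(cin, cout) list(type = "pred", cin = cin, cout = cout)

spec_seq <- function(...) list(type = "seq", mods = list(...))

spec_bottleneck <- function(c, shortcut) {
  list(type = "bottleneck", conv1 = spec_cbs(c, c, 1L, 1L),
       conv2 = spec_cbs(c, c, 3L, 1L), shortcut = shortcut)
}

spec_ca <- function(C, reduction, mid_min) {
  list(type = "ca", c = C, mid = max(mid_min, C %/% reduction))
}

spec_csp <- function(cin, cout, n, shortcut, variant = "plain", ca = NULL) {
  hidden <- cout %/% 2L
  units <- if (variant == "ca2") {
    list()
  } else {
    lapply(seq_len(n), function(i) spec_bottleneck(hidden, shortcut))
  }
  camod <- if (variant %in% c("ca1", "ca2")) {
    spec_ca(hidden, ca$reduction, ca$mid_min)
  } else {
    NULL
  }
  list(type = "csp", conv1 = spec_cbs(cin, hidden, 1L, 1L),
       conv2 = spec_cbs(cin, hidden, 1L, 1L),
       conv3 = spec_cbs(2L * hidden, cout, 1L, 1L),
       units = units, ca = camod, variant = variant)
}

spec_spp <- function(cin, cout, ks = c(5L, 9L, 13L)) {
  hidden <- cin %/% 2L
  list(type = "spp", conv1 = spec_cbs(cin, hidden, 1L, 1L),
       conv2 = spec_cbs(hidden * (length(ks) + 1L), cout, 1L, 1L), ks = ks)
}

spec_focus <- function(cout) {
  list(type = "focus", conv = spec_cbs(12L, cout, 3L, 1L))
}

build_spec <- function(cfg) {
  ch <- function(x) max(1L, as.integer(x * cfg$width_mult))
  bd <- max(as.integer(round(3 * cfg$depth_mult)), 1L)
  ca <- list(reduction = cfg$ca_reduction, mid_min = cfg$ca_mid_min)
  mk_csp <- function(cin, cout, n, shortcut, stage) {
    variant <- "plain"
    if (cfg$use_ca &&
        (stage == "backbone" || cfg$ca_placement == "backbone_neck")) {
      variant <- if (shortcut) "ca1" else "ca2"
    }
    spec_csp(cin, cout, n, shortcut, variant, ca)
  }
  base <- ch(64)
  backbone <- list(
    stem = spec_focus(base),
    dark2 = spec_seq(spec_cbs(base, ch(128), 3L, 2L),
                     mk_csp(ch(128), ch(128), bd, TRUE, "backbone")),
    dark3 = spec_seq(spec_cbs(ch(128), ch(256), 3L, 2L),
                     mk_csp(ch(256), ch(256), bd * 3L, TRUE, "backbone")),
    dark4 = spec_seq(spec_cbs(ch(256), ch(512), 3L, 2L),
                     mk_csp(ch(512), ch(512), bd * 3L, TRUE, "backbone")),
    dark5 = spec_seq(spec_cbs(ch(512), ch(1024), 3L, 2L),
                     spec_spp(ch(1024), ch(1024)),
                     mk_csp(ch(1024), ch(1024), bd, FALSE, "backbone"))
  )
  c256 <- ch(256)
  c512 <- ch(512)
  c1024 <- ch(1024)
  neck <- list(
    lateral0 = spec_cbs(c1024, c512, 1L, 1L),
    c3_p4 = mk_csp(2L * c512, c512, bd, FALSE, "neck"),
    reduce1 = spec_cbs(c512, c256, 1L, 1L),
    c3_p3 = mk_csp(2L * c256, c256, bd, FALSE, "neck"),
    bu2 = spec_cbs(c256, c256, 3L, 2L),
    c3_n3 = mk_csp(2L * c256, c512, bd, FALSE, "neck"),
    bu1 = spec_cbs(c512, c512, 3L, 2L),
    c3_n4 = mk_csp(2L * c512, c1024, bd, FALSE, "neck")
  )
  hc <- c256
  head <- lapply(c(c256, c512, c1024), function(cin) {
    list(stem = spec_cbs(cin, hc, 1L, 1L),
         cls_branch = spec_seq(spec_cbs(hc, hc, 3L, 1L),
                               spec_cbs(hc, hc, 3L, 1L)),
         reg_branch = spec_seq(spec_cbs(hc, hc, 3L, 1L),
                               spec_cbs(hc, hc, 3L, 1L)),
         cls_pred = spec_pred(hc, cfg$num_classes),
         reg_pred = spec_pred(hc, 4L),
         obj_pred = spec_pred(hc, 1L))
  })
  list(backbone = backbone, neck = neck, head = head)
}

# Named list of parameter shapes for any spec subtree.
spec_shapes <- function(spec, path = "") {
  if (is.null(spec)) return(list())
  p <- function(nm) if (nzchar(path)) paste(path, nm, sep = ".") else nm
  if (!is.null(spec$type)) {
    switch(spec$type,
      cbs = {
        out <- list()
        out[[p("w")]] <- c(spec$cout, spec$k * spec$k * spec$cin)
        out[[p("bn_g")]] <- spec$cout
        out[[p("bn_b")]] <- spec$cout
        out
      },
      pred = {
        out <- list()
        out[[p("w")]] <- c(spec$cout, spec$cin)
        out[[p("b")]] <- spec$cout
        out
      },
      ca = {
        out <- list()
        out[[p("w1")]] <- c(spec$mid, spec$c)
        out[[p("b1")]] <- spec$mid
        out[[p("bn_g")]] <- spec$mid
        out[[p("bn_b")]] <- spec$mid
        out[[p("wh")]] <- c(spec$c, spec$mid)
        out[[p("bh")]] <- spec$c
        out[[p("ww")]] <- c(spec$c, spec$mid)
        out[[p("bw")]] <- spec$c
        out
      },
      seq = {
        res <- list()
        for (i in seq_along(spec$mods)) {
          res <- c(res, spec_shapes(spec$mods[[i]], p(paste0("m", i))))
        }
        res
      },
      bottleneck = c(spec_shapes(spec$conv1, p("conv1")),
                     spec_shapes(spec$conv2, p("conv2"))),
      csp = {
        res <- c(spec_shapes(spec$conv1, p("conv1")),
                 spec_shapes(spec$conv2, p("conv2")),
                 spec_shapes(spec$conv3, p("conv3")))
        if (!is.null(spec$ca)) res <- c(res, spec_shapes(spec$ca, p("ca")))
        for (i in seq_along(spec$units)) {
          res <- c(res, spec_shapes(spec$units[[i]], p(paste0("u", i))))
        }
        res
      },
      spp = c(spec_shapes(spec$conv1, p("conv1")),
              spec_shapes(spec$conv2, p("conv2"))),
      focus = spec_shapes(spec$conv, p("conv")),
      stop_uwv("unknown spec type ", spec$type)
    )
  } else {
    res <- list()
    for (nm in names(spec)) {
      res <- c(res, spec_shapes(spec[[nm]], p(nm)))
    }
    res
  }
}

#' Build a detector
#'
#' Constructs the architecture description; weights are materialized
#' lazily by [init_detector_weights()] (parameter counting does not need
#' them).
#'
#' @param cfg A [detector_config()].
#' @return An object of class `uwv_detector`.
#' @export
build_detector <- function(cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  spec <- build_spec(cfg)
  shapes <- c(spec_shapes(spec$backbone, "backbone"),
              spec_shapes(spec$neck, "neck"))
  for (i in seq_along(spec$head)) {
    shapes <- c(shapes, spec_shapes(spec$head[[i]], paste0("head", i)))
  }
  structure(list(cfg = cfg, spec = spec, shapes = shapes, params = NULL),
            class = "uwv_detector")
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution kernels, biases and
#' normalization affine terms), a pure function of the configuration.
#'
#' @param detector A `uwv_detector`.
#' @return Integer-valued parameter count (as double to avoid overflow).
#' @export
count_parameters <- function(detector) {
  stopifnot(inherits(detector, "uwv_detector"))
  sum(vapply(detector$shapes, prod, 0))
}

#' @export
print.uwv_detector <- function(x, ...) {
  cat(sprintf(
    "<uwv_detector: depth %.2f, width %.2f, %d classes, CA %s, %.2f M parameters%s>\n",
    x$cfg$depth_mult, x$cfg$width_mult, x$cfg$num_classes,
    if (x$cfg$use_ca) "on" else "off", count_parameters(x) / 1e6,
    if (is.null(x$params)) " (weights not initialized)" else ""))
  invisible(x)
}

#' Initialize detector weights
#'
#' He-style random initialization, deterministic for a fixed seed.  The
#' objectness and classification prediction biases start at the logit of a
#' 1% prior so early training is not swamped by background terms.
#'
#' @param detector A `uwv_detector`.
#' @param seed Integer seed.
#' @return The detector with `$params` filled.
#' @export
init_detector_weights <- function(detector, seed = 0L) {
  stopifnot(inherits(detector, "uwv_detector"))
  prior_bias <- -log((1 - 0.01) / 0.01)
  with_seed(seed, {
    params <- lapply(seq_along(detector$shapes), function(i) {
      shp <- detector$shapes[[i]]
      nm <- names(detector$shapes)[i]
      leaf <- sub(".*\\.", "", nm)
      if (length(shp) == 2L) {
        matrix(stats::rnorm(prod(shp), 0, sqrt(2 / shp[2L])), shp[1L], shp[2L])
      } else if (leaf == "bn_g") {
        rep(1, shp)
      } else if (leaf == "b" && grepl("(cls|obj)_pred", nm)) {
        rep(prior_bias, shp)
      } else {
        rep(0, shp)
      }
    })
    names(params) <- names(detector$shapes)
    detector$params <- params
  })
  detector
}

# -- forward pass -----------------------------------------------------------

fwd_spec <- function(spec, x, P, path) {
  g <- function(nm) {
    v <- P[[paste(path, nm, sep = ".")]]
    if (is.null(v)) stop_uwv("missing parameter ", paste(path, nm, sep = "."))
    v
  }
  switch(spec$type,
    cbs = {
      y <- ad_conv2d(x, g("w"), NULL, k = spec$k, stride = spec$stride)
      y <- ad_batchnorm(y, g("bn_g"), g("bn_b"))
      switch(spec$act, silu = ad_silu(y), none = y,
             stop_uwv("unknown activation ", spec$act))
    },
    pred = ad_conv2d(x, g("w"), g("b"), k = 1L, stride = 1L),
    seq = {
      for (i in seq_along(spec$mods)) {
        x <- fwd_spec(spec$mods[[i]], x, P, paste(path, paste0("m", i),
                                                  sep = "."))
      }
      x
    },
    bottleneck = {
      y <- fwd_spec(spec$conv1, x, P, paste(path, "conv1", sep = "."))
      y <- fwd_spec(spec$conv2, y, P, paste(path, "conv2", sep = "."))
      if (spec$shortcut) y + x else y
    },
    csp = {
      t <- fwd_spec(spec$conv1, x, P, paste(path, "conv1", sep = "."))
      if (!is.null(spec$ca)) {
        t <- fwd_spec(spec$ca, t, P, paste(path, "ca", sep = "."))
      }
      for (i in seq_along(spec$units)) {
        t <- fwd_spec(spec$units[[i]], t, P, paste(path, paste0("u", i),
                                                   sep = "."))
      }
      r <- fwd_spec(spec$conv2, x, P, paste(path, "conv2", sep = "."))
      fwd_spec(spec$conv3, ad_concat_c(list(t, r)), P,
               paste(path, "conv3", sep = "."))
    },
    spp = {
      y <- fwd_spec(spec$conv1, x, P, paste(path, "conv1", sep = "."))
      pools <- lapply(spec$ks, function(k) ad_maxpool_same(y, k))
      fwd_spec(spec$conv2, ad_concat_c(c(list(y), pools)), P,
               paste(path, "conv2", sep = "."))
    },
    focus = {
      y <- ad_concat_c(list(ad_subsample2(x, 1L, 1L),
                            ad_subsample2(x, 2L, 1L),
                            ad_subsample2(x, 1L, 2L),
                            ad_subsample2(x, 2L, 2L)))
      fwd_spec(spec$conv, y, P, paste(path, "conv", sep = "."))
    },
    ca = {
      d <- dim(vof(x))
      H <- d[1L]
      W <- d[2L]
      ph <- ad_pool_rows(x)                       # (H,1,C)
      pw <- ad_transpose_hw(ad_pool_cols(x))      # (W,1,C)
      z <- ad_stack_hw(ph, pw)                    # (H+W,1,C)
      z <- ad_conv2d(z, g("w1"), g("b1"), k = 1L, stride = 1L)
      z <- ad_batchnorm(z, g("bn_g"), g("bn_b"))
      z <- ad_hardswish(z)
      zh <- ad_rows(z, 1L, H)
      zw <- ad_rows(z, H + 1L, H + W)
      gh <- ad_sigmoid(ad_conv2d(zh, g("wh"), g("bh"), k = 1L, stride = 1L))
      gw <- ad_sigmoid(ad_conv2d(ad_transpose_hw(zw), g("ww"), g("bw"),
                                 k = 1L, stride = 1L))
      ad_gate_mul(x, gh, gw)
    },
    stop_uwv("unknown spec type ", spec$type)
  )
}

# Full forward pass on one (H, W, 3) frame scaled to [0, 1].  P is a named
# list of weights (plain arrays or adnodes).  Returns per-level raw head
# outputs: list of list(reg, obj, cls).
forward_detector <- function(detector, x, P = detector$params) {
  if (is.null(P)) stop_uwv("detector weights not initialized")
  sp <- detector$spec
  s <- fwd_spec(sp$backbone$stem, x, P, "backbone.stem")
  d2 <- fwd_spec(sp$backbone$dark2, s, P, "backbone.dark2")
  c3 <- fwd_spec(sp$backbone$dark3, d2, P, "backbone.dark3")
  c4 <- fwd_spec(sp$backbone$dark4, c3, P, "backbone.dark4")
  c5 <- fwd_spec(sp$backbone$dark5, c4, P, "backbone.dark5")
  p5 <- fwd_spec(sp$neck$lateral0, c5, P, "neck.lateral0")
  f0 <- fwd_spec(sp$neck$c3_p4, ad_concat_c(list(ad_upsample2(p5), c4)),
                 P, "neck.c3_p4")
  p4 <- fwd_spec(sp$neck$reduce1, f0, P, "neck.reduce1")
  out2 <- fwd_spec(sp$neck$c3_p3, ad_concat_c(list(ad_upsample2(p4), c3)),
                   P, "neck.c3_p3")
  out1 <- fwd_spec(sp$neck$c3_n3,
                   ad_concat_c(list(fwd_spec(sp$neck$bu2, out2, P,
                                             "neck.bu2"), p4)),
                   P, "neck.c3_n3")
  out0 <- fwd_spec(sp$neck$c3_n4,
                   ad_concat_c(list(fwd_spec(sp$neck$bu1, out1, P,
                                             "neck.bu1"), p5)),
                   P, "neck.c3_n4")
  feats <- list(out2, out1, out0)
  lapply(seq_along(feats), function(i) {
    hp <- paste0("head", i)
    hs <- detector$spec$head[[i]]
    st <- fwd_spec(hs$stem, feats[[i]], P, paste(hp, "stem", sep = "."))
    cb <- fwd_spec(hs$cls_branch, st, P, paste(hp, "cls_branch", sep = "."))
    rb <- fwd_spec(hs$reg_branch, st, P, paste(hp, "reg_branch", sep = "."))
    list(reg = fwd_spec(hs$reg_pred, rb, P, paste(hp, "reg_pred", sep = ".")),
         obj = fwd_spec(hs$obj_pred, rb, P, paste(hp, "obj_pred", sep = ".")),
         cls = fwd_spec(hs$cls_pred, cb, P, paste(hp, "cls_pred", sep = ".")))
  })
}

# Decode raw level outputs (plain arrays) to a detection matrix in input
# pixel coordinates: center = (grid + offset) * stride, size =
# exp(pred) * stride, score = sigmoid(obj) * sigmoid(cls).
decode_outputs <- function(outputs, strides) {
  rows <- lapply(seq_along(outputs), function(l) {
    o <- outputs[[l]]
    s <- strides[l]
    d <- dim(o$reg)
    Ho <- d[1L]
    Wo <- d[2L]
    gx <- matrix(rep(seq_len(Wo) - 1L, each = Ho), Ho, Wo)
    gy <- matrix(rep(seq_len(Ho) - 1L, times = Wo), Ho, Wo)
    cx <- (as.vector(gx) + as.vector(o$reg[, , 1L])) * s
    cy <- (as.vector(gy) + as.vector(o$reg[, , 2L])) * s
    w <- exp(as.vector(o$reg[, , 3L])) * s
    h <- exp(as.vector(o$reg[, , 4L])) * s
    obj <- stats::plogis(as.vector(o$obj[, , 1L]))
    ncls <- dim(o$cls)[3L]
    cls <- matrix(stats::plogis(as.vector(o$cls)), Ho * Wo, ncls)
    cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2,
          y2 = cy + h / 2, obj = obj, cls)
  })
  do.call(rbind, rows)
}

#' Greedy non-maximum suppression
#'
#' Keeps boxes in descending score order, discarding any box whose IOU
#' with an already-kept box exceeds `thr`.
#'
#' @param boxes n x 4 box matrix.
#' @param scores Length-n scores.
#' @param thr IOU threshold.
#' @return Integer indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, thr = 0.5) {
  o <- order(-scores)
  keep <- integer()
  while (length(o) > 0L) {
    i <- o[1L]
    keep <- c(keep, i)
    o <- o[-1L]
    if (length(o) > 0L) {
      ious <- box_iou(matrix(boxes[i, ], length(o), 4L, byrow = TRUE),
                      boxes[o, , drop = FALSE])
      o <- o[ious <= thr]
    }
  }
  keep
}

# bilinear resize of one channel matrix
resize_bilinear <- function(m, new_h, new_w) {
  H <- nrow(m)
  W <- ncol(m)
  if (new_h == H && new_w == W) return(m)
  ry <- (seq_len(new_h) - 0.5) * H / new_h - 0.5
  rx <- (seq_len(new_w) - 0.5) * W / new_w - 0.5
  y0 <- pmin(pmax(floor(ry), 0), H - 1)
  x0 <- pmin(pmax(floor(rx), 0), W - 1)
  y1 <- pmin(y0 + 1, H - 1)
  x1 <- pmin(x0 + 1, W - 1)
  fy <- pmin(pmax(ry - y0, 0), 1)
  fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  cc <- m[y1 + 1, x0 + 1, drop = FALSE]
  d <- m[y1 + 1, x1 + 1, drop = FALSE]
  FY <- matrix(fy, new_h, new_w)
  FX <- matrix(fx, new_h, new_w, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + cc * FY * (1 - FX) +
    d * FY * FX
}

# aspect-preserving letterbox to a square canvas, gray padding 114
letterbox_frame <- function(frame, size) {
  H <- dim(frame)[1L]
  W <- dim(frame)[2L]
  r <- min(size / H, size / W)
  nh <- max(1L, round(H * r))
  nw <- max(1L, round(W * r))
  canvas <- array(114, c(size, size, 3L))
  for (ch in 1:3) {
    canvas[seq_len(nh), seq_len(nw), ch] <-
      resize_bilinear(frame[, , ch], nh, nw)
  }
  list(canvas = canvas, scale = r)
}

#' Run the detector on a clip
#'
#' Each frame is letterboxed to `test_size`, passed through the network,
#' decoded to boxes in original pixel coordinates, thresholded at
#' `score_thr` (score = objectness x class probability) and filtered with
#' per-class NMS at `nms_thr`.
#'
#' @param detector An initialized `uwv_detector`.
#' @param clip A [video_clip()].
#' @param score_thr,nms_thr,test_size Optional overrides of the detector
#'   configuration.
#' @return Detection data frame sorted by frame and descending score.
#' @export
detect_frames <- function(detector, clip, score_thr = NULL, nms_thr = NULL,
                          test_size = NULL) {
  stopifnot(inherits(detector, "uwv_detector"), inherits(clip, "video_clip"))
  score_thr <- score_thr %||% detector$cfg$score_thr
  nms_thr <- nms_thr %||% detector$cfg$nms_thr
  test_size <- test_size %||% detector$cfg$test_size
  out <- detection_records()
  for (i in seq_len(n_frames(clip))) {
    lb <- letterbox_frame(clip$frames[[i]], test_size)
    preds <- forward_detector(detector, lb$canvas / 255)
    dec <- decode_outputs(preds, detector$cfg$strides)
    ncls <- detector$cfg$num_classes
    for (cl in seq_len(ncls) - 1L) {
      sc <- dec[, "obj"] * dec[, 5L + cl + 1L]
      sel <- which(sc >= score_thr)
      if (length(sel) == 0L) next
      boxes <- dec[sel, 1:4, drop = FALSE] / lb$scale
      keep <- nms(boxes, sc[sel], nms_thr)
      H <- dim(clip$frames[[i]])[1L]
      W <- dim(clip$frames[[i]])[2L]
      out <- rbind(out, data.frame(
        frame = clip$frame_indices[i], class_id = cl,
        score = sc[sel][keep],
        x1 = pmin(pmax(boxes[keep, 1L], 0), W),
        y1 = pmin(pmax(boxes[keep, 2L], 0), H),
        x2 = pmin(pmax(boxes[keep, 3L], 0), W),
        y2 = pmin(pmax(boxes[keep, 4L], 0), H)
      ))
    }
  }
  out <- out[order(out$frame, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  validate_detections(out)
  out
}
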
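# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# The detector's forward pass is written against the ad_* operations below.
# Each operation accepts either plain numeric arrays (inference: no tape, no
# recording overhead beyond the arithmetic itself) or "adnode" tracked values
# (training: every op appends itself to the active tape and stores a closure
# computing vector-Jacobian products for its parents).  Feature maps are
# numeric arrays with dim (H, W, C); elementwise ops also handle vectors.

.adenv <- new.env(parent = emptyenv())
.adenv$tape <- NULL

ad_tape_begin <- function() {
  .adenv$tape <- new.env(parent = emptyenv())
  .adenv$tape$nodes <- vector("list", 256L)
  .adenv$tape$n <- 0L
  invisible(.adenv$tape)
}

ad_tape_end <- function() {
  .adenv$tape <- NULL
  invisible(NULL)
}

is_nd <- function(x) inherits(x, "adnode")
vof <- function(x) if (is_nd(x)) x$value else x

# Create a tracked node and record it on the active tape.
mk_node <- function(value, parents, backfn) {
  tape <- .adenv$tape
  if (is.null(tape)) {
    stop_uwv("autodiff op on tracked values outside an active tape")
  }
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  class(nd) <- "adnode"
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Leaf parameter: tracked, receives gradients, not produced by any op.
ad_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- list()
  nd$backfn <- NULL
  nd$grad <- NULL
  class(nd) <- "adnode"
  nd
}

# Reverse sweep from a scalar node; gradients accumulate in node$grad.
ad_backward <- function(node) {
  tape <- .adenv$tape
  if (is.null(tape)) stop_uwv("ad_backward requires an active tape")
  node$grad <- array(1, dim = if (is.null(dim(node$value))) length(node$value) else dim(node$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!is_nd(p)) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(node)
}

# Reduce a gradient for a broadcast scalar operand.
bcast_sum <- function(g, v) if (length(v) == 1L && length(g) > 1L) sum(g) else g

#' @export
Ops.adnode <- function(e1, e2) {
  if (missing(e2)) {
    v <- vof(e1)
    return(switch(.Generic,
      "+" = e1,
      "-" = mk_node(-v, list(e1), function(g) list(-g)),
      stop_uwv("unsupported unary op on adnode: ", .Generic)
    ))
  }
  v1 <- vof(e1)
  v2 <- vof(e2)
  n1 <- is_nd(e1)
  n2 <- is_nd(e2)
  bin <- function(val, d1, d2) {
    mk_node(val, list(e1, e2), function(g) {
      list(if (n1) bcast_sum(d1(g), v1) else NULL,
           if (n2) bcast_sum(d2(g), v2) else NULL)
    })
  }
  switch(.Generic,
    "+" = bin(v1 + v2, function(g) g, function(g) g),
    "-" = bin(v1 - v2, function(g) g, function(g) -g),
    "*" = bin(v1 * v2, function(g) g * v2, function(g) g * v1),
    "/" = bin(v1 / v2, function(g) g / v2,
              function(g) -g * v1 / (v2 * v2)),
    "^" = bin(v1^v2, function(g) g * v2 * v1^(v2 - 1),
              function(g) g * v1^v2 * log(v1)),
    ">" = v1 > v2, ">=" = v1 >= v2, "<" = v1 < v2, "<=" = v1 <= v2,
    "==" = v1 == v2, "!=" = v1 != v2,
    stop_uwv("unsupported op on adnode: ", .Generic)
  )
}

#' @export
Math.adnode <- function(x, ...) {
  v <- vof(x)
  switch(.Generic,
    exp = mk_node(exp(v), list(x), function(g) list(g * exp(v))),
    log = {
      extra <- list(...)
      if (length(extra) > 0L) {
        b <- extra[[1L]]
        mk_node(log(v, b), list(x), function(g) list(g / (v * log(b))))
      } else {
        mk_node(log(v), list(x), function(g) list(g / v))
      }
    },
    sqrt = mk_node(sqrt(v), list(x), function(g) list(g * 0.5 / sqrt(v))),
    atan = mk_node(atan(v), list(x), function(g) list(g / (1 + v * v))),
    abs = mk_node(abs(v), list(x), function(g) list(g * sign(v))),
    stop_uwv("unsupported math op on adnode: ", .Generic)
  )
}

# Dispatching helpers usable on plain numerics and nodes alike; the node
# branch builds the subgradient as mask arithmetic so no new primitive is
# needed.  Ties take the first argument.
nv_max <- function(a, b) {
  if (is_nd(a) || is_nd(b)) {
    m <- (vof(a) >= vof(b)) * 1
    m * a + (1 - m) * b
  } else {
    pmax(a, b)
  }
}

nv_min <- function(a, b) {
  if (is_nd(a) || is_nd(b)) {
    m <- (vof(a) <= vof(b)) * 1
    m * a + (1 - m) * b
  } else {
    pmin(a, b)
  }
}

nv_clamp <- function(x, lo, hi) nv_min(nv_max(x, lo), hi)

nv_sum <- function(x) if (is_nd(x)) ad_sum(x) else sum(x)

nv_mean <- function(x) if (is_nd(x)) ad_sum(x) / length(vof(x)) else mean(x)

ad_sum <- function(x) {
  v <- vof(x)
  if (!is_nd(x)) return(sum(v))
  mk_node(sum(v), list(x), function(g) {
    list(array(as.numeric(g), dim = dim(v) %||% length(v)))
  })
}

# Element selection from a vector node (duplicate indices accumulate).
ad_gather <- function(x, idx) {
  v <- vof(x)
  if (!is_nd(x)) return(v[idx])
  mk_node(v[idx], list(x), function(g) {
    d <- numeric(length(v))
    s <- rowsum(as.numeric(g), group = idx)
    d[as.integer(rownames(s))] <- s
    list(d)
  })
}

ad_flatten <- function(x) {
  v <- vof(x)
  if (!is_nd(x)) return(as.vector(v))
  d <- dim(v)
  mk_node(as.vector(v), list(x), function(g) list(array(g, d)))
}

ad_sigmoid <- function(x) {
  v <- vof(x)
  s <- stats::plogis(v)
  if (!is_nd(x)) return(s)
  mk_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_silu <- function(x) {
  v <- vof(x)
  s <- stats::plogis(v)
  y <- v * s
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) list(g * s * (1 + v * (1 - s))))
}

ad_hardswish <- function(x) {
  v <- vof(x)
  r6 <- pmin(pmax(v + 3, 0), 6)
  y <- v * r6 / 6
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    dv <- ifelse(v <= -3, 0, ifelse(v >= 3, 1, (2 * v + 3) / 6))
    list(g * dv)
  })
}

# -- spatial ops on (H, W, C) arrays ----------------------------------------

# 2-D convolution via im2col; w is (Cout, k*k*Cin), optional bias length Cout.
ad_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = k %/% 2L) {
  xv <- vof(x)
  wv <- vof(w)
  bv <- if (is.null(b)) NULL else vof(b)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  Cout <- nrow(wv)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, c(Hp, Wp, C))
    xp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), ] <- xv
  } else {
    xp <- xv
  }
  cols <- matrix(0, k * k * C, Ho * Wo)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      ri <- di + (seq_len(Ho) - 1L) * stride
      ci <- dj + (seq_len(Wo) - 1L) * stride
      blk <- xp[ri, ci, , drop = FALSE]
      rows <- (seq_len(C) - 1L) * (k * k) + (dj - 1L) * k + di
      cols[rows, ] <- t(matrix(blk, Ho * Wo, C))
    }
  }
  y <- wv %*% cols
  if (!is.null(bv)) y <- y + bv
  out <- array(t(y), c(Ho, Wo, Cout))
  if (!is_nd(x) && !is_nd(w) && !is_nd(b)) return(out)
  mk_node(out, list(x, w, b), function(g) {
    gm <- t(matrix(g, Ho * Wo, Cout))
    dW <- gm %*% t(cols)
    db <- if (is.null(bv)) NULL else rowSums(gm)
    dcols <- crossprod(wv, gm)
    dxp <- array(0, c(Hp, Wp, C))
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        ri <- di + (seq_len(Ho) - 1L) * stride
        ci <- dj + (seq_len(Wo) - 1L) * stride
        rows <- (seq_len(C) - 1L) * (k * k) + (dj - 1L) * k + di
        dxp[ri, ci, ] <- dxp[ri, ci, , drop = FALSE] +
          array(t(dcols[rows, , drop = FALSE]), c(Ho, Wo, C))
      }
    }
    dx <- if (pad > 0L) {
      dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
    } else {
      dxp
    }
    list(dx, dW, db)
  })
}

# Train-mode batch normalization over the spatial extent of one image.
ad_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vof(x)
  gv <- vof(gamma)
  bv <- vof(beta)
  d <- dim(xv)
  m <- d[1L] * d[2L]
  C <- d[3L]
  xm <- matrix(xv, m, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, istd, `*`)
  y <- array(sweep(sweep(xh, 2L, gv, `*`), 2L, bv, `+`), d)
  if (!is_nd(x) && !is_nd(gamma) && !is_nd(beta)) return(y)
  mk_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, C)
    dg <- colSums(gm * xh)
    db <- colSums(gm)
    dxh <- sweep(gm, 2L, gv, `*`)
    s1 <- colSums(dxh)
    s2 <- colSums(dxh * xh)
    dx <- sweep(dxh, 2L, s1 / m) - sweep(xh, 2L, s2 / m, `*`)
    dx <- sweep(dx, 2L, istd, `*`)
    list(array(dx, d), dg, db)
  })
}

# Max pooling with stride 1 and "same" output size (spatial pyramid pooling).
ad_maxpool_same <- function(x, k) {
  xv <- vof(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  p <- k %/% 2L
  xp <- array(-Inf, c(H + 2L * p, W + 2L * p, C))
  xp[(p + 1L):(p + H), (p + 1L):(p + W), ] <- xv
  best <- array(-Inf, d)
  win <- array(0L, d)
  t <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      t <- t + 1L
      blk <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE]
      upd <- blk > best
      best[upd] <- blk[upd]
      win[upd] <- t
    }
  }
  if (!is_nd(x)) return(best)
  mk_node(best, list(x), function(g) {
    dxp <- array(0, c(H + 2L * p, W + 2L * p, C))
    t <- 0L
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        t <- t + 1L
        mask <- win == t
        if (any(mask)) {
          gg <- array(0, d)
          gg[mask] <- g[mask]
          dxp[di:(di + H - 1L), dj:(dj + W - 1L), ] <-
            dxp[di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE] + gg
        }
      }
    }
    list(dxp[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE])
  })
}

# Nearest-neighbour 2x upsampling.
ad_upsample2 <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]
  y <- xv[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    d1 <- g[seq(1L, 2L * H, 2L), , , drop = FALSE] +
      g[seq(2L, 2L * H, 2L), , , drop = FALSE]
    dx <- d1[, seq(1L, 2L * W, 2L), , drop = FALSE] +
      d1[, seq(2L, 2L * W, 2L), , drop = FALSE]
    list(dx)
  })
}

# Channel concatenation.
ad_concat_c <- function(xs) {
  vs <- lapply(xs, vof)
  d1 <- dim(vs[[1L]])
  cs <- vapply(vs, function(v) dim(v)[3L], 0L)
  out <- array(unlist(vs, use.names = FALSE), c(d1[1L], d1[2L], sum(cs)))
  if (!any(vapply(xs, is_nd, TRUE))) return(out)
  mk_node(out, xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- g[, , (off + 1L):(off + cs[i]), drop = FALSE]
      off <<- off + cs[i]
      gi
    })
  })
}

# Every-other-pixel subsampling starting at (roff, coff); used by the
# space-to-depth stem.
ad_subsample2 <- function(x, roff, coff) {
  xv <- vof(x)
  d <- dim(xv)
  ri <- seq(roff, d[1L], 2L)
  ci <- seq(coff, d[2L], 2L)
  y <- xv[ri, ci, , drop = FALSE]
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    dx <- array(0, d)
    dx[ri, ci, ] <- g
    list(dx)
  })
}

# Mean over columns (per-row pooling): (H, W, C) -> (H, 1, C).
ad_pool_rows <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  m <- apply(xv, c(1L, 3L), mean)
  y <- array(m, c(H, 1L, C))
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    gm <- array(g, c(H, C)) / W
    list(aperm(array(gm, c(H, C, W)), c(1L, 3L, 2L)))
  })
}

# Mean over rows (per-column pooling): (H, W, C) -> (1, W, C).
ad_pool_cols <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  m <- apply(xv, c(2L, 3L), mean)
  y <- array(m, c(1L, W, C))
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    gm <- array(g, c(W, C)) / H
    list(aperm(array(gm, c(W, C, H)), c(3L, 1L, 2L)))
  })
}

# Stack two (len, 1, C) columns along the spatial axis into
# (len_a + len_b, 1, C).
ad_stack_hw <- function(a, b) {
  va <- vof(a)
  vb <- vof(b)
  H <- dim(va)[1L]; W <- dim(vb)[1L]; C <- dim(va)[3L]
  y <- array(rbind(array(va, c(H, C)), array(vb, c(W, C))), c(H + W, 1L, C))
  if (!is_nd(a) && !is_nd(b)) return(y)
  mk_node(y, list(a, b), function(g) {
    gm <- array(g, c(H + W, C))
    list(array(gm[seq_len(H), , drop = FALSE], c(H, 1L, C)),
         array(gm[(H + 1L):(H + W), , drop = FALSE], c(W, 1L, C)))
  })
}

# Row slice keeping (len, 1, C) shape.
ad_rows <- function(x, from, to) {
  xv <- vof(x)
  d <- dim(xv)
  y <- xv[from:to, , , drop = FALSE]
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) {
    dx <- array(0, d)
    dx[from:to, , ] <- g
    list(dx)
  })
}

ad_transpose_hw <- function(x) {
  xv <- vof(x)
  y <- aperm(xv, c(2L, 1L, 3L))
  if (!is_nd(x)) return(y)
  mk_node(y, list(x), function(g) list(aperm(g, c(2L, 1L, 3L))))
}

# Directional attention gating: out = x * gate_h * gate_w with gate_h of
# shape (H,1,C) broadcast over columns and gate_w of shape (1,W,C) broadcast
# over rows.
ad_gate_mul <- function(x, gh, gw) {
  xv <- vof(x)
  vh <- vof(gh)
  vw <- vof(gw)
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  GH <- aperm(array(array(vh, c(H, C)), c(H, C, W)), c(1L, 3L, 2L))
  GW <- aperm(array(array(vw, c(W, C)), c(W, C, H)), c(3L, 1L, 2L))
  y <- xv * GH * GW
  if (!is_nd(x) && !is_nd(gh) && !is_nd(gw)) return(y)
  mk_node(y, list(x, gh, gw), function(g) {
    dgh <- apply(g * xv * GW, c(1L, 3L), sum)
    dgw <- apply(g * xv * GH, c(2L, 3L), sum)
    list(g * GH * GW,
         array(dgh, c(H, 1L, C)),
         array(dgw, c(1L, W, C)))
  })
}
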
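# Contrast limited adaptive histogram equalization, applied independently
# to the R, G and B channel of every frame.
#
# Plain histogram equalization remaps level g through the normalized
# cumulative histogram: T(g) = round((cdf(g) - cdf_min) / (1 - cdf_min) *
# (L - 1)) with cdf_min the smallest nonzero cumulative value.  CLAHE
# computes this mapping per image tile on a clipped histogram (excess mass
# redistributed uniformly) and reconstructs each pixel by bilinear
# interpolation between the four nearest tile-center mappings, which keeps
# local contrast bounded and avoids tile seams.

#' CLAHE parameters
#'
#' @param tile_grid `c(rows, cols)` of non-overlapping tiles (default 8x8).
#' @param clip_limit Relative clip factor: the histogram ceiling is
#'   `clip_limit` times the uniform bin height of the tile (default 2;
#'   must be >= 1).
#' @param redistribute_iters Maximum clip-and-spread passes; residual
#'   excess after the last pass is spread uniformly and accepted.
#' @return A `clahe_params` list.
#' @export
clahe_params <- function(tile_grid = c(8L, 8L), clip_limit = 2,
                         redistribute_iters = 5L) {
  if (length(tile_grid) != 2L || any(tile_grid < 1L)) {
    stop_uwv("tile_grid must be two values >= 1")
  }
  if (clip_limit < 1) stop_uwv("clip_limit must be >= 1")
  structure(list(tile_grid = as.integer(tile_grid),
                 clip_limit = as.numeric(clip_limit),
                 redistribute_iters = as.integer(redistribute_iters)),
            class = "clahe_params")
}

# Level mapping 0..L-1 -> 0..L-1 from (possibly clipped, non-integer)
# histogram counts.
he_mapping <- function(counts, L = 256L) {
  n <- sum(counts)
  if (n <= 0) return(seq_len(L) - 1L)
  cdf <- cumsum(counts) / n
  nz <- cdf[cdf > 0]
  cdf_min <- nz[1L]
  if (1 - cdf_min < 1e-12) return(seq_len(L) - 1L)  # single-level tile
  out <- as.integer(round((cdf - cdf_min) / (1 - cdf_min) * (L - 1)))
  pmin(pmax(out, 0L), L - 1L)
}

#' Histogram equalization of one 8-bit channel
#'
#' @param channel Integer matrix with values 0..255.
#' @param L Number of gray levels.
#' @return Matrix of the same shape, remapped levels; monotone in the
#'   input level.  A constant channel is returned unchanged.
#' @export
histogram_equalize <- function(channel, L = 256L) {
  if (length(channel) == 0L) stop_uwv("empty channel")
  counts <- tabulate(as.integer(channel) + 1L, nbins = L)
  map <- he_mapping(counts, L)
  out <- map[as.integer(channel) + 1L]
  if (is.matrix(channel)) dim(out) <- dim(channel)
  out
}

#' Clip a histogram and redistribute the excess
#'
#' Counts above `ceiling` are cut and spread uniformly over all bins;
#' spreading can push bins back over the ceiling, so the clip-and-spread
#' pass repeats up to `iters` times.  The final pass's residual excess is
#' spread and accepted, so total mass is preserved exactly.
#'
#' @param hist Nonnegative counts per level.
#' @param ceiling Absolute per-bin ceiling (> 0).
#' @param iters Number of clip-and-spread passes.
#' @return Redistributed counts, `sum(out) == sum(hist)`.
#' @export
#' @examples
#' clip_redistribute(c(10, 0, 0, 2), 4, iters = 1) # 5.5 1.5 1.5 3.5
clip_redistribute <- function(hist, ceiling, iters = 1L) {
  if (ceiling <= 0) stop_uwv("ceiling must be > 0")
  if (any(hist < 0)) stop_uwv("histogram counts must be nonnegative")
  h <- as.numeric(hist)
  L <- length(h)
  for (i in seq_len(max(iters, 1L))) {
    excess <- sum(pmax(h - ceiling, 0))
    if (excess <= 0) break
    h <- pmin(h, ceiling) + excess / L
  }
  h
}

#' CLAHE on one 8-bit channel
#'
#' @param channel Integer matrix 0..255.
#' @param params A [clahe_params()] object.
#' @return Equalized integer matrix of the same shape.
#' @export
clahe_channel <- function(channel, params = clahe_params()) {
  if (!is.matrix(channel)) stop_uwv("channel must be a matrix")
  H <- nrow(channel)
  W <- ncol(channel)
  tr <- params$tile_grid[1L]
  tc <- params$tile_grid[2L]
  if (tr > H || tc > W) stop_uwv("tile grid larger than the image")
  L <- 256L
  # tile boundaries (as equal as possible)
  rb <- floor(seq(0L, H, length.out = tr + 1L))
  cb <- floor(seq(0L, W, length.out = tc + 1L))
  maps <- vector("list", tr * tc)
  rcent <- numeric(tr)
  ccent <- numeric(tc)
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      rows <- (rb[i] + 1L):rb[i + 1L]
      colsj <- (cb[j] + 1L):cb[j + 1L]
      tile <- channel[rows, colsj]
      counts <- tabulate(as.integer(tile) + 1L, nbins = L)
      if (max(counts) == length(tile)) {
        # single-level tile: equalization is undefined, keep the level
        maps[[(i - 1L) * tc + j]] <- seq_len(L) - 1L
        rcent[i] <- (rb[i] + rb[i + 1L] + 1) / 2
        ccent[j] <- (cb[j] + cb[j + 1L] + 1) / 2
        next
      }
      if (is.finite(params$clip_limit)) {
        ceiling_abs <- params$clip_limit * length(tile) / L
        counts <- clip_redistribute(counts, ceiling_abs,
                                    iters = params$redistribute_iters)
      }
      maps[[(i - 1L) * tc + j]] <- he_mapping(counts, L)
      rcent[i] <- (rb[i] + rb[i + 1L] + 1) / 2  # 1-based tile-center row
      ccent[j] <- (cb[j] + cb[j + 1L] + 1) / 2
    }
  }
  # bilinear interpolation between the 4 nearest tile-center mappings;
  # outside the outer centers the nearest mapping is used (constant
  # extrapolation)
  ri <- findInterval(seq_len(H), rcent)          # tile-center row below
  ci <- findInterval(seq_len(W), ccent)
  r0 <- pmin(pmax(ri, 1L), tr)
  r1 <- pmin(r0 + 1L, tr)
  r0 <- ifelse(ri < 1L, 1L, r0)
  wr <- ifelse(r1 == r0, 0,
               (seq_len(H) - rcent[r0]) / (rcent[r1] - rcent[r0]))
  wr <- pmin(pmax(wr, 0), 1)
  c0 <- pmin(pmax(ci, 1L), tc)
  c1 <- pmin(c0 + 1L, tc)
  wc <- ifelse(c1 == c0, 0,
               (seq_len(W) - ccent[c0]) / (ccent[c1] - ccent[c0]))
  wc <- pmin(pmax(wc, 0), 1)
  g1 <- as.integer(channel) + 1L
  dim(g1) <- c(H, W)
  out <- matrix(0, H, W)
  mapval <- function(i, j, g) maps[[(i - 1L) * tc + j]][g]
  for (i in sort(unique(r0))) {
    rows <- which(r0 == i)
    i1 <- r1[rows[1L]]
    for (j in sort(unique(c0))) {
      colsj <- which(c0 == j)
      j1 <- c1[colsj[1L]]
      g <- g1[rows, colsj, drop = FALSE]
      m00 <- mapval(i, j, g)
      m01 <- mapval(i, j1, g)
      m10 <- mapval(i1, j, g)
      m11 <- mapval(i1, j1, g)
      a <- wr[rows]
      b <- wc[colsj]
      A <- matrix(a, length(rows), length(colsj))
      B <- matrix(b, length(rows), length(colsj), byrow = TRUE)
      out[rows, colsj] <- (1 - A) * (1 - B) * m00 + (1 - A) * B * m01 +
        A * (1 - B) * m10 + A * B * m11
    }
  }
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}

#' Enhance a video clip with CLAHE
#'
#' CLAHE is applied independently to the R, G and B channel of every frame;
#' frame count, size and order are unchanged.
#'
#' @param clip A [video_clip()].
#' @param params A [clahe_params()] object.
#' @return The enhanced [video_clip()].
#' @export
enhance_video <- function(clip, params = clahe_params()) {
  stopifnot(inherits(clip, "video_clip"))
  frames <- vector("list", n_frames(clip))
  for (i in seq_along(clip$frames)) {
    f <- clip$frames[[i]]
    out <- array(0L, dim(f))
    for (ch in 1:3) {
      out[, , ch] <- tryCatch(
        clahe_channel(matrix(as.integer(f[, , ch]), dim(f)[1L], dim(f)[2L]),
                      params),
        error = function(e) stop_uwv("frame ", clip$frame_indices[i],
                                     ", channel ", ch, ": ",
                                     conditionMessage(e))
      )
    }
    frames[[i]] <- out
  }
  video_clip(frames, clip$frame_indices, clip$fps)
}
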
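# Media and annotation I/O.
#
# Coordinate conventions for the whole package are fixed here: frames are
# integer arrays of dim (H, W, 3) holding 8-bit R,G,B intensities 0..255;
# boxes are continuous 0-based half-open corners (x1, y1, x2, y2) so that
# w = x2 - x1.  Pascal VOC XML stores 1-based inclusive integer corners;
# the readers/writers below own the +-1 conversion and nothing else in the
# package touches it.

#' Construct a video clip
#'
#' A clip is an ordered list of same-sized 8-bit RGB frames with strictly
#' increasing 0-based frame indices; `fps` is carried as metadata only.
#'
#' @param frames List of integer arrays of dim `(H, W, 3)` with values in
#'   0..255.
#' @param frame_indices Integer vector, 0-based, strictly increasing.
#'   Defaults to `0:(T-1)`.
#' @param fps Frames per second (metadata).
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, frame_indices = NULL, fps = NA_real_) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_uwv("a clip needs at least one frame")
  }
  dims <- lapply(frames, dim)
  d1 <- dims[[1L]]
  if (is.null(d1) || length(d1) != 3L || d1[3L] != 3L) {
    stop_uwv("frames must be (H, W, 3) arrays")
  }
  if (!all(vapply(dims, identical, TRUE, d1))) {
    stop_uwv("all frames must share the same dimensions")
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1L] < 0 || rng[2L] > 255) {
    stop_uwv("frame intensities must lie in 0..255")
  }
  if (is.null(frame_indices)) frame_indices <- seq_along(frames) - 1L
  frame_indices <- as.integer(frame_indices)
  if (length(frame_indices) != length(frames) ||
      any(diff(frame_indices) <= 0L)) {
    stop_uwv("frame_indices must be strictly increasing, one per frame")
  }
  structure(list(frames = frames, frame_indices = frame_indices, fps = fps),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<video_clip: %d frames, %dx%d px, fps=%s>\n",
              length(x$frames), d[2L], d[1L], format(x$fps)))
  invisible(x)
}

#' Number of frames in a clip
#' @param x A `video_clip`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

frame_from_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3L] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]
  array(as.integer(round(px * 255)), dim(px))
}

#' Read a clip from a directory of frame images
#'
#' Frames are read in lexicographic filename order and indexed `0..T-1`.
#' PNG images are supported; 8-bit grayscale is replicated to RGB and any
#' alpha channel is dropped.
#'
#' @param path Directory containing the frame images.
#' @param fps Frames-per-second metadata to attach.
#' @return A [video_clip()].
#' @export
read_video_frames <- function(path, fps = NA_real_) {
  if (!dir.exists(path)) stop_uwv("no such frame directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop_uwv("no frame images found in ", path)
  frames <- lapply(files, function(f) {
    tryCatch(frame_from_png(f),
             error = function(e) stop_uwv("unreadable frame ", f, ": ",
                                          conditionMessage(e)))
  })
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop_uwv("mixed frame sizes in ", path)
  }
  video_clip(frames, fps = fps)
}

#' Write a clip as numbered PNG frames
#'
#' @param clip A [video_clip()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; files are `<prefix>_<index>.png` with
#'   zero-padded frame indices.
#' @return Invisibly, the written file paths.
#' @export
write_video_frames <- function(clip, dir, prefix = "frame") {
  stopifnot(inherits(clip, "video_clip"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(n_frames(clip))
  for (i in seq_len(n_frames(clip))) {
    p <- file.path(dir, sprintf("%s_%06d.png", prefix, clip$frame_indices[i]))
    png::writePNG(clip$frames[[i]] / 255, p)
    paths[i] <- p
  }
  invisible(paths)
}

voc_frame_index <- function(fname) {
  digits <- regmatches(fname, regexpr("[0-9]+", fname))
  if (length(digits) == 0L) stop_uwv("cannot infer frame index from ", fname)
  as.integer(digits)
}

#' Read Pascal VOC annotations for a clip
#'
#' One XML file per frame; the frame index is taken from the digits in the
#' filename.  VOC boxes are 1-based inclusive; they are converted to the
#' package's 0-based half-open convention (`x1 = xmin - 1`, `x2 = xmax`).
#' An optional `<trackid>` element per object (ImageNet-VID style) carries
#' track identity; objects without it get `NA`.
#'
#' @param dir Directory of per-frame VOC XML files.
#' @param classes Allowed class names; anything else is an error.
#' @return A data frame with columns `frame`, `class_name`, `track_id`,
#'   `x1`, `y1`, `x2`, `y2`.
#' @export
read_voc_annotations <- function(dir, classes = uwv_classes()) {
  if (!dir.exists(dir)) stop_uwv("no such annotation directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    doc <- tryCatch(xml2::read_xml(f),
                    error = function(e) stop_uwv("malformed XML in ", f, ": ",
                                                 conditionMessage(e)))
    objs <- xml2::xml_find_all(doc, ".//object")
    if (length(objs) == 0L) return(NULL)
    fidx <- voc_frame_index(basename(f))
    do.call(rbind, lapply(objs, function(o) {
      nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      if (!nm %in% classes) {
        stop_uwv("unknown class '", nm, "' in ", f,
                 "; allowed: ", paste(classes, collapse = ", "))
      }
      tid <- xml2::xml_find_first(o, "./trackid")
      tid <- if (length(tid) == 0L || is.na(xml2::xml_text(tid))) {
        NA_integer_
      } else {
        as.integer(xml2::xml_text(tid))
      }
      bb <- xml2::xml_find_first(o, "./bndbox")
      num <- function(tag) {
        as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
      }
      data.frame(frame = fidx, class_name = nm, track_id = tid,
                 x1 = num("xmin") - 1, y1 = num("ymin") - 1,
                 x2 = num("xmax"), y2 = num("ymax"))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), class_name = character(),
                      track_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Write Pascal VOC annotations
#'
#' Inverse of [read_voc_annotations()]: internal 0-based half-open boxes
#' become 1-based inclusive integer VOC boxes.  One XML file per frame.
#'
#' @param ann Annotation data frame (`frame`, `class_name`, `track_id`,
#'   `x1`, `y1`, `x2`, `y2`).
#' @param dir Output directory (created if missing).
#' @param image_size `c(width, height)` recorded in the XML `<size>` block.
#' @return Invisibly, the written file paths.
#' @export
write_voc_annotations <- function(ann, dir, image_size = c(0L, 0L)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- sort(unique(ann$frame))
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    sub <- ann[ann$frame == f, , drop = FALSE]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", sprintf("frame_%06d.png", f))
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(image_size[1L]))
    xml2::xml_add_child(sz, "height", as.character(image_size[2L]))
    for (i in seq_len(nrow(sub))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", sub$class_name[i])
      if (!is.na(sub$track_id[i])) {
        xml2::xml_add_child(o, "trackid", as.character(sub$track_id[i]))
      }
      bb <- xml2::xml_add_child(o, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(sub$x1[i] + 1)))
      xml2::xml_add_child(bb, "ymin", as.character(round(sub$y1[i] + 1)))
      xml2::xml_add_child(bb, "xmax", as.character(round(sub$x2[i])))
      xml2::xml_add_child(bb, "ymax", as.character(round(sub$y2[i])))
    }
    p <- file.path(dir, sprintf("frame_%06d.xml", f))
    xml2::write_xml(doc, p)
    paths[k] <- p
  }
  invisible(paths)
}

#' Construct a detection record table
#'
#' The currency between detector, post-processor and evaluator: one row per
#' detection with 0-based `frame`, 0-based integer `class_id`, `score` in
#' `[0, 1]` and a 0-based half-open box.
#'
#' @param frame Integer frame indices.
#' @param class_id Integer class ids, `0..n_classes-1`.
#' @param score Scores in `[0, 1]`.
#' @param x1,y1,x2,y2 Box corners.
#' @return A `data.frame` of detections.
#' @export
detection_records <- function(frame = integer(), class_id = integer(),
                              score = numeric(), x1 = numeric(),
                              y1 = numeric(), x2 = numeric(),
                              y2 = numeric()) {
  df <- data.frame(frame = as.integer(frame), class_id = as.integer(class_id),
                   score = as.numeric(score), x1 = as.numeric(x1),
                   y1 = as.numeric(y1), x2 = as.numeric(x2),
                   y2 = as.numeric(y2))
  validate_detections(df)
  df
}

validate_detections <- function(df) {
  need <- c("frame", "class_id", "score", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(df))) {
    stop_uwv("detections need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(df$score < 0 | df$score > 1)) {
      stop_uwv("detection scores must lie in [0, 1]")
    }
    if (any(df$x2 < df$x1) || any(df$y2 < df$y1)) {
      stop_uwv("invalid detection box: x2 >= x1 and y2 >= y1 required")
    }
  }
  invisible(df)
}

#' Write detections as JSON lines
#'
#' One JSON object per line with keys `frame`, `class_id`, `score`, `x1`,
#' `y1`, `x2`, `y2`; scores keep full double precision.
#'
#' @param records Detection data frame (see [detection_records()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections <- function(records, path) {
  validate_detections(records)
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    for (i in seq_len(nrow(records))) {
      writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read detections from JSON lines
#'
#' @param path JSONL file written by [write_detections()].
#' @return Detection data frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_uwv("no such detections file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(detection_records())
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  df <- do.call(rbind, rows)
  detection_records(df$frame, df$class_id, df$score,
                    df$x1, df$y1, df$x2, df$y2)
}
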
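# End-to-end orchestration: enhance -> detect -> frame-level optimize ->
# evaluate, with stage toggles.  The detection stage accepts either a
# built detector or precomputed detections (an "oracle" source such as
# corrupted ground truth), so the post-processor and evaluator can be
# exercised without trained weights.

#' Pipeline configuration
#'
#' @param enhance Apply CLAHE before detection.
#' @param clahe A [clahe_params()] object.
#' @param detector A built and initialized `uwv_detector`, or `NULL` when
#'   `detections` are supplied directly.
#' @param detections Precomputed detection data frame (used when
#'   `detector` is `NULL`).
#' @param optimize Apply the frame-level tubelet optimization.
#' @param similarity A [similarity_model()].
#' @param tau Tubelet link threshold.
#' @param gaussian A [gaussian_params()] object.
#' @param iou_thr Evaluation IOU threshold.
#' @param classes Class vocabulary.
#' @param out_dir Optional directory for JSONL artifacts (detections
#'   before and after optimization).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(enhance = TRUE, clahe = clahe_params(),
                            detector = NULL, detections = NULL,
                            optimize = TRUE,
                            similarity = similarity_model(), tau = 0.3,
                            gaussian = gaussian_params(), iou_thr = 0.5,
                            classes = uwv_classes(), out_dir = NULL) {
  if (is.null(detector) && is.null(detections)) {
    stop_uwv("supply a detector or precomputed detections")
  }
  structure(list(enhance = enhance, clahe = clahe, detector = detector,
                 detections = detections, optimize = optimize,
                 similarity = similarity, tau = tau, gaussian = gaussian,
                 iou_thr = iou_thr, classes = classes, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the detection pipeline on a clip
#'
#' Stages run in order: CLAHE enhancement (optional), detection (network
#' or oracle detections), frame-level tubelet optimization (optional),
#' and VOC-style evaluation when ground truth is given.  Intermediate
#' detections are written before and after optimization when `out_dir`
#' is set.
#'
#' @param cfg A [pipeline_config()].
#' @param clip A [video_clip()].
#' @param annotations Optional ground-truth annotation data frame; enables
#'   evaluation.
#' @return List with `detections_raw`, `detections`, `eval_raw`, `eval`
#'   (the latter two `NULL` without ground truth) and a per-stage `log`
#'   data frame of elapsed seconds and record counts.
#' @export
run_pipeline <- function(cfg, clip, annotations = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"), inherits(clip, "video_clip"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, count, t0) {
    log[[length(log) + 1L]] <<- data.frame(stage = name, seconds = tic() - t0,
                                           count = count)
  }
  image_size <- c(dim(clip$frames[[1L]])[2L], dim(clip$frames[[1L]])[1L])
  if (cfg$enhance) {
    t0 <- tic()
    clip <- tryCatch(enhance_video(clip, cfg$clahe),
                     error = function(e) stop_uwv("stage enhance: ",
                                                  conditionMessage(e)))
    stage("enhance", n_frames(clip), t0)
  }
  t0 <- tic()
  raw <- if (!is.null(cfg$detector)) {
    tryCatch(detect_frames(cfg$detector, clip),
             error = function(e) stop_uwv("stage detect: ",
                                          conditionMessage(e)))
  } else {
    validate_detections(cfg$detections)
  }
  stage("detect", nrow(raw), t0)
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    write_detections(raw, file.path(cfg$out_dir, "detections_raw.jsonl"))
  }
  dets <- raw
  if (cfg$optimize) {
    t0 <- tic()
    dets <- tryCatch(
      optimize_detections(raw, cfg$similarity, cfg$tau, cfg$gaussian,
                          image_size),
      error = function(e) stop_uwv("stage optimize: ", conditionMessage(e)))
    stage("optimize", nrow(dets), t0)
    if (!is.null(cfg$out_dir)) {
      write_detections(dets, file.path(cfg$out_dir, "detections_opt.jsonl"))
    }
  }
  eval_raw <- NULL
  eval_opt <- NULL
  if (!is.null(annotations)) {
    t0 <- tic()
    eval_raw <- evaluate_detections(raw, annotations, cfg$iou_thr,
                                    cfg$classes)
    eval_opt <- if (cfg$optimize) {
      evaluate_detections(dets, annotations, cfg$iou_thr, cfg$classes)
    } else {
      eval_raw
    }
    stage("evaluate", nrow(annotations), t0)
  }
  list(detections_raw = raw, detections = dets, eval_raw = eval_raw,
       eval = eval_opt, log = do.call(rbind, log))
}
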
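# End-to-end orchestration: extract frames -> projection -> anatomy ->
# coronary gate -> detect -> projection heuristic -> stenosis assignment
# -> guidewire filter -> crop -> percent regression -> hierarchical
# aggregation -> obstructive threshold. Every drop decision is logged
# with the rule that caused it.

#' Assemble a pipeline configuration
#'
#' @param models list with trained `projection`, `anatomy`, `detector`
#'   and `regressor` models.
#' @param exclusion_map projection-exclusion map (see
#'   [apply_projection_heuristic()]).
#' @param detector_score detector score threshold; defaults to the
#'   detector's dev-calibrated operating score (else 0.5).
#' @param assign_iou stenosis-to-segment assignment IoU (default 0.20).
#' @param guidewire_max_frames guidewire filter threshold (default 4).
#' @param obstructive_threshold obstructive percent threshold (default 54).
#' @param crop_scale crop-size preset (`"desk"` or `"full"`).
#' @param seed integer seed recorded for provenance.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(models, exclusion_map = list(),
                            detector_score = NULL, assign_iou = 0.20,
                            guidewire_max_frames = 4L,
                            obstructive_threshold = 54,
                            crop_scale = "desk", seed = 1L) {
  # focal-loss single-stage detectors are systematically under-confident;
  # the conventional operating point is a low score cutoff plus NMS
  if (is.null(detector_score)) detector_score <- 0.3
  structure(list(models = models, exclusion_map = exclusion_map,
                 detector_score = detector_score, assign_iou = assign_iou,
                 guidewire_max_frames = guidewire_max_frames,
                 obstructive_threshold = obstructive_threshold,
                 crop_scale = crop_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks model presence and classes, threshold ranges, exclusion-map
#' vocabulary, and that the projection bin table partitions the angle
#' domain (grid scan for gaps or overlaps).
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations; empty means ok.
#' @export
validate_config <- function(config) {
  v <- character()
  m <- config$models
  if (!inherits(m$projection, "angio_classifier"))
    v <- c(v, "missing projection classifier")
  if (!inherits(m$anatomy, "angio_classifier"))
    v <- c(v, "missing anatomy classifier")
  if (!inherits(m$detector, "angio_detector"))
    v <- c(v, "missing detector")
  else if (!"stenosis" %in% m$detector$vocab)
    v <- c(v, "detector vocabulary lacks the stenosis class")
  if (!inherits(m$regressor, "angio_regressor"))
    v <- c(v, "missing regressor")
  if (config$detector_score < 0 || config$detector_score > 1)
    v <- c(v, "detector score threshold outside [0, 1]")
  if (config$assign_iou <= 0 || config$assign_iou > 1)
    v <- c(v, "assignment IoU outside (0, 1]")
  if (config$obstructive_threshold < 0 || config$obstructive_threshold > 100)
    v <- c(v, "obstructive threshold outside [0, 100]")
  if (config$guidewire_max_frames < 0)
    v <- c(v, "negative guidewire frame threshold")
  bad_keys <- setdiff(names(config$exclusion_map), projection_labels())
  if (length(bad_keys) > 0L)
    v <- c(v, paste("exclusion map keys are not projection labels:",
                    paste(bad_keys, collapse = ", ")))
  # bin table must partition the angle domain
  prim <- seq(-180, 180, by = 2.5); sec <- seq(-50, 50, by = 2.5)
  g <- expand.grid(p = prim, s = sec)
  labs <- bin_projection(g$p, g$s)
  if (anyNA(labs) || !all(labs %in% projection_labels()))
    v <- c(v, "projection bin table does not partition the angle domain")
  v
}

#' Run the full pipeline on one exam
#'
#' @param video_set list of entries `list(video, video_id)` (all videos
#'   of one exam), each `video` an [angio_video()].
#' @param config a [pipeline_config()].
#' @param exam_id exam identifier carried into the result.
#' @return an object of class `exam_result` with per-video predictions,
#'   artery-level stenosis predictions, obstructive flags and the
#'   processing log.
#' @export
run_pipeline <- function(video_set, config, exam_id = "exam") {
  m <- config$models
  logs <- list()
  note <- function(rule, video_id, detail = "") {
    logs[[length(logs) + 1L]] <<- data.frame(
      rule = rule, video_id = video_id, detail = detail,
      stringsAsFactors = FALSE)
  }
  per_video <- list()
  frame_rows <- list()
  for (entry in video_set) {
    vid <- entry$video_id
    video <- entry$video
    ef <- tryCatch(extract_frames(video), error = function(e) {
      note("unreadable_video", vid, conditionMessage(e)); NULL
    })
    if (is.null(ef)) next
    frames <- lapply(ef$indices, function(i) frame_at(video, i))
    proj_p <- predict_frames(m$projection, frames)
    projection <- aggregate_video(proj_p)
    anat_p <- predict_frames(m$anatomy, frames)
    anatomy <- aggregate_video(anat_p)
    gated <- gate_coronary(anatomy)
    row <- data.frame(video_id = vid, projection = projection,
                      anatomy = anatomy, gated = gated,
                      n_extracted = length(ef$indices),
                      stringsAsFactors = FALSE)
    dets <- list()
    if (!gated) {
      note("gate", vid, anatomy)
    } else {
      # detection runs on well-opacified frames only: the contrast-free
      # reference is skipped, and so is any frame carrying less than 60%
      # of the window's maximal vesselness mass (underfilled views)
      vmass <- vapply(frames, function(f) {
        v <- vesselness(f)
        sum(v[v >= 0.08])  # above the noise floor
      }, numeric(1))
      ok_frame <- ef$indices != 0L & vmass >= 0.6 * max(vmass[-1L])
      dets <- lapply(seq_along(frames), function(k) {
        if (!ok_frame[k]) return(empty_detections())
        detect_objects(m$detector, frames[[k]], config$detector_score)
      })
      dets <- lapply(dets, apply_projection_heuristic,
                     projection_label = projection,
                     exclusion_map = config$exclusion_map)
      # anatomy constraints: one box per segment class, own tree only
      dets <- lapply(dets, dedupe_segments, side = anatomy)
      if (guidewire_filter(dets, config$guidewire_max_frames) == "drop") {
        note("guidewire", vid)
      } else {
        sizes <- crop_sizes(config$crop_scale)
        for (k in seq_along(dets)) {
          asg <- assign_stenosis_to_segment(dets[[k]], config$assign_iou)
          if (attr(asg, "unassigned") > 0L)
            note("unassigned", vid,
                 sprintf("frame %d: %d stenoses below assignment IoU",
                         ef$indices[k], attr(asg, "unassigned")))
          # one lesion per segment and frame: the most narrowed candidate
          by_seg <- crop_deepest_per_segment(frames[[k]], asg, sizes)
          for (seg in names(by_seg)) {
            pct <- predict_percent(m$regressor, by_seg[[seg]])
            frame_rows[[length(frame_rows) + 1L]] <- data.frame(
              exam_id = exam_id, video_id = vid,
              frame = ef$indices[k], segment = seg,
              percent = pct, stringsAsFactors = FALSE)
          }
        }
      }
    }
    per_video[[vid]] <- list(summary = row, detections = dets,
                             extracted = ef)
  }
  fp <- if (length(frame_rows) > 0L) do.call(rbind, frame_rows) else
    data.frame(exam_id = character(), video_id = character(),
               frame = integer(), segment = character(),
               percent = numeric(), stringsAsFactors = FALSE)
  arteries <- if (nrow(fp) > 0L) {
    a <- aggregate_artery(fp)
    a$obstructive <- classify_obstructive(a$percent,
                                          config$obstructive_threshold)
    a
  } else {
    data.frame(exam_id = character(), segment = character(),
               percent = numeric(), n_videos = integer(),
               n_frames = integer(), obstructive = logical(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    exam_id = exam_id,
    videos = do.call(rbind, c(lapply(per_video, `[[`, "summary"),
                              make.row.names = FALSE)),
    video_detail = per_video,
    frame_percents = fp,
    arteries = arteries,
    log = if (length(logs) > 0L) do.call(rbind, logs) else
      data.frame(rule = character(), video_id = character(),
                 detail = character())),
    class = "exam_result")
}

#' @export
print.exam_result <- function(x, ...) {
  cat(sprintf("<exam_result> %s: %d videos (%d gated), %d artery predictions\n",
              x$exam_id, if (is.null(x$videos)) 0L else nrow(x$videos),
              if (is.null(x$videos)) 0L else sum(x$videos$gated),
              nrow(x$arteries)))
  if (nrow(x$arteries) > 0L) print(x$arteries, row.names = FALSE)
  invisible(x)
}

#' Serialize an exam result to versioned JSON
#'
#' @param result an `exam_result`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
exam_result_json <- function(result, path = NULL) {
  doc <- list(schema = "angiopipe/exam_result/1",
              exam_id = result$exam_id,
              videos = result$videos,
              arteries = result$arteries,
              log = result$log)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
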
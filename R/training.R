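# Dataset-to-model plumbing: build frame/annotation/crop training sets
# from a synthetic dataset and train the four pipeline models.

# Extract the analysis frames of every video once.
extract_all_frames <- function(dataset) {
  lapply(dataset$videos, function(v) extract_frames(v$video))
}

# Frame-level classification dataset (projection or anatomy labels) over
# the train and dev splits.
build_frame_dataset <- function(dataset, task, extracted) {
  frames <- list(); labels <- character(); split <- character()
  for (vid in names(dataset$videos)) {
    v <- dataset$videos[[vid]]
    sp <- dataset$patients$split[dataset$patients$patient_id == v$patient_id]
    if (!sp %in% c("train", "dev")) next
    ef <- extracted[[vid]]
    lab <- switch(task,
                  projection = v$ground_truth$projection,
                  anatomy = v$ground_truth$anatomy)
    for (i in ef$indices) {
      frames[[length(frames) + 1L]] <- frame_at(v$video, i)
      labels <- c(labels, lab)
      split <- c(split, sp)
    }
  }
  list(frames = frames, labels = labels, split = split)
}

# Detection annotations: contrast-visible extracted frames of coronary
# train-split videos with their ground-truth boxes.
build_detection_frames <- function(dataset, extracted, max_per_video = 3L) {
  out <- list()
  for (vid in names(dataset$videos)) {
    v <- dataset$videos[[vid]]
    sp <- dataset$patients$split[dataset$patients$patient_id == v$patient_id]
    if (sp != "train") next
    if (!v$ground_truth$anatomy %in% c("lca", "rca")) next
    ef <- extracted[[vid]]
    vis <- ef$indices[v$ground_truth$ramp[ef$indices + 1L] >= 0.6]
    vis <- utils::head(sort(vis, decreasing = TRUE), max_per_video)
    for (k in vis) {
      b <- gt_boxes(v$ground_truth, frame = k)
      out[[length(out) + 1L]] <- list(
        image = frame_at(v$video, k),
        boxes = b[, c("class", box_cols)],
        meta = list(side = v$ground_truth$anatomy,
                    projection = v$ground_truth$projection),
        image_id = sprintf("%s_f%d", vid, k))
    }
  }
  out
}

# Report-label crop dataset, mirroring the label-matching rule: a
# localized stenosis acquires its label only if the parsed report carries
# a percent for its assigned segment; unmatched stenoses are removed.
# Healthy crops come from segment detections without an assigned stenosis,
# sized from the per-segment stenosis crop-size distribution, labelled 0.
build_crop_dataset <- function(dataset, detector, extracted,
                               splits = c("train", "dev"),
                               detector_score = 0.3, assign_iou = 0.20,
                               sizes = crop_sizes("desk"),
                               healthy_per_video = 2L, seed = 1L) {
  dict <- default_segment_dictionary()
  parsed <- lapply(dataset$reports, parse_report, dictionary = dict)
  crops <- list(); labels <- numeric(); split <- character()
  healthy_pool <- list()
  size_obs <- list()
  set.seed(as.integer(seed))
  for (vid in names(dataset$videos)) {
    v <- dataset$videos[[vid]]
    sp <- dataset$patients$split[dataset$patients$patient_id == v$patient_id]
    if (!sp %in% splits) next
    if (!v$ground_truth$anatomy %in% c("lca", "rca")) next
    rep_pct <- parsed[[v$exam_id]]
    ef <- extracted[[vid]]
    vis <- ef$indices[v$ground_truth$ramp[ef$indices + 1L] >= 0.6]
    per_frame_dets <- list()
    for (k in vis) {
      frame <- frame_at(v$video, k)
      dets <- detect_objects(detector, frame, detector_score)
      per_frame_dets[[as.character(k)]] <-
        dedupe_segments(dets, side = v$ground_truth$anatomy)
    }
    if (guidewire_filter(per_frame_dets) == "drop") next
    video_healthy <- list()
    for (k in vis) {
      frame <- frame_at(v$video, k)
      dets <- per_frame_dets[[as.character(k)]]
      asg <- assign_stenosis_to_segment(dets, assign_iou)
      by_seg <- crop_deepest_per_segment(frame, asg, sizes)
      assigned_segments <- character()
      for (seg in names(by_seg)) {
        lab <- rep_pct$percent[rep_pct$segment == seg]
        if (length(lab) == 0L) next  # non-matched stenosis removed
        cr <- by_seg[[seg]]
        crops[[length(crops) + 1L]] <- cr
        labels <- c(labels, lab[1L])
        split <- c(split, sp)
        assigned_segments <- c(assigned_segments, seg)
        sb <- cr$source_box
        size_obs[[seg]] <- rbind(size_obs[[seg]],
                                 data.frame(w = sb["x_max"] - sb["x_min"],
                                            h = sb["y_max"] - sb["y_min"]))
      }
      segs <- dets[dets$class %in% segment_classes() &
                     !dets$class %in% assigned_segments, , drop = FALSE]
      true_sten <- names(v$ground_truth$stenosis_pct)[
        v$ground_truth$stenosis_pct > 0]
      segs <- segs[!segs$class %in% true_sten, , drop = FALSE]
      for (j in seq_len(nrow(segs))) {
        video_healthy[[length(video_healthy) + 1L]] <-
          list(frame = frame, box = segs[j, ], split = sp)
      }
    }
    if (length(video_healthy) > 0L) {
      sc <- vapply(video_healthy, function(h) h$box$score, numeric(1))
      take <- utils::head(order(-sc), healthy_per_video)
      healthy_pool <- c(healthy_pool, video_healthy[take])
    }
  }
  # healthy crops mirroring the stenosis size distribution per segment
  all_sizes <- do.call(rbind, size_obs)
  for (hp in healthy_pool) {
    seg <- hp$box$class
    dist <- if (!is.null(size_obs[[seg]])) size_obs[[seg]] else all_sizes
    if (is.null(dist) || nrow(dist) == 0L) next
    cr <- crop_healthy_segment(hp$frame, hp$box, dist,
                               seed = sample.int(1e8, 1L), sizes = sizes)
    crops[[length(crops) + 1L]] <- cr
    labels <- c(labels, 0)
    split <- c(split, hp$split)
  }
  list(crops = crops, labels = labels, split = split)
}

#' Train all four pipeline models on a synthetic dataset
#'
#' Trains, in pipeline order: the projection classifier, the anatomy
#' classifier (transfer-initialized from the projection model), the
#' lesion detector (on contrast-visible frames of coronary train-split
#' videos) and the percent-stenosis regressor (on detector-localized
#' crops labelled by parsing the paired reports). All training respects
#' the dataset's patient-disjoint splits.
#'
#' @param dataset an [generate_dataset()] object.
#' @param seed integer seed governing all model initializations.
#' @param classifier_cfg,detector_cfg,regressor_cfg optional config
#'   overrides.
#' @return list with `projection`, `anatomy`, `detector`, `regressor`
#'   (class `angio_models`).
#' @export
train_pipeline_models <- function(dataset, seed = 1L,
                                  classifier_cfg = NULL,
                                  detector_cfg = NULL,
                                  regressor_cfg = NULL) {
  extracted <- extract_all_frames(dataset)
  ccfg <- if (is.null(classifier_cfg)) classifier_config(seed = seed)
          else classifier_cfg
  proj_ds <- build_frame_dataset(dataset, "projection", extracted)
  projection <- train_classifier(proj_ds, "projection", ccfg)
  acfg <- ccfg; acfg$init_from <- projection
  anat_ds <- build_frame_dataset(dataset, "anatomy", extracted)
  anatomy <- train_classifier(anat_ds, "anatomy", acfg)
  dcfg <- if (is.null(detector_cfg)) detector_config(seed = seed)
          else detector_cfg
  det_frames <- build_detection_frames(dataset, extracted)
  detector <- train_detector(det_frames, dcfg)
  rcfg <- if (is.null(regressor_cfg)) regressor_config(seed = seed)
          else regressor_cfg
  cd <- build_crop_dataset(dataset, detector, extracted, seed = seed)
  tr <- cd$split == "train"; dv <- cd$split == "dev"
  regressor <- train_regressor(cd$crops[tr], cd$labels[tr], rcfg,
                               dev_crops = cd$crops[dv],
                               dev_labels = cd$labels[dv])
  structure(list(projection = projection, anatomy = anatomy,
                 detector = detector, regressor = regressor,
                 extracted = extracted),
            class = "angio_models")
}

#' Evaluate the trained pipeline on a dataset split
#'
#' Runs the full pipeline on every exam of the split and scores it
#' against ground truth: video-level anatomy accuracy, stenosis-detection
#' recall at IoU 0.5 (on contrast-visible extracted frames of coronary
#' videos), artery-level mean absolute error on segments with a reported
#' stenosis, and the obstructive ROC AUC (>= 70% true label, predicted
#' percent as score).
#'
#' @param dataset an `angio_dataset`.
#' @param models an `angio_models` list.
#' @param split which split to evaluate (default `"test"`).
#' @param config optional [pipeline_config()]; built from `models` if
#'   missing.
#' @return list of metrics plus the per-exam results.
#' @export
evaluate_pipeline <- function(dataset, models, split = "test",
                              config = NULL) {
  if (is.null(config)) config <- pipeline_config(models)
  vids <- dataset_split(dataset, split)
  exams <- split(vids, vapply(vids, `[[`, character(1), "exam_id"))
  results <- list()
  anat_true <- character(); anat_pred <- character()
  det_tp <- 0L; det_gt <- 0L
  pred_rows <- list()
  for (ex in names(exams)) {
    vset <- lapply(exams[[ex]], function(v)
      list(video = v$video, video_id = v$video_id))
    res <- run_pipeline(vset, config, exam_id = ex)
    results[[ex]] <- res
    for (v in exams[[ex]]) {
      anat_true <- c(anat_true, v$ground_truth$anatomy)
      anat_pred <- c(anat_pred,
                     res$videos$anatomy[res$videos$video_id == v$video_id])
      # stenosis-detection recall on contrast-visible extracted frames
      if (v$ground_truth$anatomy %in% c("lca", "rca")) {
        det <- res$video_detail[[v$video_id]]
        if (!is.null(det)) {
          idx <- det$extracted$indices
          vis <- which(v$ground_truth$ramp[idx + 1L] >= 0.6)
          for (k in vis) {
            g <- gt_boxes(v$ground_truth, frame = idx[k])
            g <- g[g$class == "stenosis", , drop = FALSE]
            if (nrow(g) == 0L) next
            d <- if (length(det$detections) >= k) det$detections[[k]]
                 else empty_detections()
            d <- d[d$class == "stenosis", , drop = FALSE]
            det_gt <- det_gt + nrow(g)
            if (nrow(d) > 0L)
              det_tp <- det_tp + sum(match_detections(d, g, 0.5)$tp)
          }
        }
      }
    }
    if (nrow(res$arteries) > 0L) pred_rows[[ex]] <- res$arteries
  }
  preds <- if (length(pred_rows) > 0L) do.call(rbind, pred_rows) else NULL
  gt <- dataset$gt_stenosis[dataset$gt_stenosis$percent > 0, , drop = FALSE]
  test_pat <- dataset$patients$patient_id[dataset$patients$split == split]
  gt <- gt[gt$patient_id %in% test_pat, , drop = FALSE]
  mae <- NA_real_; auc <- NA_real_; n_matched <- 0L
  if (!is.null(preds)) {
    j <- merge(gt, preds, by = c("exam_id", "segment"),
               suffixes = c("_true", "_pred"))
    n_matched <- nrow(j)
    if (n_matched > 0L) {
      mae <- mean(abs(j$percent_true - j$percent_pred))
      lab <- j$percent_true >= 70
      if (length(unique(lab)) == 2L) auc <- roc_auc(j$percent_pred, lab)
    }
  }
  list(anatomy_accuracy = mean(anat_pred == anat_true),
       stenosis_recall = if (det_gt > 0L) det_tp / det_gt else NA_real_,
       artery_mae = mae,
       obstructive_auc = auc,
       n_videos = length(anat_true),
       n_gt_stenoses = det_gt,
       n_matched_arteries = n_matched,
       results = results)
}

#' Run the full desk-scale study
#'
#' Generates a synthetic dataset, trains the four pipeline models on its
#' train/dev splits and evaluates the end-to-end pipeline on the held-out
#' test split.
#'
#' @param n_patients number of patients (default 40).
#' @param seed master seed for generation and training.
#' @param config dataset configuration.
#' @return the [evaluate_pipeline()] metric list (plus `dataset` and
#'   `models` invisibly attached).
#' @export
run_study <- function(n_patients = 40L, seed = 1L,
                      config = dataset_config()) {
  dataset <- generate_dataset(n_patients, config, seed = seed)
  models <- train_pipeline_models(dataset, seed = seed)
  out <- evaluate_pipeline(dataset, models, "test")
  out$dataset <- dataset
  out$models <- models
  out
}
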
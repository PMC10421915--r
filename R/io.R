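# On-disk interchange: PNG frame directories, CSV metadata, JSON ground
# truth and UTF-8 report text.

#' Write a synthetic dataset to disk
#'
#' Layout: `<dir>/videos/<video_id>/frame_####.png` (one PNG per frame),
#' `metadata.csv` (patient_id, exam_id, video_id, primary_angle,
#' secondary_angle, fps, n_frames), `ground_truth.json`,
#' `reports/<exam_id>.txt` and `splits.csv`.
#'
#' @param dataset an `angio_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "videos"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reports"), showWarnings = FALSE)
  for (vid in names(dataset$videos)) {
    v <- dataset$videos[[vid]]
    vdir <- file.path(dir, "videos", vid)
    dir.create(vdir, showWarnings = FALSE)
    for (k in seq_along(v$video$frames)) {
      png::writePNG(v$video$frames[[k]],
                    file.path(vdir, sprintf("frame_%04d.png", k - 1L)))
    }
  }
  meta <- dataset$metadata
  utils::write.csv(meta[, c("patient_id", "exam_id", "video_id",
                            "primary_angle", "secondary_angle", "fps",
                            "n_frames")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(dataset$patients, file.path(dir, "splits.csv"),
                   row.names = FALSE)
  gt <- lapply(dataset$videos, function(v) {
    g <- v$ground_truth
    list(boxes = g$boxes, stenosis_pct = as.list(g$stenosis_pct),
         projection = g$projection, anatomy = g$anatomy)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (ex in names(dataset$reports)) {
    writeLines(dataset$reports[[ex]],
               file.path(dir, "reports", paste0(ex, ".txt")))
  }
  invisible(dir)
}

#' Read a PNG frame directory back as a video
#'
#' @param vdir directory of `frame_####.png` files in acquisition order.
#' @param metadata optional named list attached to the video.
#' @return an [angio_video()].
#' @export
read_video_dir <- function(vdir, metadata = list()) {
  files <- sort(list.files(vdir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames in ", vdir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  angio_video(frames, metadata = metadata)
}
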
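# Frame-level projection-angle and anatomic-structure classification with
# video-level aggregation and the coronary gate.

#' The 12 projection labels
#' @return character vector of the 12 joint projection labels.
#' @export
projection_labels <- function() {
  as.vector(outer(c("LAO", "RAO", "AP", "Lateral"),
                  c("cranial", "caudal", "straight"), paste))
}

#' Bin C-arm angles into one of 12 projection labels
#'
#' The default bin table partitions the angle domain: primary axis —
#' Lateral for |primary| >= 100, RAO for (-100, -10], AP for (-10, 10),
#' LAO for [10, 100); secondary axis — cranial for >= +10, caudal for
#' <= -10, straight otherwise. Total and deterministic on
#' `[-180, 180] x [-50, 50]`; boundaries are right-open so adjacent bins
#' share no point.
#'
#' @param primary_deg primary (LAO-RAO) angle in degrees, `[-180, 180]`.
#' @param secondary_deg secondary (cranial-caudal) angle, `[-50, 50]`.
#' @return character vector of joint labels such as `"LAO cranial"`.
#' @export
bin_projection <- function(primary_deg, secondary_deg) {
  if (any(primary_deg < -180 | primary_deg > 180))
    stop("primary angle out of [-180, 180]")
  if (any(secondary_deg < -50 | secondary_deg > 50))
    stop("secondary angle out of [-50, 50]")
  prim <- ifelse(abs(primary_deg) >= 100, "Lateral",
          ifelse(primary_deg <= -10, "RAO",
          ifelse(primary_deg < 10, "AP", "LAO")))
  sec <- ifelse(secondary_deg >= 10, "cranial",
         ifelse(secondary_deg <= -10, "caudal", "straight"))
  paste(prim, sec)
}

# --- frame features ---------------------------------------------------------

# Pooled-intensity descriptor of a frame: 12x12 mean-pooled gray levels
# plus coarse row/column profiles. Orientation- and shape-sensitive,
# which is what both classification tasks need.
frame_features <- function(img, grid = 12L) {
  p <- ap_pool(img, grid, grid)
  c(as.vector(p), rowMeans(p), colMeans(p))
}

feature_matrix <- function(frames, grid = 12L) {
  t(vapply(frames, frame_features, numeric(grid * grid + 2L * grid),
           grid = grid))
}

#' Default classifier configuration
#' @param ... overrides (hidden units, epochs, lr, momentum, batch_size,
#'   augment flag, zoom/shear ranges, seed, init_from).
#' @return named list.
#' @export
classifier_config <- function(...) {
  cfg <- list(hidden = 48L, epochs = 40L, lr = 0.08, momentum = 0.9,
              batch_size = 32L, augment = TRUE, zoom_range = 0.2,
              shear_range = 0.2, patience = Inf, grid = 12L, seed = 1L,
              init_from = NULL)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

augment_frame <- function(img, zoom_range, shear_range) {
  ap_affine(img,
            rot = stats::runif(1, -shear_range, shear_range),
            zoom = 1 + stats::runif(1, -zoom_range, zoom_range))
}

#' Train a frame-level classifier
#'
#' Trains a softmax frame classifier (projection or anatomy task) on
#' pooled-intensity features, minimizing cross-entropy by minibatch SGD
#' with momentum. Supports transfer initialization from another trained
#' classifier ("core model"): shape-compatible hidden layers are copied,
#' the output layer is re-initialized for the new vocabulary. Training
#' augmentations (random zoom and shear-rotate, both range 0.2) add one
#' jittered copy of each training frame.
#'
#' @param frame_dataset list with fields `frames` (list of matrices),
#'   `labels` (character) and `split` (character, `"train"`/`"dev"`);
#'   splits must hold non-overlapping patients.
#' @param task `"projection"` or `"anatomy"` (fixes the vocabulary unless
#'   `vocab` is given).
#' @param config a [classifier_config()].
#' @param vocab optional explicit label vocabulary.
#' @return an object of class `angio_classifier`.
#' @export
train_classifier <- function(frame_dataset, task = c("projection", "anatomy"),
                             config = classifier_config(), vocab = NULL) {
  task <- match.arg(task)
  frames <- frame_dataset$frames
  labels <- frame_dataset$labels
  split <- frame_dataset$split
  if (length(frames) == 0L) stop("empty dataset")
  stopifnot(length(frames) == length(labels), length(labels) == length(split))
  if (is.null(vocab)) {
    vocab <- switch(task, projection = projection_labels(),
                    anatomy = anatomy_classes())
    vocab <- intersect(vocab, unique(labels))
    if (length(vocab) < 1L) stop("label vocabulary mismatch")
  }
  if (!all(labels %in% vocab)) stop("label vocabulary mismatch")
  tr <- which(split == "train"); dv <- which(split == "dev")
  if (length(tr) == 0L) stop("empty training split")
  set.seed(config$seed)
  tr_frames <- frames[tr]; tr_labels <- labels[tr]
  if (isTRUE(config$augment)) {
    aug <- lapply(frames[tr], augment_frame,
                  zoom_range = config$zoom_range,
                  shear_range = config$shear_range)
    tr_frames <- c(tr_frames, aug)
    tr_labels <- c(tr_labels, labels[tr])
  }
  X <- feature_matrix(tr_frames, config$grid)
  scaler <- nn_scaler(X)
  X <- nn_scale(X, scaler)
  Y <- nn_onehot(tr_labels, vocab)
  dev_X <- NULL; dev_Y <- NULL
  if (length(dv) > 0L) {
    dev_X <- nn_scale(feature_matrix(frames[dv], config$grid), scaler)
    dev_Y <- nn_onehot(labels[dv], vocab)
  }
  net <- nn_new(c(ncol(X), config$hidden, length(vocab)), "softmax",
                seed = config$seed)
  if (!is.null(config$init_from)) {
    stopifnot(inherits(config$init_from, "angio_classifier"))
    net <- nn_transfer(net, config$init_from$net)
    scaler <- config$init_from$scaler  # shared feature standardization
    X <- nn_scale(feature_matrix(tr_frames, config$grid), scaler)
    if (length(dv) > 0L)
      dev_X <- nn_scale(feature_matrix(frames[dv], config$grid), scaler)
  }
  net <- nn_train(net, X, Y, epochs = config$epochs, lr = config$lr,
                  momentum = config$momentum, batch_size = config$batch_size,
                  dev_X = dev_X, dev_Y = dev_Y, patience = config$patience,
                  seed = config$seed)
  structure(list(net = net, vocab = vocab, task = task, scaler = scaler,
                 grid = config$grid, config = config),
            class = "angio_classifier")
}

#' @export
print.angio_classifier <- function(x, ...) {
  cat(sprintf("<angio_classifier> task=%s, %d classes, %d epochs trained\n",
              x$task, length(x$vocab), x$net$stopped_epoch))
  invisible(x)
}

#' Classify one frame
#'
#' @param model an `angio_classifier`.
#' @param image a frame matrix at the model's training resolution.
#' @return named probability vector over the model vocabulary (sums to 1).
#' @export
predict_frame <- function(model, image) {
  predict_frames(model, list(image))[1L, ]
}

#' Classify a batch of frames
#' @param model an `angio_classifier`.
#' @param frames list of frame matrices.
#' @return matrix of class probabilities, one row per frame.
#' @export
predict_frames <- function(model, frames) {
  X <- nn_scale(feature_matrix(frames, model$grid), model$scaler)
  P <- nn_predict(model$net, X)
  colnames(P) <- model$vocab
  P
}

#' Aggregate frame predictions to a video label
#'
#' The video label is the most common frame-level argmax; modal ties are
#' broken by the tied label with the highest average probability across
#' all frames.
#'
#' @param frame_predictions matrix of per-frame class probabilities
#'   (rows = frames) with column names, as from [predict_frames()].
#' @return the winning label (character scalar).
#' @export
aggregate_video <- function(frame_predictions) {
  P <- frame_predictions
  if (is.null(dim(P))) P <- matrix(P, 1L, dimnames = list(NULL, names(P)))
  if (nrow(P) == 0L) stop("empty prediction set")
  labs <- colnames(P)[max.col(P, ties.method = "first")]
  tab <- table(labs)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  means <- colMeans(P)[winners]
  winners[which.max(means)]
}

#' Coronary gate
#'
#' Only videos whose primary anatomic structure is a left or right
#' coronary artery flow on to lesion localization.
#'
#' @param video_anatomy_label one of the 11 anatomy classes.
#' @return `TRUE` iff the label is `lca` or `rca`.
#' @export
gate_coronary <- function(video_anatomy_label) {
  if (!video_anatomy_label %in% anatomy_classes())
    stop("unknown anatomy label: ", video_anatomy_label)
  video_anatomy_label %in% c("lca", "rca")
}
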
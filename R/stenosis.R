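# Percent-stenosis regression: crop construction, multi-aspect-ratio
# training, hierarchical frame -> video -> artery aggregation, the
# obstructive threshold, and frozen-backbone fine-tuning.

#' Crop sizes for the three aspect ratios
#'
#' Aspect ratio 1 is square, 2 is wide (2:1), 3 is tall (1:2). The desk
#' preset halves the full-scale 256-px sizes.
#'
#' @param scale `"desk"` (128/64) or `"full"` (256/128).
#' @return list of three `c(width, height)` pairs, named by aspect id.
#' @export
crop_sizes <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  b <- if (scale == "desk") 128L else 256L
  list(`1` = c(b, b), `2` = c(b, b %/% 2L), `3` = c(b %/% 2L, b))
}

# Nearest aspect id for a width/height ratio: thresholds at sqrt(2) and
# 1/sqrt(2) so every ratio has a unique nearest size.
nearest_aspect <- function(ratio) {
  if (ratio >= sqrt(2)) 2L else if (ratio <= 1 / sqrt(2)) 3L else 1L
}

#' Crop a localized stenosis from a frame
#'
#' The assignment box is expanded by 12 pixels on every side, clipped to
#' the frame, cropped and resized to the nearest of the three predetermined
#' sizes (by width/height ratio).
#'
#' @param frame grayscale frame matrix.
#' @param assignment one row of [assign_stenosis_to_segment()] output (or
#'   any list with the box columns and `segment`).
#' @param sizes a [crop_sizes()] list.
#' @param expand_px expansion margin (default 12).
#' @return an object of class `cropped_lesion` with fields `image`,
#'   `aspect_ratio_id`, `segment_label`, `source_box`, `provenance`.
#' @export
crop_stenosis <- function(frame, assignment, sizes = crop_sizes(),
                          expand_px = 12) {
  S_h <- nrow(frame); S_w <- ncol(frame)
  b <- c(assignment$x_min, assignment$y_min, assignment$x_max,
         assignment$y_max)
  if (b[1L] < 0 || b[2L] < 0 || b[3L] > S_w || b[4L] > S_h ||
      b[3L] <= b[1L] || b[4L] <= b[2L])
    stop("assignment box outside frame")
  e <- c(max(0, b[1L] - expand_px), max(0, b[2L] - expand_px),
         min(S_w, b[3L] + expand_px), min(S_h, b[4L] + expand_px))
  x0 <- floor(e[1L]); y0 <- floor(e[2L])
  x1 <- ceiling(e[3L]); y1 <- ceiling(e[4L])
  sub <- frame[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  aid <- nearest_aspect((x1 - x0) / (y1 - y0))
  sz <- sizes[[as.character(aid)]]
  structure(list(image = ap_resize(sub, sz[2L], sz[1L]),
                 aspect_ratio_id = aid,
                 segment_label = assignment$segment,
                 source_box = c(x_min = e[1L], y_min = e[2L],
                                x_max = e[3L], y_max = e[4L]),
                 provenance = "stenosis"),
            class = "cropped_lesion")
}

#' @export
print.cropped_lesion <- function(x, ...) {
  cat(sprintf("<cropped_lesion> %s, aspect %d, %dx%d, %s\n", x$segment_label,
              x$aspect_ratio_id, ncol(x$image), nrow(x$image), x$provenance))
  invisible(x)
}

#' Crop a healthy (non-stenosed) segment
#'
#' Healthy segments tend to be longer than focal stenoses; to avoid a size
#' bias, a random sub-box is cut whose width and height are drawn from the
#' empirical distribution of stenosis crop sizes of that segment. If the
#' segment box is smaller than the sampled size, the full box is used.
#'
#' @param frame grayscale frame matrix.
#' @param segment_box list/row with box columns and `class` (the segment).
#' @param stenosis_size_distribution matrix/data.frame with columns `w`,
#'   `h` of observed stenosis crop sizes for this segment.
#' @param seed integer seed.
#' @param sizes a [crop_sizes()] list.
#' @return a `cropped_lesion` with provenance `"healthy"`.
#' @export
crop_healthy_segment <- function(frame, segment_box,
                                 stenosis_size_distribution, seed = 1L,
                                 sizes = crop_sizes()) {
  set.seed(as.integer(seed))
  d <- as.data.frame(stenosis_size_distribution)
  i <- sample.int(nrow(d), 1L)
  w <- d$w[i]; h <- d$h[i]
  bx <- c(segment_box$x_min, segment_box$y_min, segment_box$x_max,
          segment_box$y_max)
  bw <- bx[3L] - bx[1L]; bh <- bx[4L] - bx[2L]
  if (w > bw || h > bh) {
    sub <- bx
  } else {
    x0 <- bx[1L] + stats::runif(1, 0, bw - w)
    y0 <- bx[2L] + stats::runif(1, 0, bh - h)
    sub <- c(x0, y0, x0 + w, y0 + h)
  }
  crop_stenosis(frame,
                list(x_min = sub[1L], y_min = sub[2L], x_max = sub[3L],
                     y_max = sub[4L], segment = segment_box$class),
                sizes = sizes, expand_px = 0) -> cl
  cl$provenance <- "healthy"
  cl
}

# --- crop features ----------------------------------------------------------

# Compact lumen-geometry descriptor of a crop: column/row width
# statistics from the distance transform of the vessel mask, direct
# percent estimates derived from them, plus segment and aspect one-hots.
# Kept deliberately low-dimensional so the contract training budget
# (50 epochs at learning rate 0.001) converges.
crop_features <- function(crop) {
  img <- crop$image
  v <- vesselness(img)
  mx <- max(v)
  geom <- if (mx > 1e-6) {
    # lumen widths from the distance transform of the vessel mask: per
    # column/row, twice the maximal distance-to-background is the local
    # width, independent of vessel orientation; interior gaps (total
    # occlusion) count as width zero rather than being dropped
    mask <- v >= mx / 2
    dt <- suppressWarnings(EBImage::distmap(EBImage::Image(mask * 1)))
    dt <- dt@.Data
    # trim the span ends: the vessel tapers where it crosses the crop
    # border, while the lesion sits centrally (the box is centered on it)
    span_stats <- function(w) {
      nz <- which(w > 0)
      if (length(nz) < 2L) return(c(0, 0, 0))
      s <- w[nz[1L]:nz[length(nz)]]
      L <- length(s)
      trim <- floor(0.2 * L)
      core <- if (L - 2L * trim >= 3L) s[(1L + trim):(L - trim)] else s
      c(min(core), stats::median(s), min(core) / max(stats::median(s), 1))
    }
    cs <- span_stats(2 * apply(dt, 2L, max))
    rs <- span_stats(2 * apply(dt, 1L, max))
    # direct percent readings: one minus the width ratio per axis
    c(cs, rs, mx,
      100 * (1 - cs[3L]), 100 * (1 - rs[3L]),
      100 * (1 - min(cs[3L], rs[3L])))
  } else rep(0, 10L)
  seg <- as.numeric(coronary_segments() == crop$segment_label)
  asp <- as.numeric(1:3 == crop$aspect_ratio_id)
  c(geom, seg, asp)
}

crop_feature_matrix <- function(crops) {
  t(vapply(crops, crop_features,
           numeric(10L + length(coronary_segments()) + 3L)))
}

# Pinch depth of a crop: core minimum over median of the lumen-width
# profile (lower = deeper narrowing). Used to pick, among candidate
# lesion boxes of one segment, the crop showing the maximal stenosis.
crop_pinch_ratio <- function(crop) {
  f <- crop_features(crop)
  min(f[3L], f[6L])  # column and row width ratios
}

# Crop every assignment and keep, per segment, the crop with the deepest
# narrowing (the segment label is the maximal stenosis, so the most
# narrowed candidate is the lesion of interest).
crop_deepest_per_segment <- function(frame, assignments, sizes,
                                     expand_px = 12) {
  out <- list()
  for (seg in unique(assignments$segment)) {
    rows <- assignments[assignments$segment == seg, , drop = FALSE]
    crops <- lapply(seq_len(nrow(rows)), function(j)
      crop_stenosis(frame, rows[j, ], sizes = sizes, expand_px = expand_px))
    depth <- vapply(crops, crop_pinch_ratio, numeric(1))
    out[[seg]] <- crops[[which.min(depth)]]
  }
  out
}

#' Default regressor configuration
#'
#' Mirrors the regression training contract: squared loss, initial
#' learning rate 0.001, momentum 0.9, batch size 12, at most 50 epochs,
#' early stopping after 8 non-improving epochs, with each epoch trained on
#' one aspect ratio in rotation.
#'
#' @param ... overrides.
#' @return named list.
#' @export
regressor_config <- function(...) {
  cfg <- list(hidden = c(48L, 24L), lr = 0.001, momentum = 0.9,
              batch_size = 12L, epochs = 50L, patience = 8L,
              augment = TRUE, hist_eq_prob = 0.5, seed = 1L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

augment_crop <- function(crop, hist_eq_prob) {
  img <- crop$image
  if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(ncol(img)))]  # h flip
  if (stats::runif(1) < 0.5) img <- img[rev(seq_len(nrow(img))), ]  # v flip
  gain <- stats::runif(1, 0.9, 1.1)       # contrast
  gamma <- stats::runif(1, 0.9, 1.1)      # gamma
  bias <- stats::runif(1, -0.05, 0.05)    # brightness
  img <- pmin(pmax((img^gamma) * gain + bias, 0), 1)
  if (stats::runif(1) < hist_eq_prob) img <- ap_hist_eq(img)
  crop$image <- img
  crop
}

#' Train the percent-stenosis regressor
#'
#' A regressor over pooled crop features whose final stage is a linear
#' output unit, with the segment label and aspect-ratio id concatenated
#' into the input of the final stages. Trained to minimize the squared
#' loss by minibatch SGD with momentum; each epoch cycles to the next
#' aspect ratio (weights carried over); training stops early when the
#' development loss has not improved for `patience` consecutive epochs.
#' Training augmentations (flips, contrast/gamma/brightness jitter,
#' randomly applied histogram equalization) add one jittered copy of each
#' training crop.
#'
#' @param crops list of `cropped_lesion` objects (training split).
#' @param labels percent labels in `[0, 100]`.
#' @param config a [regressor_config()].
#' @param dev_crops,dev_labels development split for early stopping.
#' @return an object of class `angio_regressor`.
#' @export
train_regressor <- function(crops, labels, config = regressor_config(),
                            dev_crops = NULL, dev_labels = NULL) {
  if (length(crops) == 0L) stop("empty training split")
  if (any(labels < 0 | labels > 100)) stop("labels outside [0, 100]")
  set.seed(config$seed)
  if (isTRUE(config$augment)) {
    aug <- lapply(crops, augment_crop, hist_eq_prob = config$hist_eq_prob)
    crops <- c(crops, aug)
    labels <- c(labels, labels)
  }
  X <- crop_feature_matrix(crops)
  scaler <- nn_scaler(X)
  X <- nn_scale(X, scaler)
  Y <- matrix(labels / 100, ncol = 1L)
  dev_X <- NULL; dev_Y <- NULL
  if (!is.null(dev_crops) && length(dev_crops) > 0L) {
    dev_X <- nn_scale(crop_feature_matrix(dev_crops), scaler)
    dev_Y <- matrix(dev_labels / 100, ncol = 1L)
  }
  aspects <- as.integer(vapply(crops, function(cr)
    as.numeric(cr$aspect_ratio_id), numeric(1)))
  present <- sort(unique(aspects))
  cycle <- function(ep) {
    a <- present[(ep - 1L) %% length(present) + 1L]
    which(aspects == a)
  }
  net <- nn_new(c(ncol(X), config$hidden, 1L), "linear", seed = config$seed)
  # start near the mean target: small output weights, bias at mean(Y)
  net$layers[[length(net$layers)]]$W <-
    net$layers[[length(net$layers)]]$W * 0.1
  net$layers[[length(net$layers)]]$b[] <- mean(Y)
  net <- nn_train(net, X, Y, epochs = config$epochs, lr = config$lr,
                  momentum = config$momentum,
                  batch_size = config$batch_size,
                  dev_X = dev_X, dev_Y = dev_Y, patience = config$patience,
                  epoch_subset = cycle, seed = config$seed)
  structure(list(net = net, scaler = scaler, config = config),
            class = "angio_regressor")
}

#' @export
print.angio_regressor <- function(x, ...) {
  cat(sprintf("<angio_regressor> %d epochs trained (best %d)\n",
              x$net$stopped_epoch, x$net$best_epoch))
  invisible(x)
}

#' Predict percent stenosis for a crop
#'
#' @param model an `angio_regressor`.
#' @param crop a `cropped_lesion`.
#' @return percent in `[0, 100]` (clamped).
#' @export
predict_percent <- function(model, crop) {
  predict_percents(model, list(crop))[1L]
}

#' Predict percent stenosis for a batch of crops
#' @param model an `angio_regressor`.
#' @param crops list of `cropped_lesion` objects.
#' @return numeric vector of percents in `[0, 100]`.
#' @export
predict_percents <- function(model, crops) {
  X <- nn_scale(crop_feature_matrix(crops), model$scaler)
  pmin(pmax(as.numeric(nn_predict(model$net, X)) * 100, 0), 100)
}

#' Aggregate frame-level percents to artery-level predictions
#'
#' The video-level percent of a (video, segment) group is the arithmetic
#' mean of its frame percents; the artery-level percent of an (exam,
#' segment) group is the unweighted mean of its video-level percents.
#' Lineage (contributing videos, their means and frame counts) is kept.
#'
#' @param frame_percents data.frame with columns `exam_id`, `video_id`,
#'   `segment`, `percent` (one row per frame-level prediction).
#' @return data.frame with columns `exam_id`, `segment`, `percent`,
#'   `n_videos`, `n_frames` and a `lineage` attribute (per-row data.frame
#'   of video-level means).
#' @export
aggregate_artery <- function(frame_percents) {
  if (nrow(frame_percents) == 0L)
    stop("empty prediction group")
  vid <- stats::aggregate(percent ~ exam_id + segment + video_id,
                          data = frame_percents, FUN = mean)
  vid$n_frames <- stats::aggregate(percent ~ exam_id + segment + video_id,
                                   data = frame_percents,
                                   FUN = length)$percent
  art <- stats::aggregate(percent ~ exam_id + segment, data = vid, FUN = mean)
  art$n_videos <- stats::aggregate(video_id ~ exam_id + segment, data = vid,
                                   FUN = length)$video_id
  art$n_frames <- stats::aggregate(n_frames ~ exam_id + segment, data = vid,
                                   FUN = sum)$n_frames
  art <- art[order(art$exam_id, art$segment), , drop = FALSE]
  rownames(art) <- NULL
  attr(art, "lineage") <- vid
  art
}

#' Obstructive-stenosis decision
#'
#' The clinical target is obstructive disease, defined on labels as >= 70%
#' stenosis; predictions are thresholded at 54 percent points (inclusive),
#' the F1-optimal operating point on the development data.
#'
#' @param artery_percent predicted percent in `[0, 100]`.
#' @param threshold decision threshold on the percent scale (default 54).
#' @return logical vector.
#' @export
classify_obstructive <- function(artery_percent, threshold = 54) {
  if (any(artery_percent < 0 | artery_percent > 100))
    stop("percent outside [0, 100]")
  artery_percent >= threshold
}

#' F1-optimal decision threshold
#'
#' Sweeps every candidate cut point (the unique scores) and returns the
#' threshold maximizing the F1 score of `score >= t` against the binary
#' labels; ties go to the lowest threshold.
#'
#' @param scores numeric predictions.
#' @param labels logical/0-1 ground truth.
#' @return the selected threshold.
#' @export
choose_obstructive_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    if (tp == 0L) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  cand[which.max(f1)]
}

#' Checksum of the regressor backbone parameters
#'
#' Covers every stage below the last two fully-connected layers; used to
#' audit that fine-tuning leaves the backbone bit-identical.
#'
#' @param model an `angio_regressor`.
#' @return numeric checksum.
#' @export
backbone_checksum <- function(model) {
  nl <- length(model$net$layers)
  nn_checksum(model$net, seq_len(max(nl - 2L, 0L)))
}

#' Fine-tune the regressor head on new labels
#'
#' Freezes the backbone (all stages below the last two fully-connected
#' layers; their parameters are bit-identical before and after) and
#' retrains only the final two layers. The initial learning rate is
#' chosen by grid search over `lr_grid` (dev loss after `grid_epochs`
#' epochs); the selected rate is then trained for `final_epochs` epochs,
#' dropping by a factor of 0.1 every `step_every` epochs. The dataset is
#' split 75/12.5/12.5 into train/dev/test unless an explicit `split` is
#' supplied.
#'
#' @param model a trained `angio_regressor`.
#' @param crops,labels the new-label dataset (e.g. core-lab QCA percents).
#' @param lr_grid learning-rate grid (default `10^(-4:-8)`).
#' @param grid_epochs epochs per grid candidate (default 100).
#' @param final_epochs final training epochs (default 300).
#' @param step_every epochs between 0.1x learning-rate drops (default 100).
#' @param split optional character vector (`"train"`, `"dev"`, `"test"`).
#' @param seed integer seed.
#' @return the fine-tuned `angio_regressor`; `$finetune` records the grid
#'   losses, the chosen rate and the split.
#' @export
fine_tune_head <- function(model, crops, labels,
                           lr_grid = 10^seq(-4, -8), grid_epochs = 100L,
                           final_epochs = 300L, step_every = 100L,
                           split = NULL, seed = 1L) {
  nl <- length(model$net$layers)
  if (nl < 3L) stop("model has no separable head")
  freeze <- rep(FALSE, nl)
  freeze[seq_len(nl - 2L)] <- TRUE  # backbone frozen
  set.seed(as.integer(seed))
  if (is.null(split)) {
    n <- length(crops)
    split <- sample(c(rep("train", round(0.75 * n)),
                      rep("dev", round(0.125 * n))))
    split <- c(split, rep("test", n - length(split)))[seq_len(n)]
    split <- sample(split)
  }
  tr <- which(split == "train"); dv <- which(split == "dev")
  X <- nn_scale(crop_feature_matrix(crops), model$scaler)
  Y <- matrix(labels / 100, ncol = 1L)
  grid_loss <- vapply(lr_grid, function(lr) {
    net <- nn_train(model$net, X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                    epochs = grid_epochs, lr = lr,
                    momentum = model$config$momentum,
                    batch_size = model$config$batch_size,
                    freeze = freeze, seed = seed)
    nn_loss(net, X[dv, , drop = FALSE], Y[dv, , drop = FALSE])
  }, numeric(1))
  lr0 <- lr_grid[which.min(grid_loss)]
  schedule <- function(ep) lr0 * 0.1^((ep - 1L) %/% step_every)
  net <- nn_train(model$net, X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                  epochs = final_epochs, lr = lr0,
                  momentum = model$config$momentum,
                  batch_size = model$config$batch_size,
                  lr_schedule = schedule, freeze = freeze, seed = seed)
  model$net <- net
  model$finetune <- list(lr_grid = lr_grid, grid_loss = grid_loss,
                         chosen_lr = lr0, split = split)
  model
}
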
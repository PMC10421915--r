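# Object localization: anchor-based single-stage detection of artery
# segments, stenoses and devices, plus the deterministic fusion logic
# (IoU, projection-exclusion heuristic, stenosis-to-segment assignment,
# guidewire video filter).
#
# Boxes are numeric (x_min, y_min, x_max, y_max), 0-based pixel
# coordinates, half-open on the max edges; area = (x_max - x_min) *
# (y_max - y_min).

#' Intersection over union of two boxes
#'
#' @param box_a,box_b numeric length-4 vectors `(x_min, y_min, x_max,
#'   y_max)`, half-open on the max edges.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes, 1 iff identical.
#' @export
iou <- function(box_a, box_b) {
  if (box_a[3L] <= box_a[1L] || box_a[4L] <= box_a[2L] ||
      box_b[3L] <= box_b[1L] || box_b[4L] <= box_b[2L])
    stop("degenerate box")
  ix <- max(0, min(box_a[3L], box_b[3L]) - max(box_a[1L], box_b[1L]))
  iy <- max(0, min(box_a[4L], box_b[4L]) - max(box_a[2L], box_b[2L]))
  inter <- ix * iy
  area <- function(b) (b[3L] - b[1L]) * (b[4L] - b[2L])
  inter / (area(box_a) + area(box_b) - inter)
}

# Vectorized IoU of one box against an n x 4 matrix.
iou_many <- function(box, boxes) {
  if (nrow(boxes) == 0L) return(numeric())
  ix <- pmax(0, pmin(box[3L], boxes[, 3L]) - pmax(box[1L], boxes[, 1L]))
  iy <- pmax(0, pmin(box[4L], boxes[, 4L]) - pmax(box[2L], boxes[, 2L]))
  inter <- ix * iy
  a <- (box[3L] - box[1L]) * (box[4L] - box[2L])
  b <- (boxes[, 3L] - boxes[, 1L]) * (boxes[, 4L] - boxes[, 2L])
  inter / (a + b - inter)
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

empty_detections <- function() {
  data.frame(class = character(), score = numeric(), x_min = numeric(),
             y_min = numeric(), x_max = numeric(), y_max = numeric(),
             stringsAsFactors = FALSE)
}

# --- anchors and features ---------------------------------------------------

#' Default detector configuration
#' @param ... overrides (anchor stride/scales/aspects, feature grid,
#'   hidden units, epochs, lr, focal gamma, seed).
#' @return named list.
#' @export
detector_config <- function(...) {
  cfg <- list(stride = 8L, scales = c(12, 16, 22, 30, 42, 58, 80),
              aspects = c(1, 2, 0.5, 3, 1 / 3),
              grid = 8L, hidden = 40L, epochs = 30L, lr = 0.08,
              momentum = 0.9, batch_size = 64L, focal_gamma = 2,
              neg_per_frame = 220L, pos_iou = 0.5, reg_iou = 0.4,
              bg_iou = 0.4, nms_iou = 0.45, vote_iou = 0.5, seed = 1L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# Dense multi-scale anchor grid for a square frame, clipped, as m x 4.
anchor_grid <- function(frame_size, config) {
  centers <- seq(config$stride / 2, frame_size - config$stride / 2,
                 by = config$stride)
  combos <- expand.grid(cx = centers, cy = centers, s = config$scales,
                        a = config$aspects)
  w <- combos$s * sqrt(combos$a)
  h <- combos$s / sqrt(combos$a)
  m <- cbind(combos$cx - w / 2, combos$cy - h / 2,
             combos$cx + w / 2, combos$cy + h / 2)
  m[, 1L] <- pmax(m[, 1L], 0); m[, 2L] <- pmax(m[, 2L], 0)
  m[, 3L] <- pmin(m[, 3L], frame_size); m[, 4L] <- pmin(m[, 4L], frame_size)
  keep <- (m[, 3L] - m[, 1L]) >= 4 & (m[, 4L] - m[, 2L]) >= 4
  m[keep, , drop = FALSE]
}

# Vesselness image: attenuation below the median gray level.
vesselness <- function(img) pmax(stats::median(img) - img, 0)

# Per-anchor features: integral-pooled vesselness and lumen-width
# (distance transform) grids, axis energy profiles (lumen-narrowing
# cues: min/mean/ratio of per-row and per-column pooled energy) and log
# box size.
anchor_features <- function(img, anchors, grid = 8L) {
  v <- vesselness(img)
  ii <- ap_integral(v)
  pool <- ap_box_pool(ii, anchors, grid, grid)
  mask <- v >= max(v) / 2
  dt <- suppressWarnings(EBImage::distmap(EBImage::Image(mask * 1)))@.Data
  pool_dt <- ap_box_pool(ap_integral(dt), anchors, grid, grid)
  # rows of `pool` are gy-major: cell (gy, gx) at column (gy-1)*grid+gx
  colE <- matrix(vapply(seq_len(grid), function(gx)
    rowSums(pool[, (seq_len(grid) - 1L) * grid + gx, drop = FALSE]),
    numeric(nrow(pool))), nrow = nrow(pool))
  rowE <- matrix(vapply(seq_len(grid), function(gy)
    rowSums(pool[, (gy - 1L) * grid + seq_len(grid), drop = FALSE]),
    numeric(nrow(pool))), nrow = nrow(pool))
  prof <- function(E) {
    mn <- do.call(pmin, as.data.frame(E))
    mu <- rowMeans(E)
    cbind(mn, mu, mn / pmax(mu, 1e-6))
  }
  cbind(pool, pool_dt, prof(colE), prof(rowE),
        log(anchors[, 3L] - anchors[, 1L]),
        log(anchors[, 4L] - anchors[, 2L]))
}

# --- training ---------------------------------------------------------------

#' Train the lesion detector
#'
#' A single-stage anchor-based detector: a dense multi-scale anchor grid
#' is scored by a softmax network (focal-loss objective, gamma 2) on
#' integral-image pooled vesselness features, with a class-agnostic linear
#' box refinement fitted on positive anchors by ridge regression. Anchors
#' with IoU >= 0.5 against a ground-truth box take its class; anchors
#' below 0.4 against every box are background; the band between is
#' ignored.
#'
#' @param annotated_frames list of entries `list(image, boxes, meta)`
#'   where `boxes` is a data.frame with `class` and the four box columns,
#'   and `meta` optionally carries `side` and `projection`.
#' @param config a [detector_config()].
#' @param scope `"all_lcarca"` (default) or `"rca_lao"`; the latter
#'   refuses frames from the left coronary tree and keeps only RCA frames
#'   in LAO projections.
#' @param vocab detector class vocabulary.
#' @return an object of class `angio_detector`.
#' @export
train_detector <- function(annotated_frames, config = detector_config(),
                           scope = c("all_lcarca", "rca_lao"),
                           vocab = detector_classes()) {
  scope <- match.arg(scope)
  if (length(annotated_frames) == 0L) stop("empty annotation set")
  if (scope == "rca_lao") {
    sides <- vapply(annotated_frames, function(f)
      tolower(if (is.null(f$meta$side)) "" else f$meta$side), character(1))
    if (any(sides == "lca"))
      stop("scope rca_lao refuses LCA-labeled frames")
    projs <- vapply(annotated_frames, function(f)
      if (is.null(f$meta$projection)) "" else f$meta$projection, character(1))
    annotated_frames <- annotated_frames[startsWith(projs, "LAO")]
    if (length(annotated_frames) == 0L)
      stop("no RCA-LAO frames in annotation set")
  }
  S <- nrow(annotated_frames[[1L]]$image)
  anchors <- anchor_grid(S, config)
  bg <- "__background__"
  classes <- c(vocab, bg)
  set.seed(config$seed)
  Xs <- list(); ys <- list(); regX <- list(); regY <- list(); regG <- list()
  for (fr in annotated_frames) {
    gt <- fr$boxes
    if (nrow(gt) > 0L && any(gt$x_max > S | gt$y_max > S | gt$x_min < 0 |
                             gt$y_min < 0))
      stop("annotation box outside frame")
    gtm <- as.matrix(gt[box_cols])
    best_iou <- rep(0, nrow(anchors)); best_gt <- rep(NA_integer_,
                                                     nrow(anchors))
    for (g in seq_len(nrow(gtm))) {
      ious <- iou_many(gtm[g, ], anchors)
      upd <- ious > best_iou
      best_iou[upd] <- ious[upd]; best_gt[upd] <- g
    }
    pos <- which(best_iou >= config$pos_iou)
    reg <- which(best_iou >= config$reg_iou)  # wider band for regression
    neg <- which(best_iou < config$bg_iou)
    if (length(neg) > config$neg_per_frame)
      neg <- sample(neg, config$neg_per_frame)
    take <- unique(c(pos, reg, neg))
    if (length(take) == 0L) next
    feats <- anchor_features(fr$image, anchors[take, , drop = FALSE],
                             config$grid)
    cls_rows <- match(c(pos, neg), take)
    Xs[[length(Xs) + 1L]] <- feats[cls_rows, , drop = FALSE]
    ys[[length(ys) + 1L]] <- c(gt$class[best_gt[pos]],
                               rep(bg, length(neg)))
    if (length(reg) > 0L) {
      a <- anchors[reg, , drop = FALSE]
      g <- gtm[best_gt[reg], , drop = FALSE]
      aw <- a[, 3L] - a[, 1L]; ah <- a[, 4L] - a[, 2L]
      regX[[length(regX) + 1L]] <- feats[match(reg, take), , drop = FALSE]
      regY[[length(regY) + 1L]] <- cbind(
        ((g[, 1L] + g[, 3L]) - (a[, 1L] + a[, 3L])) / (2 * aw),
        ((g[, 2L] + g[, 4L]) - (a[, 2L] + a[, 4L])) / (2 * ah),
        log((g[, 3L] - g[, 1L]) / aw),
        log((g[, 4L] - g[, 2L]) / ah))
      regG[[length(regG) + 1L]] <- gt$class[best_gt[reg]] == "stenosis"
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  scaler <- nn_scaler(X)
  X <- nn_scale(X, scaler)
  net <- nn_new(c(ncol(X), config$hidden, length(classes)), "softmax",
                seed = config$seed)
  net <- nn_train(net, X, nn_onehot(y, classes), epochs = config$epochs,
                  lr = config$lr, momentum = config$momentum,
                  batch_size = config$batch_size,
                  focal_gamma = config$focal_gamma, seed = config$seed)
  # two box-refinement heads: compact lesions vs elongated segments
  boxreg <- NULL
  if (length(regX) > 0L) {
    RX <- cbind(1, nn_scale(do.call(rbind, regX), scaler))
    RY <- do.call(rbind, regY)
    is_sten <- unlist(regG)
    lambda <- 1e-2
    fit <- function(rows) {
      if (sum(rows) < 8L) rows <- rep(TRUE, nrow(RX))
      X <- RX[rows, , drop = FALSE]
      solve(crossprod(X) + lambda * diag(ncol(X)),
            crossprod(X, RY[rows, , drop = FALSE]))
    }
    boxreg <- list(stenosis = fit(is_sten), segment = fit(!is_sten))
  }
  structure(list(net = net, boxreg = boxreg, classes = classes, vocab = vocab,
                 scaler = scaler, config = config, frame_size = S,
                 anchors = anchors, scope = scope),
            class = "angio_detector")
}

#' @export
print.angio_detector <- function(x, ...) {
  cat(sprintf("<angio_detector> scope=%s, %d classes, %d anchors/frame\n",
              x$scope, length(x$vocab), nrow(x$anchors)))
  invisible(x)
}

# Greedy per-class non-maximum suppression.
nms <- function(det, iou_threshold) {
  keep <- logical(nrow(det))
  for (cls in unique(det$class)) {
    idx <- which(det$class == cls)
    idx <- idx[order(-det$score[idx])]
    taken <- integer()
    for (i in idx) {
      b <- as.numeric(det[i, box_cols])
      if (length(taken) == 0L ||
          all(iou_many(b, as.matrix(det[taken, box_cols])) <= iou_threshold)) {
        taken <- c(taken, i)
      }
    }
    keep[taken] <- TRUE
  }
  det[keep, , drop = FALSE]
}

#' Detect objects in a frame
#'
#' Scores every anchor, refines positive anchors with the linear box
#' regressor, clips to the frame and applies per-class non-maximum
#' suppression. All returned detections have `score >= score_threshold`.
#'
#' @param detector an `angio_detector`.
#' @param frame matrix at the detector's training resolution.
#' @param score_threshold minimum class probability retained.
#' @return data.frame with columns `class`, `score`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @export
detect_objects <- function(detector, frame, score_threshold = 0.5) {
  if (nrow(frame) != detector$frame_size || ncol(frame) != detector$frame_size)
    stop("frame resolution does not match detector")
  anchors <- detector$anchors
  feats <- anchor_features(frame, anchors, detector$config$grid)
  X <- nn_scale(feats, detector$scaler)
  P <- nn_predict(detector$net, X)
  colnames(P) <- detector$classes
  Pv <- P[, detector$vocab, drop = FALSE]
  best <- max.col(Pv, ties.method = "first")
  score <- Pv[cbind(seq_len(nrow(Pv)), best)]
  keep <- which(score >= score_threshold)
  if (length(keep) == 0L) return(empty_detections())
  S <- detector$frame_size
  boxes <- anchors[keep, , drop = FALSE]
  if (!is.null(detector$boxreg)) {
    boxes <- apply_boxreg(detector, X[keep, , drop = FALSE], boxes,
                          detector$vocab[best[keep]], clamp = 1, S = S)
  }
  ok <- boxes[, 3L] > boxes[, 1L] & boxes[, 4L] > boxes[, 2L]
  det <- data.frame(class = detector$vocab[best[keep]], score = score[keep],
                    x_min = boxes[, 1L], y_min = boxes[, 2L],
                    x_max = boxes[, 3L], y_max = boxes[, 4L],
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  kept <- nms(det, detector$config$nms_iou)
  # box voting: each surviving box is the score-weighted mean of the
  # overlapping pre-suppression candidates of its class
  vote <- detector$config$vote_iou
  if (!is.null(vote) && nrow(kept) > 0L) {
    for (i in seq_len(nrow(kept))) {
      same <- det[det$class == kept$class[i], , drop = FALSE]
      ious <- iou_many(as.numeric(kept[i, box_cols]),
                       as.matrix(same[box_cols]))
      sup <- same[ious >= vote, , drop = FALSE]
      if (nrow(sup) > 1L) {
        w <- sup$score / sum(sup$score)
        kept[i, box_cols] <- colSums(as.matrix(sup[box_cols]) * w)
      }
    }
  }
  # second refinement pass: re-pool features at the voted boxes and apply
  # the regressor once more (small localization cascade)
  if (!is.null(detector$boxreg) && nrow(kept) > 0L) {
    bm <- as.matrix(kept[box_cols])
    f2 <- nn_scale(anchor_features(frame, bm, detector$config$grid),
                   detector$scaler)
    bm <- apply_boxreg(detector, f2, bm, kept$class, clamp = 0.5, S = S)
    good <- bm[, 3L] > bm[, 1L] & bm[, 4L] > bm[, 2L]
    kept[good, box_cols] <- bm[good, , drop = FALSE]
    # refined boxes can re-cluster; suppress duplicates once more
    kept <- nms(kept, detector$config$nms_iou)
  }
  rownames(kept) <- NULL
  kept
}

# Apply the class-group box-refinement heads to scaled features.
apply_boxreg <- function(detector, Xs, boxes, classes, clamp, S) {
  X1 <- cbind(1, Xs)
  D <- matrix(0, nrow(X1), 4L)
  sten <- classes == "stenosis"
  if (any(sten)) D[sten, ] <- X1[sten, , drop = FALSE] %*%
      detector$boxreg$stenosis
  if (any(!sten)) D[!sten, ] <- X1[!sten, , drop = FALSE] %*%
      detector$boxreg$segment
  aw <- boxes[, 3L] - boxes[, 1L]; ah <- boxes[, 4L] - boxes[, 2L]
  cx <- (boxes[, 1L] + boxes[, 3L]) / 2 + D[, 1L] * aw
  cy <- (boxes[, 2L] + boxes[, 4L]) / 2 + D[, 2L] * ah
  w <- aw * exp(pmin(pmax(D[, 3L], -clamp), clamp))
  h <- ah * exp(pmin(pmax(D[, 4L], -clamp), clamp))
  cbind(pmax(cx - w / 2, 0), pmax(cy - h / 2, 0),
        pmin(cx + w / 2, S), pmin(cy + h / 2, S))
}

# --- fusion logic -----------------------------------------------------------

#' Remove projection-excluded artery segments from a detection set
#'
#' Some artery segments are foreshortened or invisible in certain
#' projections; the exclusion map (projection label -> excluded segment
#' classes) removes such detections. Non-segment classes (stenosis,
#' guidewire, ...) are never removed. With an empty map this is the
#' identity; it never adds detections and is idempotent.
#'
#' @param detections detection data.frame.
#' @param projection_label one of the 12 projection labels.
#' @param exclusion_map named list: projection label -> character vector
#'   of excluded segment classes.
#' @return filtered detection data.frame.
#' @export
apply_projection_heuristic <- function(detections, projection_label,
                                       exclusion_map = list()) {
  if (!projection_label %in% projection_labels())
    stop("unknown projection label: ", projection_label)
  excl <- exclusion_map[[projection_label]]
  if (is.null(excl) || nrow(detections) == 0L) return(detections)
  excl <- intersect(excl, segment_classes())
  out <- detections[!(detections$class %in% excl), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign stenosis detections to artery segments
#'
#' Each stenosis box pairs with the artery-segment box of greatest IoU
#' among those with IoU >= `min_iou` (default 0.20); stenoses with no
#' qualifying segment are unassigned and dropped. Equal-IoU ties go to
#' the lowest segment-class index in the canonical ordering.
#'
#' @param detections detection data.frame for one frame.
#' @param min_iou assignment eligibility threshold.
#' @return data.frame with the stenosis box columns, `score`, `segment`
#'   and `iou`; the `"unassigned"` attribute counts dropped stenoses.
#' @export
assign_stenosis_to_segment <- function(detections, min_iou = 0.20) {
  sten <- detections[detections$class == "stenosis", , drop = FALSE]
  segs <- detections[detections$class %in% segment_classes(), , drop = FALSE]
  out <- list(); dropped <- 0L
  seg_order <- match(segs$class, segment_classes())
  segm <- as.matrix(segs[box_cols])
  for (i in seq_len(nrow(sten))) {
    b <- as.numeric(sten[i, box_cols])
    if (nrow(segs) == 0L) { dropped <- dropped + 1L; next }
    ious <- iou_many(b, segm)
    elig <- which(ious >= min_iou)
    if (length(elig) == 0L) { dropped <- dropped + 1L; next }
    best <- elig[order(-ious[elig], seg_order[elig])][1L]
    out[[length(out) + 1L]] <- data.frame(
      x_min = b[1L], y_min = b[2L], x_max = b[3L], y_max = b[4L],
      score = sten$score[i], segment = segs$class[best], iou = ious[best],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) == 0L) {
    data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
               y_max = numeric(), score = numeric(), segment = character(),
               iou = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  attr(res, "unassigned") <- dropped
  res
}

# Anatomical deduplication: each coronary segment appears at most once
# in a frame, so keep only the top-scoring box per segment class (other
# classes pass through). Optionally restrict segments to one coronary
# tree when the video's anatomy is known.
dedupe_segments <- function(detections, side = NULL) {
  is_seg <- detections$class %in% segment_classes()
  if (!is.null(side) && side %in% c("lca", "rca")) {
    allowed <- tree_segments(if (side == "lca") "LCA" else "RCA")
    drop <- is_seg & !(detections$class %in% allowed)
    detections <- detections[!drop, , drop = FALSE]
    is_seg <- detections$class %in% segment_classes()
  }
  segs <- detections[is_seg, , drop = FALSE]
  if (nrow(segs) > 1L) {
    keep <- unlist(lapply(split(seq_len(nrow(segs)), segs$class), function(i)
      i[which.max(segs$score[i])]), use.names = FALSE)
    segs <- segs[sort(keep), , drop = FALSE]
  }
  out <- rbind(segs, detections[!is_seg, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Guidewire video filter
#'
#' Videos in which an intracoronary guidewire is detected in more than
#' `max_frames` frames (default 4) likely show an intervention in
#' progress and are dropped from stenosis estimation.
#'
#' @param per_frame_detections list of detection data.frames, one per
#'   extracted frame of a video.
#' @param max_frames strict threshold on guidewire-containing frames.
#' @return `"keep"` or `"drop"`.
#' @export
guidewire_filter <- function(per_frame_detections, max_frames = 4L) {
  n_gw <- sum(vapply(per_frame_detections, function(d)
    any(d$class == "guidewire"), logical(1)))
  if (n_gw > max_frames) "drop" else "keep"
}

# --- evaluation matching ----------------------------------------------------

# Greedy true-positive matching: detections in descending score order,
# each consuming at most one unmatched ground-truth box of its class at
# IoU >= iou_threshold. Returns the detections with a `tp` flag and the
# number of ground truths.
match_detections <- function(detections, ground_truths, iou_threshold = 0.5) {
  det <- detections[order(-detections$score), , drop = FALSE]
  tp <- logical(nrow(det))
  used <- logical(nrow(ground_truths))
  gtm <- as.matrix(ground_truths[box_cols])
  for (i in seq_len(nrow(det))) {
    same <- which(!used & ground_truths$class == det$class[i])
    if (length(same) == 0L) next
    ious <- iou_many(as.numeric(det[i, box_cols]),
                     gtm[same, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      used[same[j]] <- TRUE
    }
  }
  det$tp <- tp
  det
}

# --- COCO-style interchange -------------------------------------------------

#' Convert annotated frames to COCO-style JSON
#'
#' Boxes are emitted as `[x, y, w, h]`; the conversion from the internal
#' half-open `(x_min, y_min, x_max, y_max)` convention is exact and
#' round-trips bit-identically through [from_coco()].
#'
#' @param annotated_frames list of `list(image_id, boxes)` entries (the
#'   `image` matrix itself is not serialized).
#' @param path optional output file; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
to_coco <- function(annotated_frames, path = NULL) {
  cats <- detector_classes()
  images <- lapply(seq_along(annotated_frames), function(i)
    list(id = i, file_name = as.character(
      if (!is.null(annotated_frames[[i]]$image_id))
        annotated_frames[[i]]$image_id else i)))
  anns <- list()
  for (i in seq_along(annotated_frames)) {
    b <- annotated_frames[[i]]$boxes
    for (j in seq_len(nrow(b))) {
      anns[[length(anns) + 1L]] <- list(
        id = length(anns) + 1L, image_id = i,
        category_id = match(b$class[j], cats),
        bbox = c(b$x_min[j], b$y_min[j],
                 b$x_max[j] - b$x_min[j], b$y_max[j] - b$y_min[j]))
    }
  }
  doc <- list(
    images = images,
    categories = lapply(seq_along(cats), function(k)
      list(id = k, name = cats[k])),
    annotations = anns)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Read COCO-style JSON back to annotated-frame boxes
#'
#' @param json a JSON string or file path produced by [to_coco()].
#' @return list of `list(image_id, boxes)` entries in the internal
#'   half-open convention.
#' @export
from_coco <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  cats <- vapply(doc$categories, function(c) c$name, character(1))
  cat_id <- vapply(doc$categories, function(c) as.integer(c$id), integer(1))
  out <- lapply(doc$images, function(im)
    list(image_id = im$file_name, boxes = empty_annotation_boxes()))
  names(out) <- vapply(doc$images, function(im) as.character(im$id),
                       character(1))
  for (a in doc$annotations) {
    bb <- as.numeric(a$bbox)
    row <- data.frame(class = cats[match(a$category_id, cat_id)],
                      x_min = bb[1L], y_min = bb[2L],
                      x_max = bb[1L] + bb[3L], y_max = bb[2L] + bb[4L],
                      stringsAsFactors = FALSE)
    key <- as.character(a$image_id)
    out[[key]]$boxes <- rbind(out[[key]]$boxes, row)
  }
  unname(out)
}

empty_annotation_boxes <- function() {
  data.frame(class = character(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), stringsAsFactors = FALSE)
}
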
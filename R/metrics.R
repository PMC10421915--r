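# Evaluation layer: classification reports, detection average precision,
# ROC AUC, subsample-bootstrap confidence intervals, ICC(2,2),
# Bland-Altman agreement and fixed-threshold operating points.

#' Per-class classification report
#'
#' One-vs-rest positive predictive value (precision), sensitivity
#' (recall) and F1 (their harmonic mean) per class, with supports, a
#' confusion matrix (rows = truth, columns = prediction) and
#' frequency-weighted averages. Classes with zero support get `NA`
#' metrics; undefined metrics are excluded (with their weight) from the
#' weighted averages rather than counted as zero.
#'
#' @param pred_labels,true_labels equal-length label vectors.
#' @param vocabulary label vocabulary; labels outside it are an error.
#' @return an object of class `classification_report` with fields
#'   `per_class` (data.frame), `weighted` (named numeric) and `confusion`
#'   (matrix).
#' @export
classification_report <- function(pred_labels, true_labels, vocabulary) {
  stopifnot(length(pred_labels) == length(true_labels))
  if (!all(pred_labels %in% vocabulary) || !all(true_labels %in% vocabulary))
    stop("label outside vocabulary")
  p <- factor(pred_labels, levels = vocabulary)
  t <- factor(true_labels, levels = vocabulary)
  cm <- table(truth = t, prediction = p)
  support <- rowSums(cm)
  tp <- diag(cm)
  ppv <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  sens <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(ppv) & !is.na(sens) & (ppv + sens) > 0,
               2 * ppv * sens / (ppv + sens),
               ifelse(!is.na(ppv) & !is.na(sens), 0, NA_real_))
  per <- data.frame(class = vocabulary, ppv = as.numeric(ppv),
                    sensitivity = as.numeric(sens), f1 = as.numeric(f1),
                    support = as.numeric(support), stringsAsFactors = FALSE)
  wavg <- function(x) {
    ok <- !is.na(x) & support > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * support[ok]) / sum(support[ok])
  }
  structure(list(per_class = per,
                 weighted = c(ppv = wavg(ppv), sensitivity = wavg(sens),
                              f1 = wavg(f1)),
                 confusion = unclass(cm),
                 accuracy = sum(tp) / length(t)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("weighted: PPV %.3f, sensitivity %.3f, F1 %.3f; accuracy %.3f\n",
              x$weighted["ppv"], x$weighted["sensitivity"],
              x$weighted["f1"], x$accuracy))
  invisible(x)
}

#' Average precision of a detection class
#'
#' Greedy score-ordered matching against unmatched ground truths of the
#' class (a detection is a true positive iff IoU >= `iou_threshold`),
#' followed by the exact all-point precision-recall integral (the
#' precision envelope). Classes with no ground truths have undefined AP.
#'
#' @param detections data.frame with `image_id`, `class`, `score` and box
#'   columns.
#' @param ground_truths data.frame with `image_id`, `class` and box
#'   columns.
#' @param iou_threshold true-positive IoU threshold (default 0.5).
#' @param class the class evaluated.
#' @return AP in `[0, 1]`, or `NA` if the class has no ground truths.
#' @export
average_precision <- function(detections, ground_truths,
                              iou_threshold = 0.5, class) {
  gt <- ground_truths[ground_truths$class == class, , drop = FALSE]
  if (nrow(gt) == 0L) return(NA_real_)
  det <- detections[detections$class == class, , drop = FALSE]
  if (nrow(det) == 0L) return(0)
  rows <- list()
  for (img in unique(c(det$image_id, gt$image_id))) {
    d <- det[det$image_id == img, , drop = FALSE]
    g <- gt[gt$image_id == img, , drop = FALSE]
    if (nrow(d) == 0L) next
    rows[[length(rows) + 1L]] <- match_detections(d, g, iou_threshold)
  }
  m <- do.call(rbind, rows)
  m <- m[order(-m$score), , drop = FALSE]
  tp <- cumsum(m$tp)
  fp <- cumsum(!m$tp)
  recall <- tp / nrow(gt)
  precision <- tp / (tp + fp)
  # precision envelope, exact area under the PR staircase
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Support-weighted mean average precision
#'
#' @inheritParams average_precision
#' @param classes classes to average over; classes without ground truths
#'   are excluded (their AP is undefined).
#' @return list with `mAP` and the per-class AP vector.
#' @export
mean_average_precision <- function(detections, ground_truths,
                                   iou_threshold = 0.5,
                                   classes = unique(ground_truths$class)) {
  ap <- vapply(classes, function(cl)
    average_precision(detections, ground_truths, iou_threshold, cl),
    numeric(1))
  names(ap) <- classes
  support <- vapply(classes, function(cl)
    sum(ground_truths$class == cl), numeric(1))
  ok <- !is.na(ap) & support > 0
  list(mAP = if (any(ok)) sum(ap[ok] * support[ok]) / sum(support[ok])
             else NA_real_,
       per_class = ap)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with midranks for
#' ties.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param binary_labels logical/0-1 ground truth; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, binary_labels) {
  y <- as.logical(binary_labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval over 80% resamples
#'
#' Each iteration resamples `ceiling(fraction * n)` records (an
#' m-out-of-n bootstrap, with replacement by default), computes the
#' metric, and the 5th and 95th percentiles of the resulting distribution
#' are reported. Note the 5th/95th percentile pair is nominally a 90%
#' interval; it is reported as such by convention here. `replace = FALSE`
#' switches to plain subsampling without replacement. Iterations on which
#' the metric is undefined (`NA`/error) are redrawn, up to a hard cap.
#' Deterministic given the seed.
#'
#' @param metric_fn function of a data subset (vector or data.frame
#'   rows).
#' @param data a vector or data.frame with at least 10 records.
#' @param fraction resample fraction (default 0.8).
#' @param iterations number of resamples (default 1000).
#' @param seed integer seed.
#' @param probs percentile pair (default `c(0.05, 0.95)`).
#' @param replace draw with replacement (default `TRUE`).
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(metric_fn, data, fraction = 0.8,
                         iterations = 1000L, seed = 1L,
                         probs = c(0.05, 0.95), replace = TRUE) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 10L) stop("need at least 10 records")
  m <- ceiling(fraction * n)
  set.seed(as.integer(seed))
  vals <- numeric(iterations)
  for (i in seq_len(iterations)) {
    v <- NA_real_
    tries <- 0L
    while (is.na(v)) {
      tries <- tries + 1L
      if (tries > 100L) stop("metric undefined on repeated subsamples")
      idx <- sample.int(n, m, replace = replace)
      sub <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
      v <- tryCatch(suppressWarnings(as.numeric(metric_fn(sub))[1L]),
                    error = function(e) NA_real_)
    }
    vals[i] <- v
  }
  q <- stats::quantile(vals, probs, names = FALSE)
  c(lower = q[1L], upper = q[2L])
}

#' Intraclass correlation ICC(2,2)
#'
#' Two-way random-effects, absolute-agreement, average-measures
#' intraclass correlation between two raters, from the two-way
#' mean-squares decomposition, with the conventional reliability bands:
#' poor (< 0.5), moderate (0.50-0.75), good (0.76-0.90), excellent
#' (0.91-1.0).
#'
#' @param ratings_a,ratings_b paired continuous ratings, n >= 3.
#' @return list with `icc` and `band` (`NA` when both raters are
#'   constant).
#' @export
icc_2_2 <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b))
  n <- length(ratings_a)
  if (n < 3L) stop("need at least 3 paired ratings")
  X <- cbind(ratings_a, ratings_b)
  if (stats::sd(ratings_a) == 0 && stats::sd(ratings_b) == 0)
    return(list(icc = NA_real_, band = NA_character_))
  k <- 2L
  grand <- mean(X)
  rm <- rowMeans(X); cm <- colMeans(X)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  mse <- sum((X - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  band <- if (icc < 0.5) "poor" else if (icc <= 0.75) "moderate"
          else if (icc <= 0.90) "good" else "excellent"
  list(icc = icc, band = band)
}

#' Bland-Altman agreement
#'
#' @param x,y paired measurements (n >= 2).
#' @return list with `bias` (mean of `x - y`) and `limits`
#'   (`bias +- 1.96 sd(x - y)`).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, limits = c(lower = bias - 1.96 * s,
                               upper = bias + 1.96 * s))
}

#' Operating point at a decision threshold
#'
#' The 2x2 table of `score >= threshold` against the binary labels.
#' Alternatively answers fixed-sensitivity or fixed-specificity queries
#' by exhaustive threshold search: `fixed_sensitivity` returns the
#' largest threshold whose sensitivity is at least the target.
#'
#' @param scores numeric predictions.
#' @param labels logical/0-1 ground truth; both classes required.
#' @param threshold decision threshold (ignored if a fixed query is
#'   given).
#' @param fixed_sensitivity,fixed_specificity optional targets in
#'   `[0, 1]`.
#' @return named list with `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
operating_point <- function(scores, labels, threshold = NULL,
                            fixed_sensitivity = NULL,
                            fixed_specificity = NULL) {
  y <- as.logical(labels)
  if (sum(y) == 0L || sum(!y) == 0L) stop("both classes must be present")
  eval_at <- function(t) {
    pred <- scores >= t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    list(threshold = t,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }
  if (!is.null(fixed_sensitivity)) {
    cand <- sort(unique(c(scores, -Inf)))
    sens <- vapply(cand, function(t) eval_at(t)$sensitivity, numeric(1))
    ok <- cand[sens >= fixed_sensitivity]
    return(eval_at(max(ok)))
  }
  if (!is.null(fixed_specificity)) {
    cand <- sort(unique(c(scores, Inf)))
    spec <- vapply(cand, function(t) eval_at(t)$specificity, numeric(1))
    ok <- cand[spec >= fixed_specificity]
    return(eval_at(min(ok)))
  }
  eval_at(threshold)
}
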
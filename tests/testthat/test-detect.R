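test_that("IoU handles the canonical cases", {
  expect_identical(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_identical(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 5, 15, 15)), 25 / 175,
               tolerance = 1e-12)
  expect_identical(iou(c(0, 0, 10, 10), c(5, 5, 15, 15)),
                   iou(c(5, 5, 15, 15), c(0, 0, 10, 10)))
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("IoU matches pixel enumeration on random integer boxes", {
  set.seed(8)
  for (i in 1:200) {
    a <- random_box(20L); b <- random_box(20L)
    expect_equal(iou(a, b), pixel_iou(a, b), tolerance = 1e-12)
  }
})

test_that("stenosis assignment picks the greatest-overlap segment", {
  det <- data.frame(
    class = c("stenosis", "rca_prox", "rca_mid"),
    score = c(0.9, 0.8, 0.7),
    x_min = c(10, 8, 16), y_min = c(10, 8, 14),
    x_max = c(20, 22, 30), y_max = c(20, 22, 30),
    stringsAsFactors = FALSE)
  a <- assign_stenosis_to_segment(det)
  expect_identical(nrow(a), 1L)
  expect_identical(a$segment, "rca_prox")  # larger overlap than rca_mid
  expect_gte(a$iou, 0.20)
  # below threshold -> unassigned
  det2 <- det
  det2[2:3, c("x_min", "y_min", "x_max", "y_max")] <-
    cbind(c(40, 60), c(40, 60), c(50, 70), c(50, 70))
  a2 <- assign_stenosis_to_segment(det2)
  expect_identical(nrow(a2), 0L)
  expect_identical(attr(a2, "unassigned"), 1L)
})

test_that("stenosis assignment agrees with a brute-force oracle", {
  set.seed(13)
  seg_levels <- segment_classes()
  for (rep in 1:200) {
    n_seg <- sample(1:5, 1); n_st <- sample(1:3, 1)
    det <- data.frame(
      class = c(rep("stenosis", n_st),
                sample(seg_levels, n_seg, replace = FALSE)),
      score = runif(n_st + n_seg),
      t(replicate(n_st + n_seg, random_box(20L))),
      stringsAsFactors = FALSE)
    names(det)[3:6] <- c("x_min", "y_min", "x_max", "y_max")
    got <- assign_stenosis_to_segment(det)
    # oracle: exhaustive pairwise IoU argmax with canonical-order ties
    st <- det[det$class == "stenosis", ]
    sg <- det[det$class != "stenosis", ]
    want_n <- 0L
    for (i in seq_len(nrow(st))) {
      ious <- apply(sg[, 3:6], 1, function(b)
        iou(as.numeric(st[i, 3:6]), as.numeric(b)))
      if (max(ious) >= 0.20) {
        want_n <- want_n + 1L
        best <- which(ious == max(ious))
        best <- best[order(match(sg$class[best], seg_levels))][1]
        expect_identical(got$segment[want_n], sg$class[best])
        expect_equal(got$iou[want_n], max(ious), tolerance = 1e-12)
      }
    }
    expect_identical(nrow(got), want_n)
    if (nrow(got) > 0) expect_true(all(got$iou >= 0.20))
  }
})

test_that("the projection heuristic removes only mapped segment classes", {
  det <- data.frame(class = c("lad_mid", "lad_mid", "stenosis", "guidewire"),
                    score = c(0.9, 0.8, 0.7, 0.6),
                    x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                    stringsAsFactors = FALSE)
  expect_identical(apply_projection_heuristic(det, "LAO straight"), det)
  out <- apply_projection_heuristic(
    det, "LAO straight", list(`LAO straight` = "lad_mid"))
  expect_identical(nrow(out), 2L)
  expect_false("lad_mid" %in% out$class)
  expect_true(all(c("stenosis", "guidewire") %in% out$class))
  # non-segment classes are never removed even if mapped
  out2 <- apply_projection_heuristic(
    det, "LAO straight", list(`LAO straight` = c("stenosis", "lad_mid")))
  expect_true("stenosis" %in% out2$class)
  # idempotent, never adds
  expect_identical(apply_projection_heuristic(
    out, "LAO straight", list(`LAO straight` = "lad_mid")), out)
  expect_error(apply_projection_heuristic(det, "sideways"), "unknown")
})

test_that("the guidewire filter drops videos strictly above 4 frames", {
  gw <- data.frame(class = "guidewire", score = 0.9, x_min = 0, y_min = 0,
                   x_max = 5, y_max = 5, stringsAsFactors = FALSE)
  none <- gw[0, ]
  expect_identical(guidewire_filter(c(replicate(5, gw, simplify = FALSE),
                                      list(none))), "drop")
  expect_identical(guidewire_filter(c(replicate(4, gw, simplify = FALSE),
                                      list(none, none))), "keep")
  expect_identical(guidewire_filter(replicate(8, none, simplify = FALSE)),
                   "keep")
})

test_that("detection scope and threshold contracts hold", {
  set.seed(4)
  mk_frame <- function(side) {
    img <- matrix(0.8, 64, 64) + matrix(rnorm(4096, 0, 0.01), 64)
    img[20:30, 10:50] <- 0.3
    list(image = img,
         boxes = data.frame(class = if (side == "rca") "rca_mid"
                            else "lad_mid",
                            x_min = 9, y_min = 19, x_max = 51, y_max = 31,
                            stringsAsFactors = FALSE),
         meta = list(side = side, projection = "LAO straight"))
  }
  frames <- replicate(6, mk_frame("rca"), simplify = FALSE)
  expect_error(train_detector(c(frames, list(mk_frame("lca"))),
                              detector_config(epochs = 1L),
                              scope = "rca_lao"),
               "refuses LCA")
  det <- train_detector(frames, detector_config(epochs = 4L,
                                                scales = c(16, 32, 48)),
                        scope = "rca_lao")
  f <- frames[[1]]$image
  expect_identical(nrow(detect_objects(det, f, 1.0)), 0L)
  d0 <- detect_objects(det, f, 0)
  d5 <- detect_objects(det, f, 0.5)
  expect_true(all(d5$score >= 0.5))
  expect_gte(nrow(d0), nrow(d5))   # monotone filtering
  expect_error(detect_objects(det, matrix(0, 32, 32), 0.5), "resolution")
})

test_that("COCO conversion round-trips bit-exactly", {
  frames <- list(
    list(image_id = "a",
         boxes = data.frame(class = c("rca_mid", "stenosis"),
                            x_min = c(1, 10.5), y_min = c(2, 11.25),
                            x_max = c(20, 18.5), y_max = c(12, 19.75),
                            stringsAsFactors = FALSE)),
    list(image_id = "b",
         boxes = data.frame(class = "guidewire", x_min = 0, y_min = 0,
                            x_max = 5, y_max = 64,
                            stringsAsFactors = FALSE)))
  back <- from_coco(to_coco(frames))
  expect_identical(back[[1]]$image_id, "a")
  expect_identical(back[[1]]$boxes, frames[[1]]$boxes)
  expect_identical(back[[2]]$boxes, frames[[2]]$boxes)
})

test_that("greedy TP matching consumes each ground truth once", {
  gt <- data.frame(class = "stenosis", x_min = 0, y_min = 0, x_max = 10,
                   y_max = 10, stringsAsFactors = FALSE)
  det <- data.frame(class = "stenosis", score = c(0.9, 0.8),
                    x_min = c(0, 1), y_min = c(0, 1),
                    x_max = c(10, 11), y_max = c(10, 11),
                    stringsAsFactors = FALSE)
  m <- angiopipe:::match_detections(det, gt, 0.5)
  expect_identical(m$tp, c(TRUE, FALSE))  # duplicate is a false positive
})
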
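test_that("stenosis crops follow the 12-px expansion and nearest-size rule", {
  frame <- matrix(runif(512 * 512), 512, 512)
  sizes <- crop_sizes("full")
  cl <- crop_stenosis(frame, list(x_min = 100, y_min = 100, x_max = 200,
                                  y_max = 200, segment = "rca_mid"),
                      sizes = sizes)
  expect_identical(unname(cl$source_box),
                   c(88, 88, 212, 212))       # expanded by 12 on each side
  expect_identical(cl$aspect_ratio_id, 1L)    # ratio 1 -> square
  expect_identical(dim(cl$image), c(256L, 256L))
  # clipped at the frame edge, no error
  edge <- crop_stenosis(frame, list(x_min = 0, y_min = 0, x_max = 30,
                                    y_max = 30, segment = "lm"),
                        sizes = sizes)
  expect_identical(unname(edge$source_box[1:2]), c(0, 0))
  # w/h = 3 -> wide 2:1 size
  wide <- crop_stenosis(frame, list(x_min = 100, y_min = 100, x_max = 280,
                                    y_max = 160, segment = "lad_prox"),
                        sizes = sizes)
  expect_identical(wide$aspect_ratio_id, 2L)
  expect_identical(dim(wide$image), c(128L, 256L))
  tall <- crop_stenosis(frame, list(x_min = 100, y_min = 100, x_max = 160,
                                    y_max = 280, segment = "lad_prox"),
                        sizes = sizes)
  expect_identical(tall$aspect_ratio_id, 3L)
  expect_error(crop_stenosis(frame, list(x_min = -5, y_min = 0, x_max = 30,
                                         y_max = 30, segment = "lm")),
               "outside")
  # output dimensions are always exactly one of the three sizes
  set.seed(2)
  for (i in 1:25) {
    b <- sort(sample(0:511, 2)); d <- sort(sample(0:511, 2))
    if (b[1] == b[2] || d[1] == d[2]) next
    cl <- crop_stenosis(frame, list(x_min = b[1], y_min = d[1],
                                    x_max = b[2], y_max = d[2],
                                    segment = "rca_mid"), sizes = sizes)
    dims <- vapply(sizes, function(s) paste(s[2], s[1]), character(1))
    expect_true(paste(dim(cl$image), collapse = " ") %in% dims)
  }
})

test_that("healthy crops mirror the stenosis size distribution", {
  frame <- matrix(runif(256 * 256), 256, 256)
  seg <- list(x_min = 10, y_min = 10, x_max = 240, y_max = 240,
              class = "rca_mid")
  degen <- data.frame(w = 40, h = 40)
  c1 <- crop_healthy_segment(frame, seg, degen, seed = 1)
  expect_identical(unname(c1$source_box[3] - c1$source_box[1]), 40)
  expect_identical(unname(c1$source_box[4] - c1$source_box[2]), 40)
  expect_identical(c1$provenance, "healthy")
  expect_identical(crop_healthy_segment(frame, seg, degen, seed = 5)$source_box,
                   crop_healthy_segment(frame, seg, degen, seed = 5)$source_box)
  # sampled sizes reproduce the target distribution
  set.seed(9)
  target <- data.frame(w = sample(20:120, 400, replace = TRUE),
                       h = sample(20:120, 400, replace = TRUE))
  ws <- vapply(1:1000, function(s) {
    cc <- crop_healthy_segment(frame, seg, target, seed = s)
    unname(cc$source_box[3] - cc$source_box[1])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ws, target$w))
  expect_gt(ks$p.value, 0.01)
  # fallback to the full box when the segment is too small
  tiny <- list(x_min = 0, y_min = 0, x_max = 15, y_max = 15,
               class = "lm")
  c2 <- crop_healthy_segment(frame, tiny, degen, seed = 2)
  expect_identical(unname(c2$source_box), c(0, 0, 15, 15))
})

test_that("regression learns constant targets and beats the mean baseline", {
  set.seed(21)
  mk <- function(pcts) lapply(seq_along(pcts), function(i)
    synthetic_crop(pcts[i], seed = i,
                   aspect = ((i - 1) %% 3) + 1))
  # constant-zero targets
  zero_crops <- mk(rep(0, 30))
  m0 <- train_regressor(zero_crops[1:24], rep(0, 24),
                        regressor_config(epochs = 12L, augment = FALSE))
  expect_lt(abs(mean(predict_percents(m0, zero_crops[25:30]))), 5)
  # graded stenoses: beat the all-mean predictor by >= 30%
  pcts <- round(runif(90, 0, 95))
  crops <- mk(pcts)
  tr <- 1:60; dv <- 61:75; te <- 76:90
  m <- train_regressor(crops[tr], pcts[tr],
                       regressor_config(seed = 2),
                       dev_crops = crops[dv], dev_labels = pcts[dv])
  pred <- predict_percents(m, crops[te])
  expect_true(all(pred >= 0 & pred <= 100))
  mae <- mean(abs(pred - pcts[te]))
  base <- mean(abs(mean(pcts[tr]) - pcts[te]))
  expect_lt(mae, 0.7 * base)
  # early-stop contract
  h <- m$net$history
  expect_lte(nrow(h), 50L)
  expect_identical(predict_percents(m, crops[te]), pred)  # determinism
  expect_error(train_regressor(crops[1:5], c(10, 20, 150, 30, 40)),
               "outside")
})

test_that("two-stage aggregation equals the brute-force nested mean", {
  df <- data.frame(exam_id = "E1", video_id = "V1", segment = "rca_mid",
                   percent = c(60, 70, 80))
  a <- aggregate_artery(df)
  expect_identical(a$percent, 70)
  df2 <- rbind(df, data.frame(exam_id = "E1", video_id = "V2",
                              segment = "rca_mid", percent = c(80, 80)))
  a2 <- aggregate_artery(df2)
  expect_identical(a2$percent, mean(c(70, 80)))
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    df3 <- data.frame(
      exam_id = sample(c("E1", "E2"), n, replace = TRUE),
      video_id = sample(paste0("V", 1:4), n, replace = TRUE),
      segment = sample(c("lad_prox", "rca_mid"), n, replace = TRUE),
      percent = runif(n, 0, 100))
    got <- aggregate_artery(df3)
    # brute force
    for (r in seq_len(nrow(got))) {
      sub <- df3[df3$exam_id == got$exam_id[r] &
                   df3$segment == got$segment[r], ]
      vm <- tapply(sub$percent, sub$video_id, mean)
      expect_equal(got$percent[r], mean(vm), tolerance = 1e-12)
    }
    # permutation invariance
    perm <- df3[sample(nrow(df3)), ]
    got_p <- aggregate_artery(perm)
    expect_equal(got$percent, got_p$percent, tolerance = 1e-12)
    # lineage consistency: artery mean equals mean of lineage video means
    lin <- attr(got, "lineage")
    for (r in seq_len(nrow(got))) {
      v <- lin[lin$exam_id == got$exam_id[r] &
                 lin$segment == got$segment[r], ]
      expect_equal(got$percent[r], mean(v$percent), tolerance = 1e-12)
    }
  }
  expect_error(aggregate_artery(df[0, ]), "empty")
})

test_that("the obstructive threshold is inclusive at 54", {
  expect_true(classify_obstructive(54))
  expect_false(classify_obstructive(53.9))
  expect_true(classify_obstructive(70, threshold = 70))
  expect_error(classify_obstructive(120), "outside")
})

test_that("the F1-optimal threshold equals the exhaustive sweep", {
  set.seed(77)
  for (i in 1:20) {
    scores <- round(runif(60, 0, 100), 1)
    labels <- runif(60) < plogis((scores - 55) / 12)
    if (length(unique(labels)) < 2) next
    t_star <- choose_obstructive_threshold(scores, labels)
    # independent sweep
    cand <- sort(unique(scores))
    f1s <- sapply(cand, function(t) {
      tp <- sum(scores >= t & labels); fp <- sum(scores >= t & !labels)
      fn <- sum(scores < t & labels)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    })
    expect_identical(t_star, cand[which.max(f1s)])
  }
})

test_that("head fine-tuning freezes the backbone and improves dev MAE", {
  set.seed(55)
  pcts <- round(runif(80, 0, 95))
  crops <- lapply(seq_along(pcts), function(i)
    synthetic_crop(pcts[i], seed = 100 + i, aspect = ((i - 1) %% 3) + 1))
  m <- train_regressor(crops[1:50], pcts[1:50],
                       regressor_config(epochs = 20L, seed = 3),
                       dev_crops = crops[51:60], dev_labels = pcts[51:60])
  # relabel: linearly rescaled targets
  new_labels <- pmax(pmin(0.6 * pcts + 10, 100), 0)
  split <- rep(c("train", "dev", "test"), c(60, 10, 10))
  before <- backbone_checksum(m)
  ft <- fine_tune_head(m, crops, new_labels, grid_epochs = 20L,
                       final_epochs = 60L, step_every = 20L,
                       split = split, seed = 9)
  expect_identical(backbone_checksum(ft), before)
  dv <- which(split == "dev")
  mae_before <- mean(abs(predict_percents(m, crops[dv]) - new_labels[dv]))
  mae_after <- mean(abs(predict_percents(ft, crops[dv]) - new_labels[dv]))
  expect_lt(mae_after, mae_before)
  # the chosen rate is the grid's dev-loss argmin by construction
  expect_identical(ft$finetune$chosen_lr,
                   ft$finetune$lr_grid[which.min(ft$finetune$grid_loss)])
  expect_identical(length(ft$finetune$grid_loss), 5L)
})
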
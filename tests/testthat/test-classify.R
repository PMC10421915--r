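test_that("projection binning matches the default bin table", {
  expect_identical(bin_projection(30, 25), "LAO cranial")
  expect_identical(bin_projection(0, 0), "AP straight")
  expect_identical(bin_projection(-45, -20), "RAO caudal")
  expect_identical(bin_projection(150, 0), "Lateral straight")
  expect_identical(bin_projection(-180, 50), "Lateral cranial")
  expect_error(bin_projection(200, 0), "out of")
  expect_error(bin_projection(0, 60), "out of")
})

test_that("projection binning partitions the whole angle domain", {
  g <- expand.grid(p = seq(-180, 180, by = 1.25),
                   s = seq(-50, 50, by = 1.25))
  labs <- bin_projection(g$p, g$s)
  expect_true(all(labs %in% projection_labels()))
  expect_identical(length(unique(labs)), 12L)
  # right-open boundaries: -10 is RAO, 10 is LAO, boundaries unambiguous
  expect_identical(bin_projection(-10, 0), "RAO straight")
  expect_identical(bin_projection(10, 0), "LAO straight")
  expect_identical(bin_projection(100, 0), "Lateral straight")
  expect_identical(bin_projection(0, 10), "AP cranial")
  expect_identical(bin_projection(0, -10), "AP caudal")
})

test_that("video aggregation is mode with mean-probability tie-break", {
  P <- rbind(c(A = 0.8, B = 0.1, C = 0.1),
             c(A = 0.6, B = 0.3, C = 0.1),
             c(A = 0.2, B = 0.7, C = 0.1))
  expect_identical(aggregate_video(P), "A")
  # 1-1 tie: A has higher mean probability
  P2 <- rbind(c(A = 0.7, B = 0.25, C = 0.05),
              c(A = 0.45, B = 0.5, C = 0.05))
  expect_identical(aggregate_video(P2), "A")
  expect_error(aggregate_video(P[0, , drop = FALSE]), "empty")
})

test_that("video aggregation agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:100) {
    P <- random_predictions(sample(1:6, 1), 3L)
    expect_identical(aggregate_video(P), oracle_aggregate(P))
  }
})

test_that("the coronary gate passes exactly the two coronary classes", {
  expect_true(gate_coronary("rca"))
  expect_true(gate_coronary("lca"))
  expect_false(gate_coronary("femoral_artery"))
  expect_false(gate_coronary("catheter"))
  expect_error(gate_coronary("spleen"), "unknown")
  passed <- vapply(anatomy_classes(), gate_coronary, logical(1))
  expect_identical(sum(passed), 2L)
})

test_that("frame predictions are a valid probability simplex", {
  ds <- list(frames = c(replicate(12, matrix(runif(256), 16), simplify = FALSE),
                        replicate(12, matrix(runif(256) * 0.3, 16),
                                  simplify = FALSE)),
             labels = rep(c("lca", "rca"), each = 12),
             split = rep(c("train", "train", "dev"), 8))
  m <- train_classifier(ds, "anatomy",
                        classifier_config(epochs = 5L, grid = 4L,
                                          augment = FALSE))
  img <- matrix(runif(256), 16)
  p <- predict_frame(m, img)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(p, predict_frame(m, img))   # inference determinism
  expect_gt(-sum(p * log(p)), 0)               # finite logits, entropy > 0
})

test_that("a single-class training set is memorized and transfer init helps", {
  set.seed(3)
  mk_frames <- function(n, bright, noise = 0.12) {
    replicate(n, {
      f <- matrix(0.7, 24, 24)
      if (bright) f[6:18, 6:18] <- 0.45 else f[2:10, 14:22] <- 0.5
      f + matrix(rnorm(576, 0, noise), 24, 24)
    }, simplify = FALSE)
  }
  one <- list(frames = mk_frames(10, TRUE, 0.03), labels = rep("lca", 10),
              split = rep("train", 10))
  m1 <- train_classifier(one, "anatomy",
                         classifier_config(epochs = 8L, augment = FALSE),
                         vocab = c("lca", "rca"))
  P <- predict_frames(m1, one$frames)
  expect_true(all(colnames(P)[max.col(P)] == "lca"))

  # transfer: epoch-1 dev loss lower with init from a trained core model,
  # median over paired seeds
  frames <- c(mk_frames(28, TRUE), mk_frames(28, FALSE))
  labels <- rep(c("lca", "femoral_artery"), each = 28)
  split <- rep(rep(c("train", "dev"), c(20, 8)), 2)
  base <- list(frames = frames, labels = labels, split = split)
  donor <- train_classifier(base, "anatomy",
                            classifier_config(epochs = 25L, augment = FALSE))
  losses <- vapply(1:5, function(s) {
    cold <- train_classifier(base, "anatomy",
                             classifier_config(epochs = 1L, augment = FALSE,
                                               lr = 0.02, seed = s))
    warm <- train_classifier(base, "anatomy",
                             classifier_config(epochs = 1L, augment = FALSE,
                                               lr = 0.02, seed = s,
                                               init_from = donor))
    c(cold$net$history$dev_loss[1], warm$net$history$dev_loss[1])
  }, numeric(2))
  expect_lt(stats::median(losses[2, ]), stats::median(losses[1, ]))
})
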
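test_that("classification report matches hand-computed 2-class metrics", {
  vocab <- c("pos", "neg")
  # TP=3 FP=1 FN=2 for the positive class
  truth <- c(rep("pos", 5), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", "neg", "pos", "neg", "neg", "neg")
  r <- classification_report(pred, truth, vocab)
  pc <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pc$ppv, 0.75, tolerance = 1e-12)
  expect_equal(pc$sensitivity, 0.6, tolerance = 1e-12)
  expect_equal(pc$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_identical(unname(rowSums(r$confusion)),
                   as.numeric(table(factor(truth, vocab))))
  # perfect predictions
  p <- classification_report(truth, truth, vocab)
  expect_true(all(p$per_class$f1 == 1))
  expect_error(classification_report(c("a"), c("pos"), vocab), "vocabulary")
})

test_that("weighted averages equal support-weighted brute force", {
  set.seed(19)
  vocab <- letters[1:4]
  for (i in 1:30) {
    truth <- sample(vocab[1:3], 80, replace = TRUE)  # class d: zero support
    pred <- sample(vocab, 80, replace = TRUE)
    r <- classification_report(pred, truth, vocab)
    pc <- r$per_class
    expect_true(is.na(pc$f1[pc$class == "d"]))
    ok <- !is.na(pc$f1) & pc$support > 0
    expect_equal(unname(r$weighted["f1"]),
                 sum(pc$f1[ok] * pc$support[ok]) / sum(pc$support[ok]),
                 tolerance = 1e-12)
  }
})

test_that("AP reproduces the hand-worked three-detection example", {
  gts <- data.frame(image_id = 1, class = "stenosis",
                    x_min = c(0, 20), y_min = c(0, 20),
                    x_max = c(10, 30), y_max = c(10, 30))
  det <- data.frame(image_id = 1, class = "stenosis",
                    score = c(0.9, 0.8, 0.7),
                    x_min = c(0, 40, 20), y_min = c(0, 40, 20),
                    x_max = c(10, 50, 30), y_max = c(10, 50, 30))
  # staircase: TP (p=1, r=.5), FP (p=.5), TP (p=2/3, r=1)
  expect_equal(average_precision(det, gts, 0.5, "stenosis"),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect single detection
  expect_equal(average_precision(det[1, ], gts[1, ], 0.5, "stenosis"), 1)
  # all disjoint from ground truth
  off <- det; off$x_min <- off$x_min + 200; off$x_max <- off$x_max + 200
  expect_equal(average_precision(off, gts, 0.5, "stenosis"), 0)
  # no ground truths -> undefined
  expect_true(is.na(average_precision(det, gts[0, ], 0.5, "stenosis")))
})

test_that("mAP is support-weighted and non-increasing in the IoU threshold", {
  set.seed(23)
  mk <- function(n, cls) data.frame(
    image_id = sample(1:3, n, replace = TRUE), class = cls,
    t(replicate(n, random_box(20L))))
  gts <- rbind(mk(6, "rca_mid"), mk(3, "stenosis"))
  names(gts)[3:6] <- c("x_min", "y_min", "x_max", "y_max")
  det <- cbind(gts[sample(nrow(gts), 7), ], score = runif(7))
  det$x_min <- det$x_min + sample(0:2, 7, replace = TRUE)
  maps <- vapply(c(0.1, 0.3, 0.5, 0.7),
                 function(t) mean_average_precision(det, gts, t)$mAP,
                 numeric(1))
  expect_true(all(diff(maps) <= 1e-12))
  m <- mean_average_precision(det, gts, 0.5)
  w <- c(6, 3)[match(names(m$per_class), c("rca_mid", "stenosis"))]
  expect_equal(m$mAP, sum(m$per_class * w) / sum(w), tolerance = 1e-12)
})

test_that("ROC AUC equals the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(3)
  expect_equal(roc_auc(runif(4000), rep(0:1, 2000)), 0.5, tolerance = 0.05)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- sample(1:15, n, replace = TRUE)  # ties on purpose
    y <- runif(n) < 0.4
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y], s[!y], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, y), mean(pairs), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("bootstrap intervals are deterministic, nested and degenerate-safe", {
  x <- rnorm(50)
  ci1 <- bootstrap_ci(mean, x, iterations = 200, seed = 7)
  ci2 <- bootstrap_ci(mean, x, iterations = 200, seed = 7)
  expect_identical(ci1, ci2)
  cst <- bootstrap_ci(function(d) 3.25, x, iterations = 50, seed = 1)
  expect_identical(unname(cst), c(3.25, 3.25))
  wide <- bootstrap_ci(mean, x, iterations = 200, seed = 7,
                       probs = c(0.01, 0.99))
  expect_lte(wide[1], ci1[1]); expect_gte(wide[2], ci1[2])
  expect_error(bootstrap_ci(mean, rnorm(5)), "at least 10")
})

test_that("ICC(2,2) matches an aov-based variance decomposition", {
  set.seed(41)
  a <- rnorm(40, 50, 15)
  expect_equal(icc_2_2(a, a)$icc, 1, tolerance = 1e-9)
  expect_identical(icc_2_2(a, a)$band, "excellent")
  # shuffling destroys agreement
  big <- rnorm(500, 50, 15)
  expect_lt(icc_2_2(big, sample(big))$icc, 0.2)
  # oracle: two-way ANOVA mean squares via aov
  for (i in 1:10) {
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.3, 0.7)
    d <- data.frame(v = c(x, y), subj = factor(rep(1:n, 2)),
                    rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(v ~ subj + rater, d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    oracle <- (msr - mse) / (msr + (msc - mse) / n)
    expect_equal(icc_2_2(x, y)$icc, oracle, tolerance = 1e-9)
  }
  expect_true(is.na(icc_2_2(rep(1, 5), rep(1, 5))$icc))
  expect_error(icc_2_2(1:2, 1:2), "at least 3")
})

test_that("ICC reliability bands follow the stated cut points", {
  band_of <- function(v) {
    if (v < 0.5) "poor" else if (v <= 0.75) "moderate"
    else if (v <= 0.90) "good" else "excellent"
  }
  for (target in c(0.2, 0.6, 0.8, 0.97)) {
    set.seed(round(100 * target))
    x <- rnorm(300)
    noise <- sqrt(2 * (1 - target) / target)
    y <- x + rnorm(300, 0, noise)
    got <- icc_2_2(x, y)
    expect_identical(got$band, band_of(got$icc))
  }
})

test_that("Bland-Altman bias and limits match the direct formula", {
  x <- c(1, 2, 3, 4)
  expect_identical(bland_altman(x, x)$bias, 0)
  expect_identical(unname(bland_altman(x, x)$limits), c(0, 0))
  off <- bland_altman(x, x - 5)
  expect_identical(off$bias, 5)
  expect_identical(unname(off$limits), c(5, 5))
  set.seed(61)
  a <- rnorm(100); b <- rnorm(100)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mean(a - b), tolerance = 1e-12)
  expect_equal(unname(ba$limits),
               mean(a - b) + c(-1.96, 1.96) * sd(a - b), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("operating points behave at extreme and fixed-sensitivity queries", {
  set.seed(71)
  s <- runif(200); y <- runif(200) < plogis(6 * (s - 0.5))
  lo <- operating_point(s, y, threshold = min(s) - 1)
  expect_identical(lo$sensitivity, 1)
  expect_identical(lo$specificity, 0)
  hi <- operating_point(s, y, threshold = max(s) + 1)
  expect_identical(hi$sensitivity, 0)
  expect_identical(hi$specificity, 1)
  q <- operating_point(s, y, fixed_sensitivity = 0.8)
  expect_gte(q$sensitivity, 0.8)
  # oracle: largest threshold among all candidates with sens >= 0.8
  cand <- sort(unique(c(s, -Inf)))
  sens <- vapply(cand, function(t) mean(s[y] >= t), numeric(1))
  expect_identical(q$threshold, max(cand[sens >= 0.8]))
  expect_error(operating_point(s, rep(TRUE, 200), 0.5), "both classes")
})
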
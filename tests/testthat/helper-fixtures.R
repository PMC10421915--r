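# Shared fixture builders (everything generated in code at test time).

# A tiny video whose frames are flat gray except a square patch whose
# darkness follows `ramp` (one value per frame).
patch_video <- function(ramp, size = 32L) {
  frames <- lapply(ramp, function(r) {
    f <- matrix(0.8, size, size)
    f[10:20, 10:20] <- 0.8 - 0.5 * r
    f
  })
  angio_video(frames)
}

# Random valid integer box inside a grid.
random_box <- function(grid = 20L) {
  x <- sort(sample(0:grid, 2L))
  y <- sort(sample(0:grid, 2L))
  while (x[1L] == x[2L]) x <- sort(sample(0:grid, 2L))
  while (y[1L] == y[2L]) y <- sort(sample(0:grid, 2L))
  c(x[1L], y[1L], x[2L], y[2L])
}

# Pixel-enumeration IoU oracle for integer boxes.
pixel_iou <- function(a, b) {
  pix <- function(bx) {
    g <- expand.grid(x = bx[1L]:(bx[3L] - 1L), y = bx[2L]:(bx[4L] - 1L))
    paste(g$x, g$y)
  }
  pa <- pix(a); pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Brute-force video-label oracle: mode of argmax, ties by highest mean
# probability among the tied labels.
oracle_aggregate <- function(P) {
  labs <- colnames(P)[apply(P, 1L, which.max)]
  counts <- table(labs)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  mean_p <- colMeans(P)[tied]
  tied[which.max(mean_p)]
}

# Random frame-prediction matrix over k labels.
random_predictions <- function(n, k = 3L) {
  P <- matrix(stats::runif(n * k), n, k)
  P <- P / rowSums(P)
  colnames(P) <- LETTERS[seq_len(k)]
  P
}

# A small crop fixture with a vessel band of given minimum width ratio.
synthetic_crop <- function(percent, segment = "rca_mid", seed = 1L,
                           aspect = 1L) {
  set.seed(seed)
  sz <- crop_sizes("desk")[[as.character(aspect)]]
  w <- sz[1L]; h <- sz[2L]
  img <- matrix(0.85, h, w)
  cy <- h / 2
  base <- 8
  for (x in seq_len(w)) {
    t <- (x - 1) / (w - 1)
    dip <- (percent / 100) * exp(-((t - 0.5) / 0.12)^2)
    half <- base * (1 - dip) / 2
    ys <- which(abs(seq_len(h) - cy) <= half)
    img[ys, x] <- 0.25
  }
  img <- pmin(pmax(img + matrix(stats::rnorm(h * w, 0, 0.01), h, w), 0), 1)
  structure(list(image = img, aspect_ratio_id = as.integer(aspect),
                 segment_label = segment,
                 source_box = c(x_min = 0, y_min = 0, x_max = w, y_max = h),
                 provenance = if (percent > 0) "stenosis" else "healthy"),
            class = "cropped_lesion")
}
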
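# Low-level grayscale image utilities.
#
# Images are numeric matrices with rows indexing y (top to bottom) and
# columns indexing x, values in [0, 1].  Pixel (ix, iy) is 0-based and
# covers the half-open unit square [ix, ix+1) x [iy, iy+1); it lives at
# matrix position [iy + 1, ix + 1].

#' Bilinear image resize
#'
#' @param img numeric matrix (grayscale image).
#' @param out_h,out_w output height and width in pixels.
#' @return numeric matrix of dimension `out_h` x `out_w`.
#' @keywords internal
ap_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # map output pixel centres back to input pixel centres
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

#' Mean-pool an image to a fixed grid
#' @keywords internal
ap_pool <- function(img, gh, gw) {
  h <- nrow(img); w <- ncol(img)
  ry <- floor((seq_len(h) - 1) * gh / h) + 1
  rx <- floor((seq_len(w) - 1) * gw / w) + 1
  s <- rowsum(img, ry)                      # gh x w
  s <- t(rowsum(t(s), rx))                  # gh x gw sums
  cnt <- outer(tabulate(ry, gh), tabulate(rx, gw))
  s / cnt
}

#' Gaussian kernel (1-D, normalized)
#' @keywords internal
ap_gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflect padding (same-size output).
ap_filter_sep <- function(img, k) {
  n <- length(k); half <- (n - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  refl <- function(idx, m) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    ifelse(idx > m, 2L * m - idx, idx)
  }
  # rows
  out <- matrix(0, h, w)
  for (i in seq_len(n)) {
    rows <- refl(seq_len(h) + i - 1L - half, h)
    out <- out + k[i] * img[rows, , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (i in seq_len(n)) {
    cols <- refl(seq_len(w) + i - 1L - half, w)
    out2 <- out2 + k[i] * out[, cols, drop = FALSE]
  }
  out2
}

#' Integral image (summed-area table)
#'
#' Returns an (h+1) x (w+1) matrix `ii` such that the sum of pixels in the
#' half-open box rows [r0, r1), cols [c0, c1) (0-based) is
#' `ii[r1+1, c1+1] - ii[r0+1, c1+1] - ii[r1+1, c0+1] + ii[r0+1, c0+1]`.
#' @keywords internal
ap_integral <- function(img) {
  h <- nrow(img); w <- ncol(img)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- t(apply(apply(img, 2L, cumsum), 1L, cumsum))
  ii
}

# Mean-pool a set of boxes into a gh x gw grid using an integral image.
# boxes: n x 4 matrix (x_min, y_min, x_max, y_max), 0-based half-open,
# assumed clipped to the image. Returns n x (gh*gw) feature matrix.
ap_box_pool <- function(ii, boxes, gh = 8L, gw = 8L) {
  n <- nrow(boxes)
  feats <- matrix(0, n, gh * gw)
  x0 <- boxes[, 1L]; y0 <- boxes[, 2L]; x1 <- boxes[, 3L]; y1 <- boxes[, 4L]
  for (gy in seq_len(gh)) {
    ra <- round(y0 + (gy - 1L) * (y1 - y0) / gh)
    rb <- round(y0 + gy * (y1 - y0) / gh)
    rb <- pmax(rb, ra + 1)
    for (gx in seq_len(gw)) {
      ca <- round(x0 + (gx - 1L) * (x1 - x0) / gw)
      cb <- round(x0 + gx * (x1 - x0) / gw)
      cb <- pmax(cb, ca + 1)
      s <- ii[cbind(rb + 1, cb + 1)] - ii[cbind(ra + 1, cb + 1)] -
        ii[cbind(rb + 1, ca + 1)] + ii[cbind(ra + 1, ca + 1)]
      feats[, (gy - 1L) * gw + gx] <- s / ((rb - ra) * (cb - ca))
    }
  }
  feats
}

# Global histogram equalization (256 bins).
ap_hist_eq <- function(img) {
  v <- pmin(pmax(img, 0), 1)
  q <- findInterval(v, seq(0, 1, length.out = 257), rightmost.closed = TRUE)
  cdf <- cumsum(tabulate(q, 256)) / length(v)
  matrix(cdf[q], nrow(img), ncol(img))
}

# Affine augmentation: rotation (radians), isotropic zoom, shear; inverse
# mapping with bilinear sampling, edge padding.
ap_affine <- function(img, rot = 0, zoom = 1, shear = 0) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  xs <- matrix(seq_len(w) - 1 - cx, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1 - cy, h, w)
  cs <- cos(rot); sn <- sin(rot)
  # inverse of rotate+zoom+shear
  xi <- (cs * xs + sn * ys) / zoom + shear * ys + cx
  yi <- (-sn * xs + cs * ys) / zoom + cy
  x0 <- pmin(pmax(floor(xi), 0), w - 1); y0 <- pmin(pmax(floor(yi), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- pmin(pmax(xi - x0, 0), 1); fy <- pmin(pmax(yi - y0, 0), 1)
  id <- function(yy, xx) img[cbind(as.vector(yy + 1), as.vector(xx + 1))]
  v <- id(y0, x0) * (1 - fy) * (1 - fx) + id(y0, x1) * (1 - fy) * fx +
    id(y1, x0) * fy * (1 - fx) + id(y1, x1) * fy * fx
  matrix(v, h, w)
}

# Bilinear sample of an image at continuous 0-based pixel-centre
# coordinates (x, y); points outside the image are clamped.
ap_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  id <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  id(y0, x0) * (1 - fy) * (1 - fx) + id(y0, x1) * (1 - fy) * fx +
    id(y1, x0) * fy * (1 - fx) + id(y1, x1) * fy * fx
}
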
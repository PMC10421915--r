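# Peak-contrast frame selection by structural similarity.
#
# An angiogram cine run starts before contrast injection, so frame 0 is a
# contrast-free reference. The frame least similar to the reference (by
# SSIM) is taken as the peak-contrast frame, and a window of up to 8
# frames around it is retained for all downstream analysis.

#' Construct an angiogram video object
#'
#' @param frames list of equal-sized numeric matrices (grayscale, values in
#'   `[0, data_range]`), ordered in acquisition time. Frame indices are
#'   0-based throughout the package.
#' @param metadata optional named list (angles, identifiers, fps).
#' @param data_range declared gray-level range (default 1).
#' @return an object of class `angio_video`.
#' @export
angio_video <- function(frames, metadata = list(), data_range = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == d), logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimensions")
  structure(list(frames = frames, metadata = metadata,
                 data_range = data_range),
            class = "angio_video")
}

#' @export
print.angio_video <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<angio_video> %d frames, %dx%d px, data range %g\n",
              length(x$frames), d[1L], d[2L], x$data_range))
  invisible(x)
}

#' Structural similarity index (SSIM) between two frames
#'
#' Canonical SSIM: the product of luminance, contrast and structure terms
#' with stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for
#' data range `L`. The default computes local statistics under an 11x11
#' Gaussian window (sigma 1.5) and averages the SSIM map; `method =
#' "global"` evaluates the same formula once with whole-image moments
#' (useful as a windowless reference on small patches).
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param data_range declared dynamic range of the inputs.
#' @param method `"gaussian"` (windowed, default) or `"global"`.
#' @param window_size,sigma Gaussian window parameters.
#' @return a similarity value in `[-1, 1]`; 1 for identical images.
#' @export
compute_ssim <- function(a, b, data_range = 1,
                         method = c("gaussian", "global"),
                         window_size = 11L, sigma = 1.5) {
  method <- match.arg(method)
  if (!is.matrix(a) || !is.matrix(b)) stop("frames must be matrices")
  if (!all(dim(a) == dim(b))) stop("frame shape mismatch")
  if (any(dim(a) == 0L)) stop("zero-size frame")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  if (method == "global") {
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cab <- mean((a - mu_a) * (b - mu_b))
    return(((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
             ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
  }
  k <- ap_gaussian_kernel(window_size, sigma)
  mu_a <- ap_filter_sep(a, k); mu_b <- ap_filter_sep(b, k)
  va <- ap_filter_sep(a * a, k) - mu_a^2
  vb <- ap_filter_sep(b * b, k) - mu_b^2
  cab <- ap_filter_sep(a * b, k) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(smap)
}

ssim_curve <- function(video, resolution = NULL) {
  frames <- video$frames
  if (!is.null(resolution)) {
    frames <- lapply(frames, ap_resize, out_h = resolution, out_w = resolution)
  }
  ref <- frames[[1L]]
  vapply(frames, compute_ssim, numeric(1), b = ref,
         data_range = video$data_range)
}

#' Select the peak-contrast frame of a video
#'
#' Returns the 0-based index of the frame with the lowest SSIM against the
#' reference frame (frame 0), the frame most likely to contain peak
#' contrast. Ties are broken towards the earliest frame.
#'
#' @param video an [angio_video()].
#' @param resolution optional working resolution frames are resized to
#'   before SSIM.
#' @return integer 0-based frame index (>= 1).
#' @export
select_peak_frame <- function(video, resolution = NULL) {
  if (length(video$frames) < 2L) stop("video must have at least 2 frames")
  curve <- ssim_curve(video, resolution)
  which.min(curve[-1L])  # which.min takes the earliest minimum
}

#' Extract the analysis frame window of a video
#'
#' Retains the reference frame (index 0), the peak-contrast frame and the
#' 3 frames immediately preceding and following it, clipped to the video
#' and deduplicated — hence at most 8 frames.
#'
#' @inheritParams select_peak_frame
#' @return an object of class `extracted_frames` with fields
#'   `reference_index` (0), `peak_index`, `indices` (sorted, unique,
#'   0-based) and `ssim_curve`.
#' @export
extract_frames <- function(video, resolution = NULL) {
  if (length(video$frames) < 2L) stop("video must have at least 2 frames")
  curve <- ssim_curve(video, resolution)
  peak <- which.min(curve[-1L])
  n <- length(video$frames)
  idx <- sort(unique(pmax(0L, pmin(n - 1L, c(0L, (peak - 3L):(peak + 3L))))))
  structure(list(reference_index = 0L, peak_index = as.integer(peak),
                 indices = as.integer(idx), ssim_curve = curve),
            class = "extracted_frames")
}

#' @export
print.extracted_frames <- function(x, ...) {
  cat(sprintf("<extracted_frames> peak=%d, indices={%s}\n", x$peak_index,
              paste(x$indices, collapse = ",")))
  invisible(x)
}

# 1-based list access for a 0-based frame index.
frame_at <- function(video, index0) video$frames[[index0 + 1L]]
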
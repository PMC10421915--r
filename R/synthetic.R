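# Synthetic coronary angiogram generator.
#
# Desk-scale cine runs are rendered from parametric vessel trees:
# quadratic-Bezier centerlines with a Gaussian cross profile whose full
# width at half maximum equals the local lumen width. A stenosis is a
# localized multiplicative width dip (1 - percent/100) over a cosine arc
# window, so the rendered minimum lumen width is analytically known.
# Contrast follows a piecewise-linear opacity ramp 0 -> 1 -> 0.4 peaking
# exactly at the configured frame, which makes the SSIM-minimum frame
# unambiguous. Projection angles deterministically rotate and foreshorten
# the tree so that projection classification is learnable from pixels.

STENOSIS_ARC_HALFWIDTH <- 0.18  # fraction of segment arc covered by a lesion
RENDER_BG <- 0.85               # background gray level
RENDER_DEPTH <- 0.65            # contrast attenuation depth at full opacity

# --- vessel tree geometry (unit coordinates) --------------------------------

tree_geometry <- function(side) {
  if (side == "LCA") {
    n <- list(A = c(0.30, 0.18), B = c(0.42, 0.26), C = c(0.50, 0.42),
              D = c(0.54, 0.60), E = c(0.52, 0.78), F = c(0.30, 0.40),
              G = c(0.24, 0.56), H = c(0.26, 0.72))
    segs <- list(
      list("lm",       "A", "B", c(0.36, 0.21)),
      list("lad_prox", "B", "C", c(0.47, 0.33)),
      list("lad_mid",  "C", "D", c(0.54, 0.51)),
      list("lad_dist", "D", "E", c(0.55, 0.70)),
      list("lcx_prox", "B", "F", c(0.34, 0.31)),
      list("lcx_mid",  "F", "G", c(0.25, 0.47)),
      list("lcx_dist", "G", "H", c(0.23, 0.65)))
  } else {
    n <- list(A = c(0.62, 0.20), B = c(0.70, 0.38), C = c(0.66, 0.58),
              D = c(0.52, 0.70), E = c(0.36, 0.74))
    segs <- list(
      list("rca_prox", "A", "B", c(0.69, 0.28)),
      list("rca_mid",  "B", "C", c(0.71, 0.49)),
      list("rca_dist", "C", "D", c(0.60, 0.68)),
      list("pda",      "D", "E", c(0.44, 0.74)))
  }
  list(nodes = n, segs = segs)
}

#' Generate a synthetic coronary vessel tree
#'
#' Builds a `vessel_spec`: smooth quadratic-Bezier segment centerlines for
#' one coronary tree (or a parametric non-coronary distractor), with
#' stenoses drawn from a configurable distribution. Deterministic given
#' the seed.
#'
#' @param side `"LCA"`, `"RCA"` or `"other"` (distractor).
#' @param stenosis_config list with any of: `n` (number of stenoses),
#'   `percents` (explicit percent vector, recycled to `n`),
#'   `percent_range` (default `c(20, 99)`), `segments` (explicit segment
#'   labels), `arcs` (explicit arc positions in `[0,1]`).
#' @param seed integer seed.
#' @param frame_size target frame size in pixels (geometry scales with it).
#' @param distractor_class anatomy class rendered when `side = "other"`.
#' @return an object of class `vessel_spec`.
#' @export
generate_vessel_tree <- function(side, stenosis_config = list(), seed = 1L,
                                 frame_size = 128L,
                                 distractor_class = "femoral_artery") {
  side <- toupper(side)
  if (!side %in% c("LCA", "RCA", "OTHER")) stop("unknown side: ", side)
  set.seed(as.integer(seed))
  ws <- frame_size / 128
  if (side == "OTHER") {
    if (!is.null(stenosis_config$n) && stenosis_config$n > 0)
      stop("distractor specs carry no stenoses")
    paths <- distractor_paths(distractor_class, ws)
    return(structure(list(segment_paths = paths,
                          stenoses = empty_stenoses(),
                          anatomy_class = distractor_class, side = "other",
                          frame_size = as.integer(frame_size)),
                     class = "vessel_spec"))
  }
  geo <- tree_geometry(side)
  nodes <- lapply(geo$nodes, function(p) p + stats::runif(2, -0.02, 0.02))
  paths <- lapply(geo$segs, function(s) {
    list(label = s[[1L]],
         p0 = nodes[[s[[2L]]]],
         p1 = s[[4L]] + stats::runif(2, -0.02, 0.02),
         p2 = nodes[[s[[3L]]]],
         width = stats::runif(1, 4.8, 6.5) * ws)
  })
  labels <- vapply(paths, `[[`, character(1), "label")
  cfg <- stenosis_config
  n_st <- if (!is.null(cfg$n)) cfg$n else 0L
  st <- empty_stenoses()
  if (n_st > 0L) {
    segs <- if (!is.null(cfg$segments)) cfg$segments
            else sample(labels, n_st, replace = FALSE)
    if (!all(segs %in% labels)) stop("stenosis references unknown segment")
    arcs <- if (!is.null(cfg$arcs)) rep_len(cfg$arcs, n_st)
            else stats::runif(n_st, 0.3, 0.7)
    if (!is.null(cfg$percents)) {
      pct <- rep_len(cfg$percents, n_st)
    } else {
      rng <- if (!is.null(cfg$percent_range)) cfg$percent_range else c(20, 99)
      pct <- round(stats::runif(n_st, rng[1L], rng[2L]))
    }
    if (any(pct < 0 | pct > 100)) stop("stenosis percent outside [0,100]")
    st <- data.frame(segment = segs, arc = arcs, percent = pct,
                     stringsAsFactors = FALSE)
  }
  structure(list(segment_paths = paths, stenoses = st,
                 anatomy_class = tolower(side), side = side,
                 frame_size = as.integer(frame_size)),
            class = "vessel_spec")
}

empty_stenoses <- function() {
  data.frame(segment = character(), arc = numeric(), percent = numeric(),
             stringsAsFactors = FALSE)
}

# Parametric distractor shapes; polyline paths, label NA (non-coronary).
distractor_paths <- function(class, ws) {
  pl <- function(pts, width) list(label = NA_character_, pts = pts,
                                  width = width * ws)
  switch(class,
    femoral_artery = list(
      pl(cbind(seq(0.44, 0.56, length.out = 40),
               seq(0.08, 0.92, length.out = 40) +
                 0.03 * sin(seq(0, 3, length.out = 40))), 11)),
    pigtail_catheter = {
      th <- seq(0, 2.1 * pi, length.out = 60)
      loop <- cbind(0.50 + 0.09 * cos(th), 0.32 + 0.09 * sin(th))
      tail <- cbind(seq(0.59, 0.55, length.out = 30),
                    seq(0.32, 0.90, length.out = 30))
      list(pl(loop, 2.6), pl(tail, 2.6))
    },
    catheter = list(
      pl(cbind(seq(0.10, 0.90, length.out = 50),
               0.25 + 0.15 * sin(seq(0, 2, length.out = 50))), 2.2)),
    ventriculography = {
      th <- seq(0, 2 * pi, length.out = 50)
      list(pl(cbind(0.50 + 0.16 * cos(th), 0.50 + 0.22 * sin(th)), 26))
    },
    stop("unknown distractor class: ", class)
  )
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat(sprintf("<vessel_spec> side=%s, %d segments, %d stenoses\n", x$side,
              length(x$segment_paths), nrow(x$stenoses)))
  invisible(x)
}

# --- acquisition parameters -------------------------------------------------

#' Acquisition parameters for a synthetic cine run
#'
#' @param primary_angle C-arm primary (LAO-RAO) angle, degrees in
#'   `[-180, 180]`.
#' @param secondary_angle secondary (cranial-caudal) angle, degrees in
#'   `[-50, 50]`.
#' @param n_frames frame count.
#' @param fps frames per second (default 15).
#' @param frame_size frame edge length in pixels (default 128).
#' @param contrast_peak_frame 0-based index at which vessel opacity peaks;
#'   must satisfy `1 <= peak < n_frames` (frame 0 is contrast-free).
#' @param noise_sd additive Gaussian noise standard deviation (gray-level
#'   units on the `[0,1]` scale).
#' @param seed seed for the noise stream.
#' @return a validated list of class `acquisition_params`.
#' @export
acquisition_params <- function(primary_angle = 0, secondary_angle = 0,
                               n_frames = 20L, fps = 15,
                               frame_size = 128L,
                               contrast_peak_frame = NULL,
                               noise_sd = 0.02, seed = 1L) {
  if (primary_angle < -180 || primary_angle > 180)
    stop("primary angle out of [-180, 180]")
  if (secondary_angle < -50 || secondary_angle > 50)
    stop("secondary angle out of [-50, 50]")
  if (n_frames < 2L) stop("need at least 2 frames")
  if (is.null(contrast_peak_frame))
    contrast_peak_frame <- max(1L, floor(n_frames * 0.55))
  if (contrast_peak_frame < 1L || contrast_peak_frame >= n_frames)
    stop("contrast_peak_frame must lie in [1, n_frames - 1]")
  structure(list(primary_angle = primary_angle,
                 secondary_angle = secondary_angle,
                 n_frames = as.integer(n_frames), fps = fps,
                 frame_size = as.integer(frame_size),
                 contrast_peak_frame = as.integer(contrast_peak_frame),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_params")
}

# Projection transform: rotation scales with the primary angle, vertical
# foreshortening and shear with the secondary angle. pts: n x 2 (px).
project_points <- function(pts, acq, S) {
  th <- acq$primary_angle * pi / 180 * 0.25
  sc <- 1 - 0.25 * abs(acq$secondary_angle) / 50
  sh <- 0.12 * acq$secondary_angle / 50
  cx <- S / 2; cy <- S / 2
  x <- pts[, 1L] - cx; y <- pts[, 2L] - cy
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  cbind(xr + cx, yr * sc + sh * xr + cy)
}

bezier_points <- function(p0, p1, p2, t) {
  cbind((1 - t)^2 * p0[1L] + 2 * t * (1 - t) * p1[1L] + t^2 * p2[1L],
        (1 - t)^2 * p0[2L] + 2 * t * (1 - t) * p1[2L] + t^2 * p2[2L])
}

# Sample one path at parameter values t (unit coords -> pixels).
path_points <- function(path, t, S) {
  if (!is.null(path$pts)) {
    # polyline: interpolate by arc parameter
    pts <- path$pts * S
    n <- nrow(pts)
    u <- t * (n - 1L) + 1
    i0 <- pmin(floor(u), n - 1L); f <- u - i0
    pts[i0, , drop = FALSE] * (1 - f) + pts[i0 + 1L, , drop = FALSE] * f
  } else {
    bezier_points(path$p0 * S, path$p1 * S, path$p2 * S, t)
  }
}

# Width profile along a path: baseline times one minus the stenosis dip.
path_width <- function(path, t, stenoses) {
  w <- rep(path$width, length(t))
  if (is.na(path$label) || nrow(stenoses) == 0L) return(w)
  rows <- stenoses[stenoses$segment == path$label, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    d <- abs(t - rows$arc[i])
    inwin <- d < STENOSIS_ARC_HALFWIDTH
    dip <- numeric(length(t))
    dip[inwin] <- (rows$percent[i] / 100) *
      0.5 * (1 + cos(pi * d[inwin] / STENOSIS_ARC_HALFWIDTH))
    w <- w * (1 - pmin(dip, 1))
  }
  pmax(w, 0)
}

# Render the static vessel-opacity image (max over Gaussian tube profile).
render_tree_image <- function(spec, acq) {
  S <- acq$frame_size
  if (S < 32L) stop("frame_size too small to contain the vessel tree")
  V <- matrix(0, S, S)
  for (path in spec$segment_paths) {
    severe <- !is.na(path$label) && nrow(spec$stenoses) > 0L &&
      any(spec$stenoses$segment == path$label & spec$stenoses$percent >= 75)
    coarse <- path_points(path, seq(0, 1, length.out = 30), S)
    L <- sum(sqrt(rowSums(diff(coarse)^2)))
    ns <- min(4000L, max(80L, ceiling(L / (if (severe) 0.08 else 0.35))))
    t <- seq(0, 1, length.out = ns)
    pts <- project_points(path_points(path, t, S), acq, S)
    w <- path_width(path, t, spec$stenoses)
    sg <- w / 2.3548  # FWHM = lumen width
    for (i in seq_len(ns)) {
      if (sg[i] < 0.12) next  # total occlusion gap
      R <- max(2L, ceiling(2.5 * sg[i]))
      x <- pts[i, 1L]; y <- pts[i, 2L]
      r0 <- max(1L, floor(y) - R + 1L); r1 <- min(S, floor(y) + R + 1L)
      c0 <- max(1L, floor(x) - R + 1L); c1 <- min(S, floor(x) + R + 1L)
      if (r0 > r1 || c0 > c1) next
      dy <- (r0:r1) - 1 - y; dx <- (c0:c1) - 1 - x
      g <- exp(-outer(dy^2, dx^2, "+") / (2 * sg[i]^2))
      V[r0:r1, c0:c1] <- pmax(V[r0:r1, c0:c1], g)
    }
  }
  V
}

# Piecewise-linear contrast opacity ramp 0 -> 1 -> 0.4.
contrast_ramp <- function(n_frames, peak) {
  k <- seq_len(n_frames) - 1L
  up <- pmin(k / peak, 1)
  r <- up
  if (peak < n_frames - 1L) {
    fade <- 1 - 0.6 * (k - peak) / (n_frames - 1L - peak)
    r[k > peak] <- fade[k > peak]
  }
  r
}

# Ground-truth boxes (0-based half-open, clipped) from projected samples.
tree_ground_truth_boxes <- function(spec, acq) {
  S <- acq$frame_size
  rows <- list()
  for (path in spec$segment_paths) {
    if (is.na(path$label)) next
    t <- seq(0, 1, length.out = 80)
    pts <- project_points(path_points(path, t, S), acq, S)
    w <- path_width(path, t, spec$stenoses)
    half <- w / 2 + 1
    rows[[length(rows) + 1L]] <- data.frame(
      class = path$label, segment = path$label,
      x_min = max(0, floor(min(pts[, 1L] - half))),
      y_min = max(0, floor(min(pts[, 2L] - half))),
      x_max = min(S, ceiling(max(pts[, 1L] + half))),
      y_max = min(S, ceiling(max(pts[, 2L] + half))),
      stringsAsFactors = FALSE)
    st <- spec$stenoses[spec$stenoses$segment == path$label, , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      sel <- abs(t - st$arc[i]) <= STENOSIS_ARC_HALFWIDTH
      p2 <- pts[sel, , drop = FALSE]
      m <- path$width / 2 + 3
      rows[[length(rows) + 1L]] <- data.frame(
        class = "stenosis", segment = path$label,
        x_min = max(0, floor(min(p2[, 1L] - m))),
        y_min = max(0, floor(min(p2[, 2L] - m))),
        x_max = min(S, ceiling(max(p2[, 1L] + m))),
        y_max = min(S, ceiling(max(p2[, 2L] + m))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(class = character(), segment = character(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric()))
  }
  do.call(rbind, rows)
}

#' Render a synthetic angiogram cine run
#'
#' Frame 0 contains no contrast; vessel opacity ramps linearly to its
#' maximum exactly at `acq$contrast_peak_frame` and then fades to 0.4.
#' Gaussian noise of standard deviation `acq$noise_sd` is added to every
#' frame. Ground truth carries per-frame axis-aligned boxes for every
#' rendered segment and stenosis, per-segment stenosis percents, the
#' projection bin and the anatomy class.
#'
#' @param spec a [generate_vessel_tree()] spec.
#' @param acq an [acquisition_params()] object.
#' @return list with elements `video` ([angio_video()]) and
#'   `ground_truth` (class `synthetic_ground_truth`).
#' @export
render_video <- function(spec, acq) {
  stopifnot(inherits(spec, "vessel_spec"), inherits(acq, "acquisition_params"))
  S <- acq$frame_size
  V <- render_tree_image(spec, acq)
  ramp <- contrast_ramp(acq$n_frames, acq$contrast_peak_frame)
  set.seed(acq$seed)
  frames <- lapply(seq_len(acq$n_frames), function(k) {
    f <- RENDER_BG - RENDER_DEPTH * ramp[k] * V
    if (acq$noise_sd > 0) f <- f + matrix(stats::rnorm(S * S, 0, acq$noise_sd), S, S)
    pmin(pmax(f, 0), 1)
  })
  boxes1 <- tree_ground_truth_boxes(spec, acq)
  per_frame <- if (nrow(boxes1) == 0L) {
    cbind(frame = integer(), boxes1, visible = logical())
  } else {
    do.call(rbind, lapply(seq_len(acq$n_frames), function(k) {
      cbind(frame = k - 1L, boxes1, visible = ramp[k] >= 0.3)
    }))
  }
  rownames(per_frame) <- NULL
  pct <- stats::setNames(rep(0, length(spec$segment_paths)),
                         vapply(spec$segment_paths, `[[`, character(1), "label"))
  pct <- pct[!is.na(names(pct))]
  for (i in seq_len(nrow(spec$stenoses))) {
    s <- spec$stenoses$segment[i]
    pct[s] <- max(pct[s], spec$stenoses$percent[i])
  }
  gt <- structure(list(
    boxes = per_frame,
    stenosis_pct = pct,
    projection = bin_projection(acq$primary_angle, acq$secondary_angle),
    anatomy = spec$anatomy_class,
    ramp = ramp), class = "synthetic_ground_truth")
  video <- angio_video(frames, metadata = list(
    primary_angle = acq$primary_angle, secondary_angle = acq$secondary_angle,
    fps = acq$fps, n_frames = acq$n_frames))
  list(video = video, ground_truth = gt)
}

# Boxes of one 0-based frame index.
gt_boxes <- function(gt, frame = NULL, visible_only = FALSE) {
  b <- gt$boxes
  if (!is.null(frame)) b <- b[b$frame == frame, , drop = FALSE]
  if (visible_only) b <- b[b$visible, , drop = FALSE]
  b
}

#' Geometry of each stenosis under a given acquisition
#'
#' Returns, per configured stenosis, the projected center point, the unit
#' normal to the centerline, the baseline width and the expected rendered
#' minimum lumen width (baseline times `1 - percent/100`). Used to verify
#' rendered lumen narrowing.
#'
#' @param spec a `vessel_spec`.
#' @param acq an `acquisition_params`.
#' @return data.frame, one row per stenosis.
#' @export
stenosis_geometry <- function(spec, acq) {
  S <- acq$frame_size
  out <- list()
  for (i in seq_len(nrow(spec$stenoses))) {
    st <- spec$stenoses[i, ]
    path <- spec$segment_paths[[
      which(vapply(spec$segment_paths, `[[`, character(1), "label") ==
              st$segment)[1L]]]
    eps <- 1e-3
    p <- project_points(path_points(path, c(st$arc - eps, st$arc, st$arc + eps),
                                    S), acq, S)
    tangent <- p[3L, ] - p[1L, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    out[[i]] <- data.frame(
      segment = st$segment, arc = st$arc, percent = st$percent,
      x = p[2L, 1L], y = p[2L, 2L],
      nx = -tangent[2L], ny = tangent[1L],
      baseline_width = path$width,
      expected_width = path$width * (1 - st$percent / 100),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Measure vessel width across a point by half-maximum crossing
#'
#' Samples a vesselness image along the normal direction through a point
#' at fine sub-pixel steps and returns the extent over which the profile
#' stays above half of its maximum (the rendered FWHM lumen width).
#'
#' @param img vesselness image (vessel bright), e.g. `median(f) - f` of a
#'   rendered frame.
#' @param x,y profile center (0-based pixel coordinates).
#' @param nx,ny unit normal direction.
#' @param max_half maximum half-extent searched, px.
#' @return width in pixels.
#' @export
measure_vessel_width <- function(img, x, y, nx, ny, max_half = 12) {
  s <- seq(-max_half, max_half, by = 0.02)
  prof <- ap_sample(img, x + s * nx, y + s * ny)
  half <- max(prof) / 2
  above <- which(prof >= half)
  if (length(above) == 0L) return(0)
  (max(above) - min(above)) * 0.02
}

# --- report text generation -------------------------------------------------

report_phrases <- function() {
  c(lm = "left main", lad_prox = "proximal LAD", lad_mid = "mid LAD",
    lad_dist = "distal LAD", lcx_prox = "proximal circumflex",
    lcx_mid = "mid circumflex", lcx_dist = "distal circumflex",
    rca_prox = "proximal RCA", rca_mid = "mid RCA",
    rca_dist = "distal RCA", pda = "PDA")
}

#' Generate synthetic procedure-report text from ground truth
#'
#' Emits one clause per stenosed segment using segment synonyms and "N%"
#' phrasing; 100% lesions randomly use an occlusion keyword instead of a
#' percent. The output is parseable by [parse_report()] back to the same
#' (segment, percent) records.
#'
#' @param ground_truth either a `synthetic_ground_truth` or a data.frame
#'   with columns `segment` and `percent`.
#' @param seed integer seed for template choices.
#' @return a character scalar of report text.
#' @export
generate_report_text <- function(ground_truth, seed = 1L) {
  if (inherits(ground_truth, "synthetic_ground_truth")) {
    pct <- ground_truth$stenosis_pct
    df <- data.frame(segment = names(pct), percent = as.numeric(pct),
                     stringsAsFactors = FALSE)
    df <- df[df$percent > 0, , drop = FALSE]
  } else {
    df <- ground_truth
  }
  set.seed(as.integer(seed))
  phr <- report_phrases()
  clauses <- character()
  if (stats::runif(1) < 0.3)
    clauses <- "Selective coronary angiography was performed"
  for (i in seq_len(nrow(df))) {
    syn <- phr[[df$segment[i]]]
    p <- df$percent[i]
    if (p == 100 && stats::runif(1) < 0.5) {
      clauses <- c(clauses, sprintf("total occlusion of the %s", syn))
    } else {
      tpl <- sample(c("%d%% stenosis in the %s", "the %2$s has a %1$d%% lesion",
                      "%2$s with %1$d%% stenosis"), 1L)
      clauses <- c(clauses, sprintf(tpl, as.integer(p), syn))
    }
  }
  if (length(clauses) == 0L) clauses <- "No significant coronary disease"
  paste0(paste(clauses, collapse = ", "), ".")
}

# --- dataset generation -----------------------------------------------------

#' Default synthetic-dataset configuration
#'
#' Desk-scale study conditions: 128x128 frames at 15 fps, 16-24 frames per
#' video, per-tree stenosis count in {0,1,2} with percents uniform on
#' [20, 99], and one distractor video per distractor class per patient.
#'
#' @param ... overrides of the listed defaults.
#' @return named list of generator settings.
#' @export
dataset_config <- function(...) {
  cfg <- list(frame_size = 128L, n_frames_range = c(16L, 24L), fps = 15,
              noise_sd = 0.02,
              distractors = c("femoral_artery", "pigtail_catheter"),
              n_stenoses_choices = 0:2,
              n_stenoses_probs = c(0.25, 0.5, 0.25),
              percent_range = c(20, 99))
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# 70/10/20 patient split sizes (every split non-empty).
split_sizes <- function(n_patients) {
  if (n_patients < 5L) stop("need at least 5 patients to populate all splits")
  dev <- max(1L, as.integer(floor(0.1 * n_patients)))
  test <- max(1L, as.integer(floor(0.2 * n_patients)))
  train <- as.integer(n_patients) - dev - test
  c(train = train, dev = dev, test = test)
}

#' Generate a synthetic angiogram dataset
#'
#' Renders, per patient (one exam each), one LCA run, one RCA run and one
#' distractor run per configured distractor class, together with ground
#' truth, acquisition metadata and a paired free-text report. Patients are
#' assigned to non-overlapping train (70%), dev (10%) and test (20%)
#' splits.
#'
#' @param n_patients number of patients (>= 5).
#' @param config a [dataset_config()] list.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return an object of class `angio_dataset` with fields `videos`
#'   (named list of video entries), `metadata` (data.frame), `reports`
#'   (named list by exam), `gt_stenosis` (exam-level labels), `patients`
#'   (split assignment) and `config`.
#' @export
generate_dataset <- function(n_patients, config = dataset_config(),
                             seed = 1L) {
  sz <- split_sizes(n_patients)
  set.seed(as.integer(seed))
  split <- sample(rep(c("train", "dev", "test"), sz))
  patients <- data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
                         split = split, stringsAsFactors = FALSE)
  videos <- list()
  meta <- list()
  reports <- list()
  gt_rows <- list()
  for (pi in seq_len(n_patients)) {
    pid <- patients$patient_id[pi]
    exam <- paste0("E", substring(pid, 2L))
    classes <- c("LCA", "RCA", config$distractors)
    exam_pct <- numeric()
    for (vi in seq_along(classes)) {
      vid_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
      cls <- classes[vi]
      vid_id <- sprintf("%s_V%d", pid, vi)
      n_frames <- sample(seq(config$n_frames_range[1L],
                             config$n_frames_range[2L]), 1L)
      acq <- acquisition_params(
        primary_angle = stats::runif(1, -180, 180),
        secondary_angle = stats::runif(1, -50, 50),
        n_frames = n_frames, fps = config$fps,
        frame_size = config$frame_size,
        contrast_peak_frame = sample(seq(max(1L, floor(n_frames * 0.4)),
                                         floor(n_frames * 0.75)), 1L),
        noise_sd = config$noise_sd, seed = vid_seed)
      if (cls %in% c("LCA", "RCA")) {
        nst <- sample(config$n_stenoses_choices, 1L,
                      prob = config$n_stenoses_probs)
        spec <- generate_vessel_tree(
          cls, stenosis_config = list(n = nst,
                                      percent_range = config$percent_range),
          seed = vid_seed, frame_size = config$frame_size)
      } else {
        spec <- generate_vessel_tree("other", seed = vid_seed,
                                     frame_size = config$frame_size,
                                     distractor_class = cls)
      }
      rv <- render_video(spec, acq)
      videos[[vid_id]] <- list(video = rv$video, ground_truth = rv$ground_truth,
                               spec = spec, acq = acq,
                               patient_id = pid, exam_id = exam,
                               video_id = vid_id)
      meta[[vid_id]] <- data.frame(
        patient_id = pid, exam_id = exam, video_id = vid_id,
        primary_angle = acq$primary_angle,
        secondary_angle = acq$secondary_angle,
        fps = acq$fps, n_frames = acq$n_frames,
        anatomy = spec$anatomy_class, stringsAsFactors = FALSE)
      pct <- rv$ground_truth$stenosis_pct
      for (s in names(pct)) {
        exam_pct[s] <- max(exam_pct[s], pct[[s]], 0, na.rm = TRUE)
      }
    }
    stenosed <- exam_pct[exam_pct > 0]
    gt_df <- data.frame(segment = names(exam_pct),
                        percent = as.numeric(exam_pct),
                        stringsAsFactors = FALSE)
    reports[[exam]] <- generate_report_text(
      data.frame(segment = names(stenosed), percent = as.numeric(stenosed),
                 stringsAsFactors = FALSE),
      seed = sample.int(.Machine$integer.max %/% 2L, 1L))
    gt_rows[[exam]] <- cbind(exam_id = exam, patient_id = pid, gt_df)
  }
  structure(list(videos = videos,
                 metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
                 reports = reports,
                 gt_stenosis = do.call(rbind, c(gt_rows,
                                                make.row.names = FALSE)),
                 patients = patients, config = config,
                 seed = as.integer(seed)),
            class = "angio_dataset")
}

#' @export
print.angio_dataset <- function(x, ...) {
  cat(sprintf("<angio_dataset> %d patients (%s), %d videos, %d frames px=%d\n",
              nrow(x$patients),
              paste(table(x$patients$split)[c("train", "dev", "test")],
                    collapse = "/"),
              length(x$videos),
              sum(x$metadata$n_frames), x$config$frame_size))
  invisible(x)
}

# Video entries of one split ("train", "dev", "test").
dataset_split <- function(dataset, split) {
  pats <- dataset$patients$patient_id[dataset$patients$split == split]
  dataset$videos[vapply(dataset$videos, function(v)
    v$patient_id %in% pats, logical(1))]
}
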
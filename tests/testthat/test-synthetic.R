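test_that("vessel trees respect side, stenosis bounds and determinism", {
  s0 <- generate_vessel_tree("RCA", list(), seed = 1)
  expect_identical(nrow(s0$stenoses), 0L)
  labs <- vapply(s0$segment_paths, `[[`, character(1), "label")
  expect_true(all(labs %in% tree_segments("RCA")))

  s1 <- generate_vessel_tree("LCA", list(n = 1, percents = 100), seed = 2)
  expect_identical(s1$stenoses$percent, 100)
  expect_true(all(s1$stenoses$segment %in% tree_segments("LCA")))

  a <- generate_vessel_tree("RCA", list(n = 3, percent_range = c(10, 90)),
                            seed = 7)
  b <- generate_vessel_tree("RCA", list(n = 3, percent_range = c(10, 90)),
                            seed = 7)
  expect_identical(a, b)

  expect_error(generate_vessel_tree("XCA"), "unknown side")
  expect_error(generate_vessel_tree("RCA", list(n = 1, percents = 120)),
               "outside")
})

test_that("rendered contrast peaks at the configured frame", {
  spec <- generate_vessel_tree("RCA", list(), seed = 3)
  acq <- acquisition_params(n_frames = 20, contrast_peak_frame = 10,
                            noise_sd = 0)
  rv <- render_video(spec, acq)
  ref <- rv$video$frames[[1]]
  d <- vapply(rv$video$frames, function(f) sum((f - ref)^2), numeric(1))
  expect_identical(which.max(d) - 1L, 10L)
  expect_identical(max(abs(ref - ref[1, 1])), 0)  # frame 0 contrast-free
})

test_that("ground-truth boxes are contained in the frame", {
  for (sd in 1:4) {
    spec <- generate_vessel_tree(c("LCA", "RCA")[sd %% 2 + 1],
                                 list(n = 2), seed = sd)
    acq <- acquisition_params(primary_angle = runif(1, -180, 180),
                              secondary_angle = runif(1, -50, 50),
                              n_frames = 8, contrast_peak_frame = 4)
    rv <- render_video(spec, acq)
    b <- rv$ground_truth$boxes
    expect_true(all(b$x_min >= 0 & b$x_min < b$x_max &
                      b$x_max <= acq$frame_size))
    expect_true(all(b$y_min >= 0 & b$y_min < b$y_max &
                      b$y_max <= acq$frame_size))
  }
})

test_that("rendered lumen narrows to the configured percent", {
  spec <- generate_vessel_tree(
    "RCA", list(n = 1, percents = 60, segments = "rca_mid", arcs = 0.5),
    seed = 11)
  acq <- acquisition_params(n_frames = 12, contrast_peak_frame = 6,
                            noise_sd = 0)
  rv <- render_video(spec, acq)
  g <- stenosis_geometry(spec, acq)
  peak <- rv$video$frames[[acq$contrast_peak_frame + 1]]
  v <- pmax(stats::median(peak) - peak, 0)
  w <- measure_vessel_width(v, g$x, g$y, g$nx, g$ny)
  expect_lt(abs(w - g$expected_width), 1)  # 40% of baseline, +- 1 px
})

test_that("rendered severity is monotone in the configured percent", {
  widths <- vapply(c(20, 50, 80), function(p) {
    spec <- generate_vessel_tree(
      "RCA", list(n = 1, percents = p, segments = "rca_mid", arcs = 0.5),
      seed = 5)
    acq <- acquisition_params(n_frames = 8, contrast_peak_frame = 4,
                              noise_sd = 0)
    rv <- render_video(spec, acq)
    g <- stenosis_geometry(spec, acq)
    peak <- rv$video$frames[[5]]
    v <- pmax(stats::median(peak) - peak, 0)
    measure_vessel_width(v, g$x, g$y, g$nx, g$ny)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("dataset splits are 70/10/20 and patient-disjoint", {
  ds <- generate_dataset(10, dataset_config(n_frames_range = c(6L, 8L),
                                            frame_size = 64L), seed = 1)
  tab <- table(ds$patients$split)
  expect_identical(as.integer(tab[c("train", "dev", "test")]), c(7L, 1L, 2L))
  ds2 <- generate_dataset(10, dataset_config(n_frames_range = c(6L, 8L),
                                             frame_size = 64L), seed = 1)
  expect_identical(ds$patients, ds2$patients)
  expect_error(generate_dataset(3), "at least 5")
  # disjointness by construction across many seeds
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:60, 1)
    sz <- angiopipe:::split_sizes(n)
    expect_identical(sum(sz), as.integer(n))
    expect_true(all(sz >= 1L))
  }
  # per-split video presence
  for (sp in c("train", "dev", "test")) {
    vids <- angiopipe:::dataset_split(ds, sp)
    anat <- vapply(vids, function(v) v$ground_truth$anatomy, character(1))
    expect_true(all(c("lca", "rca") %in% anat))
  }
})

test_that("dataset writing and PNG round-trip preserve frames", {
  ds <- generate_dataset(5, dataset_config(n_frames_range = c(4L, 5L),
                                           frame_size = 48L,
                                           distractors = "femoral_artery"),
                         seed = 2)
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  vid <- names(ds$videos)[1]
  back <- read_video_dir(file.path(dir, "videos", vid))
  orig <- ds$videos[[vid]]$video
  expect_identical(length(back$frames), length(orig$frames))
  expect_lt(max(abs(back$frames[[1]] - orig$frames[[1]])), 1 / 255)
  reports <- list.files(file.path(dir, "reports"))
  expect_identical(length(reports), 5L)
  unlink(dir, recursive = TRUE)
})
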
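test_that("a single still spec occupies every frame with no background", {
  spec <- list(behavior_spec("still", "still", 10))
  sc <- sample_behavior_script(spec, 10, seed = 1, background = NULL)
  expect_equal(unname(sc$labels[, "background"]), rep(0L, 10))
  expect_equal(unname(sc$labels[, "still"]), rep(1L, 10))
})

test_that("invalid configurations are rejected", {
  expect_error(sample_behavior_script(list(), 10), "invalid configuration")
  expect_error(sample_behavior_script(list(behavior_spec("a", "still", 5)), 0),
               "invalid configuration")
  expect_error(behavior_spec("a", "still", 0.5), "mean_bout_frames")
  expect_error(
    sample_behavior_script(list(behavior_spec("a", "overlay_flash", 5, 0.2,
                                              overlapping = TRUE)), 10),
    "non-overlapping")
})

test_that("labels are deterministic given the seed", {
  specs <- default_behavior_specs()
  a <- sample_behavior_script(specs, 500, seed = 7)
  b <- sample_behavior_script(specs, 500, seed = 7)
  expect_identical(a$labels, b$labels)
  c <- sample_behavior_script(specs, 500, seed = 8)
  expect_false(identical(a$labels, c$labels))
})

test_that("empirical class frequencies match the chain's stationary distribution", {
  # rare class configured near 1% via a 3-state chain plus background
  specs <- list(behavior_spec("common1", "locomote", 30, 1),
                behavior_spec("common2", "spin", 25, 1),
                behavior_spec("rare", "twitch", 6, 0.10))
  pi <- chain_stationary(specs, default_background())
  expect_lt(pi["rare"], 0.02)
  expect_gt(pi["rare"], 0.005)
  sc <- sample_behavior_script(specs, 1e5, seed = 42)
  emp <- colMeans(sc$labels)
  for (nm in names(pi))
    expect_lt(abs(emp[nm] - pi[nm]) / pi[nm], 0.30)
})

test_that("rendering encodes the behavior state", {
  st_still <- list(pos = c(16, 16), angle = 0, mode = "still", flash = FALSE)
  f1 <- render_frame(st_still, 1, c(32, 32), noise_sd = 0)
  for (t in 2:11)
    expect_identical(render_frame(st_still, t, c(32, 32), noise_sd = 0), f1)
  expect_true(all(f1 >= 0 & f1 <= 255))

  # locomotion advances the intensity-weighted centroid by the velocity
  cents <- sapply(0:5, function(k) {
    img <- render_frame(list(pos = c(22 + 2 * k, 32), angle = 0,
                             mode = "still", flash = FALSE), k, c(64, 64), 0)
    wgt <- img - min(img)
    sum(col(img) * wgt) / sum(wgt)
  })
  expect_true(all(abs(diff(cents) - 2) < 0.1))

  # flash shifts the mean intensity by its amplitude
  base <- render_frame(list(pos = c(16, 16), angle = 0, mode = "locomote",
                            flash = FALSE), 1, c(32, 32), 0)
  flash <- render_frame(list(pos = c(16, 16), angle = 0, mode = "locomote",
                             flash = TRUE), 1, c(32, 32), 0)
  # (rounding to 8-bit levels leaves the mean shift within a fraction of a level)
  expect_equal(mean(flash) - mean(base), default_render_params()$flash_amp,
               tolerance = 0.02)
  expect_error(render_frame(st_still, 1, c(16, 16)), "invalid configuration")
})

test_that("generate_dataset writes aligned videos and labels that round-trip", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(dir, n_videos = 2, n_frames = 60, size = c(32, 32),
                         seed = 5)
  expect_length(ds$video_names, 2)
  for (v in ds$video_names) {
    clip <- read_video(video_path(dir, v))
    lab <- read_labels(labels_path(dir, v), dim(clip$frames)[4])
    expect_equal(dim(clip$frames)[4], 60)
    expect_equal(nrow(lab), 60)
    expect_identical(unname(lab), unname(ds$labels[[v]]))
    expect_true(all(colSums(lab) > 0))  # every class present in every video
  }
  # regeneration with the same seed is bit-identical
  dir2 <- withr::local_tempdir()
  ds2 <- generate_dataset(dir2, n_videos = 2, n_frames = 60, size = c(32, 32),
                          seed = 5)
  expect_identical(ds$labels, ds2$labels)
  a <- read_video(video_path(dir, ds$video_names[1]))$frames
  b <- read_video(video_path(dir2, ds2$video_names[1]))$frames
  expect_identical(a, b)
})
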
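make_track <- function(n = 50, seed = 81) {
  sc <- sample_behavior_script(default_behavior_specs(), n, seed = seed)
  synthetic_keypoints(sc, seed = seed + 1)
}

test_that("low-confidence keypoints are linearly interpolated with edge extension", {
  tr <- make_track(20)
  tr$conf[] <- 1
  tr$coords[5, "nose", ] <- c(99, 99)
  tr$conf[5, "nose"] <- 0.5
  tr$coords[4, "nose", ] <- c(0, 0)
  tr$coords[6, "nose", ] <- c(2, 2)
  out <- interpolate_low_confidence(tr)
  expect_equal(out$coords[5, "nose", ], c(x = 1, y = 1))
  # confident frames never change
  expect_identical(out$coords[-5, , ], tr$coords[-5, , ])
  # leading gap takes the first confident value
  tr2 <- make_track(20)
  tr2$conf[] <- 1
  tr2$conf[1:3, "tailtip"] <- 0.1
  tr2$coords[1:3, "tailtip", 1] <- -5
  out2 <- interpolate_low_confidence(tr2)
  expect_equal(out2$coords[1, "tailtip", ], out2$coords[4, "tailtip", ])
  tr3 <- make_track(10)
  tr3$conf[, "nose"] <- 0.2
  expect_error(interpolate_low_confidence(tr3), "nose")
})

test_that("body-axis alignment puts the nose right, the tailbase left, and is rotation invariant", {
  tr <- interpolate_low_confidence(make_track(40))
  al <- align_to_body_axis(tr)
  expect_true(all(abs(al$coords[, "nose", 2]) < 1e-9))
  expect_true(all(al$coords[, "nose", 1] > 0))
  expect_equal(al$coords[, "tailbase", 1], -al$coords[, "nose", 1],
               tolerance = 1e-9)
  # apply a global rotation + translation to the raw coordinates
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr2 <- tr
  for (t in seq_len(dim(tr$coords)[1]))
    tr2$coords[t, , ] <- t(R %*% t(tr$coords[t, , ])) +
      matrix(c(0.1, -0.2), 7, 2, byrow = TRUE)
  al2 <- align_to_body_axis(tr2)
  expect_equal(al2$coords, al$coords, tolerance = 1e-6)
})

test_that("the feature expansion yields 44 features with the documented geometry", {
  tr <- interpolate_low_confidence(make_track(60))
  ff <- expand_features(tr)
  expect_equal(ncol(ff), 44)
  expect_equal(nrow(ff), 60)
  # symmetric rest posture: left/right paw angles mirror in sign
  sym <- make_track(5)
  body <- rbind(c(0.08, 0), c(0.03, 0.035), c(0.03, -0.035),
                c(-0.03, 0.035), c(-0.03, -0.035), c(-0.08, 0), c(-0.16, 0))
  for (t in 1:5) sym$coords[t, , ] <- body + 0.5
  sym$conf[] <- 1
  fs <- expand_features(sym)
  # columns 34..37: forepaw L/R then hindpaw L/R angles vs the body axis
  expect_equal(fs[1, 34], -fs[1, 35], tolerance = 1e-9)
  expect_equal(fs[1, 36], -fs[1, 37], tolerance = 1e-9)
  # elongated posture increases the nose-tailbase distance (column 38)
  elong <- sym
  elong$coords[, 1, 1] <- elong$coords[, 1, 1] + 0.05
  expect_gt(expand_features(elong)[1, 38], fs[1, 38])
})

test_that("windowing gives 1364 features with boundary replication", {
  tr <- interpolate_low_confidence(make_track(40))
  ff <- expand_features(tr)
  w <- window_features(ff)
  expect_equal(ncol(w), 1364)
  # constant track: every windowed row identical
  cst <- matrix(rep(ff[1, ], each = 40), 40)
  wc <- window_features(cst)
  expect_true(all(apply(wc, 2, function(col) all(col == col[1]))))
  # frame 1 replicates itself across the left half of the window
  expect_equal(w[1, 1:44], ff[1, ])
  expect_equal(w[1, 44 * 15 + 1:44], ff[1, ])
})

test_that("the MLP has the documented parameter count and is deterministic at eval", {
  mlp <- keypoint_mlp(5)
  expect_equal(count_parameters(mlp),
               1364 * 256 + 256 + 256 * 128 + 128 + 128 * 5 + 5)
  set.seed(82)
  x <- matrix(rnorm(3 * 1364), 3)
  expect_identical(keypoint_predict(mlp, x), keypoint_predict(mlp, x))
})

test_that("the keypoint classifier learns the synthetic behaviors end to end", {
  # four videos of keypoint tracks: train on two, thresholds on the third,
  # evaluate on the fourth
  specs <- default_behavior_specs()
  tracks <- list(); labels <- list()
  for (v in 1:4) {
    for (att in 1:50) {
      sc <- sample_behavior_script(specs, 800, seed = 900 + 10 * v + att)
      if (all(colSums(sc$labels) > 0)) break
    }
    nm <- paste0("v", v)
    tr <- interpolate_low_confidence(synthetic_keypoints(sc, seed = v))
    tracks[[nm]] <- window_features(expand_features(tr))
    labels[[nm]] <- sc$labels
  }
  split <- list(train = c("v1", "v2"), validation = "v3", test = "v4")
  fit <- train_keypoint_classifier(tracks, labels, split, steps = 1500L,
                                   seed = 4)
  preds <- fit$predict(tracks$v4)
  f1 <- macro_f1_nonbg(preds, labels$v4)
  expect_gte(f1, 0.7)
})
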
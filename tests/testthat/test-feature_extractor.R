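test_that("positive-class weights follow (N_neg/N_pos)^beta", {
  lab <- cbind(c(rep(1, 1), rep(0, 99)))
  expect_equal(positive_class_weight(lab, 0), 1)   # beta = 0: equal weighting
  expect_equal(positive_class_weight(lab, 1), 99)  # 99 negatives per positive
  bal <- cbind(rep(c(0, 1), 50))
  expect_equal(positive_class_weight(bal, 0.7), 1)
  expect_error(positive_class_weight(cbind(rep(0, 10)), 0.25), "split")
})

test_that("bias initialization makes sigmoid(bias) equal the class prevalence exactly", {
  lab <- cbind(c(rep(1, 1), rep(0, 99)))
  b <- init_classifier_bias(lab)
  expect_equal(1 / (1 + exp(-b)), 0.01)
  expect_equal(init_classifier_bias(cbind(rep(c(0, 1), 50))), 0)
  expect_equal(init_classifier_bias(cbind(c(rep(1, 10), rep(0, 90)))),
               log(1 / 9))
  # exact for arbitrary label matrices
  set.seed(51)
  m <- matrix(rbinom(500, 1, runif(5, 0.05, 0.9)), 100, byrow = TRUE)
  bb <- init_classifier_bias(m)
  expect_equal(1 / (1 + exp(-bb)), colMeans(m), tolerance = 1e-12)
})

test_that("label smoothing maps 0/1 to 0.05/0.95 and is affine", {
  expect_equal(smooth_labels(c(0, 1)), c(0.05, 0.95))
  set.seed(52)
  y <- matrix(rbinom(60, 1, 0.4), 10)
  expect_equal(mean(smooth_labels(y)), 0.05 + 0.9 * mean(y))
  expect_error(smooth_labels(c(0, 0.5)), "binary")
})

test_that("focal loss at gamma 0 equals weighted binary cross-entropy", {
  set.seed(53)
  p <- matrix(runif(200, 0.01, 0.99), 50)
  y <- matrix(rbinom(200, 1, 0.5), 50)
  w <- runif(4, 0.5, 3)
  wm <- matrix(w, 50, 4, byrow = TRUE)
  bce <- -mean(wm * y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_bce(p, y, gamma = 0, w = w), bce, tolerance = 1e-6)
  # hand value: single element, y = 1, p = 0.5, gamma = 1
  expect_equal(focal_bce(matrix(0.5), matrix(1), gamma = 1, w = 1),
               -(1 - 0.5) * log(0.5), tolerance = 1e-6)
  # strictly decreasing in p for a positive target
  ps <- seq(0.1, 0.9, by = 0.1)
  ls <- sapply(ps, function(pp) focal_bce(matrix(pp), matrix(1), 1, 1))
  expect_true(all(diff(ls) < 0))
})

test_that("L2-SP penalizes drift from anchors and decay of new weights, excluding biases", {
  params <- list("a.w" = 1 + 2, "a.b" = 5, "new.w" = c(0, 0))
  anchors <- list("a.w" = 1)
  expect_equal(l2sp_penalty(params, anchors, alpha = 1e-5, beta = 1e-3),
               (1e-5 / 2) * 4)
  params0 <- list("a.w" = 1, "a.b" = 99, "new.w" = c(0, 0))
  expect_equal(l2sp_penalty(params0, anchors, 1e-5, 1e-3), 0)
  # perturbing only a bias leaves the penalty unchanged
  paramsB <- list("a.w" = 1, "a.b" = -7, "new.w" = c(0, 0))
  expect_equal(l2sp_penalty(paramsB, anchors, 1e-5, 1e-3),
               l2sp_penalty(params0, anchors, 1e-5, 1e-3))
  expect_error(l2sp_penalty(list("a.w" = c(1, 2)), list("a.w" = 1), 1, 1),
               "shape")
})

test_that("fusion is the sigmoid of the average logit, symmetric and monotone", {
  z <- matrix(0, 2, 2)
  expect_equal(fuse_streams(z, z), matrix(0.5, 2, 2))
  expect_equal(fuse_streams(matrix(2), matrix(0)), matrix(1 / (1 + exp(-1))),
               tolerance = 1e-10)
  set.seed(54)
  a <- matrix(rnorm(12), 4); b <- matrix(rnorm(12), 4)
  expect_equal(fuse_streams(a, b), fuse_streams(b, a))
  expect_true(all(fuse_streams(a + 0.5, b) > fuse_streams(a, b)))
})

test_that("channel inflation replicates the mean RGB kernel", {
  set.seed(55)
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  wi <- inflate_input_channels(w, 20)
  expect_equal(dim(wi), c(3, 3, 20, 4))
  for (c in 2:20) expect_equal(wi[, , c, ], wi[, , 1, ])
  expect_equal(apply(wi, c(1, 2, 4), mean), apply(w, c(1, 2, 4), mean))
  w1 <- array(1, c(3, 3, 3, 2))
  expect_true(all(inflate_input_channels(w1, 20) == 1))
  expect_error(inflate_input_channels(array(1, c(3, 3, 4, 2))), "3 input")
})

test_that("every preset emits 512 features per stream and eval mode is deterministic", {
  set.seed(56)
  stack <- array(runif(32 * 32 * 3 * 11), c(32, 32, 3, 11))
  fg <- flow_generator("nano", seed = 1)
  for (preset in c("tiny", "resnet18", "resnet50", "tiny3d")) {
    fe <- feature_extractor(4, preset, seed = 2)
    out <- two_stream_forward(fe, fg, stack)
    expect_equal(ncol(out$spatial_features), 512)
    expect_equal(ncol(out$flow_features), 512)
    expect_equal(ncol(out$spatial_logits), 4)
    out2 <- two_stream_forward(fe, fg, stack)
    expect_equal(out, out2, tolerance = 1e-12)
  }
  # dropout active in train mode changes outputs across passes
  fe <- feature_extractor(4, "tiny", seed = 2)
  set.seed(1)
  a <- two_stream_forward(fe, fg, stack, train = TRUE)
  b <- two_stream_forward(fe, fg, stack, train = TRUE)
  expect_false(identical(a$spatial_logits, b$spatial_logits))
})

test_that("feature records round-trip through disk with width 1024", {
  set.seed(57)
  rec <- list(spatial_features = matrix(rnorm(20 * 512), 20),
              flow_features = matrix(rnorm(20 * 512), 20),
              spatial_logits = matrix(rnorm(20 * 5), 20),
              flow_logits = matrix(rnorm(20 * 5), 20))
  dir <- file.path(withr::local_tempdir(), "record")
  write_feature_record(rec, dir)
  back <- read_feature_record(dir)
  for (nm in names(rec))
    expect_equal(unname(back[[nm]]), unname(rec[[nm]]), tolerance = 1e-15)
  expect_equal(ncol(cbind(back$spatial_features, back$flow_features)), 1024)
  expect_error(write_feature_record(rec, dir), "overwrite")
  expect_silent(write_feature_record(rec, dir, overwrite = TRUE))
})

test_that("imbalance handling improves rare-class performance over plain training", {
  d <- small_dataset()
  split <- list(train = c("v1", "v2"), validation = "v3", test = "v3")
  stats <- compute_channel_stats(lapply(split$train, function(v)
    list(frames = d$frames[[v]])))
  frames_std <- lapply(d$frames, standardize_frames, stats = stats)
  flow <- trained_nano_flow()$model
  cache <- lapply(d$frames, function(f)
    ethoflow:::precompute_flow_inputs(flow, f))
  rare <- which(colnames(d$labels$v1) == "twitch")
  recall_of <- function(use_imbalance) {
    cfgL <- if (use_imbalance) classifier_loss_config()
      else classifier_loss_config(beta_pos = 0)
    res <- train_feature_stage(frames_std, cache, d$labels, split,
                               steps = 400L, batch_size = 8L,
                               loss_cfg = cfgL,
                               use_bias_init = use_imbalance, seed = 5)
    rec <- extract_features(res$model, frames_std$v3, cache$v3)
    p <- fuse_streams(rec$spatial_logits, rec$flow_logits)
    preds <- (p[, rare] > 0.5) + 0L
    y <- d$labels$v3[, rare]
    m <- suppressWarnings(eval_metrics(cbind(preds), cbind(y)))
    c(recall = unname(m$recall[1]), f1 = unname(m$f1[1]))
  }
  r_with <- recall_of(TRUE)
  r_without <- recall_of(FALSE)
  expect_gte(r_with["recall"], r_without["recall"])
  expect_gt(r_with["f1"], r_without["f1"])
  expect_gt(r_with["recall"], 0)
})
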
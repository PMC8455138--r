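test_that("the TGM preserves sequence length and rejects wrong feature widths", {
  set.seed(61)
  sm <- sequence_model(5, seed = 1)
  f <- matrix(rnorm(180 * 1024), 180)
  lg <- tgm_forward(sm, f)
  expect_equal(dim(lg), c(180, 5))
  for (Tn in c(1, 7, 200)) {
    fi <- matrix(rnorm(Tn * 1024), Tn)
    expect_equal(nrow(tgm_forward(sm, fi)), Tn)
  }
  expect_error(tgm_forward(sm, matrix(0, 10, 512)), "feature width")
})

test_that("logits only depend on frames within the analytic receptive field", {
  set.seed(62)
  sm <- sequence_model(4, seed = 2)
  r <- receptive_field_radius(sm$cfg)
  expect_equal(r, 28)
  f <- matrix(rnorm(180 * 1024), 180)
  base <- tgm_forward(sm, f)
  f2 <- f
  f2[100, ] <- f2[100, ] + 100
  changed <- which(rowSums(abs(tgm_forward(sm, f2) - base)) > 1e-9)
  expect_true(all(changed >= 100 - r & changed <= 100 + r))
  # a perturbation outside the field leaves the center frame untouched
  f3 <- f
  f3[100 + r + 5, ] <- f3[100 + r + 5, ] + 100
  expect_equal(tgm_forward(sm, f3)[100, ], base[100, ], tolerance = 1e-12)
})

test_that("late fusion averages the input head and the learned-feature head", {
  set.seed(63)
  sm <- sequence_model(3, seed = 3)
  f <- matrix(rnorm(60 * 1024), 60)
  sm$params[["head_out.w"]]$value[] <- 0
  sm$params[["head_out.b"]]$value[] <- 0
  lg <- tgm_forward(sm, f)
  head_in <- sweep(f %*% sm$params[["head_in.w"]]$value, 2,
                   sm$params[["head_in.b"]]$value, "+")
  expect_equal(lg, head_in / 2, tolerance = 1e-12)
})

test_that("chunking pads the tail with a mask and stitching restores T rows", {
  set.seed(64)
  f <- matrix(rnorm(600 * 8), 600)
  y <- matrix(rbinom(600 * 3, 1, 0.3), 600)
  ch <- chunk_sequences(f, y, 180L)
  expect_length(ch, 4)
  expect_equal(sum(ch[[4]]$mask), 60)
  expect_equal(sum(sapply(ch, function(c) sum(c$mask))), 600)
  # masked frames do not affect the loss
  cfg <- sequence_config(filter_length = 5, sequence_length = 20, d_input = 8,
                         c_out = 3, n_filters = 4, tgm_layers = 2,
                         penultimate_channels = 6,
                         input_dropout = 0, output_dropout = 0)
  sm <- sequence_model(3, cfg, seed = 4)
  chunk <- chunk_sequences(f[1:15, ], y[1:15, ], 20L)[[1]]
  l1 <- sequence_loss(sm, chunk, rep(1, 3), train = FALSE)$loss$value
  chunk$labels[16:20, ] <- 1 - chunk$labels[16:20, ]
  l2 <- sequence_loss(sm, chunk, rep(1, 3), train = FALSE)$loss$value
  expect_equal(l1, l2)
  # stitched inference has exactly T rows
  smd <- sequence_model(3, sequence_config(d_input = 8, sequence_length = 20,
                                           input_dropout = 0,
                                           output_dropout = 0,
                                           penultimate_channels = 6),
                        seed = 5)
  p <- sequence_predict(smd, f)
  expect_equal(dim(p), c(600, 3))
  expect_true(all(p > 0 & p < 1))
})

test_that("the sequence loss reduces to closed forms in degenerate settings", {
  cfg <- sequence_config(filter_length = 5, sequence_length = 20, d_input = 8,
                         c_out = 3, n_filters = 4, tgm_layers = 1,
                         penultimate_channels = 6,
                         input_dropout = 0, output_dropout = 0)
  sm <- sequence_model(2, cfg, seed = 6)
  # zero all head weights/biases -> constant p = 0.5; with gamma = 0 and
  # smoothed targets the loss is exactly log(2)
  for (nm in c("head_in.w", "head_in.b", "head_out.w", "head_out.b",
               "reduce.w", "reduce.b", "temporal.w", "temporal.b"))
    sm$params[[nm]]$value[] <- 0
  f <- matrix(rnorm(20 * 8), 20)
  y <- matrix(rbinom(40, 1, 0.5), 20)
  chunk <- chunk_sequences(f, y, 20L)[[1]]
  l <- sequence_loss(sm, chunk, rep(1, 2),
                     classifier_loss_config(gamma = 0), train = FALSE)
  expect_equal(l$loss$value, log(2), tolerance = 1e-10)
  # plain L2 penalty equals (alpha/2) * sum(w^2) on a hand-built model
  toy <- structure(list(params = list(
    "a.w" = ethoflow:::ag_param(matrix(c(3, 4), 1)),
    "a.b" = ethoflow:::ag_param(1))), class = "toy")
  pen <- ethoflow:::apply_l2sp_grads(toy, NULL, 0, 0.01)
  expect_equal(pen, 0.01 / 2 * 25)
  expect_equal(ethoflow:::apply_l2sp_grads(toy, NULL, 0, 0), 0)
})

test_that("the default parameter count sits in the expected range for K up to 10", {
  for (K in c(2, 5, 10)) {
    sm <- sequence_model(K, seed = 7)
    n <- count_parameters(sm)
    expect_gte(n, 150e3)
    expect_lte(n, 400e3)
  }
})
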
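# The optimization loop is exercised with a stub quadratic model so the
# schedule logic (plateau decay, stopping, best selection) is isolated from
# network behavior.

stub_model <- function() {
  structure(list(params = list("w.w" = ethoflow:::ag_param(c(2, -1)))),
            class = "stub")
}

test_that("a flat monitor walks the learning rate down 1e-4, 1e-5, 1e-6 and stops at the floor", {
  m <- stub_model()
  lrs <- c()
  cfg <- train_config("feature", lr_init = 1e-4,
                      plateau_patience_steps = 10L, eval_interval = 10L,
                      max_steps = 10000L)
  res <- train_model(
    m,
    step_fn = function(mm) {
      p <- mm$params[["w.w"]]
      ethoflow:::ag_mean(ethoflow:::ag_square(p))
    },
    val_fn = function(mm) 0.5,  # constant: never improves after the first eval
    config = cfg)
  lrs <- unique(res$log$lr)
  expect_equal(lrs, c(1e-4, 1e-5, 1e-6))
  expect_lt(1e-6 * 0.1, cfg$lr_floor)  # the next decay would cross the floor
  expect_lt(max(res$log$step), 10000L) # stopped early
})

test_that("the flow stage runs to its step cap regardless of the monitor", {
  m <- stub_model()
  cfg <- train_config("flow", lr_init = 1e-3, max_steps = 60L,
                      eval_interval = 20L, plateau_patience_steps = 20L)
  res <- train_model(
    m,
    step_fn = function(mm) ethoflow:::ag_mean(ethoflow:::ag_square(mm$params[["w.w"]])),
    val_fn = function(mm) 1,
    config = cfg)
  expect_equal(max(res$log$step), 60L)
})

test_that("best selection follows the stage direction with earliest-tie rule", {
  cps <- list(list(step = 1, monitor = 0.5), list(step = 2, monitor = 0.3),
              list(step = 3, monitor = 0.4))
  expect_equal(select_best(cps, "flow"), 2)
  cps2 <- list(list(step = 1, monitor = 0.2), list(step = 2, monitor = 0.8),
               list(step = 3, monitor = 0.8))
  expect_equal(select_best(cps2, "sequence"), 2)
  expect_error(select_best(list(), "flow"), "no checkpoints")
})

test_that("inference uses the best weights, which differ from final when the monitor degrades", {
  # a stub whose monitor first improves then worsens as the weight shrinks
  m <- stub_model()
  m$params[["w.w"]]$value <- 5
  cfg <- train_config("sequence", lr_init = 0.5, max_steps = 40L,
                      eval_interval = 5L, plateau_patience_steps = 1000L)
  res <- train_model(
    m,
    step_fn = function(mm) ethoflow:::ag_mean(ethoflow:::ag_square(mm$params[["w.w"]])),
    val_fn = function(mm) -abs(mm$params[["w.w"]]$value[1] - 3),  # peak at w = 3
    config = cfg)
  best <- res$checkpoints[[res$best]]
  final <- res$checkpoints[[length(res$checkpoints)]]
  expect_gt(best$monitor, final$monitor)
  expect_false(identical(best$weights, final$weights))
  m2 <- load_weights(res$model, best$weights)
  expect_equal(m2$params[["w.w"]]$value, best$weights[["w.w"]])
})

test_that("the background class is excluded from the F1 monitor", {
  preds <- cbind(background = c(1L, 1L, 1L, 1L), a = c(1L, 0L, 1L, 0L))
  labs <- cbind(background = c(0L, 0L, 0L, 0L), a = c(1L, 0L, 1L, 0L))
  # background disastrously wrong, behavior perfect: monitor must be 1
  expect_equal(macro_f1_nonbg(preds, labs), 1)
})

test_that("training runs are reproducible given the seed", {
  run_once <- function() {
    set.seed(77)
    m <- stub_model()
    m$params[["w.w"]]$value <- c(2, -1)
    train_model(
      m,
      step_fn = function(mm) {
        noise <- ethoflow:::ag_const(rnorm(2, sd = 0.1))
        ethoflow:::ag_mean(ethoflow:::ag_square(
          ethoflow:::ag_add(mm$params[["w.w"]], noise)))
      },
      val_fn = function(mm) sum(mm$params[["w.w"]]$value^2),
      config = train_config("flow", lr_init = 1e-2, max_steps = 30L,
                            eval_interval = 10L))$log
  }
  expect_identical(run_once(), run_once())
})

test_that("a non-finite loss aborts with a diagnostic", {
  m <- stub_model()
  expect_error(train_model(
    m,
    step_fn = function(mm) ethoflow:::ag_const(NaN),
    val_fn = function(mm) 0,
    config = train_config("flow", max_steps = 5L, eval_interval = 5L)),
    "non-finite")
})

test_that("checkpoint weights round-trip and reproduce validation metrics", {
  set.seed(78)
  sm <- sequence_model(3, sequence_config(d_input = 8, sequence_length = 20,
                                          penultimate_channels = 6,
                                          input_dropout = 0, output_dropout = 0),
                       seed = 9)
  f <- matrix(rnorm(40 * 8), 40)
  p1 <- sequence_predict(sm, f)
  w <- ethoflow:::model_weights(sm)
  sm2 <- sequence_model(3, sm$cfg, seed = 123)  # different init
  sm2 <- load_weights(sm2, w)
  expect_equal(sequence_predict(sm2, f), p1, tolerance = 1e-14)
})
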
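# Shared optimization loop: ADAM, plateau-based learning-rate decay,
# stage-specific stopping rules, checkpointing and best-model selection.

#' Training configuration
#'
#' Stage stopping rules: the flow generator always stops at `max_steps`
#' (10,000 by default); feature extractors stop at the first of
#' learning-rate floor, `max_steps` (20,000) or the wall-clock limit;
#' sequence models at the first of floor or `max_steps` (100,000). The
#' learning rate is multiplied by `lr_decay_factor` whenever the monitored
#' validation metric fails to improve by more than 1e-4 (absolute for
#' losses, relative for F1) within `plateau_patience_steps`.
#'
#' @param stage One of `"flow"`, `"feature"`, `"sequence"`.
#' @param lr_init Initial learning rate.
#' @param lr_decay_factor Multiplicative decay at each plateau (0.1).
#' @param plateau_patience_steps Patience window in training steps.
#' @param lr_floor Stop when the learning rate drops below this.
#' @param max_steps Stage step cap; `NULL` uses the stage default.
#' @param eval_interval Steps between validation evaluations.
#' @param max_hours Wall-clock cap (feature stage; `Inf` disables).
#' @param seed Seed for batch order and dropout draws.
#' @return Configuration list.
#' @export
train_config <- function(stage = c("flow", "feature", "sequence"),
                         lr_init = 1e-4, lr_decay_factor = 0.1,
                         plateau_patience_steps = 5000L, lr_floor = 5e-7,
                         max_steps = NULL, eval_interval = 100L,
                         max_hours = Inf, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(lr_decay_factor > 0, lr_decay_factor < 1, lr_floor < lr_init)
  if (is.null(max_steps))
    max_steps <- switch(stage, flow = 10000L, feature = 20000L, sequence = 100000L)
  list(stage = stage, lr_init = lr_init, lr_decay_factor = lr_decay_factor,
       plateau_patience_steps = as.integer(plateau_patience_steps),
       lr_floor = lr_floor, max_steps = as.integer(max_steps),
       eval_interval = as.integer(eval_interval), max_hours = max_hours,
       seed = seed,
       monitor_mode = if (stage == "flow") "min" else "max")
}

model_weights <- function(model)
  lapply(Filter(function(p) inherits(p, "ag_node"), model$params),
         function(p) p$value)

#' Load a set of weights into a model
#' @param model A model object of this package.
#' @param weights Named list of arrays (from a checkpoint).
#' @return The model with updated parameter values.
#' @export
load_weights <- function(model, weights) {
  for (nm in names(weights)) model$params[[nm]]$value <- weights[[nm]]
  model
}

# L2-SP gradient: anchored weights decay towards their anchors, new weights
# (and, for from-scratch models, all weights when anchors are NULL) towards
# zero. Biases and kernel metadata are excluded. Returns the penalty value.
apply_l2sp_grads <- function(model, anchors, alpha, beta, new_names = character()) {
  pen <- 0
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (!inherits(p, "ag_node") || grepl("\\.(b|mu|sigma)$", nm)) next
    if (!is.null(anchors[[nm]]) && !(nm %in% new_names)) {
      g <- alpha * (p$value - anchors[[nm]])
      pen <- pen + alpha / 2 * sum((p$value - anchors[[nm]])^2)
    } else {
      g <- beta * p$value
      pen <- pen + beta / 2 * sum(p$value^2)
    }
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  pen
}

improved <- function(new, best, mode) {
  if (is.null(best)) return(TRUE)
  if (mode == "min") best - new > 1e-4
  else new - best > 1e-4 * max(abs(best), 1e-8)
}

#' Generic training loop
#'
#' Runs ADAM over the model's parameters, calling `step_fn(model)` to build
#' each step's loss graph and `val_fn(model)` every `eval_interval` steps for
#' the monitored validation metric (validation loss for the flow stage,
#' macro F1 over non-background classes for classifiers). Saves a checkpoint
#' at every evaluation; training aborts on a non-finite loss.
#'
#' @param model Model object holding `params`.
#' @param step_fn Function(model) returning a scalar autodiff node (or a list
#'   with element `loss`).
#' @param val_fn Function(model) returning the scalar monitor value.
#' @param config A [train_config()].
#' @param reg_fn Optional function(model) adding regularization gradients in
#'   place and returning the penalty value.
#' @param verbose Print progress lines.
#' @return List with `model` (final weights), `checkpoints`, `log`
#'   (data.frame of step, loss, monitor, lr), `best` (best checkpoint index).
#' @export
train_model <- function(model, step_fn, val_fn, config, reg_fn = NULL,
                        verbose = FALSE) {
  params <- Filter(function(p) inherits(p, "ag_node"), model$params)
  opt <- adam_new(params, lr = config$lr_init)
  lr <- config$lr_init
  best_mon <- NULL
  since_improve <- 0L
  checkpoints <- list()
  log <- list()
  t0 <- Sys.time()
  step <- 0L
  while (step < config$max_steps) {
    step <- step + 1L
    ag_zero_grads(params)
    res <- step_fn(model)
    loss <- if (inherits(res, "ag_node")) res else res$loss
    if (!is.finite(loss$value))
      stop("non-finite training loss at step ", step, "; aborting")
    ag_backward(loss)
    pen <- if (!is.null(reg_fn)) reg_fn(model) else 0
    opt$lr <- lr
    opt <- adam_step(opt)
    if (step %% config$eval_interval == 0L || step == config$max_steps) {
      mon <- val_fn(model)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(step = step, monitor = mon, weights = model_weights(model))
      log[[length(log) + 1L]] <-
        data.frame(step = step, loss = loss$value + pen, monitor = mon, lr = lr)
      if (verbose)
        message(sprintf("step %d loss %.5f monitor %.5f lr %.2g",
                        step, loss$value + pen, mon, lr))
      if (improved(mon, best_mon, config$monitor_mode)) {
        best_mon <- mon
        since_improve <- 0L
      } else {
        since_improve <- since_improve + config$eval_interval
        if (since_improve >= config$plateau_patience_steps) {
          lr <- lr * config$lr_decay_factor
          since_improve <- 0L
        }
      }
      if (config$stage != "flow" && lr < config$lr_floor) break
      if (is.finite(config$max_hours) &&
          difftime(Sys.time(), t0, units = "hours") > config$max_hours) break
    }
  }
  best <- select_best(checkpoints, config$stage)
  list(model = model, checkpoints = checkpoints,
       log = do.call(rbind, log), best = best)
}

#' Select the best checkpoint of a run
#'
#' Minimum validation loss for the flow stage, maximum mean non-background
#' F1 for classifier stages; ties go to the earliest checkpoint. Inference
#' should use these weights, not the final ones.
#'
#' @param checkpoints List of checkpoints from [train_model()].
#' @param stage Training stage (determines the direction).
#' @return Index of the best checkpoint.
#' @export
select_best <- function(checkpoints, stage) {
  if (length(checkpoints) == 0L) stop("no checkpoints")
  mons <- vapply(checkpoints, function(cp) cp$monitor, numeric(1))
  if (stage == "flow") which.min(mons) else which.max(mons)
}

#' Macro F1 over non-background classes
#'
#' The validation monitor for classifier stages: the background column
#' (first) is excluded.
#'
#' @param preds,labels T x K binary matrices, background first.
#' @return Mean F1 over columns 2..K.
#' @export
macro_f1_nonbg <- function(preds, labels) {
  m <- suppressWarnings(eval_metrics(preds[, -1, drop = FALSE],
                                     labels[, -1, drop = FALSE]))
  m$macro_f1
}
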
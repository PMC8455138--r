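# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

# Small clean locomotion video (32 x 32, no noise) used for flow training.
locomotion_frames <- function() {
  if (!is.null(.fix$loco)) return(.fix$loco)
  spec <- list(behavior_spec("locomote", "locomote", 30, 1))
  sc <- sample_behavior_script(spec, 400, seed = 2, background = NULL)
  pars <- modifyList(default_render_params(), list(sigma = 3.5, speed = 2))
  v <- render_video(sc, size = c(32, 32), noise_sd = 0, seed = 3,
                    params = pars) / 255
  frames <- array(0, c(32, 32, 3, 400))
  for (c in 1:3) frames[, , c, ] <- v
  .fix$loco <- frames
  frames
}

# A nano flow generator trained on the locomotion fixture (one run shared by
# the reconstruction-improvement and flow-magnitude checks).
trained_nano_flow <- function() {
  if (!is.null(.fix$flow)) return(.fix$flow)
  frames <- locomotion_frames()
  set.seed(1)
  fm <- flow_generator("nano", seed = 1)
  cfg <- flow_loss_config()
  val_stacks <- lapply(seq(310, 390, 10), function(t) frame_stack(frames, t))
  vp0 <- flow_total_loss(fm, val_stacks, cfg)$components["pixel"]
  params <- Filter(function(p) inherits(p, "ag_node"), fm$params)
  opt <- adam_new(params, lr = 1e-3)
  for (s in 1:400) {
    ag_zero_grads(params)
    ts <- sample(6:295, 2)
    tl <- flow_total_loss(fm, lapply(ts, function(t) frame_stack(frames, t)), cfg)
    ag_backward(tl$loss)
    opt <- adam_step(opt)
    if (s == 300) opt$lr <- 2e-4
  }
  vp1 <- flow_total_loss(fm, val_stacks, cfg)$components["pixel"]
  .fix$flow <- list(model = fm, val_pixel_init = vp0, val_pixel_final = vp1,
                    steps_500_pixel = NULL)
  .fix$flow
}

# Tiny multi-behavior dataset in memory (3 videos x 300 frames at 32 x 32)
# for classifier tests that need labels with a rare class.
small_dataset <- function() {
  if (!is.null(.fix$small)) return(.fix$small)
  specs <- default_behavior_specs()
  frames <- list(); labels <- list()
  for (v in 1:3) {
    for (att in 1:50) {
      sc <- sample_behavior_script(specs, 300, seed = 100 * v + att)
      if (all(colSums(sc$labels) > 0)) break
    }
    img <- render_video(sc, size = c(32, 32), noise_sd = 3, seed = v,
                        params = modifyList(default_render_params(),
                                            list(sigma = 3.5))) / 255
    fr <- array(0, c(32, 32, 3, 300))
    for (c in 1:3) fr[, , c, ] <- img
    nm <- paste0("v", v)
    frames[[nm]] <- fr
    labels[[nm]] <- sc$labels
  }
  .fix$small <- list(frames = frames, labels = labels)
  .fix$small
}
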
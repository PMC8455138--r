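# End-to-end orchestration: flow generator -> two-stream feature extractor ->
# feature records on disk -> sequence model -> postprocessed ethograms and
# metrics, at desk scale on the synthetic dataset or any project directory
# with the same layout.

#' Write a feature record to disk
#'
#' One record per video: `spatial_features`, `flow_features` (T x 512) and
#' `spatial_logits`, `flow_logits` (T x K), stored as CSV (doubles
#' round-trip exactly).
#'
#' @param record Named list of the four matrices.
#' @param dir Record directory (created if needed).
#' @param overwrite Overwrite an existing record.
#' @return `dir`, invisibly.
#' @export
write_feature_record <- function(record, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("feature record exists at ", dir, "; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("spatial_features", "flow_features", "spatial_logits", "flow_logits")) {
    # 17 significant digits so doubles survive the text round trip exactly
    chr <- formatC(record[[nm]], format = "g", digits = 17)
    data.table::fwrite(data.table::as.data.table(chr),
                       file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read a feature record written by [write_feature_record()]
#' @param dir Record directory.
#' @return Named list of the four matrices.
#' @export
read_feature_record <- function(dir) {
  out <- lapply(c("spatial_features", "flow_features",
                  "spatial_logits", "flow_logits"), function(nm) {
    as.matrix(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
  })
  names(out) <- c("spatial_features", "flow_features",
                  "spatial_logits", "flow_logits")
  out
}

# Highest-resolution flows for every frame of a video, computed in batches.
# frames: H x W x 3 x T (0-1 intensities). Returns (H/2, W/2, 20, T).
# For the pairwise nano preset every adjacent pair's flow is computed once
# and the per-frame stacks are assembled from the shared pairs.
precompute_flow_inputs <- function(flow_model, frames, batch = 16L) {
  Tn <- dim(frames)[4]
  d <- dim(frames)
  out <- array(0, dim = c(d[1] / 2, d[2] / 2, 20L, Tn))
  if (identical(flow_model$preset, "nano")) {
    pair_flow <- function(a_idx, b_idx) {
      n <- length(a_idx)
      pf <- array(0, dim = c(d[1] / 2, d[2] / 2, 2L, n))
      for (i in seq(1, n, by = 64L)) {
        ii <- i:min(i + 63L, n)
        pin <- array(0, dim = c(d[1], d[2], 6L, length(ii)))
        pin[, , 1:3, ] <- frames[, , , a_idx[ii]]
        pin[, , 4:6, ] <- frames[, , , b_idx[ii]]
        xp <- ag_const(pin)
        e1 <- ag_leaky_relu(pconv(flow_model, "e1", xp, 2L, 1L))
        e2 <- ag_leaky_relu(pconv(flow_model, "e2", e1, 2L, 1L))
        f4 <- pconv(flow_model, "f4", e2, 1L, 1L)
        fu <- ag_upsample2x(f4, gain = 2)
        d1 <- ag_leaky_relu(pconv(flow_model, "d1",
                                  ag_concat_c(list(e1, ag_upsample2x(e2), fu)), 1L, 1L))
        f2 <- ag_add(pconv(flow_model, "f2", d1, 1L, 1L), fu)
        pf[, , , ii] <- f2$value
      }
      pf
    }
    pf <- pair_flow(1:(Tn - 1L), 2:Tn)                   # consecutive pairs
    bnd <- unique(pmin(pmax(c(1:5, (Tn - 4):Tn), 1L), Tn))
    pfid <- pair_flow(bnd, bnd)                          # replicated-frame pairs
    id_of <- stats::setNames(seq_along(bnd), bnd)
    for (t in seq_len(Tn)) {
      idx <- pmin(pmax((t - 5L):(t + 5L), 1L), Tn)
      for (j in 1:10) {
        a <- idx[j]; b <- idx[j + 1L]
        out[, , (2 * j - 1):(2 * j), t] <-
          if (a == b) pfid[, , , id_of[[as.character(a)]]] else pf[, , , a]
      }
    }
    return(out)
  }
  ts <- seq_len(Tn)
  for (i in seq(1, Tn, by = batch)) {
    idx <- ts[i:min(i + batch - 1L, Tn)]
    stacks <- lapply(idx, function(t) frame_stack(frames, t))
    pyr <- flow_forward(flow_model, stacks)
    out[, , , idx] <- pyr[[1]]
  }
  out
}

# Assemble the flow-stream input batch from cached half-res flows.
flow_batch_input <- function(flow_cache, idx, size) {
  flow_to_stream_input(flow_cache[, , , idx, drop = FALSE], size)
}

#' Train the flow generator on a set of videos
#'
#' @param frames_list Named list of H x W x 3 x T arrays (0-1 intensities),
#'   training videos.
#' @param val_frames_list Validation videos (monitored via total flow loss).
#' @param preset Flow architecture preset.
#' @param steps,batch_size,lr,eval_interval Desk-scale training settings.
#' @param seed Integer seed.
#' @param cfg A [flow_loss_config()].
#' @param verbose Print progress.
#' @return [train_model()] result with the best weights loaded into `$model`.
#' @export
train_flow_stage <- function(frames_list, val_frames_list, preset = "nano",
                             steps = 300L, batch_size = 2L, lr = 1e-3,
                             eval_interval = 100L, seed = 1L,
                             cfg = flow_loss_config(), verbose = FALSE) {
  set.seed(seed)
  model <- flow_generator(preset, seed = seed)
  anchors <- model_weights(model)
  # fixed validation stacks
  val_stacks <- unlist(lapply(val_frames_list, function(f) {
    Tn <- dim(f)[4]
    lapply(unique(round(seq(6, Tn - 5, length.out = 4))),
           function(t) frame_stack(f, t))
  }), recursive = FALSE)
  sample_batch <- function() {
    vids <- sample(seq_along(frames_list), batch_size, replace = TRUE)
    lapply(vids, function(v) {
      Tn <- dim(frames_list[[v]])[4]
      frame_stack(frames_list[[v]], sample(seq_len(Tn), 1))
    })
  }
  config <- train_config("flow", lr_init = lr, max_steps = steps,
                         eval_interval = eval_interval,
                         plateau_patience_steps = steps, seed = seed)
  res <- train_model(
    model,
    step_fn = function(m) flow_total_loss(m, sample_batch(), cfg)$loss,
    val_fn = function(m) flow_total_loss(m, val_stacks, cfg)$loss$value,
    config = config,
    reg_fn = function(m) apply_l2sp_grads(m, anchors, alpha = 1e-5, beta = 0),
    verbose = verbose)
  res$model <- load_weights(res$model, res$checkpoints[[res$best]]$weights)
  res
}

#' Train the two-stream feature extractor
#'
#' Flows are precomputed with the (frozen) flow generator; the classifier
#' loss is the weighted focal loss on the fused logits, with label
#' smoothing, positive-class weighting, bias initialization and L2-SP
#' regularization towards the initial weights.
#'
#' @param frames_std Named list of standardized frame arrays.
#' @param flow_cache Named list of cached half-resolution flow inputs.
#' @param labels Named list of label matrices.
#' @param split A split assignment (`train` / `validation` names).
#' @param preset Feature-extractor preset.
#' @param steps,batch_size,lr,eval_interval Desk-scale settings.
#' @param loss_cfg A [classifier_loss_config()].
#' @param use_bias_init Initialize readout biases at the class log odds.
#' @param seed Integer seed.
#' @param verbose Print progress.
#' @return [train_model()] result (best weights loaded) plus `class_weights`.
#' @export
train_feature_stage <- function(frames_std, flow_cache, labels, split,
                                preset = "tiny", steps = 600L, batch_size = 8L,
                                lr = 5e-4, eval_interval = 100L,
                                loss_cfg = classifier_loss_config(),
                                use_bias_init = TRUE, seed = 1L,
                                verbose = FALSE) {
  set.seed(seed)
  train_labels <- do.call(rbind, labels[split$train])
  K <- ncol(train_labels)
  w <- positive_class_weight(train_labels, loss_cfg$beta_pos)
  bias <- if (use_bias_init) init_classifier_bias(train_labels) else NULL
  model <- feature_extractor(K, preset, seed = seed, bias_init = bias)
  anchors <- model_weights(model)
  size <- dim(frames_std[[1]])[1:2]
  draw_batch <- function(vids) {
    v <- sample(vids, 1)
    Tn <- dim(frames_std[[v]])[4]
    ts <- sample(seq_len(Tn), batch_size)
    centers <- array(frames_std[[v]][, , , ts, drop = FALSE],
                     dim = c(size[1], size[2], 3, batch_size))
    fl <- flow_batch_input(flow_cache[[v]], ts, size)
    list(sp = centers, fl = fl, y = labels[[v]][ts, , drop = FALSE])
  }
  step_fn <- function(m) {
    b <- draw_batch(split$train)
    sp <- stream_forward_ag(m, "sp", ag_const(b$sp), train = TRUE)
    fl <- stream_forward_ag(m, "fl", ag_const(b$fl), train = TRUE)
    fused <- ag_scale(ag_add(sp$logits, fl$logits), 0.5)
    y <- if (loss_cfg$label_smoothing) smooth_labels(b$y) else b$y
    ag_focal_loss(fused, y, loss_cfg$gamma, w)
  }
  # fixed validation frames for the F1 monitor
  val_idx <- lapply(split$validation, function(v) {
    Tn <- dim(frames_std[[v]])[4]
    unique(round(seq(1, Tn, length.out = 120)))
  })
  names(val_idx) <- split$validation
  val_fn <- function(m) {
    preds <- list(); labs <- list()
    for (v in split$validation) {
      ts <- val_idx[[v]]
      sp_in <- array(frames_std[[v]][, , , ts], c(size[1], size[2], 3, length(ts)))
      fl_in <- flow_batch_input(flow_cache[[v]], ts, size)
      sp <- stream_forward_ag(m, "sp", ag_const(sp_in), train = FALSE)
      fl <- stream_forward_ag(m, "fl", ag_const(fl_in), train = FALSE)
      p <- fuse_streams(sp$logits$value, fl$logits$value)
      preds[[v]] <- (p > 0.5) + 0L
      labs[[v]] <- labels[[v]][ts, , drop = FALSE]
    }
    macro_f1_nonbg(do.call(rbind, preds), do.call(rbind, labs))
  }
  config <- train_config("feature", lr_init = lr, max_steps = steps,
                         eval_interval = eval_interval,
                         plateau_patience_steps = max(200L, steps %/% 2L),
                         seed = seed)
  res <- train_model(
    model, step_fn, val_fn, config,
    reg_fn = function(m) apply_l2sp_grads(m, anchors, loss_cfg$l2sp_alpha,
                                          loss_cfg$l2sp_beta, m$new_params),
    verbose = verbose)
  res$model <- load_weights(res$model, res$checkpoints[[res$best]]$weights)
  res$class_weights <- w
  res
}

#' Extract per-frame features and logits for one video
#'
#' @param model Trained [feature_extractor()].
#' @param frames_std Standardized H x W x 3 x T array.
#' @param flow_cache Cached half-res flows for the video ((H/2) x (W/2) x 20 x T).
#' @param batch Frames per forward batch.
#' @return Feature record (list of four matrices).
#' @export
extract_features <- function(model, frames_std, flow_cache, batch = 24L) {
  Tn <- dim(frames_std)[4]
  size <- dim(frames_std)[1:2]
  K <- model$n_classes
  rec <- list(spatial_features = matrix(0, Tn, 512),
              flow_features = matrix(0, Tn, 512),
              spatial_logits = matrix(0, Tn, K),
              flow_logits = matrix(0, Tn, K))
  for (i in seq(1, Tn, by = batch)) {
    idx <- i:min(i + batch - 1L, Tn)
    sp_in <- array(frames_std[, , , idx], c(size[1], size[2], 3, length(idx)))
    fl_in <- flow_batch_input(flow_cache, idx, size)
    sp <- stream_forward_ag(model, "sp", ag_const(sp_in), train = FALSE)
    fl <- stream_forward_ag(model, "fl", ag_const(fl_in), train = FALSE)
    rec$spatial_features[idx, ] <- sp$features$value
    rec$flow_features[idx, ] <- fl$features$value
    rec$spatial_logits[idx, ] <- sp$logits$value
    rec$flow_logits[idx, ] <- fl$logits$value
  }
  rec
}

#' Extract features for a project video and persist them
#'
#' @param project_dir Project root.
#' @param video_name Video directory name under `DATA/`.
#' @param feat_model,flow_model Trained models.
#' @param stats Channel statistics from the training subset.
#' @param overwrite Overwrite an existing record.
#' @return The feature record, invisibly.
#' @export
extract_and_store <- function(project_dir, video_name, feat_model, flow_model,
                              stats, overwrite = FALSE) {
  clip <- read_video(video_path(project_dir, video_name))
  fstd <- standardize_frames(clip$frames, stats)
  cache <- precompute_flow_inputs(flow_model, clip$frames)
  rec <- extract_features(feat_model, fstd, cache)
  write_feature_record(rec, file.path(project_dir, "DATA", video_name, "record"),
                       overwrite = overwrite)
  invisible(rec)
}

#' Train the TGM sequence model on saved feature records
#'
#' @param records Named list of feature records.
#' @param labels Named list of label matrices.
#' @param split A split assignment.
#' @param steps,lr,eval_interval Desk-scale settings.
#' @param cfg A [sequence_config()].
#' @param loss_cfg A [classifier_loss_config()].
#' @param seed Integer seed.
#' @param verbose Print progress.
#' @return [train_model()] result (best weights loaded) plus `class_weights`.
#' @export
train_sequence_stage <- function(records, labels, split, steps = 800L,
                                 lr = 1e-3, eval_interval = 100L,
                                 cfg = sequence_config(),
                                 loss_cfg = classifier_loss_config(),
                                 seed = 1L, verbose = FALSE) {
  set.seed(seed)
  feats <- lapply(records, function(r) cbind(r$spatial_features, r$flow_features))
  train_labels <- do.call(rbind, labels[split$train])
  K <- ncol(train_labels)
  w <- positive_class_weight(train_labels, loss_cfg$beta_pos)
  bias <- init_classifier_bias(train_labels)
  model <- sequence_model(K, cfg, seed = seed, bias_init = bias)
  chunks <- unlist(lapply(split$train, function(v)
    chunk_sequences(feats[[v]], labels[[v]], cfg$sequence_length)),
    recursive = FALSE)
  step_fn <- function(m) {
    ch <- chunks[[sample(length(chunks), 1)]]
    sequence_loss(m, ch, w, loss_cfg, train = TRUE)$loss
  }
  val_fn <- function(m) {
    preds <- list(); labs <- list()
    for (v in split$validation) {
      p <- sequence_predict(m, feats[[v]])
      preds[[v]] <- (p > 0.5) + 0L
      labs[[v]] <- labels[[v]]
    }
    macro_f1_nonbg(do.call(rbind, preds), do.call(rbind, labs))
  }
  config <- train_config("sequence", lr_init = lr, max_steps = steps,
                         eval_interval = eval_interval,
                         plateau_patience_steps = max(300L, steps %/% 3L),
                         seed = seed)
  res <- train_model(
    model, step_fn, val_fn, config,
    reg_fn = function(m) apply_l2sp_grads(m, NULL, 0, cfg$l2_alpha),
    verbose = verbose)
  res$model <- load_weights(res$model, res$checkpoints[[res$best]]$weights)
  res$class_weights <- w
  res
}

#' Run the full desk-scale pipeline on a project directory
#'
#' Reads videos and labels, splits 60/20/20, computes channel statistics on
#' the training subset, trains the flow generator, trains the two-stream
#' feature extractor with imbalance handling, extracts per-frame features to
#' disk, trains the sequence model, optimizes per-class thresholds on the
#' validation set, applies bout-length postprocessing, and evaluates on the
#' test split (using the validation thresholds).
#'
#' @param project_dir Project root with `DATA/<video>/` entries.
#' @param seed Integer seed driving every stage.
#' @param flow_preset,feature_preset Architecture presets.
#' @param flow_steps,feature_steps,sequence_steps Stage step budgets.
#' @param use_imbalance Enable positive weighting (beta 0.25), focal gamma 1
#'   and bias initialization; `FALSE` uses beta 0, gamma 1, no bias init.
#' @param verbose Print stage progress.
#' @return List with models, thresholds, cutoffs, per-split predictions and
#'   `metrics_feature` / `metrics_sequence` on the test split.
#' @export
run_pipeline <- function(project_dir, seed = 1L,
                         flow_preset = "nano", feature_preset = "tiny",
                         flow_steps = 300L, feature_steps = 600L,
                         sequence_steps = 800L, use_imbalance = TRUE,
                         verbose = FALSE) {
  vids <- project_videos(project_dir)
  frames <- list(); labels <- list()
  for (v in vids) {
    clip <- read_video(video_path(project_dir, v))
    frames[[v]] <- clip$frames
    labels[[v]] <- read_labels(labels_path(project_dir, v), dim(clip$frames)[4])
  }
  fps <- read_video_fps(project_dir, vids[1])
  split <- make_splits(labels, n_replicates = 1, seed = seed)[[1]]
  stats <- compute_channel_stats(lapply(split$train, function(v)
    list(frames = frames[[v]])))
  frames_std <- lapply(frames, standardize_frames, stats = stats)
  if (verbose) message("training flow generator (", flow_preset, ")")
  flow_res <- train_flow_stage(frames[split$train], frames[split$validation],
                               preset = flow_preset, steps = flow_steps,
                               seed = seed, verbose = verbose)
  flow_model <- flow_res$model
  if (verbose) message("precomputing flows")
  flow_cache <- lapply(frames, function(f) precompute_flow_inputs(flow_model, f))
  loss_cfg <- if (use_imbalance) classifier_loss_config()
    else classifier_loss_config(beta_pos = 0)
  if (verbose) message("training feature extractor (", feature_preset, ")")
  feat_res <- train_feature_stage(frames_std, flow_cache, labels, split,
                                  preset = feature_preset,
                                  steps = feature_steps,
                                  loss_cfg = loss_cfg,
                                  use_bias_init = use_imbalance,
                                  seed = seed, verbose = verbose)
  feat_model <- feat_res$model
  if (verbose) message("extracting features")
  records <- list()
  for (v in vids) {
    records[[v]] <- extract_features(feat_model, frames_std[[v]], flow_cache[[v]])
    write_feature_record(records[[v]],
                         file.path(project_dir, "DATA", v, "record"),
                         overwrite = TRUE)
  }
  if (verbose) message("training sequence model")
  seq_res <- train_sequence_stage(records, labels, split,
                                  steps = sequence_steps,
                                  loss_cfg = loss_cfg,
                                  seed = seed, verbose = verbose)
  seq_model <- seq_res$model
  feats <- lapply(records, function(r) cbind(r$spatial_features, r$flow_features))
  fe_probs <- lapply(vids, function(v)
    fuse_streams(records[[v]]$spatial_logits, records[[v]]$flow_logits))
  sq_probs <- lapply(vids, function(v) sequence_predict(seq_model, feats[[v]]))
  names(fe_probs) <- names(sq_probs) <- vids
  # validation thresholds; bout cutoffs from training labels
  val_labels <- do.call(rbind, labels[split$validation])
  thr_fe <- optimize_thresholds(do.call(rbind, fe_probs[split$validation]), val_labels)
  thr_sq <- optimize_thresholds(do.call(rbind, sq_probs[split$validation]), val_labels)
  cutoffs <- bout_length_cutoff(labels[split$train])
  post <- function(probs_list, thr) lapply(probs_list, function(p) {
    out <- postprocess_predictions(p, thr$tau, cutoffs)
    colnames(out) <- colnames(labels[[1]])
    out
  })
  preds_fe <- post(fe_probs, thr_fe)
  preds_sq <- post(sq_probs, thr_sq)
  test_labels <- do.call(rbind, labels[split$test])
  metrics_feature <- suppressWarnings(eval_metrics(
    do.call(rbind, preds_fe[split$test]), test_labels,
    do.call(rbind, fe_probs[split$test])))
  metrics_sequence <- suppressWarnings(eval_metrics(
    do.call(rbind, preds_sq[split$test]), test_labels,
    do.call(rbind, sq_probs[split$test])))
  list(split = split, stats = stats, fps = fps,
       flow_model = flow_model, feat_model = feat_model, seq_model = seq_model,
       flow_log = flow_res$log, feat_log = feat_res$log, seq_log = seq_res$log,
       thresholds_feature = thr_fe, thresholds_sequence = thr_sq,
       cutoffs = cutoffs, probs_feature = fe_probs, probs_sequence = sq_probs,
       preds_feature = preds_fe, preds_sequence = preds_sq, labels = labels,
       metrics_feature = metrics_feature, metrics_sequence = metrics_sequence,
       class_names = colnames(labels[[1]]))
}

read_video_fps <- function(project_dir, name) {
  meta <- file.path(project_dir, "DATA", name, "meta.yaml")
  if (file.exists(meta)) yaml::read_yaml(meta)$fps else 30
}
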
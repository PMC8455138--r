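# Keypoint-based comparison classifier: 7 tracked body points expanded to 44
# per-frame behavioral features, windowed over +/-15 frames (1364 features),
# classified by a small MLP trained with the same imbalance-aware tricks as
# the main pipeline.

KEYPOINT_NAMES <- c("nose", "forepaw_left", "forepaw_right",
                    "hindpaw_left", "hindpaw_right", "tailbase", "tailtip")
PAWS <- c("forepaw_left", "forepaw_right", "hindpaw_left", "hindpaw_right")

#' Simulate keypoint tracks from a behavior script
#'
#' Generates arena-normalized coordinates of the 7 body points (nose, left
#' and right forepaw, left and right hindpaw, tailbase, tailtip) consistent
#' with each behavior's kinematic signature: locomotion translates the body
#' along its heading, spinning rotates it, twitching adds a high-frequency
#' positional alternation, and the flash overlay is given a postural
#' signature (paws contracted toward the body). Confidences are near 1 with
#' occasional dips below 0.9 so that interpolation is exercised.
#'
#' @param script Output of [sample_behavior_script()].
#' @param seed Integer seed.
#' @param jitter Coordinate noise sd (arena units).
#' @return `keypoint_track` list: `coords` (T x 7 x 2), `conf` (T x 7),
#'   `point_names`.
#' @export
synthetic_keypoints <- function(script, seed = 1L, jitter = 0.004) {
  set.seed(seed)
  n <- length(script$states)
  body <- rbind(nose = c(0.08, 0),
                forepaw_left = c(0.030, 0.035),
                forepaw_right = c(0.030, -0.035),
                hindpaw_left = c(-0.030, 0.035),
                hindpaw_right = c(-0.030, -0.035),
                tailbase = c(-0.080, 0),
                tailtip = c(-0.160, 0.004))
  pos <- c(0.5, 0.5) + stats::runif(2, -0.06, 0.06)
  theta <- stats::runif(1, 0, 2 * pi)
  heading <- theta
  coords <- array(0, dim = c(n, 7, 2),
                  dimnames = list(NULL, KEYPOINT_NAMES, c("x", "y")))
  conf <- matrix(1, n, 7, dimnames = list(NULL, KEYPOINT_NAMES))
  speed <- 2 / 64  # matches the renderer's 2 px/frame at 64-px arena width
  prev <- ""
  has_flash <- ncol(script$overlays) > 0
  for (t in seq_len(n)) {
    st <- script$states[t]
    mode <- if (st == "background") "still" else script$modes[[st]]
    if (st != prev && mode == "locomote") heading <- stats::runif(1, 0, 2 * pi)
    prev <- st
    b <- body
    if (mode == "locomote") {
      pos <- pos + speed * c(cos(heading), sin(heading))
      pos <- pmin(pmax(pos, 0.15), 0.85)
      theta <- heading
      b["nose", 1] <- b["nose", 1] + 0.02  # stretched posture
    } else if (mode == "spin") {
      theta <- theta + 0.35
      # curled body while turning: tail swings off the body axis
      b["tailtip", ] <- c(-0.10, 0.10)
    } else if (mode == "twitch") {
      # paw tremor accompanies the positional alternation
      b[c("forepaw_left", "forepaw_right"), 2] <-
        b[c("forepaw_left", "forepaw_right"), 2] + 0.02 * (-1)^t
    }
    if (has_flash && any(script$overlays[t, ] == 1L))
      b[PAWS, ] <- b[PAWS, ] * 0.5        # crouch during the flash
    ct <- cos(theta); stn <- sin(theta)
    R <- matrix(c(ct, stn, -stn, ct), 2, 2)
    p0 <- if (mode == "twitch") pos + c(0.03 * (-1)^t, 0) else pos
    pts <- t(R %*% t(b)) + matrix(p0, 7, 2, byrow = TRUE)
    coords[t, , ] <- pts + matrix(stats::rnorm(14, sd = jitter), 7, 2)
    conf[t, ] <- pmin(1, 1 - abs(stats::rnorm(7, sd = 0.015)))
    dip <- stats::runif(7) < 0.03
    conf[t, dip] <- stats::runif(sum(dip), 0.2, 0.8)
  }
  structure(list(coords = coords, conf = conf, point_names = KEYPOINT_NAMES),
            class = "keypoint_track")
}

#' Interpolate low-confidence keypoints
#'
#' Frames where a point's confidence falls below the threshold are replaced
#' by linear interpolation between the nearest flanking confident frames;
#' leading/trailing gaps take the nearest confident value.
#'
#' @param track A `keypoint_track`.
#' @param threshold Confidence threshold (default 0.9).
#' @return The track with interpolated coordinates.
#' @export
interpolate_low_confidence <- function(track, threshold = 0.9) {
  n <- dim(track$coords)[1]
  for (p in seq_len(dim(track$coords)[2])) {
    good <- which(track$conf[, p] >= threshold)
    if (length(good) == 0)
      stop("keypoint '", track$point_names[p], "' is never confident")
    if (length(good) == n) next
    for (d in 1:2) {
      v <- track$coords[, p, d]
      track$coords[, p, d] <- stats::approx(good, v[good], xout = seq_len(n),
                                            rule = 2)$y
    }
  }
  track
}

# centroid = mean of the 4 paw coordinates (recomputed, never stored)
track_centroid <- function(coords) {
  (coords[, "forepaw_left", ] + coords[, "forepaw_right", ] +
     coords[, "hindpaw_left", ] + coords[, "hindpaw_right", ]) / 4
}

#' Align keypoints to the body axis
#'
#' Per frame, translates so the nose-tailbase midpoint is at the origin and
#' rotates so the tailbase-to-nose vector points along +x (nose right,
#' tailbase left). Degenerate frames (coincident nose and tailbase) reuse
#' the previous frame's rotation and are flagged.
#'
#' @param track Interpolated `keypoint_track`.
#' @return List: `coords` (T x 7 x 2 aligned), `centroid_aligned` (T x 2),
#'   `angle` (rotation applied per frame), `degenerate` (logical T).
#' @export
align_to_body_axis <- function(track) {
  co <- track$coords
  n <- dim(co)[1]
  out <- co
  cen <- track_centroid(co)
  cen_out <- matrix(0, n, 2)
  ang <- numeric(n)
  degenerate <- logical(n)
  prev_a <- 0
  for (t in seq_len(n)) {
    nose <- co[t, "nose", ]; tb <- co[t, "tailbase", ]
    mid <- (nose + tb) / 2
    v <- nose - tb
    if (sqrt(sum(v^2)) < 1e-9) {
      a <- prev_a
      degenerate[t] <- TRUE
    } else a <- atan2(v[2], v[1])
    prev_a <- a
    ang[t] <- a
    R <- matrix(c(cos(-a), sin(-a), -sin(-a), cos(-a)), 2, 2)
    pts <- t(R %*% (t(co[t, , ]) - mid))
    out[t, , ] <- pts
    cen_out[t, ] <- as.numeric(R %*% (cen[t, ] - mid))
  }
  list(coords = out, centroid_aligned = cen_out, angle = ang,
       degenerate = degenerate)
}

dist2 <- function(a, b) sqrt(rowSums((a - b)^2))

polygon_area <- function(pts_list) {
  # shoelace over the ordered point list (each element T x 2)
  n <- length(pts_list)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + pts_list[[i]][, 1] * pts_list[[j]][, 2] -
      pts_list[[j]][, 1] * pts_list[[i]][, 2]
  }
  abs(s) / 2
}

#' Expand keypoints to the 44 per-frame behavioral features
#'
#' The pinned enumeration: raw x,y of the 7 points plus centroid (16);
#' body-axis-aligned x,y of the same 8 (16); angles of the tail and of each
#' of the 4 paws relative to the body axis (5); distances nose-tailbase,
#' tailbase-tailtip, ipsilateral fore/hind paw (averaged over sides),
#' forepaw-nose (averaged), left-right forepaw, left-right hindpaw (6); and
#' the area of the body polygon through nose, paws and tailbase (1).
#'
#' @param track Interpolated, arena-normalized `keypoint_track`.
#' @return T x 44 feature matrix.
#' @export
expand_features <- function(track) {
  co <- track$coords
  n <- dim(co)[1]
  cen <- track_centroid(co)
  al <- align_to_body_axis(track)
  ac <- al$coords
  raw <- cbind(matrix(co, n, 14), cen)                 # 16
  aligned <- cbind(matrix(ac, n, 14), al$centroid_aligned)  # 16
  tail_vec <- ac[, "tailtip", ] - ac[, "tailbase", ]
  ang_tail <- atan2(tail_vec[, 2], tail_vec[, 1])
  ang_paws <- sapply(PAWS, function(p) atan2(ac[, p, 2], ac[, p, 1]))  # 4
  d_nose_tb <- dist2(co[, "nose", ], co[, "tailbase", ])
  d_tb_tip <- dist2(co[, "tailbase", ], co[, "tailtip", ])
  d_ipsi <- (dist2(co[, "forepaw_left", ], co[, "hindpaw_left", ]) +
               dist2(co[, "forepaw_right", ], co[, "hindpaw_right", ])) / 2
  d_fp_nose <- (dist2(co[, "forepaw_left", ], co[, "nose", ]) +
                  dist2(co[, "forepaw_right", ], co[, "nose", ])) / 2
  d_fp_lr <- dist2(co[, "forepaw_left", ], co[, "forepaw_right", ])
  d_hp_lr <- dist2(co[, "hindpaw_left", ], co[, "hindpaw_right", ])
  area <- polygon_area(list(co[, "nose", ], co[, "forepaw_right", ],
                            co[, "hindpaw_right", ], co[, "tailbase", ],
                            co[, "hindpaw_left", ], co[, "forepaw_left", ]))
  out <- cbind(raw, aligned, ang_tail, ang_paws,
               d_nose_tb, d_tb_tip, d_ipsi, d_fp_nose, d_fp_lr, d_hp_lr, area)
  colnames(out) <- NULL
  stopifnot(ncol(out) == 44L)
  out
}

#' Window per-frame features over +/- 15 frames
#'
#' Concatenates features of frames `t-15 .. t+15` (boundary frames
#' replicated), giving 44 * 31 = 1364 inputs per frame.
#'
#' @param features T x 44 matrix.
#' @param half_window Window radius in frames (default 15).
#' @return T x (44 * (2*half_window+1)) matrix.
#' @export
window_features <- function(features, half_window = 15L) {
  Tn <- nrow(features)
  k <- ncol(features)
  w <- 2L * half_window + 1L
  out <- matrix(0, Tn, k * w)
  for (o in seq_len(w)) {
    idx <- pmin(pmax(seq_len(Tn) + o - half_window - 1L, 1L), Tn)
    out[, ((o - 1L) * k + 1L):(o * k)] <- features[idx, , drop = FALSE]
  }
  out
}

#' Create the keypoint MLP classifier
#'
#' 1364 -> 256 -> 128 -> K with ReLU activations and dropout 0.35 between
#' layers, trained with the same focal loss, positive weighting, bias
#' initialization and scheduling as the main pipeline.
#'
#' @param n_classes K, including background.
#' @param d_input Input width (1364 for the default window).
#' @param seed Weight seed.
#' @param bias_init Optional output-bias vector.
#' @param dropout Dropout probability (0.35).
#' @return A `keypoint_mlp` model object.
#' @export
keypoint_mlp <- function(n_classes, d_input = 1364L, seed = 1L,
                         bias_init = NULL, dropout = 0.35) {
  set.seed(seed)
  params <- list()
  params <- new_linear(params, "fc1", d_input, 256L)
  params <- new_linear(params, "fc2", 256L, 128L)
  params <- new_linear(params, "out", 128L, n_classes, 0.1)
  if (!is.null(bias_init)) params[["out.b"]]$value <- bias_init
  structure(list(n_classes = n_classes, d_input = d_input, params = params,
                 dropout = dropout), class = "keypoint_mlp")
}

keypoint_forward_ag <- function(model, x, train = FALSE) {
  h <- ag_dropout(ag_relu(plinear(model, "fc1", x)), model$dropout, train)
  h <- ag_dropout(ag_relu(plinear(model, "fc2", h)), model$dropout, train)
  plinear(model, "out", h)
}

#' Keypoint classifier probabilities
#' @param model A [keypoint_mlp()].
#' @param x N x 1364 windowed feature matrix (standardized as in training).
#' @return N x K probability matrix.
#' @export
keypoint_predict <- function(model, x) {
  z <- keypoint_forward_ag(model, ag_const(x), train = FALSE)$value
  1 / (1 + exp(-z))
}

#' Train the keypoint comparison classifier
#'
#' Trains the MLP on windowed keypoint features with the training tricks of
#' the main pipeline: weighted binary focal loss with label smoothing,
#' positive-class weighting, bias initialization, plain L2 regularization,
#' learning-rate scheduling on validation-F1 saturation, best-weight
#' selection, validation-optimized thresholds and bout-length
#' postprocessing. Features are standardized per column with training-set
#' statistics.
#'
#' @param features Named list of T x 1364 windowed feature matrices
#'   (one per video, from [window_features()]).
#' @param labels Matching named list of T x K label matrices.
#' @param split Split assignment with `train`, `validation` video names.
#' @param steps,batch_size,lr,eval_interval Desk-scale settings.
#' @param loss_cfg A [classifier_loss_config()].
#' @param seed Integer seed.
#' @return List with `model`, `feature_stats` (per-column mean/sd),
#'   `thresholds` (validation-optimized), `cutoffs` (training bout filter),
#'   `class_weights`, the training `log`, and `predict(features)` returning
#'   postprocessed ethograms for a new feature matrix.
#' @export
train_keypoint_classifier <- function(features, labels, split,
                                      steps = 1500L, batch_size = 64L,
                                      lr = 1e-3, eval_interval = 100L,
                                      loss_cfg = classifier_loss_config(),
                                      seed = 1L) {
  set.seed(seed)
  xtr <- do.call(rbind, features[split$train])
  ytr <- do.call(rbind, labels[split$train])
  mu <- colMeans(xtr)
  sdv <- pmax(apply(xtr, 2, stats::sd), 1e-4)
  std <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  xtr <- std(xtr)
  w <- positive_class_weight(ytr, loss_cfg$beta_pos)
  bias <- init_classifier_bias(ytr)
  model <- keypoint_mlp(ncol(ytr), d_input = ncol(xtr), seed = seed,
                        bias_init = bias)
  xval <- std(do.call(rbind, features[split$validation]))
  yval <- do.call(rbind, labels[split$validation])
  step_fn <- function(m) {
    idx <- sample(nrow(xtr), batch_size)
    z <- keypoint_forward_ag(m, ag_const(xtr[idx, , drop = FALSE]), train = TRUE)
    y <- ytr[idx, , drop = FALSE]
    if (loss_cfg$label_smoothing) y <- smooth_labels(y)
    ag_focal_loss(z, y, loss_cfg$gamma, w)
  }
  val_fn <- function(m)
    macro_f1_nonbg((keypoint_predict(m, xval) > 0.5) + 0L, yval)
  config <- train_config("sequence", lr_init = lr, max_steps = steps,
                         eval_interval = eval_interval,
                         plateau_patience_steps = max(300L, steps %/% 3L),
                         seed = seed)
  res <- train_model(model, step_fn, val_fn, config,
                     reg_fn = function(m) apply_l2sp_grads(m, NULL, 0, 1e-4))
  model <- load_weights(res$model, res$checkpoints[[res$best]]$weights)
  thresholds <- optimize_thresholds(keypoint_predict(model, xval), yval)
  cutoffs <- bout_length_cutoff(labels[split$train])
  list(model = model, feature_stats = list(mean = mu, sd = sdv),
       thresholds = thresholds, cutoffs = cutoffs, class_weights = w,
       log = res$log,
       predict = function(x) {
         p <- keypoint_predict(model, std(x))
         postprocess_predictions(p, thresholds$tau, cutoffs)
       })
}
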
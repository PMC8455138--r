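# Temporal Gaussian Mixture sequence classifier over saved 1024-d per-frame
# features. Temporal kernels are learned mixtures of Gaussians over a
# length-L window (soft attention over mixtures), giving a wide receptive
# field with few parameters. Two late-fusion heads - a 1-D convolution over
# the raw input features and one over the learned features - are averaged
# before the sigmoid.

#' Sequence model configuration
#'
#' @param filter_length Temporal window L of every Gaussian-mixture kernel
#'   (odd; default 15 frames).
#' @param c_in,c_out Input/output channel counts of the TGM stack.
#' @param tgm_layers Number of stacked TGM layers.
#' @param n_filters Gaussians per mixture.
#' @param input_dropout,output_dropout Dropout on the raw input features and
#'   on the learned features.
#' @param d_input Feature dimensionality D (spatial 512 + flow 512).
#' @param sequence_length Training chunk length in frames.
#' @param penultimate_channels Width of the reduced penultimate layer.
#' @param l2_alpha Plain L2 weight penalty (the sequence model is trained
#'   from scratch, so no starting-point anchor is used).
#' @return Configuration list.
#' @export
sequence_config <- function(filter_length = 15L, c_in = 1L, c_out = 8L,
                            tgm_layers = 3L, n_filters = 8L,
                            input_dropout = 0.5, output_dropout = 0.5,
                            d_input = 1024L, sequence_length = 180L,
                            penultimate_channels = 128L, l2_alpha = 0.01) {
  stopifnot(filter_length %% 2L == 1L, tgm_layers >= 1L,
            sequence_length >= filter_length)
  list(filter_length = as.integer(filter_length), c_in = as.integer(c_in),
       c_out = as.integer(c_out), tgm_layers = as.integer(tgm_layers),
       n_filters = as.integer(n_filters), input_dropout = input_dropout,
       output_dropout = output_dropout, d_input = as.integer(d_input),
       sequence_length = as.integer(sequence_length),
       penultimate_channels = as.integer(penultimate_channels),
       l2_alpha = l2_alpha)
}

#' Analytic temporal receptive-field radius of the sequence model
#'
#' Each TGM layer spans `(L-1)/2` frames on either side, as does the
#' kernel-15 temporal convolution in the learned-feature head; the 1x1 heads
#' add nothing.
#'
#' @param cfg A [sequence_config()].
#' @return Radius in frames.
#' @export
receptive_field_radius <- function(cfg = sequence_config()) {
  cfg$tgm_layers * (cfg$filter_length - 1L) %/% 2L +
    (cfg$filter_length - 1L) %/% 2L
}

inv_softplus <- function(y) log(expm1(y))

#' Create a TGM sequence model
#'
#' @param n_classes K, including background.
#' @param cfg A [sequence_config()].
#' @param seed Weight-initialization seed.
#' @param bias_init Optional output-bias vector (class log odds).
#' @return A `sequence_model` object.
#' @export
sequence_model <- function(n_classes, cfg = sequence_config(), seed = 1L,
                           bias_init = NULL) {
  set.seed(seed)
  params <- list()
  L <- cfg$filter_length
  cins <- c(cfg$c_in, rep(cfg$c_out, cfg$tgm_layers - 1L))
  for (l in seq_len(cfg$tgm_layers)) {
    M <- cfg$n_filters
    nm <- sprintf("tgm%d", l)
    # centers uniform across the window, widths L/4, soft attention logits ~ 0
    params[[paste0(nm, ".mu")]] <- ag_param(seq(0, L - 1, length.out = M))
    params[[paste0(nm, ".sigma")]] <- ag_param(rep(inv_softplus(L / 4), M))
    params[[paste0(nm, ".att")]] <-
      ag_param(matrix(stats::rnorm(cins[l] * cfg$c_out * M, sd = 0.1),
                      nrow = cins[l] * cfg$c_out))
    params[[paste0(nm, ".b")]] <- ag_param(rep(0, cfg$c_out))
  }
  params <- new_linear(params, "head_in", cfg$d_input, n_classes, 0.1)
  params <- new_linear(params, "reduce", cfg$d_input, cfg$penultimate_channels)
  params <- new_conv(params, "temporal", 1, L, cfg$penultimate_channels,
                     cfg$penultimate_channels)
  params <- new_linear(params, "head_out", cfg$penultimate_channels, n_classes, 0.1)
  if (!is.null(bias_init)) {
    params[["head_in.b"]]$value <- bias_init
    params[["head_out.b"]]$value <- bias_init
  }
  structure(list(cfg = cfg, n_classes = n_classes, params = params),
            class = "sequence_model")
}

# Build the (1, L, c_in, c_out) kernel node of TGM layer l from its Gaussian
# centers, widths and attention logits.
tgm_kernel_ag <- function(model, l, c_in) {
  cfg <- model$cfg
  L <- cfg$filter_length
  nm <- sprintf("tgm%d", l)
  mu <- model$params[[paste0(nm, ".mu")]]
  sg <- model$params[[paste0(nm, ".sigma")]]
  att <- model$params[[paste0(nm, ".att")]]
  M <- cfg$n_filters
  # width = softplus(sigma_raw) + 0.1 (strictly positive)
  width <- ag_add_scalar(ag_log(ag_add_scalar(ag_exp(sg), 1)), 0.1)
  # basis G: M x L, G[m, t] = exp(-(t - mu_m)^2 / (2 width_m^2)), rows sum 1
  tgrid <- matrix(seq(0, L - 1), nrow = M, ncol = L, byrow = TRUE)
  muM <- ag_matmul(ag_reshape(mu, c(M, 1L)), ag_const(matrix(1, 1, L)))
  wM <- ag_matmul(ag_reshape(width, c(M, 1L)), ag_const(matrix(1, 1, L)))
  z <- ag_div(ag_sub(ag_const(tgrid), muM), wM)
  G <- ag_normalize_rows(ag_exp(ag_scale(ag_square(z), -0.5)))
  S <- ag_softmax_rows(att)            # (c_in*c_out) x M
  kern <- ag_matmul(S, G)              # (c_in*c_out) x L, rows: ci fastest
  ag_reshape(ag_transpose(kern), c(L, c_in, cfg$c_out))
}

# features node: (D, T, C, 1). Returns T x K logits node.
sequence_forward_ag <- function(model, feats, train = FALSE) {
  cfg <- model$cfg
  D <- cfg$d_input
  Tn <- dim(feats$value)[2]
  x <- ag_dropout(feats, cfg$input_dropout, train)
  h <- x
  cins <- c(cfg$c_in, rep(cfg$c_out, cfg$tgm_layers - 1L))
  for (l in seq_len(cfg$tgm_layers)) {
    k <- tgm_kernel_ag(model, l, cins[l])
    h <- ag_relu(ag_tconv(h, k, model$params[[sprintf("tgm%d.b", l)]]))
  }
  # collapse the c_out channels by averaging -> (D, T) learned features
  hm <- ag_matmul(ag_reshape(h, c(D * Tn, cfg$c_out)),
                  ag_const(matrix(1 / cfg$c_out, cfg$c_out, 1)))
  learned <- ag_reshape(hm, c(D, Tn))
  learned <- ag_dropout(learned, cfg$output_dropout, train)
  # learned-feature head: 1x1 reduce to 128 channels, kernel-15 temporal
  # conv, then a 1x1 classification layer
  red <- ag_relu(plinear(model, "reduce", ag_transpose(learned)))  # T x 128
  # (T, 128) memory (t fastest) matches the (1, T, 128, 1) tconv layout
  red4 <- ag_reshape(red, c(1L, Tn, cfg$penultimate_channels, 1L))
  kt <- ag_reshape(model$params[["temporal.w"]],
                   c(cfg$filter_length, cfg$penultimate_channels,
                     cfg$penultimate_channels))
  tc <- ag_relu(ag_tconv(red4, kt, model$params[["temporal.b"]]))
  # (1, T, 128, 1) -> T x 128 matrix: memory order is (t fastest) x channel
  tmat <- ag_reshape(tc, c(Tn, cfg$penultimate_channels))
  head_learned <- plinear(model, "head_out", tmat)                # T x K
  head_input <- plinear(model, "head_in", ag_transpose(ag_reshape(x, c(D, Tn))))
  ag_scale(ag_add(head_input, head_learned), 0.5)
}

#' Sequence-model forward pass
#'
#' @param model A [sequence_model()].
#' @param features T x D feature matrix (concatenated spatial and flow
#'   features).
#' @return T x K logit matrix (apply `sigmoid` for probabilities).
#' @export
tgm_forward <- function(model, features) {
  if (ncol(features) != model$cfg$d_input)
    stop("feature width ", ncol(features), " does not match configured D = ",
         model$cfg$d_input)
  feats <- ag_const(array(t(features),
                          dim = c(model$cfg$d_input, nrow(features), 1L, 1L)))
  sequence_forward_ag(model, feats, train = FALSE)$value
}

#' Split a feature/label sequence into fixed-length training chunks
#'
#' Non-overlapping chunks of `length` frames; the final partial chunk is
#' zero-padded with a mask so padded frames never contribute to the loss, and
#' stitching predictions back discards them.
#'
#' @param features T x D matrix.
#' @param labels T x K matrix (optional).
#' @param length Chunk length.
#' @return List of chunks: `features`, `labels`, `mask` (1 = real frame),
#'   `start` (0-based frame offset).
#' @export
chunk_sequences <- function(features, labels = NULL, length = 180L) {
  stopifnot(length >= 1L)
  Tn <- nrow(features)
  starts <- seq(0L, Tn - 1L, by = length)
  lapply(starts, function(s) {
    idx <- (s + 1L):min(s + length, Tn)
    f <- matrix(0, length, ncol(features))
    f[seq_along(idx), ] <- features[idx, , drop = FALSE]
    l <- NULL
    if (!is.null(labels)) {
      l <- matrix(0, length, ncol(labels))
      l[seq_along(idx), ] <- labels[idx, , drop = FALSE]
    }
    mask <- rep(0, length)
    mask[seq_along(idx)] <- 1
    list(features = f, labels = l, mask = mask, start = s)
  })
}

#' Predict per-frame probabilities for a whole video
#'
#' Runs [tgm_forward()] on non-overlapping chunks and stitches the
#' predictions back in order, discarding padded frames.
#'
#' @param model A [sequence_model()].
#' @param features T x D matrix.
#' @return T x K probability matrix.
#' @export
sequence_predict <- function(model, features) {
  Tn <- nrow(features)
  chunks <- chunk_sequences(features, NULL, model$cfg$sequence_length)
  out <- matrix(0, Tn, model$n_classes)
  for (ch in chunks) {
    logits <- tgm_forward(model, ch$features)
    keep <- which(ch$mask == 1)
    out[ch$start + keep, ] <- 1 / (1 + exp(-logits[keep, , drop = FALSE]))
  }
  out
}

#' Sequence training loss on one chunk
#'
#' The same weighted binary focal loss as the feature extractor (with label
#' smoothing), masked to real frames; the plain L2 penalty
#' `(l2_alpha/2) * sum(w^2)` is added by the training engine.
#'
#' @param model A [sequence_model()].
#' @param chunk One element of [chunk_sequences()].
#' @param class_weights Positive-class weights (length K).
#' @param loss_cfg A [classifier_loss_config()].
#' @param train Enable dropout.
#' @return List with `loss` (autodiff scalar node).
#' @export
sequence_loss <- function(model, chunk, class_weights,
                          loss_cfg = classifier_loss_config(), train = TRUE) {
  feats <- ag_const(array(t(chunk$features),
                          dim = c(model$cfg$d_input, nrow(chunk$features), 1L, 1L)))
  logits <- sequence_forward_ag(model, feats, train)
  y <- chunk$labels
  if (loss_cfg$label_smoothing) y <- smooth_labels(y)
  mask <- matrix(chunk$mask, nrow(y), ncol(y))
  list(loss = ag_focal_loss(logits, y, loss_cfg$gamma, class_weights, mask))
}
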
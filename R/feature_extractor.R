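# Two-stream per-frame classifier: a spatial stream on the center RGB frame
# and a flow stream on the 10 stacked flow fields, each reduced to 512
# features plus K logits, fused by late averaging. Trained with a
# class-imbalance-aware focal loss, label smoothing, positive-class
# weighting, classifier bias initialization and L2-SP regularization.

#' Classifier loss configuration
#'
#' @param gamma Focal exponent (default 1).
#' @param beta_pos Positive-weight exponent in \[0, 1\] (default 0.25).
#' @param label_smoothing Use 0.05/0.95 targets instead of hard 0/1.
#' @param l2sp_alpha,l2sp_beta L2-SP weights: decay of pretrained weights
#'   towards their anchors, and plain decay of newly initialized weights.
#' @return Configuration list.
#' @export
classifier_loss_config <- function(gamma = 1, beta_pos = 0.25,
                                   label_smoothing = TRUE,
                                   l2sp_alpha = 1e-5, l2sp_beta = 1e-3) {
  stopifnot(gamma >= 0, beta_pos >= 0, beta_pos <= 1)
  list(gamma = gamma, beta_pos = beta_pos, label_smoothing = label_smoothing,
       l2sp_alpha = l2sp_alpha, l2sp_beta = l2sp_beta)
}

#' Positive-class loss weights from training labels
#'
#' `w_k = (N_neg,k / N_pos,k) ^ beta_pos`: with `beta_pos = 1` positive
#' examples are weighted fully by their inverse frequency; with
#' `beta_pos = 0` all examples are weighted equally (`w_k = 1`).
#'
#' @param labels T x K binary training label matrix.
#' @param beta_pos Exponent in \[0, 1\].
#' @return Numeric vector of K positive-class weights.
#' @export
positive_class_weight <- function(labels, beta_pos = 0.25) {
  npos <- colSums(labels == 1)
  nneg <- colSums(labels == 0)
  if (any(npos == 0))
    stop("class(es) with zero positive training frames: ",
         paste(colnames(labels)[npos == 0], collapse = ", "),
         "; ensure the split satisfies the class-coverage constraint")
  (nneg / npos)^beta_pos
}

#' Initialize classifier biases to the class log odds
#'
#' `b_k = log(N_pos,k / N_neg,k)`, so that `sigmoid(b_k)` equals the
#' empirical positive rate and an untrained model already guesses rare
#' classes at their base rate.
#'
#' @param labels T x K binary training label matrix.
#' @return Numeric vector of K biases.
#' @export
init_classifier_bias <- function(labels) {
  npos <- colSums(labels == 1)
  nneg <- colSums(labels == 0)
  if (any(npos == 0) || any(nneg == 0))
    stop("bias initialization needs >= 1 positive and >= 1 negative frame per class")
  log(npos / nneg)
}

#' Smooth binary targets
#' @param y Binary labels (0/1).
#' @return Targets with 1 -> 0.95 and 0 -> 0.05.
#' @export
smooth_labels <- function(y) {
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  y * 0.9 + 0.05
}

#' Weighted binary focal loss
#'
#' `-mean( w_k (1-p)^gamma y log p + p^gamma (1-y) log(1-p) )`. At
#' `gamma = 0` and unit weights this is the (weighted) binary cross-entropy;
#' larger `gamma` down-weights confidently correct predictions.
#'
#' @param p Probability matrix (T x K), entries in (0, 1); clamped to
#'   `[1e-7, 1 - 1e-7]`.
#' @param targets Targets, same shape (may be smoothed).
#' @param gamma Focal exponent.
#' @param w Positive-class weights (length K or scalar).
#' @return Scalar loss (mean over elements).
#' @export
focal_bce <- function(p, targets, gamma = 1, w = 1) {
  if (!identical(dim(p), dim(targets)) && length(p) != length(targets))
    stop("shape mismatch")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  wm <- if (length(w) > 1) matrix(w, nrow(p), ncol(p), byrow = TRUE) else w
  -mean(wm * (1 - p)^gamma * targets * log(p) +
          p^gamma * (1 - targets) * log(1 - p))
}

# Focal loss from logits with analytic gradient (used in training graphs).
# mask: optional 0/1 matrix; loss averaged over unmasked elements.
ag_focal_loss <- function(logits, targets, gamma, w, mask = NULL) {
  z <- logits$value
  p <- 1 / (1 + exp(-z))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  wm <- if (length(w) > 1) matrix(w, nrow(z), ncol(z), byrow = TRUE) else
    matrix(w, nrow(z), ncol(z))
  y <- targets
  t1 <- (1 - p)^gamma * log(p)
  t2 <- p^gamma * log(1 - p)
  el <- -(wm * y * t1 + (1 - y) * t2)
  m <- if (is.null(mask)) matrix(1, nrow(z), ncol(z)) else mask
  denom <- sum(m)
  val <- sum(el * m) / denom
  ag_op(val, list(logits), function(g) {
    d1 <- (1 - p)^(gamma + 1) - gamma * p * (1 - p)^gamma * log(p)
    d2 <- gamma * p^gamma * (1 - p) * log(1 - p) - p^(gamma + 1)
    list(g * (-(wm * y * d1 + (1 - y) * d2)) * m / denom)
  })
}

#' L2-SP regularization penalty
#'
#' `(alpha/2) ||w_s - w_s0||^2 + (beta/2) ||w_new||^2` over weight tensors,
#' where anchored (pretrained) weights decay towards their starting point and
#' new weights (e.g. the final readout) decay to zero. Biases and
#' normalization parameters are excluded.
#'
#' @param params Named list of weight arrays (current values).
#' @param anchors Named list of anchor arrays for the pretrained subset;
#'   parameters without an anchor are treated as new.
#' @param alpha,beta Penalty weights.
#' @return Scalar penalty.
#' @export
l2sp_penalty <- function(params, anchors, alpha = 1e-5, beta = 1e-3) {
  tot <- 0
  for (nm in names(params)) {
    if (grepl("\\.b$", nm) || grepl("\\.kt$", nm)) next  # biases / metadata
    w <- params[[nm]]
    if (!is.numeric(w)) next
    if (!is.null(anchors[[nm]])) {
      a <- anchors[[nm]]
      if (!identical(dim_of(w), dim_of(a))) stop("anchor shape mismatch for ", nm)
      tot <- tot + alpha / 2 * sum((w - a)^2)
    } else {
      tot <- tot + beta / 2 * sum(w^2)
    }
  }
  tot
}

#' Fuse two-stream logits into probabilities
#'
#' Late average fusion: `p = sigmoid((f_spatial + f_motion) / 2)`.
#'
#' @param spatial_logits,flow_logits T x K logit matrices.
#' @return T x K probability matrix in (0, 1).
#' @export
fuse_streams <- function(spatial_logits, flow_logits) {
  if (!identical(dim(spatial_logits), dim(flow_logits))) stop("shape mismatch")
  1 / (1 + exp(-(spatial_logits + flow_logits) / 2))
}

#' Adapt 3-channel input weights to more channels
#'
#' Replaces the input-channel dimension of a first-layer kernel by the mean
#' over the three source channels, replicated `n_target` times (used when a
#' frame-trained stem must consume a 20-channel flow stack).
#'
#' @param w kh x kw x 3 x cout weight array.
#' @param n_target Number of target input channels (default 20).
#' @return kh x kw x n_target x cout array.
#' @export
inflate_input_channels <- function(w, n_target = 20L) {
  d <- dim(w)
  if (length(d) != 4L || d[3] != 3L) stop("source kernel must have 3 input channels")
  m <- (w[, , 1, , drop = FALSE] + w[, , 2, , drop = FALSE] +
          w[, , 3, , drop = FALSE]) / 3
  out <- array(0, dim = c(d[1], d[2], n_target, d[4]))
  for (c in seq_len(n_target)) out[, , c, ] <- m[, , 1, ]
  out
}

# Resize the highest-resolution flows to the spatial input size for the flow
# stream (values rescaled to full-resolution pixel units).
flow_to_stream_input <- function(flow_half, size) {
  2 * cpp_resize_bilinear(flow_half, as.integer(size[1]), as.integer(size[2]))
}

# ---- architectures ----------------------------------------------------------

new_linear <- function(params, name, din, dout, gain = sqrt(2)) {
  params[[paste0(name, ".w")]] <- ag_param(init_linear_w(din, dout, gain))
  params[[paste0(name, ".b")]] <- ag_param(rep(0, dout))
  params
}

plinear <- function(model, name, x)
  ag_linear(x, model$params[[paste0(name, ".w")]],
            model$params[[paste0(name, ".b")]])

stream_params <- function(params, s, cin, preset) {
  pre <- function(nm) paste0(s, ".", nm)
  if (preset == "tiny") {
    params <- new_conv(params, pre("c1"), 3, 3, cin, 16)
    params <- new_conv(params, pre("c2"), 3, 3, 16, 32)
    params <- new_conv(params, pre("c3"), 3, 3, 32, 64)
    params <- new_conv(params, pre("c4"), 3, 3, 64, 128)
    params <- new_linear(params, pre("fc"), 128, 512)
  } else if (preset == "resnet18") {
    params <- new_conv(params, pre("stem1"), 7, 7, cin, 64)
    params <- new_conv(params, pre("stem2"), 3, 3, 64, 64)
    widths <- c(64, 128, 256, 512)
    cprev <- 64
    for (st in 1:4) for (b in 1:2) {
      nm <- sprintf("s%db%d", st, b)
      cin_b <- if (b == 1) cprev else widths[st]
      params <- new_conv(params, pre(paste0(nm, ".a")), 3, 3, cin_b, widths[st])
      params <- new_conv(params, pre(paste0(nm, ".b2")), 3, 3, widths[st], widths[st])
      if (b == 1 && cin_b != widths[st])
        params <- new_conv(params, pre(paste0(nm, ".sc")), 1, 1, cin_b, widths[st])
      if (b == 2) cprev <- widths[st]
    }
    params <- new_linear(params, pre("fc"), 512, 512)
  } else if (preset == "resnet50") {
    params <- new_conv(params, pre("stem1"), 7, 7, cin, 64)
    params <- new_conv(params, pre("stem2"), 3, 3, 64, 64)
    widths <- c(256, 512, 1024, 2048)
    nblocks <- c(3, 4, 6, 3)
    cprev <- 64
    for (st in 1:4) for (b in seq_len(nblocks[st])) {
      nm <- sprintf("s%db%d", st, b)
      mid <- widths[st] / 4
      cin_b <- if (b == 1) cprev else widths[st]
      params <- new_conv(params, pre(paste0(nm, ".a")), 1, 1, cin_b, mid)
      params <- new_conv(params, pre(paste0(nm, ".b2")), 3, 3, mid, mid)
      params <- new_conv(params, pre(paste0(nm, ".c")), 1, 1, mid, widths[st])
      if (b == 1) params <- new_conv(params, pre(paste0(nm, ".sc")), 1, 1, cin_b, widths[st])
      if (b == nblocks[st]) cprev <- widths[st]
    }
    params <- new_linear(params, pre("proj"), 2048, 512)
    params <- new_linear(params, pre("fc"), 512, 512)
  } else if (preset == "tiny3d") {
    params <- new_conv3d(params, pre("c1"), 3, 3, 3, cin, 16)
    params <- new_conv3d(params, pre("c2"), 3, 3, 3, 16, 32)
    params <- new_conv3d(params, pre("c3"), 3, 3, 3, 32, 64)
    params <- new_conv3d(params, pre("c4"), 3, 3, 3, 64, 128)
    params <- new_linear(params, pre("fc"), 128, 512)
  }
  params
}

#' Create a two-stream feature extractor
#'
#' Presets: `"tiny"` (small strided CNN for desk-scale training),
#' `"resnet18"`, `"resnet50"` (residual streams, normalization-free; resnet50
#' adds a 2048 -> 512 projection), `"tiny3d"` (3-D convolutions over all 11
#' frames). Every preset emits 512 features per stream plus K logits; dropout
#' (default 0.25) sits before the final readout.
#'
#' @param n_classes K, including the background class.
#' @param preset Architecture preset.
#' @param seed Weight-initialization seed.
#' @param bias_init Optional K-vector of output biases (from
#'   [init_classifier_bias()]), applied to both streams.
#' @param dropout Dropout probability before the readout.
#' @return A `feature_extractor` model object.
#' @export
feature_extractor <- function(n_classes,
                              preset = c("tiny", "resnet18", "resnet50", "tiny3d"),
                              seed = 1L, bias_init = NULL, dropout = 0.25) {
  preset <- match.arg(preset)
  set.seed(seed)
  params <- list()
  flow_cin <- if (preset == "tiny3d") 2L else 20L
  params <- stream_params(params, "sp", 3L, preset)
  params <- stream_params(params, "fl", flow_cin, preset)
  for (s in c("sp", "fl")) {
    params[[paste0(s, ".out.w")]] <- ag_param(init_linear_w(512, n_classes, 0.1))
    b <- if (is.null(bias_init)) rep(0, n_classes) else bias_init
    params[[paste0(s, ".out.b")]] <- ag_param(b)
  }
  new_names <- c("sp.out.w", "sp.out.b", "fl.out.w", "fl.out.b")
  structure(list(preset = preset, n_classes = n_classes, params = params,
                 dropout = dropout, new_params = new_names),
            class = "feature_extractor")
}

res_block <- function(model, pre, nm, x, stride, bottleneck = FALSE) {
  p <- function(s) paste0(pre, ".", nm, ".", s)
  sc <- x
  if (!is.null(model$params[[paste0(p("sc"), ".w")]]))
    sc <- pconv(model, p("sc"), x, stride, 0L)
  if (bottleneck) {
    h <- ag_relu(pconv(model, p("a"), x, stride, 0L))
    h <- ag_relu(pconv(model, p("b2"), h, 1L, 1L))
    h <- pconv(model, p("c"), h, 1L, 0L)
  } else {
    h <- ag_relu(pconv(model, p("a"), x, stride, 1L))
    h <- pconv(model, p("b2"), h, 1L, 1L)
  }
  ag_relu(ag_add(h, sc))
}

# One stream forward. x: (H, W, C, N) node (or (H, W, C, 11) for tiny3d).
stream_forward_ag <- function(model, s, x, train = FALSE) {
  pre <- function(nm) paste0(s, ".", nm)
  preset <- model$preset
  if (preset == "tiny") {
    h <- ag_leaky_relu(pconv(model, pre("c1"), x, 2L, 1L))
    h <- ag_leaky_relu(pconv(model, pre("c2"), h, 2L, 1L))
    h <- ag_leaky_relu(pconv(model, pre("c3"), h, 2L, 1L))
    h <- ag_leaky_relu(pconv(model, pre("c4"), h, 2L, 1L))
    g <- ag_global_avgpool(h)
    feat <- ag_relu(plinear(model, pre("fc"), g))
  } else if (preset %in% c("resnet18", "resnet50")) {
    h <- ag_relu(pconv(model, pre("stem1"), x, 2L, 3L))
    h <- ag_relu(pconv(model, pre("stem2"), h, 2L, 1L))
    bottleneck <- preset == "resnet50"
    nblocks <- if (bottleneck) c(3, 4, 6, 3) else rep(2L, 4)
    for (st in 1:4) for (b in seq_len(nblocks[st])) {
      stride <- if (b == 1 && st > 1) 2L else 1L
      h <- res_block(model, s, sprintf("s%db%d", st, b), h, stride, bottleneck)
    }
    g <- ag_global_avgpool(h)
    if (bottleneck) g <- ag_relu(plinear(model, pre("proj"), g))
    feat <- ag_relu(plinear(model, pre("fc"), g))
  } else { # tiny3d: time-major batch of one stack
    h <- ag_leaky_relu(ag_conv3d(model, pre("c1"), x, 2L, 1L, pad_t = TRUE))
    h <- ag_leaky_relu(ag_conv3d(model, pre("c2"), h, 2L, 1L, pad_t = TRUE))
    h <- ag_leaky_relu(ag_conv3d(model, pre("c3"), h, 2L, 1L, pad_t = TRUE))
    h <- ag_leaky_relu(ag_conv3d(model, pre("c4"), h, 2L, 1L, pad_t = TRUE))
    g <- ag_global_avgpool(h)  # T x 128
    Tn <- nrow(g$value)
    g <- ag_matmul(ag_const(matrix(1 / Tn, 1, Tn)), g)  # temporal mean
    feat <- ag_relu(plinear(model, pre("fc"), g))
  }
  fd <- ag_dropout(feat, model$dropout, train)
  logits <- plinear(model, pre("out"), fd)
  list(features = feat, logits = logits)
}

#' Two-stream forward pass for a batch of frame stacks
#'
#' Computes flows on the fly (hidden two-stream), feeds the center frame to
#' the spatial stream and the 10 highest-resolution flows (bilinearly
#' resized to the spatial input size) to the flow stream, and returns
#' per-frame features and per-stream logits. In eval mode
#' (`train = FALSE`, the default) the pass is deterministic.
#'
#' @param model A [feature_extractor()].
#' @param flow_model A [flow_generator()].
#' @param stacks List of H x W x 3 x 11 arrays (standardized frames).
#' @param train Enable dropout.
#' @return List with `spatial_features`, `flow_features` (N x 512),
#'   `spatial_logits`, `flow_logits` (N x K).
#' @export
two_stream_forward <- function(model, flow_model, stacks, train = FALSE) {
  if (!is.list(stacks)) stacks <- list(stacks)
  input <- stack_to_input(stacks)
  pyr <- flow_forward(flow_model, input)
  d <- dim(input)
  if (model$preset == "tiny3d") {
    # consume all 11 frames spatially and the 10 flows temporally; batch of 1
    stopifnot(length(stacks) == 1L)
    sp_in <- ag_const(stacks[[1]])
    fl <- flow_to_stream_input(pyr[[1]], d[1:2])
    dim(fl) <- c(d[1], d[2], 2L, 10L)
    fl_in <- ag_const(fl)
  } else {
    centers <- array(0, dim = c(d[1], d[2], 3, length(stacks)))
    for (n in seq_along(stacks)) centers[, , , n] <- stacks[[n]][, , , 6]
    sp_in <- ag_const(centers)
    fl_in <- ag_const(flow_to_stream_input(pyr[[1]], d[1:2]))
  }
  sp <- stream_forward_ag(model, "sp", sp_in, train)
  fl <- stream_forward_ag(model, "fl", fl_in, train)
  list(spatial_features = sp$features$value, flow_features = fl$features$value,
       spatial_logits = sp$logits$value, flow_logits = fl$logits$value)
}
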
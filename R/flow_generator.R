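# Optic-flow generator: encoder-decoder networks mapping 11 frames to 10
# two-channel displacement fields at 2-3 scales, trained with unsupervised
# reconstruction losses (Charbonnier pixel error, SSIM, flow smoothness,
# optional L1 flow sparsity).

#' Flow-generator loss configuration
#'
#' Defaults: Charbonnier `alpha = 0.4` (pixel) and `0.3` (smoothness) with
#' `eps = 1e-7`; weights `lambda0 = 1` (pixel), `lambda1 = 1` (SSIM),
#' `lambda2 = (0.01, 0.02, 0.04)` per scale largest to smallest, and
#' `lambda3 = 0.05` for the L1 flow sparsity used by the 3-D preset (which
#' also scales `lambda2` by 0.25).
#'
#' @param charbonnier_alpha_pixel,charbonnier_alpha_smooth,epsilon Charbonnier
#'   parameters.
#' @param lambda0,lambda1,lambda2,lambda3 Loss weights.
#' @param sparsity Enable the sparsity term (3-D preset).
#' @return Configuration list.
#' @export
flow_loss_config <- function(charbonnier_alpha_pixel = 0.4,
                             charbonnier_alpha_smooth = 0.3,
                             epsilon = 1e-7,
                             lambda0 = 1, lambda1 = 1,
                             lambda2 = c(0.01, 0.02, 0.04),
                             lambda3 = 0.05,
                             sparsity = FALSE) {
  l2 <- lambda2
  if (sparsity) l2 <- l2 * 0.25
  list(alpha_pixel = charbonnier_alpha_pixel,
       alpha_smooth = charbonnier_alpha_smooth,
       eps = epsilon, lambda0 = lambda0, lambda1 = lambda1,
       lambda2 = l2, lambda3 = lambda3, sparsity = sparsity)
}

#' Generalized Charbonnier penalty
#'
#' `rho(x) = (x^2 + eps^2)^alpha`, a robust differentiable surrogate for the
#' absolute error; `alpha = 0.5, eps = 0` recovers `|x|`.
#'
#' @param x Numeric input (any shape).
#' @param alpha Exponent.
#' @param eps Stabilizer (>= 0).
#' @return Elementwise penalty, same shape as `x`.
#' @export
charbonnier <- function(x, alpha = 0.4, eps = 1e-7) {
  stopifnot(eps >= 0)
  (x^2 + eps^2)^alpha
}

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Warp an image by a flow field
#'
#' Reconstructs the prior frame from the next frame and the displacement
#' field: `I0_hat(i, j) = I1(i + Vx(i,j), j + Vy(i,j))` by bilinear sampling
#' with border replication. Differentiable when used inside the training
#' graph.
#'
#' @param next_frame H x W (x C) image array.
#' @param flow H x W x 2 displacement field (channel 1 = x, channel 2 = y),
#'   in pixels.
#' @return Reconstructed image, same shape as `next_frame`.
#' @export
warp_with_flow <- function(next_frame, flow) {
  img <- as4d(next_frame)
  fl <- as4d(flow)
  if (!all(dim(img)[1:2] == dim(fl)[1:2]) || dim(fl)[3] != 2L)
    stop("flow must be H x W x 2 matching the image")
  out <- cpp_warp_fw(img, fl)
  dim(out) <- dim(next_frame)
  out
}

ssim_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

ag_ssim_loss <- function(x, y, data_range = 1, size = 11L, sigma = 1.5) {
  k <- ssim_kernel(size, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- ag_gauss_blur(x, k); my <- ag_gauss_blur(y, k)
  mx2 <- ag_square(mx); my2 <- ag_square(my)
  mxy <- ag_mul(mx, my)
  sx <- ag_sub(ag_gauss_blur(ag_square(x), k), mx2)
  sy <- ag_sub(ag_gauss_blur(ag_square(y), k), my2)
  sxy <- ag_sub(ag_gauss_blur(ag_mul(x, y), k), mxy)
  num <- ag_mul(ag_add_scalar(ag_scale(mxy, 2), c1),
                ag_add_scalar(ag_scale(sxy, 2), c2))
  den <- ag_mul(ag_add_scalar(ag_add(mx2, my2), c1),
                ag_add_scalar(ag_add(sx, sy), c2))
  ag_mean(ag_sub(ag_const(1), ag_div(num, den)))
}

#' Structural-similarity loss
#'
#' Mean of `1 - SSIM` with an 11 x 11 Gaussian window (`sigma = 1.5`) and the
#' standard stabilization constants on the declared dynamic range. Zero iff
#' the images are identical.
#'
#' @param i0,i0_hat Image arrays of identical shape.
#' @param data_range Dynamic range of the inputs (1 for 0-1 intensities).
#' @return Scalar loss in \[0, 2\].
#' @export
ssim_loss <- function(i0, i0_hat, data_range = 1) {
  if (!identical(dim(i0), dim(i0_hat))) stop("shape mismatch")
  ag_ssim_loss(ag_const(as4d(i0)), ag_const(as4d(i0_hat)), data_range)$value
}

ag_pixel_loss <- function(i0, i0_hat, cfg) {
  ag_mean(ag_charbonnier(ag_sub(i0_hat, i0), cfg$alpha_pixel, cfg$eps))
}

#' Charbonnier pixel reconstruction loss
#' @param i0 Original image array.
#' @param i0_hat Reconstruction (same shape).
#' @param cfg A [flow_loss_config()].
#' @return Scalar mean Charbonnier penalty of the residual.
#' @export
pixel_loss <- function(i0, i0_hat, cfg = flow_loss_config()) {
  if (!identical(dim(i0), dim(i0_hat))) stop("shape mismatch")
  ag_pixel_loss(ag_const(as4d(i0)), ag_const(as4d(i0_hat)), cfg)$value
}

ag_smoothness_loss <- function(flow, cfg) {
  # flow: (h, w, 2, N) node; Charbonnier of the four spatial gradients
  d <- dim(flow$value)
  gh <- ag_diff_h(flow)  # d/dy over rows
  gw <- ag_diff_w(flow)  # d/dx over cols
  t1 <- ag_mean(ag_charbonnier(gh, cfg$alpha_smooth, cfg$eps))
  t2 <- ag_mean(ag_charbonnier(gw, cfg$alpha_smooth, cfg$eps))
  ag_scale(ag_add(t1, t2), 0.5)
}

#' Flow smoothness loss
#'
#' Mean Charbonnier penalty (`alpha = 0.3`) of the x and y spatial gradients
#' of both flow channels; minimized by spatially constant flow.
#'
#' @param flow H x W x 2 (x N) flow array.
#' @param cfg A [flow_loss_config()].
#' @return Scalar loss.
#' @export
smoothness_loss <- function(flow, cfg = flow_loss_config()) {
  ag_smoothness_loss(ag_const(as4d(flow)), cfg)$value
}

#' Flow sparsity loss (mean absolute displacement)
#' @param flow Flow array.
#' @return Scalar `mean(|V|)`.
#' @export
sparsity_loss <- function(flow) mean(abs(flow))

# finite differences with gradients (rows / cols of 4-D arrays)
ag_diff_h <- function(x) {
  d <- dim(x$value)
  v <- x$value[2:d[1], , , , drop = FALSE] - x$value[1:(d[1] - 1), , , , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[2:d[1], , , ] <- gx[2:d[1], , , ] + g
    gx[1:(d[1] - 1), , , ] <- gx[1:(d[1] - 1), , , ] - g
    list(gx)
  })
}

ag_diff_w <- function(x) {
  d <- dim(x$value)
  v <- x$value[, 2:d[2], , , drop = FALSE] - x$value[, 1:(d[2] - 1), , , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, 2:d[2], , ] <- gx[, 2:d[2], , ] + g
    gx[, 1:(d[2] - 1), , ] <- gx[, 1:(d[2] - 1), , ] - g
    list(gx)
  })
}

# ---- architectures ----------------------------------------------------------

new_conv <- function(params, name, kh, kw, cin, cout, final = FALSE) {
  gain <- if (final) 0.1 else sqrt(2)
  params[[paste0(name, ".w")]] <- ag_param(init_conv_w(kh, kw, cin, cout, gain))
  params[[paste0(name, ".b")]] <- ag_param(rep(0, cout))
  params
}

pconv <- function(model, name, x, stride = 1L, pad = 1L) {
  ag_conv2d(x, model$params[[paste0(name, ".w")]],
            model$params[[paste0(name, ".b")]], stride, pad)
}

#' Create a flow-generator model
#'
#' Presets: `"nano"` (2 output scales, < 50k parameters: a small two-frame
#' flow net applied to each adjacent pair with shared weights, so pair flow
#' is independent of temporal context — robust for desk-scale training),
#' `"tiny"` (U-Net style, 3 scales, ~1.9M parameters),
#' `"medium"` (wider variant of tiny), `"tiny3d"` (3-D convolutions with
#' temporal kernels of 3 on encoder/decoder and 2 on the last encoder and
#' skip layers; 16/32/64 feature maps; trained with the extra sparsity loss).
#'
#' @param preset Architecture preset name.
#' @param seed Integer seed for weight initialization.
#' @return A `flow_generator` model object.
#' @export
flow_generator <- function(preset = c("nano", "tiny", "medium", "tiny3d"),
                           seed = 1L) {
  preset <- match.arg(preset)
  set.seed(seed)
  params <- list()
  if (preset == "nano") {
    # pairwise-shared U-Net: one small two-frame flow net applied to each of
    # the 10 adjacent pairs with shared weights, so a pair's flow cannot
    # depend on the surrounding temporal context
    params <- new_conv(params, "e1", 3, 3, 6, 12)
    params <- new_conv(params, "e2", 3, 3, 12, 24)
    params <- new_conv(params, "f4", 3, 3, 24, 2, final = TRUE)
    params <- new_conv(params, "d1", 3, 3, 38, 12)
    params <- new_conv(params, "f2", 3, 3, 12, 2, final = TRUE)
    n_scales <- 2L
  } else if (preset == "tiny") {
    params <- new_conv(params, "c1", 7, 7, 33, 64)
    params <- new_conv(params, "c2", 5, 5, 64, 128)
    params <- new_conv(params, "c3", 3, 3, 128, 256)
    params <- new_conv(params, "c4", 3, 3, 256, 256)
    params <- new_conv(params, "f8", 3, 3, 256, 20, final = TRUE)
    params <- new_conv(params, "u4", 3, 3, 256, 128)
    params <- new_conv(params, "i4", 3, 3, 404, 64)
    params <- new_conv(params, "f4", 3, 3, 64, 20, final = TRUE)
    params <- new_conv(params, "i2", 3, 3, 212, 32)
    params <- new_conv(params, "f2", 3, 3, 32, 20, final = TRUE)
    n_scales <- 3L
  } else if (preset == "medium") {
    params <- new_conv(params, "c1", 7, 7, 33, 96)
    params <- new_conv(params, "c2", 5, 5, 96, 192)
    params <- new_conv(params, "c3", 3, 3, 192, 384)
    params <- new_conv(params, "c3b", 3, 3, 384, 384)
    params <- new_conv(params, "c4", 3, 3, 384, 384)
    params <- new_conv(params, "f8", 3, 3, 384, 20, final = TRUE)
    params <- new_conv(params, "u4", 3, 3, 384, 192)
    params <- new_conv(params, "i4", 3, 3, 596, 96)
    params <- new_conv(params, "f4", 3, 3, 96, 20, final = TRUE)
    params <- new_conv(params, "i2", 3, 3, 308, 48)
    params <- new_conv(params, "f2", 3, 3, 48, 20, final = TRUE)
    n_scales <- 3L
  } else { # tiny3d
    params <- new_conv3d(params, "e1", 3, 3, 3, 3, 16)
    params <- new_conv3d(params, "e2", 3, 3, 3, 16, 32)
    params <- new_conv3d(params, "e3", 2, 3, 3, 32, 64)
    params <- new_conv(params, "f8", 3, 3, 64, 2, final = TRUE)
    params <- new_conv3d(params, "s4", 2, 3, 3, 32, 32)
    params <- new_conv(params, "i4", 3, 3, 98, 32)
    params <- new_conv(params, "f4", 3, 3, 32, 2, final = TRUE)
    params <- new_conv3d(params, "s2", 2, 3, 3, 16, 16)
    params <- new_conv(params, "i2", 3, 3, 50, 16)
    params <- new_conv(params, "f2", 3, 3, 16, 2, final = TRUE)
    n_scales <- 3L
  }
  structure(list(preset = preset, params = params, n_scales = n_scales),
            class = "flow_generator")
}

# 3-D conv kernels stored as one 5-D-like parameter: (kh, kw, cin, cout, kt)
new_conv3d <- function(params, name, kt, kh, kw, cin, cout) {
  for (dt in seq_len(kt))
    params <- new_conv(params, paste0(name, ".t", dt), kh, kw, cin, cout)
  # share a single bias: zero the per-slice biases except the first
  params[[paste0(name, ".kt")]] <- kt
  params
}

# x: (H, W, C, T) node treated as time-major batch. 'same' temporal padding
# when pad_t, otherwise T shrinks by kt - 1.
ag_conv3d <- function(model, name, x, stride = 1L, pad = 1L, pad_t = TRUE) {
  kt <- model$params[[paste0(name, ".kt")]]
  T_ <- dim(x$value)[4]
  if (pad_t) {
    r <- (kt - 1L) %/% 2L
    zdim <- dim(x$value); zdim[4] <- 1L
    z <- ag_const(array(0, dim = zdim))
    xs <- c(rep(list(z), r), list(x), rep(list(z), kt - 1L - r))
    x <- ag_concat_n(xs)
    T_ <- T_ + kt - 1L
  }
  To <- T_ - kt + 1L
  out <- NULL
  for (dt in seq_len(kt)) {
    sl <- ag_slice_n(x, dt:(dt + To - 1L))
    y <- pconv(model, paste0(name, ".t", dt), sl, stride, pad)
    out <- if (is.null(out)) y else ag_add(out, y)
  }
  out
}

# Concatenate 4-D nodes along the batch dimension.
ag_concat_n <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  ns <- vapply(vals, function(v) dim(v)[4], numeric(1))
  out <- array(0, dim = c(dim(vals[[1]])[1:3], sum(ns)))
  at <- 0
  for (v in vals) { out[, , , at + seq_len(dim(v)[4])] <- v; at <- at + dim(v)[4] }
  ag_op(out, xs, function(g) {
    at <- 0
    lapply(ns, function(n) {
      sl <- g[, , , at + seq_len(n), drop = FALSE]
      at <<- at + n
      sl
    })
  })
}

#' Count trainable parameters of a model
#' @param model Any model object of this package (holds `params`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p)
    if (inherits(p, "ag_node")) length(p$value) else 0L, numeric(1)))
}

# stack node x: (H, W, 33, N). Returns list of flow nodes largest->smallest.
flow_forward_ag <- function(model, x) {
  p <- model$preset
  if (p == "nano") {
    # rebatch the 11-frame stacks as 10 N adjacent pairs (6 channels each)
    d <- dim(x$value)
    N <- d[4]
    pairs <- array(0, dim = c(d[1], d[2], 6L, 10L * N))
    for (n in seq_len(N)) for (t in 1:10)
      pairs[, , , t + 10 * (n - 1)] <-
        x$value[, , (3 * (t - 1) + 1):(3 * t + 3), n]
    xp <- ag_const(pairs)
    e1 <- ag_leaky_relu(pconv(model, "e1", xp, 2L, 1L))
    e2 <- ag_leaky_relu(pconv(model, "e2", e1, 2L, 1L))
    f4 <- pconv(model, "f4", e2, 1L, 1L)
    u <- ag_upsample2x(e2)
    fu <- ag_upsample2x(f4, gain = 2)
    d1 <- ag_leaky_relu(pconv(model, "d1", ag_concat_c(list(e1, u, fu)), 1L, 1L))
    f2 <- ag_add(pconv(model, "f2", d1, 1L, 1L), fu)
    # (h, w, 2, 10 N) pair-major batches reshape to (h, w, 20, N) pyramids
    lapply(list(f2, f4), function(f) {
      df <- dim(f$value)
      ag_reshape(f, c(df[1], df[2], 20L, N))
    })
  } else if (p %in% c("tiny", "medium")) {
    c1 <- ag_leaky_relu(pconv(model, "c1", x, 1L, 3L))
    c2 <- ag_leaky_relu(pconv(model, "c2", c1, 2L, 2L))
    c3 <- ag_leaky_relu(pconv(model, "c3", c2, 2L, 1L))
    if (p == "medium") c3 <- ag_leaky_relu(pconv(model, "c3b", c3, 1L, 1L))
    c4 <- ag_leaky_relu(pconv(model, "c4", c3, 2L, 1L))
    f8 <- pconv(model, "f8", c4, 1L, 1L)
    u4 <- ag_leaky_relu(pconv(model, "u4", ag_upsample2x(c4), 1L, 1L))
    fu8 <- ag_upsample2x(f8, gain = 2)
    i4 <- ag_leaky_relu(pconv(model, "i4", ag_concat_c(list(c3, u4, fu8)), 1L, 1L))
    f4 <- ag_add(pconv(model, "f4", i4, 1L, 1L), fu8)
    fu4 <- ag_upsample2x(f4, gain = 2)
    i2 <- ag_leaky_relu(pconv(model, "i2", ag_concat_c(list(c2, ag_upsample2x(i4), fu4)), 1L, 1L))
    f2 <- ag_add(pconv(model, "f2", i2, 1L, 1L), fu4)
    list(f2, f4, f8)
  } else { # tiny3d: x must be (H, W, 3, 11), batch of one stack
    e1 <- ag_leaky_relu(ag_conv3d(model, "e1", x, 2L, 1L, pad_t = TRUE))
    e2 <- ag_leaky_relu(ag_conv3d(model, "e2", e1, 2L, 1L, pad_t = TRUE))
    e3 <- ag_leaky_relu(ag_conv3d(model, "e3", e2, 2L, 1L, pad_t = FALSE))  # T = 10
    f8 <- pconv(model, "f8", e3, 1L, 1L)                                    # (h8, w8, 2, 10)
    s4 <- ag_leaky_relu(ag_conv3d(model, "s4", e2, 1L, 1L, pad_t = FALSE))
    u4 <- ag_upsample2x(e3)
    fu8 <- ag_upsample2x(f8, gain = 2)
    i4 <- ag_leaky_relu(pconv(model, "i4", ag_concat_c(list(s4, u4, fu8)), 1L, 1L))
    f4 <- ag_add(pconv(model, "f4", i4, 1L, 1L), fu8)
    s2 <- ag_leaky_relu(ag_conv3d(model, "s2", e1, 1L, 1L, pad_t = FALSE))
    fu4 <- ag_upsample2x(f4, gain = 2)
    i2 <- ag_leaky_relu(pconv(model, "i2", ag_concat_c(list(s2, ag_upsample2x(i4), fu4)), 1L, 1L))
    f2 <- ag_add(pconv(model, "f2", i2, 1L, 1L), fu4)
    # reorder (h, w, 2, 10) -> (h, w, 20, 1); channel-within-time layout matches
    lapply(list(f2, f4, f8), function(f)
      ag_reshape(f, c(dim(f$value)[1:2], 20L, 1L)))
  }
}

# Accept (H, W, 3, 11) stacks (single or list) and produce the channel-
# concatenated (H, W, 33, N) input array.
stack_to_input <- function(stacks) {
  if (!is.list(stacks)) stacks <- list(stacks)
  d <- dim(stacks[[1]])
  stopifnot(length(d) == 4L, d[4] == 11L)
  out <- array(0, dim = c(d[1], d[2], 33L, length(stacks)))
  for (n in seq_along(stacks)) {
    s <- stacks[[n]]
    for (t in 1:11) out[, , (3 * (t - 1) + 1):(3 * t), n] <- s[, , , t]
  }
  out
}

#' Run the flow generator on an 11-frame stack
#'
#' @param model A [flow_generator()].
#' @param stack H x W x 3 x 11 array (one stack), a list of such stacks, or a
#'   pre-concatenated H x W x 33 x N array.
#' @return `flow_pyramid`: list of flow arrays, largest scale first, each
#'   h x w x 20 x N (10 fields x 2 channels; channel 2(t-1)+1 is the x
#'   displacement of field t), in pixels at that scale.
#' @export
flow_forward <- function(model, stack) {
  if (model$preset == "tiny3d") {
    stopifnot(length(dim(stack)) == 4L, dim(stack)[4] == 11L)
    x <- ag_const(stack)
  } else {
    if (is.list(stack) || dim(stack)[3] != 33L) stack <- stack_to_input(stack)
    x <- ag_const(stack)
  }
  structure(lapply(flow_forward_ag(model, x), function(f) f$value),
            class = "flow_pyramid")
}

# Multi-scale targets: list over scales of list(i0 = (h, w, 3, 10N), i1 = ...)
# time-major within sample to match the flow reshape (h, w, 2, 10N).
multiscale_targets <- function(input, n_scales) {
  d <- dim(input)  # (H, W, 33, N)
  N <- d[4]
  i0 <- array(0, dim = c(d[1], d[2], 3, 10 * N))
  i1 <- array(0, dim = c(d[1], d[2], 3, 10 * N))
  for (n in seq_len(N)) for (t in 1:10) {
    i0[, , , t + 10 * (n - 1)] <- input[, , (3 * (t - 1) + 1):(3 * t), n]
    i1[, , , t + 10 * (n - 1)] <- input[, , (3 * t + 1):(3 * t + 3), n]
  }
  out <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    i0 <- cpp_avgpool2(i0); i1 <- cpp_avgpool2(i1)
    out[[s]] <- list(i0 = i0, i1 = i1)
  }
  out
}

#' Total flow-generator training loss
#'
#' Weighted sum of per-scale pixel (Charbonnier) and SSIM reconstruction
#' losses of the warped next frame against the current frame, per-scale
#' smoothness, and (for the 3-D preset) L1 flow sparsity. L2-SP style
#' regularization is added by the training engine, not here.
#'
#' @param model A [flow_generator()].
#' @param stacks Input stacks (see [flow_forward()]).
#' @param cfg A [flow_loss_config()].
#' @return List with `loss` (scalar autodiff node) and `components` (named
#'   numeric vector of unweighted parts for logging).
#' @export
flow_total_loss <- function(model, stacks, cfg = flow_loss_config()) {
  if (model$preset == "tiny3d") {
    input3d <- if (is.list(stacks)) stacks[[1]] else stacks
    x <- ag_const(input3d)
    # build a (H, W, 33, 1) view for target construction
    input <- stack_to_input(list(input3d))
  } else {
    if (is.list(stacks) || dim(stacks)[3] != 33L) stacks <- stack_to_input(stacks)
    input <- stacks
    x <- ag_const(input)
  }
  flows <- flow_forward_ag(model, x)
  targets <- multiscale_targets(input, length(flows))
  N <- dim(input)[4]
  total <- NULL
  comp <- c(pixel = 0, ssim = 0, smooth = 0, sparsity = 0)
  for (s in seq_along(flows)) {
    f <- flows[[s]]
    d <- dim(f$value)
    fp <- ag_reshape(f, c(d[1], d[2], 2L, 10L * N))
    warped <- ag_warp(ag_const(targets[[s]]$i1), fp)
    lp <- ag_pixel_loss(ag_const(targets[[s]]$i0), warped, cfg)
    ls <- ag_ssim_loss(ag_const(targets[[s]]$i0), warped)
    lsm <- ag_smoothness_loss(fp, cfg)
    comp["pixel"] <- comp["pixel"] + lp$value
    comp["ssim"] <- comp["ssim"] + ls$value
    comp["smooth"] <- comp["smooth"] + lsm$value
    term <- ag_add(ag_add(ag_scale(lp, cfg$lambda0), ag_scale(ls, cfg$lambda1)),
                   ag_scale(lsm, cfg$lambda2[min(s, length(cfg$lambda2))]))
    if (cfg$sparsity) {
      lsp <- ag_mean(ag_abs(fp))
      comp["sparsity"] <- comp["sparsity"] + lsp$value
      term <- ag_add(term, ag_scale(lsp, cfg$lambda3))
    }
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  list(loss = total, components = comp)
}
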
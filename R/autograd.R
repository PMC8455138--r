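# Minimal reverse-mode automatic differentiation engine.
#
# Nodes are environments holding `value` (numeric array/matrix/scalar), `grad`,
# `parents` (list of nodes) and `backward` (function mapping the node's grad to
# a list of parent grads, NULL entries for parents that need no gradient).
# A global monotone id gives a valid reverse topological order for free.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

ag_node <- function(value, parents = list(), backward = NULL, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$req <- req
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) {
  n <- ag_node(value, req = TRUE)
  n$is_param <- TRUE
  n
}

ag_const <- function(value) ag_node(value, req = FALSE)

as_ag <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

ag_op <- function(value, parents, backward) {
  req <- any(vapply(parents, function(p) isTRUE(p$req), logical(1)))
  ag_node(value, parents = parents, backward = if (req) backward else NULL, req = req)
}

# Reverse pass from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # collect reachable nodes (iterative DFS)
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    if (isTRUE(n$req)) for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  loss$grad <- 1
  for (n in nodes[ord]) {
    if (is.null(n$backward) || is.null(n$grad)) next
    grads <- n$backward(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      g <- grads[[i]]
      if (is.null(g) || !isTRUE(p$req)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value * b$value, list(a, b),
        function(g) list(g * b$value, g * a$value))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  v <- a$value / b$value
  ag_op(v, list(a, b),
        function(g) list(g / b$value, -g * v / b$value))
}

ag_scale <- function(x, s) {
  ag_op(x$value * s, list(x), function(g) list(g * s))
}

ag_add_scalar <- function(x, s) {
  ag_op(x$value + s, list(x), function(g) list(g))
}

ag_neg <- function(x) ag_scale(x, -1)

ag_square <- function(x) ag_op(x$value^2, list(x), function(g) list(2 * g * x$value))

ag_exp <- function(x) {
  v <- exp(x$value)
  ag_op(v, list(x), function(g) list(g * v))
}

ag_log <- function(x) ag_op(log(x$value), list(x), function(g) list(g / x$value))

ag_abs <- function(x) ag_op(abs(x$value), list(x), function(g) list(g * sign(x$value)))

ag_relu <- function(x) {
  m <- x$value > 0
  ag_op(x$value * m, list(x), function(g) list(g * m))
}

ag_leaky_relu <- function(x, slope = 0.1) {
  m <- slope + (1 - slope) * (x$value > 0)
  ag_op(x$value * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  ag_op(v, list(x), function(g) list(g * v * (1 - v)))
}

# Generalized Charbonnier penalty rho(x) = (x^2 + eps^2)^alpha, elementwise.
ag_charbonnier <- function(x, alpha, eps) {
  base <- x$value^2 + eps^2
  ag_op(base^alpha, list(x),
        function(g) list(g * alpha * base^(alpha - 1) * 2 * x$value))
}

ag_dropout <- function(x, p, train = TRUE) {
  if (!train || p <= 0) return(x)
  mask <- array((stats::runif(length(x$value)) > p) / (1 - p), dim = dim_of(x$value))
  ag_op(x$value * mask, list(x), function(g) list(g * mask))
}

dim_of <- function(v) if (is.null(dim(v))) length(v) else dim(v)

# ---- reductions -------------------------------------------------------------

ag_mean <- function(x) {
  n <- length(x$value)
  ag_op(mean(x$value), list(x),
        function(g) list(array(g / n, dim = dim_of(x$value))))
}

ag_sum <- function(x) {
  ag_op(sum(x$value), list(x),
        function(g) list(array(g, dim = dim_of(x$value))))
}

# ---- shape ops --------------------------------------------------------------

ag_reshape <- function(x, newdim) {
  olddim <- dim_of(x$value)
  v <- x$value
  dim(v) <- newdim
  ag_op(v, list(x), function(g) { dim(g) <- olddim; list(g) })
}

# Concatenate 4-D arrays along the channel dimension.
ag_concat_c <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  ag_op(out, xs, function(g) {
    at <- 0
    lapply(cs, function(nc) {
      sl <- g[, , at + seq_len(nc), , drop = FALSE]
      at <<- at + nc
      sl
    })
  })
}

# Select along the batch (4th) dimension.
ag_slice_n <- function(x, idx) {
  v <- x$value[, , , idx, drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, dim = dim(x$value))
    for (i in seq_along(idx)) gx[, , , idx[i]] <- gx[, , , idx[i]] + g[, , , i]
    list(gx)
  })
}

# ---- linear algebra ---------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value %*% b$value, list(a, b),
        function(g) list(g %*% t(b$value), t(a$value) %*% g))
}

# x: N x D, w: D x M, b: length M
ag_linear <- function(x, w, b) {
  v <- sweep(x$value %*% w$value, 2, b$value, "+")
  ag_op(v, list(x, w, b), function(g)
    list(g %*% t(w$value), t(x$value) %*% g, colSums(g)))
}

ag_softmax_rows <- function(x) {
  m <- x$value - apply(x$value, 1, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ag_op(v, list(x), function(g) {
    dot <- rowSums(g * v)
    list(v * (g - dot))
  })
}

# Normalize each row to sum to one (for temporal mixture kernels).
ag_normalize_rows <- function(x) {
  rs <- rowSums(x$value)
  v <- x$value / rs
  ag_op(v, list(x), function(g) {
    list(g / rs - rowSums(g * x$value) / rs^2)
  })
}

# ---- image / conv ops -------------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  pad <- as.integer(pad)
  if (length(pad) == 1L) pad <- c(pad, pad)
  v <- cpp_conv2d_fw(x$value, w$value, b$value, as.integer(stride), pad[1], pad[2])
  ag_op(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(x$value, w$value, g, as.integer(stride), pad[1], pad[2])
    list(r$gx, r$gw, r$gb)
  })
}

# Temporal convolution along dim 2 of a (D, T, C, N) tensor ('same' zero
# padding); kernel (L, Cin, Cout).
ag_tconv <- function(x, k, b) {
  v <- cpp_tconv_fw(x$value, k$value, b$value)
  ag_op(v, list(x, k, b), function(g) {
    r <- cpp_tconv_bw(x$value, k$value, g)
    list(r$gx, r$gk, r$gb)
  })
}

ag_transpose <- function(x) {
  ag_op(t(x$value), list(x), function(g) list(t(g)))
}

# Bilinear 2x upsampling; `gain` multiplies activations (flow fields use
# gain = 2 so displacement stays in pixels of the finer scale).
ag_upsample2x <- function(x, gain = 1) {
  d <- dim(x$value)
  v <- cpp_resize_bilinear(x$value, 2L * d[1], 2L * d[2])
  if (gain != 1) v <- v * gain
  ag_op(v, list(x), function(g)
    list(cpp_resize_bilinear_bw(g * gain, d[1], d[2])))
}

ag_warp <- function(img, flow) {
  img <- as_ag(img); flow <- as_ag(flow)
  v <- cpp_warp_fw(img$value, flow$value)
  ag_op(v, list(img, flow), function(g) {
    r <- cpp_warp_bw(img$value, flow$value, g)
    list(r$gimg, r$gflow)
  })
}

ag_gauss_blur <- function(x, kernel) {
  ag_op(cpp_gauss_blur(x$value, kernel), list(x),
        function(g) list(cpp_gauss_blur(g, kernel)))
}

# Global average pool: (H, W, C, N) -> N x C matrix.
ag_global_avgpool <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, nrow = d[1] * d[2])  # (H*W) x (C*N)
  v <- matrix(colMeans(m), nrow = d[3], ncol = d[4])  # C x N
  ag_op(t(v), list(x), function(g) {
    # g: N x C
    gx <- array(0, dim = d)
    per <- t(g) / (d[1] * d[2])  # C x N
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      gx[, , c, n] <- per[c, n]
    list(gx)
  })
}

# ---- optimizer --------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / corr1
    vhat <- opt$v[[i]] / corr2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# Kaiming-style initialization for conv / linear weights.
init_conv_w <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = gain / sqrt(fan_in)),
        dim = c(kh, kw, cin, cout))
}

init_linear_w <- function(din, dout, gain = sqrt(2)) {
  matrix(stats::rnorm(din * dout, sd = gain / sqrt(din)), nrow = din)
}
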
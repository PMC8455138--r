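test_that("charbonnier penalty has the stated closed forms", {
  expect_equal(charbonnier(0, 0.4, 1e-3), (1e-3)^0.8)
  expect_equal(charbonnier(c(-2, 2), 0.5, 0), c(2, 2))  # reduces to |x|
  expect_equal(charbonnier(3, 0.4, 1e-7), 9^0.4, tolerance = 1e-10)
  x <- seq(0, 3, by = 0.5)
  expect_true(all(diff(charbonnier(x, 0.4, 1e-7)) > 0))  # monotone in |x|
})

test_that("warping reconstructs shifted and ramp images exactly in the interior", {
  set.seed(41)
  H <- 12; W <- 14
  i0 <- matrix(runif(H * W), H, W)
  # zero flow is the identity everywhere
  fl0 <- array(0, c(H, W, 2))
  expect_equal(warp_with_flow(i0, fl0), i0)
  # integer shift: I1 = I0 shifted +1 px in x; flow Vx = +1 recovers I0
  i1 <- cbind(i0[, 1], i0[, -W])
  fl1 <- array(0, c(H, W, 2)); fl1[, , 1] <- 1
  rec <- warp_with_flow(i1, fl1)
  expect_equal(rec[, 1:(W - 1)], i0[, 1:(W - 1)])
  # ramp image, half-pixel flow: bilinear closed form j + 0.5
  ramp <- matrix(rep(seq_len(W), each = H), H, W)
  flh <- array(0, c(H, W, 2)); flh[, , 1] <- 0.5
  out <- warp_with_flow(ramp, flh)
  expect_equal(out[, 1:(W - 1)], ramp[, 1:(W - 1)] + 0.5)
  expect_error(warp_with_flow(i0, array(0, c(H, W + 1, 2))), "flow")
})

test_that("pixel, SSIM, smoothness and sparsity losses attain their stated values", {
  set.seed(42)
  a <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_lt(pixel_loss(a, a), 1e-5)  # (eps^2)^0.4 floor
  expect_equal(pixel_loss(a, a + 1), 1, tolerance = 1e-5)
  # permutation invariance of the mean
  d <- array(rnorm(24 * 24 * 3), c(24, 24, 3))
  perm <- array(sample(d), dim(d))
  expect_equal(pixel_loss(a, a + d), pixel_loss(a, a + perm), tolerance = 1e-12)

  expect_equal(ssim_loss(a, a), 0, tolerance = 1e-10)
  b <- array(runif(64 * 64), c(64, 64, 1))
  c2 <- array(runif(64 * 64), c(64, 64, 1))
  expect_equal(ssim_loss(b, c2), ssim_loss(c2, b))
  expect_equal(ssim_loss(b, c2), 1, tolerance = 0.2)  # independent noise

  flc <- array(2, c(10, 10, 2))
  expect_lt(smoothness_loss(flc), 1e-3)     # constant flow
  ramp_fl <- array(0, c(10, 10, 2))
  ramp_fl[, , 1] <- matrix(rep(seq_len(10), each = 10), 10, 10)  # unit x-grad
  expect_equal(smoothness_loss(ramp_fl), 0.25, tolerance = 1e-3)
  expect_equal(smoothness_loss(ramp_fl + 5), smoothness_loss(ramp_fl))

  expect_equal(sparsity_loss(array(0, c(4, 4, 2))), 0)
  expect_equal(sparsity_loss(array(2, c(4, 4, 2))), 2)
  v <- array(rnorm(32), c(4, 4, 2))
  expect_equal(sparsity_loss(3 * v), 3 * sparsity_loss(v))
})

test_that("flow pyramids have the documented scales, counts and upsampling gain", {
  set.seed(43)
  st <- array(runif(64 * 64 * 3 * 11), c(64, 64, 3, 11))
  tm <- flow_generator("tiny", seed = 1)
  pyr <- flow_forward(tm, st)
  expect_length(pyr, 3)
  expect_equal(dim(pyr[[1]]), c(32, 32, 20, 1))
  expect_equal(dim(pyr[[2]]), c(16, 16, 20, 1))
  expect_equal(dim(pyr[[3]]), c(8, 8, 20, 1))
  # parameter count within 10% of 1.9M
  expect_lt(abs(count_parameters(tm) - 1.9e6) / 1.9e6, 0.10)
  # 2x upsampling doubles constant activations
  ones <- ethoflow:::ag_const(array(1, c(8, 8, 2, 1)))
  up <- ethoflow:::ag_upsample2x(ones, gain = 2)
  expect_equal(unique(as.vector(up$value)), 2)
  # nano preset is CI-sized with 2 scales
  nm <- flow_generator("nano", seed = 1)
  expect_lt(count_parameters(nm), 5e4)
  expect_length(flow_forward(nm, st), 2)
  # 3-D preset produces the same pyramid shapes
  t3 <- flow_generator("tiny3d", seed = 1)
  p3 <- flow_forward(t3, st)
  expect_equal(dim(p3[[1]]), c(32, 32, 20, 1))
  expect_error(flow_forward(nm, st[, , , 1:9]))
})

test_that("flows stay continuous floats end to end", {
  set.seed(44)
  st <- array(runif(32 * 32 * 3 * 11), c(32, 32, 3, 11))
  pyr <- flow_forward(flow_generator("nano", seed = 2), st)
  expect_type(pyr[[1]], "double")
  # values are not quantized to integer levels
  expect_gt(length(unique(as.vector(pyr[[1]]))), 1000)
})

test_that("injecting the true flow for a pure translation drives the pixel loss to its floor", {
  set.seed(45)
  base <- matrix(runif(32 * 32), 32, 32)
  i0 <- base
  i1 <- cbind(base[, 1], base[, -32])  # shift +1 px in x
  fl <- array(0, c(32, 32, 2)); fl[, , 1] <- 1
  rec <- warp_with_flow(i1, fl)
  expect_lt(pixel_loss(i0[, 2:31], rec[, 2:31]), 1e-5)
  expect_lt(smoothness_loss(fl), 1e-3)
})

test_that("total loss reduces to the pixel term when other weights vanish", {
  set.seed(46)
  st <- array(runif(32 * 32 * 3 * 11), c(32, 32, 3, 11))
  fm <- flow_generator("nano", seed = 3)
  cfg0 <- flow_loss_config(lambda1 = 0, lambda2 = c(0, 0, 0))
  tl <- flow_total_loss(fm, st, cfg0)
  expect_equal(tl$loss$value, unname(tl$components["pixel"]), tolerance = 1e-12)
  # loss is non-negative and finite for the full configuration
  tl2 <- flow_total_loss(fm, st)
  expect_gte(tl2$loss$value, 0)
})

test_that("short training on synthetic locomotion improves reconstruction and recovers the velocity", {
  tr <- trained_nano_flow()
  # validation pixel loss at least halved from initialization
  expect_lt(tr$val_pixel_final, 0.5 * tr$val_pixel_init)
  # mean flow magnitude over the agent's support within 30% of the true
  # velocity (2 px/frame full-res = 1 px at the half-res output)
  frames <- locomotion_frames()
  mags <- sapply(c(100, 200, 250), function(tt) {
    st <- frame_stack(frames, tt)
    pyr <- flow_forward(tr$model, st)
    i0 <- ethoflow:::cpp_avgpool2(st)[, , 1, 5]
    supp <- i0 > stats::quantile(i0, 0.9)
    mean(sapply(1:10, function(p) {
      f <- pyr[[1]]
      mean(sqrt(f[, , 2 * p - 1, 1]^2 + f[, , 2 * p, 1]^2)[supp])
    }))
  })
  expect_lt(abs(mean(mags) - 1), 0.30)
})
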
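# The reverse-mode tape: every operator's analytic gradient is checked
# against central finite differences, and the composed cascade gradient is
# checked end-to-end.

fd_max_err <- function(loss_fn, x, gx, eps = 1e-6, n_probe = 10, seed = 1) {
  set.seed(seed)
  idx <- sample(length(x), min(n_probe, length(x)))
  max(abs(vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (loss_fn(xp) - loss_fn(xm)) / (2 * eps) - gx[i]
  }, 0)))
}

test_that("convolution and pooling kernels backpropagate exactly", {
  set.seed(10)
  h <- 6; w <- 5; ci <- 3; co <- 2; d <- 4
  x <- array(rnorm(h * w * ci), c(h, w, ci))
  wt <- array(rnorm(9 * ci * co) * 0.3, c(3, 3, ci, co))
  b <- rnorm(co)
  tgt <- array(rnorm(h * w * co), c(h, w, co))
  g <- cinerecon:::cpp_conv2d_bwd(x, wt, cinerecon:::cpp_conv2d_fwd(x, wt, b) - tgt)
  expect_lt(fd_max_err(function(xx)
    sum((cinerecon:::cpp_conv2d_fwd(xx, wt, b) - tgt)^2) / 2, x, g$gx), 1e-6)
  expect_lt(fd_max_err(function(ww)
    sum((cinerecon:::cpp_conv2d_fwd(x, ww, b) - tgt)^2) / 2, wt, g$gw), 1e-6)

  x3 <- array(rnorm(h * w * d * ci), c(h, w, d, ci))
  w3 <- array(rnorm(27 * ci * co) * 0.2, c(3, 3, 3, ci, co))
  t3 <- array(rnorm(h * w * d * co), c(h, w, d, co))
  g3 <- cinerecon:::cpp_conv3d_bwd(x3, w3,
                                   cinerecon:::cpp_conv3d_fwd(x3, w3, b) - t3)
  expect_lt(fd_max_err(function(xx)
    sum((cinerecon:::cpp_conv3d_fwd(xx, w3, b) - t3)^2) / 2, x3, g3$gx), 1e-6)
  expect_lt(fd_max_err(function(ww)
    sum((cinerecon:::cpp_conv3d_fwd(x3, ww, b) - t3)^2) / 2, w3, g3$gw), 1e-6)

  xp <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  r <- cinerecon:::cpp_maxpool2d_fwd(xp)
  tp <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  gp <- cinerecon:::cpp_maxpool_bwd(r$idx, r$out - tp, length(xp))
  expect_lt(fd_max_err(function(xx) {
    rr <- cinerecon:::cpp_maxpool2d_fwd(xx)
    sum((rr$out - tp)^2) / 2
  }, xp, gp, eps = 1e-7), 1e-5)
})

test_that("transposed convolutions backpropagate exactly", {
  set.seed(11)
  ci <- 3; co <- 2; b <- rnorm(co)
  xu <- array(rnorm(3 * 4 * ci), c(3, 4, ci))
  wu <- array(rnorm(4 * ci * co) * 0.3, c(2, 2, ci, co))
  tu <- array(rnorm(6 * 8 * co), c(6, 8, co))
  gu <- cinerecon:::cpp_upconv2d_bwd(xu, wu,
                                     cinerecon:::cpp_upconv2d_fwd(xu, wu, b) - tu)
  expect_lt(fd_max_err(function(xx)
    sum((cinerecon:::cpp_upconv2d_fwd(xx, wu, b) - tu)^2) / 2, xu, gu$gx), 1e-6)
  expect_lt(fd_max_err(function(ww)
    sum((cinerecon:::cpp_upconv2d_fwd(xu, ww, b) - tu)^2) / 2, wu, gu$gw), 1e-6)
  d <- 3
  xu3 <- array(rnorm(3 * 4 * d * ci), c(3, 4, d, ci))
  tu3 <- array(rnorm(6 * 8 * d * co), c(6, 8, d, co))
  gu3 <- cinerecon:::cpp_upconv3d_bwd(xu3, wu,
                                      cinerecon:::cpp_upconv3d_fwd(xu3, wu, b) - tu3)
  expect_lt(fd_max_err(function(xx)
    sum((cinerecon:::cpp_upconv3d_fwd(xx, wu, b) - tu3)^2) / 2, xu3, gu3$gx),
    1e-6)
})

test_that("bilinear warping backpropagates in both arguments", {
  set.seed(12)
  img <- array(rnorm(8 * 7 * 2), c(8, 7, 2))
  disp <- array(rnorm(8 * 7 * 2) * 0.7, c(8, 7, 2))
  tgt <- array(rnorm(8 * 7 * 2), c(8, 7, 2))
  g <- cinerecon:::cpp_warp_bwd(img, disp,
                                cinerecon:::cpp_warp_fwd(img, disp) - tgt)
  expect_lt(fd_max_err(function(ii)
    sum((cinerecon:::cpp_warp_fwd(ii, disp) - tgt)^2) / 2, img, g$gimg), 1e-6)
  expect_lt(fd_max_err(function(dd)
    sum((cinerecon:::cpp_warp_fwd(img, dd) - tgt)^2) / 2, disp, g$gdisp), 1e-6)
})

test_that("the composed cascade gradient matches finite differences", {
  # exact check: use the double-precision reference convolution path
  old <- options(cinerecon.conv_precision = "double")
  on.exit(options(old))
  ph <- tiny_phantom(seed = 13)
  acq <- acquire(ph$sequence, accel = 2, seed = 14)
  cfg <- train_config(accelerations = 2, seed = 1)
  model <- tiny_model(n_frames = 4, iterations = 2, zero_init = FALSE,
                      seed = 15)
  r <- cinerecon:::grd_loss_and_grads(model, ph$sequence$frames,
                                      acq$kspace$spectra, acq$mask$masks, cfg)
  flat <- cinerecon:::model_flat_params(model)
  for (nm in c("grn.enc.1.w", "grn.final.w", "rec.final.w", "rec.dec.1.up.w")) {
    err <- fd_max_err(function(pp) {
      f2 <- flat; f2[[nm]] <- array(pp, dim = dim(flat[[nm]]))
      m2 <- cinerecon:::model_set_flat(model, f2)
      cinerecon:::grd_loss_and_grads(m2, ph$sequence$frames,
                                     acq$kspace$spectra, acq$mask$masks,
                                     cfg)$loss
    }, flat[[nm]], r$grads[[nm]], eps = 1e-5, n_probe = 3, seed = 16)
    expect_lt(err, 1e-6)
  }
})
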
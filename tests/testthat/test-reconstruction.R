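# Motion-augmented generation, residual dealiasing, and the unrolled cascade.

test_that("motion augmentation enforces data consistency around the template", {
  ph <- tiny_phantom(seed = 21)
  s <- ph$sequence
  kfull <- sequence_to_kspace(s)
  tmpl <- abs(s$frames[, , 1])
  zdisp <- array(0, c(16, 16, 2, 4))
  # all-ones masks: DC replaces everything -> G_n = inverse FFT of acquired
  ones <- sampling_mask(array(1, c(16, 16, 4)), 1)
  g <- motion_augment(tmpl, zdisp, kfull, ones)
  for (f in 1:4)
    expect_lt(max(abs(g[, , f] - inverse_fft(kfull$spectra[, , f]))), 1e-10)
  # all-zero masks: nothing acquired -> G_n is the lifted template
  zeros <- sampling_mask(array(0, c(16, 16, 4)), Inf)
  kz <- kspace_sequence(array(0 + 0i, c(16, 16, 4)), TRUE)
  gz <- motion_augment(tmpl, zdisp, kz, zeros)
  for (f in 1:4) expect_lt(max(abs(gz[, , f] - tmpl)), 1e-10)
  # half-sampled masks with +/-1 px translations: on-support spectra equal
  # the acquired data, off-support equal the warped template's
  disp <- zdisp; disp[, , 2, 1] <- 1; disp[, , 2, 2] <- -1
  acq <- acquire(s, accel = 2, seed = 22)
  gh <- motion_augment(tmpl, disp, acq$kspace, acq$mask)
  for (f in 1:4) {
    m <- acq$mask$masks[, , f]
    sp <- forward_fft(gh[, , f])
    expect_lt(max(abs((sp - acq$kspace$spectra[, , f]) * m)), 1e-9)
    wt <- forward_fft(as.complex(warp_image(tmpl, disp[, , , f])) +
                        0i * tmpl)
    expect_lt(max(abs((sp - wt) * (1 - m))), 1e-9)
  }
  expect_error(motion_augment(tmpl[1:8, ], zdisp, kfull, ones), "mismatch")
})

test_that("residual dealiasing is the identity at zero initialisation", {
  x <- rand_complex_seq(16, 16, 4, seed = 23)
  g <- rand_complex_seq(16, 16, 4, seed = 24)
  g0 <- rand_complex_seq(16, 16, 4, seed = 25)
  net <- recon_init(recon_config(channels = c(4, 8, 4)), seed = 26)
  z <- dealias_step(net, g, g0, x)
  expect_equal(z, x)
  # determinism with non-zero weights
  net2 <- recon_init(recon_config(channels = c(4, 8, 4),
                                  zero_init_final_layer = FALSE), seed = 27)
  z1 <- dealias_step(net2, g, g0, x)
  z2 <- dealias_step(net2, g, g0, x)
  expect_identical(z1, z2)
  expect_false(all(z1 == x))
  # motion-free mode takes only X_prev (2 input channels)
  net0 <- recon_init(recon_config(channels = c(4, 8, 4),
                                  motion_mode = "none"), seed = 28)
  expect_equal(dealias_step(net0, NULL, NULL, x), x)
  expect_error(dealias_step(net0, g, g0, x), "motion")
  expect_error(dealias_step(net2, NULL, NULL, x), "missing")
})

test_that("cascade is the identity at zero init and exact under full sampling", {
  ph <- tiny_phantom(seed = 29)
  s <- ph$sequence
  model <- tiny_model(n_frames = 4, iterations = 3, zero_init = TRUE)
  acq <- acquire(s, accel = 2, seed = 30)
  st <- unrolled_forward(model, acq$kspace, acq$mask)
  expect_length(st, 3)
  x0 <- attr(st, "x0")
  for (k in 1:3) expect_lt(max(abs(st[[k]]$x - x0)), 1e-12)
  # full sampling: DC overwrites everything at every iteration
  ones <- sampling_mask(array(1, c(16, 16, 4)), 1)
  stf <- unrolled_forward(model, undersample(sequence_to_kspace(s), ones),
                          ones)
  for (k in 1:3) expect_lt(max(abs(stf[[k]]$x - s$frames)), 1e-6)
})

test_that("every iterate satisfies data consistency on the sampled support", {
  ph <- tiny_phantom(seed = 31)
  model <- tiny_model(n_frames = 4, iterations = 2, zero_init = FALSE)
  acq <- acquire(ph$sequence, accel = 2, seed = 32)
  st <- unrolled_forward(model, acq$kspace, acq$mask)
  for (k in seq_along(st)) for (f in 1:4) {
    sp <- forward_fft(st[[k]]$x[, , f])
    expect_lt(max(abs((sp - acq$kspace$spectra[, , f]) *
                        acq$mask$masks[, , f])), 1e-6)
    spg <- forward_fft(st[[k]]$g[, , f])
    expect_lt(max(abs((spg - acq$kspace$spectra[, , f]) *
                        acq$mask$masks[, , f])), 1e-6)
  }
  # iteration states carry motion artifacts of matching shape
  expect_equal(dim(st[[1]]$velocities), c(16, 16, 2, 4))
  expect_s3_class(st[[1]]$deformations, "deformation_set")
})

test_that("motion-free cascade shares FFT/DC behaviour with the full model", {
  ph <- tiny_phantom(seed = 33)
  acq <- acquire(ph$sequence, accel = 2, seed = 34)
  m_full <- tiny_model(n_frames = 4, iterations = 2, zero_init = TRUE)
  m_none <- tiny_model(n_frames = 4, iterations = 2, motion_mode = "none",
                       zero_init = TRUE)
  sf <- unrolled_forward(m_full, acq$kspace, acq$mask)
  sn <- unrolled_forward(m_none, acq$kspace, acq$mask)
  # identical zero-filled starting points and identical identity iterates:
  # removing the motion branch changes no DC or FFT behaviour
  expect_equal(attr(sf, "x0"), attr(sn, "x0"))
  for (k in 1:2) expect_equal(sf[[k]]$x, sn[[k]]$x)
  expect_null(sn[[1]]$g)
})

test_that("pairwise-reference cascade runs and differs from groupwise", {
  ph <- tiny_phantom(seed = 35)
  acq <- acquire(ph$sequence, accel = 2, seed = 36)
  m_g <- tiny_model(n_frames = 4, zero_init = FALSE, seed = 37)
  m_p <- tiny_model(n_frames = 4, zero_init = FALSE, seed = 37,
                    mode = "pairwise")
  sg <- unrolled_forward(m_g, acq$kspace, acq$mask)
  sp <- unrolled_forward(m_p, acq$kspace, acq$mask)
  expect_true(all(sp[[1]]$velocities[, , , 1] == 0))
  expect_false(isTRUE(all.equal(sg[[2]]$x, sp[[2]]$x)))
})
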
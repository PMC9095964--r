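# Groupwise registration network, implicit template, and the registration
# loss.

test_that("zero-initialised GRN predicts identity motion, deterministically", {
  grn <- grn_init(reg_config(channels = c(4, 8, 4)), n_frames = 4, seed = 1)
  mags <- abs(rand_complex_seq(16, 16, 4, seed = 2))
  v <- predict_velocities(grn, mags)
  expect_equal(dim(v), c(16, 16, 2, 4))
  expect_true(all(v == 0))
  # non-zero final layer: deterministic and centered
  grn2 <- grn_init(reg_config(channels = c(4, 8, 4),
                              zero_init_final_layer = FALSE),
                   n_frames = 4, seed = 1)
  v1 <- predict_velocities(grn2, mags)
  v2 <- predict_velocities(grn2, mags)
  expect_identical(v1, v2)
  expect_false(all(v1 == 0))
  # per-pixel frame-sum of the centered fields is zero
  expect_lt(max(abs(apply(v1, c(1, 2, 3), sum))), 1e-5)
  expect_error(predict_velocities(grn, mags[, , 1:3]), "frame count")
})

test_that("pairwise mode forces the reference frame's field to zero", {
  grn <- grn_init(reg_config(channels = c(4, 8, 4), mode = "pairwise",
                             reference_frame_index = 2,
                             zero_init_final_layer = FALSE),
                  n_frames = 4, seed = 3)
  v <- predict_velocities(grn, abs(rand_complex_seq(16, 16, 4, seed = 4)))
  expect_true(all(v[, , , 2] == 0))
  expect_false(all(v[, , , 1] == 0))
})

test_that("implicit template is the mean of forward-warped frames", {
  set.seed(5)
  frames <- array(abs(rnorm(8 * 8 * 3)), c(8, 8, 3))
  ident <- array(0, c(8, 8, 2, 3))
  expect_equal(compute_template(frames, ident),
               apply(frames, c(1, 2), mean))
  # N = 1: the single warped frame
  expect_equal(compute_template(frames[, , 1, drop = FALSE],
                                ident[, , , 1, drop = FALSE]),
               frames[, , 1])
  # two copies of a square translated by +/-2 px with opposite transforms
  # recover the centered square away from borders
  sq <- matrix(0, 16, 16); sq[6:11, 6:11] <- 1
  fr <- array(0, c(16, 16, 2))
  fr[, , 1] <- warp_image(sq, array(rep(c(2, 0), each = 256), c(16, 16, 2)))
  fr[, , 2] <- warp_image(sq, array(rep(c(-2, 0), each = 256), c(16, 16, 2)))
  tf <- array(0, c(16, 16, 2, 2))
  tf[, , 1, 1] <- -2; tf[, , 1, 2] <- 2
  tmpl <- compute_template(array(c(fr), c(16, 16, 2)), tf)
  int <- 3:14
  expect_lt(max(abs(tmpl[int, int] - sq[int, int])), 1e-6)
})

test_that("reference selection dispatches by mode", {
  set.seed(6)
  frames <- array(abs(rnorm(8 * 8 * 3)), c(8, 8, 3))
  fwd <- array(0, c(8, 8, 2, 3))
  expect_equal(select_reference("groupwise", frames, fwd),
               compute_template(frames, fwd))
  expect_equal(select_reference("pairwise", frames,
                                reference_frame_index = 1),
               frames[, , 1])
  expect_error(select_reference("pairwise", frames,
                                reference_frame_index = 9), "invalid")
})

test_that("registration loss: zero on static case, hand arithmetic on toy", {
  # identical static frames + zero velocities -> exactly zero
  frames <- array(rep(matrix(abs(rnorm(16)), 4, 4), 2), c(4, 4, 2))
  zv <- array(0, c(4, 4, 2, 2))
  defs <- invert_by_negation(zv, n_steps = 2)
  expect_equal(registration_loss(frames, defs, zv, alpha = 0.05), 0)
  expect_error(registration_loss(frames, defs, zv, alpha = -1), "alpha")

  # zero velocities on a moving pair: loss reduces to twice the mean MSE
  # against the plain frame average, plus nothing from smoothness
  set.seed(7)
  mv <- array(abs(rnorm(32)), c(4, 4, 2))
  avg <- apply(mv, c(1, 2), mean)
  expected <- mean((avg - mv[, , 1])^2) / 2 + mean((avg - mv[, , 2])^2) / 2 +
    mean((mv[, , 1] - avg)^2) / 2 + mean((mv[, , 2] - avg)^2) / 2
  got <- registration_loss(mv, defs, zv, alpha = 0.05)
  expect_equal(got, expected, tolerance = 1e-12)

  # hand-built toy: integer 1-px shifts and a ramp velocity; compare against
  # independent index arithmetic
  f1 <- matrix(c(0, 0, 0, 0,
                 0, 1, 2, 0,
                 0, 3, 4, 0,
                 0, 0, 0, 0), 4, 4, byrow = TRUE)
  f2 <- cbind(f1[, 2:4], f1[, 4])        # f1 shifted one column left
  frames2 <- array(c(f1, f2), c(4, 4, 2))
  dfwd <- array(0, c(4, 4, 2, 2)); dbwd <- array(0, c(4, 4, 2, 2))
  dfwd[, , 2, 2] <- -1; dbwd[, , 2, 2] <- 1   # T_2 shifts f2 back right
  defs2 <- structure(list(forward = dfwd, backward = dbwd),
                     class = "deformation_set")
  s <- 0.3
  vr <- array(0, c(4, 4, 2, 2))
  vr[, , 1, 1] <- matrix(s * (seq_len(4) - 1), 4, 4)
  # independent arithmetic: warp by integer shifts with border replication
  shift_right <- function(m) cbind(m[, 1], m[, 1:3])
  w1 <- f1                              # identity transform on frame 1
  w2 <- shift_right(f2)                 # d = -1 column: sample at x - 1
  tmpl <- (w1 + w2) / 2
  t1 <- (mean((tmpl - w1)^2) + mean((tmpl - w2)^2)) / 2
  b1 <- tmpl                            # identity backward on frame 1
  b2 <- cbind(tmpl[, 2:4], tmpl[, 4])   # d = +1 column with replication
  t2 <- (mean((f1 - b1)^2) + mean((f2 - b2)^2)) / 2
  alpha <- 0.05
  expected2 <- t1 + t2 + alpha * (s^2 / 2)
  got2 <- registration_loss(frames2, defs2, vr, alpha = alpha)
  expect_equal(got2, expected2, tolerance = 1e-6)
})
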
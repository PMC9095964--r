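# Stationary velocity fields: centering, scaling-and-squaring integration,
# warping, smoothness penalty.

test_that("velocity centering removes the mean field", {
  set.seed(1)
  h <- 8; w <- 8
  # fields already summing to zero are unchanged
  u <- array(rnorm(h * w * 2), c(h, w, 2))
  v <- array(0, c(h, w, 2, 2)); v[, , , 1] <- u; v[, , , 2] <- -u
  expect_lt(max(abs(center_velocities(v) - v)), 1e-7)
  # identical fields collapse to zero
  vi <- array(rep(u, 3), c(h, w, 2, 3))
  expect_lt(max(abs(center_velocities(vi))), 1e-12)
  # two frames (+u, -u + c) -> (+u - c/2, -u + c/2), algebra on a toy
  cst <- 0.8
  v2 <- v; v2[, , , 2] <- -u + cst
  cv <- center_velocities(v2)
  expect_lt(max(abs(cv[, , , 1] - (u - cst / 2))), 1e-12)
  expect_lt(max(abs(cv[, , , 2] - (-u + cst / 2))), 1e-12)
  expect_lt(max(abs(cv[, , , 1] + cv[, , , 2])), 1e-12)
})

test_that("integration: identity, translation, and linear-field exponential", {
  h <- 64; w <- 64
  z <- array(0, c(h, w, 2))
  expect_identical(integrate_velocity(z), z)
  cf <- z; cf[, , 1] <- 0.7; cf[, , 2] <- -0.4
  phi <- integrate_velocity(cf)
  int <- 5:60
  expect_lt(max(abs(phi[int, int, 1] - 0.7)), 1e-9)
  expect_lt(max(abs(phi[int, int, 2] + 0.4)), 1e-9)
  # separable linear field v = a (x - x0): flow is (e^a - 1)(x - x0)
  a <- 0.1; c0 <- (h + 1) / 2
  yy <- matrix(seq_len(h), h, w) - c0
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - c0
  v <- z; v[, , 1] <- a * yy; v[, , 2] <- a * xx
  phi <- integrate_velocity(v, 7)
  exact <- v / a * (exp(a) - 1)
  int <- 10:55
  expect_lt(max(abs(phi[int, int, ] - exact[int, int, ])), 1e-3)
  expect_error(integrate_velocity(z + NA_real_), "finite")
})

test_that("integration is stable in the number of squaring steps", {
  v <- smooth_field(64, 64, amp = 2, seed = 2)
  p6 <- integrate_velocity(v, 6)
  p7 <- integrate_velocity(v, 7)
  p8 <- integrate_velocity(v, 8)
  int <- 8:57
  expect_lt(max(abs(p6[int, int, ] - p7[int, int, ])), 1e-3)
  expect_lt(max(abs(p7[int, int, ] - p8[int, int, ])), 1e-3)
})

test_that("negated-field integration yields consistent inverses", {
  h <- 64; w <- 64
  z <- array(0, c(h, w, 2, 2))
  d0 <- invert_by_negation(z)
  expect_true(all(d0$forward == 0) && all(d0$backward == 0))
  cf <- array(0, c(h, w, 2, 1)); cf[, , 1, 1] <- 1.2
  dc <- invert_by_negation(cf)
  int <- 5:60
  expect_lt(max(abs(dc$forward[int, int, 1, 1] - 1.2)), 1e-9)
  expect_lt(max(abs(dc$backward[int, int, 1, 1] + 1.2)), 1e-9)
  # smooth random fields: T o T^{-1} close to identity
  errs <- sapply(1:5, function(i) {
    v <- smooth_field(64, 64, amp = 2, seed = 10 + i)
    f <- integrate_velocity(v); b <- integrate_velocity(-v)
    comp <- compose_displacements(f, b)
    int <- 8:57
    mean(sqrt(comp[int, int, 1]^2 + comp[int, int, 2]^2))
  })
  expect_lt(mean(errs), 0.1)
})

test_that("warping: identity, integer shift, bilinear weights, linearity", {
  r <- matrix(as.numeric(1:16), 4, 4)
  z <- array(0, c(4, 4, 2))
  expect_lt(max(abs(warp_image(r, z) - r)), 1e-7)
  # displacement (0, +1): contents shift left by one column (backward map),
  # with the last column replicated
  d <- z; d[, , 2] <- 1
  w <- warp_image(r, d)
  expect_equal(w[, 1:3], r[, 2:4])
  expect_equal(w[, 4], r[, 4])
  # half-pixel displacement splits a one-hot into two 0.5 neighbours
  oh <- matrix(0, 4, 4); oh[2, 3] <- 1
  dh <- z; dh[, , 2] <- 0.5
  wh <- warp_image(oh, dh)
  expect_equal(wh[2, 2], 0.5)
  expect_equal(wh[2, 3], 0.5)
  expect_equal(sum(wh), 1)
  # exact linearity in the image argument
  set.seed(3)
  i1 <- matrix(rnorm(64), 8, 8); i2 <- matrix(rnorm(64), 8, 8)
  dd <- smooth_field(8, 8, 1.5, sigma = 2, seed = 4)
  lhs <- warp_image(2.5 * i1 - 1.3 * i2, dd)
  rhs <- 2.5 * warp_image(i1, dd) - 1.3 * warp_image(i2, dd)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  # complex frames warp componentwise
  ic <- i1 + 2i * i2
  expect_lt(max(abs(warp_image(ic, dd) -
                      (warp_image(i1, dd) + 2i * warp_image(i2, dd)))), 1e-12)
  expect_error(warp_image(i1, array(0, c(4, 4, 2))), "mismatch")
})

test_that("smoothness penalty: zero for constants, slope^2 for a ramp", {
  h <- 4; w <- 4
  cst <- array(2.5, c(h, w, 2, 3))
  expect_equal(smoothness_penalty(cst), 0)
  expect_equal(smoothness_penalty(array(0, c(h, w, 2, 1))), 0)
  s <- 0.7
  v <- array(0, c(h, w, 2, 1))
  v[, , 1, 1] <- matrix(s * (seq_len(h) - 1), h, w)   # ramp along rows
  expect_equal(smoothness_penalty(v), s^2, tolerance = 1e-12)
  # two frames average
  v2 <- array(0, c(h, w, 2, 2)); v2[, , , 1] <- v[, , , 1]
  expect_equal(smoothness_penalty(v2), s^2 / 2, tolerance = 1e-12)
})
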
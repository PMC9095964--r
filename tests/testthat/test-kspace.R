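# Acquisition model: centered orthonormal FFT, Gaussian-density Cartesian
# masks, zero-filling and data consistency.

test_that("centered orthonormal FFT: impulse, Parseval, round trip", {
  for (d in list(c(8, 8), c(16, 12), c(9, 7))) {
    h <- d[1]; w <- d[2]
    imp <- matrix(0 + 0i, h, w)
    imp[h %/% 2 + 1, w %/% 2 + 1] <- 1
    S <- forward_fft(imp)
    expect_lt(max(abs(Mod(S) - 1 / sqrt(h * w))), 1e-12)
    x <- rand_complex_frame(h, w, seed = h * 100 + w)
    expect_lt(max(abs(inverse_fft(forward_fft(x)) - x)) / max(abs(x)), 1e-10)
    expect_lt(abs(sum(Mod(x)^2) - sum(Mod(forward_fft(x))^2)) /
                sum(Mod(x)^2), 1e-10)
  }
  expect_error(forward_fft(1:4), "2D")
})

test_that("forward FFT matches a naive O(n^2) centered DFT", {
  # independent brute-force oracle with explicit centered index arithmetic
  naive_dft <- function(x) {
    h <- nrow(x); w <- ncol(x)
    ky <- seq_len(h) - 1 - h %/% 2; kx <- seq_len(w) - 1 - w %/% 2
    out <- matrix(0 + 0i, h, w)
    for (a in seq_len(h)) for (b in seq_len(w)) {
      s <- 0 + 0i
      for (m in seq_len(h)) for (n in seq_len(w))
        s <- s + x[m, n] *
          exp(-2i * pi * (ky[a] * ky[m] / h + kx[b] * kx[n] / w))
      out[a, b] <- s / sqrt(h * w)
    }
    out
  }
  x <- rand_complex_frame(8, 8, seed = 42)
  expect_lt(max(abs(forward_fft(x) - naive_dft(x))), 1e-8)
})

test_that("mask generator honours line count, central lines and presets", {
  m <- generate_mask(144, 176, 3, acceleration = 8, rng_seed = 1)
  expect_equal(dim(m$masks), c(176, 144, 3))
  centre <- (144 %/% 2 + 1) + (-2:2)
  for (f in 1:3) {
    lines <- which(m$masks[1, , f] == 1)
    expect_length(lines, 18)                     # round(144 / 8)
    expect_true(all(centre %in% lines))
    expect_true(all(apply(m$masks[, , f], 2, function(cl)
      all(cl == cl[1]))))                        # fully sampled along FE
  }
  # acceleration 1: all ones
  m1 <- generate_mask(16, 16, 2, acceleration = 1, rng_seed = 2)
  expect_true(all(m1$masks == 1))
  # presets: round(n_pe / R) lines for the protocol accelerations
  for (R in c(8, 12, 16)) {
    mr <- generate_mask(144, 176, 1, R, rng_seed = R)
    expect_equal(sum(mr$masks[1, , 1]), round(144 / R))
  }
  # reproducibility and frame independence
  a <- generate_mask(64, 64, 4, 8, rng_seed = 7)
  b <- generate_mask(64, 64, 4, 8, rng_seed = 7)
  expect_identical(a$masks, b$masks)
  expect_false(all(a$masks[, , 1] == a$masks[, , 2]))
  sh <- generate_mask(64, 64, 4, 8, rng_seed = 7, shared = TRUE)
  expect_true(all(sh$masks[, , 1] == sh$masks[, , 4]))
  # degenerate line budget collapses to the 5 central lines, with a warning
  expect_warning(md <- generate_mask(16, 8, 1, 16), "central")
  expect_equal(sum(md$masks[1, , 1]), 5)
  expect_error(generate_mask(64, 64, 1, 0.5), "acceleration")
})

test_that("undersampling zeroes exactly the unsampled entries", {
  k <- kspace_sequence(rand_complex_seq(8, 8, 2, seed = 3))
  ones <- sampling_mask(array(1, c(8, 8, 2)), 1)
  expect_equal(undersample(k, ones)$spectra, k$spectra)
  # hand-written 2-line mask on a 4x4 toy
  mk <- array(0, c(4, 4, 1)); mk[, c(2, 3), 1] <- 1
  kt <- kspace_sequence(rand_complex_seq(4, 4, 1, seed = 4))
  u <- undersample(kt, sampling_mask(mk, 2))
  expect_true(u$is_undersampled)
  expect_true(all(u$spectra[, c(1, 4), 1] == 0))
  expect_equal(u$spectra[, c(2, 3), 1], kt$spectra[, c(2, 3), 1])
  expect_error(undersample(k, sampling_mask(mk, 2)), "mismatch")
})

test_that("zero-filled reconstruction inverts full sampling and is linear", {
  x <- dyn_sequence(rand_complex_seq(8, 8, 3, seed = 5))
  k <- sequence_to_kspace(x)
  expect_lt(max(abs(zero_fill_recon(k)$frames - x$frames)), 1e-10)
  z <- kspace_sequence(array(0 + 0i, c(8, 8, 2)), TRUE)
  expect_true(all(zero_fill_recon(z)$frames == 0))
  # aliased recon of an undersampled bright pixel still matches acquired
  # data on the sampled support after re-projection
  ph <- array(0 + 0i, c(16, 16, 1)); ph[9, 9, 1] <- 1
  ks <- sequence_to_kspace(dyn_sequence(ph))
  # 8x on a 16-line toy collapses to the 5 central lines (warns by contract)
  m <- suppressWarnings(generate_mask(16, 16, 1, 8, rng_seed = 6))
  u <- undersample(ks, m)
  zf <- zero_fill_recon(u)
  reproj <- forward_fft(zf$frames[, , 1])
  expect_lt(max(abs((reproj - u$spectra[, , 1]) * m$masks[, , 1])), 1e-10)
})

test_that("data consistency is exact, idempotent and a fixed point", {
  set.seed(8)
  for (rep in 1:5) {
    h <- 8; w <- 8
    x <- rand_complex_frame(h, w)
    truth <- rand_complex_frame(h, w)
    mask <- matrix(rep(rbinom(w, 1, 0.5), each = h), h, w)
    acq <- forward_fft(truth) * mask
    out <- data_consistency(x, acq, mask)
    sp <- forward_fft(out)
    expect_lt(max(abs((sp - acq) * mask)) / max(abs(acq)), 1e-10)
    expect_lt(max(abs((sp - forward_fft(x)) * (1 - mask))) /
                max(abs(x)), 1e-10)
    # idempotence and fixed point
    expect_lt(max(abs(data_consistency(out, acq, mask) - out)), 1e-10)
  }
  y <- rand_complex_frame(8, 8)
  acq <- forward_fft(y)
  expect_lt(max(abs(data_consistency(rand_complex_frame(8, 8), acq,
                                     matrix(1, 8, 8)) - y)), 1e-10)
  expect_lt(max(abs(data_consistency(y, 0 * acq, matrix(0, 8, 8)) - y)),
            1e-10)
  expect_error(data_consistency(y, acq, matrix(1, 4, 4)), "mismatch")
})

test_that("mask sampling density decreases away from the center", {
  n_draw <- 300
  n_pe <- 64
  freq <- numeric(n_pe)
  for (i in seq_len(n_draw))
    freq <- freq + generate_mask(n_pe, 8, 1, 8, rng_seed = 1000 + i)$masks[1, , 1]
  freq <- freq / n_draw
  off <- abs(seq_len(n_pe) - (n_pe %/% 2 + 1))
  ring <- tapply(freq, off, mean)
  slack <- 4 * sqrt(0.25 / n_draw)
  expect_true(all(diff(ring) <= slack))
  expect_true(all(ring[as.character(0:2)] == 1))   # central lines forced
})
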
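# Shared fixtures: all inputs are generated in code at test time.

rand_complex_frame <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(complex(real = rnorm(h * w), imaginary = rnorm(h * w)), h, w)
}

rand_complex_seq <- function(h, w, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(complex(real = rnorm(h * w * n), imaginary = rnorm(h * w * n)),
        dim = c(h, w, n))
}

# smooth random velocity field via separable Gaussian smoothing of white
# noise, rescaled to a maximum absolute value of `amp` pixels
smooth_field <- function(h, w, amp, sigma = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blur1 <- function(m) {
    k <- dnorm(seq(-3 * sigma, 3 * sigma), sd = sigma)
    k <- k / sum(k)
    pad <- 3 * sigma
    sm_col <- apply(m, 2, function(col) {
      ext <- c(rep(col[1], pad), col, rep(col[length(col)], pad))
      stats::filter(ext, k)[(pad + 1):(pad + length(col))]
    })
    t(apply(sm_col, 1, function(row) {
      ext <- c(rep(row[1], pad), row, rep(row[length(row)], pad))
      stats::filter(ext, k)[(pad + 1):(pad + length(row))]
    }))
  }
  v <- array(0, dim = c(h, w, 2))
  for (c in 1:2) {
    m <- blur1(matrix(rnorm(h * w), h, w))
    v[, , c] <- m / max(abs(m)) * amp
  }
  v
}

# a small joint model for fast structural tests
tiny_model <- function(n_frames = 4, channels = c(4, 8, 4), iterations = 2,
                       motion_mode = "full", seed = 11,
                       zero_init = TRUE, mode = "groupwise") {
  grd_model(
    n_frames,
    reg = reg_config(channels = channels, integration_steps = 4,
                     zero_init_final_layer = zero_init, mode = mode),
    recon = recon_config(channels = channels, iterations = iterations,
                         motion_mode = motion_mode,
                         zero_init_final_layer = zero_init),
    seed = seed)
}

tiny_phantom <- function(h = 16, w = 16, n = 4, seed = 5, ...) {
  generate_sequence(phantom_config(height = h, width = w, n_frames = n,
                                   contraction_amplitude = 1.5,
                                   translation_amplitude = 0.5,
                                   seed = seed, ...))
}

# undersampled acquisition of a sequence
acquire <- function(seq, accel, seed = 3) {
  mask <- generate_mask(seq$width, seq$height, seq$frame_count, accel,
                        rng_seed = seed)
  list(mask = mask, kspace = undersample(sequence_to_kspace(seq), mask))
}
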
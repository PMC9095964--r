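# Synthetic dynamic phantom with known ground-truth motion.
#
# The scene is a bright annulus ("myocardium") around a mid-intensity disk
# ("blood pool") on a piecewise-smooth static background.  Motion is
# prescribed as per-frame stationary velocity fields (a radial contraction
# localised around the annulus, modulated sinusoidally over the cycle, plus a
# cyclic bulk translation); frame n is the template scene warped by the
# integrated negated field, so the prescribed fields are exactly the
# frame-to-template velocities the registration network is asked to recover.
# A smooth static low-frequency phase map makes the frames complex; optional
# complex Gaussian noise is added last.

#' Phantom configuration
#'
#' @param height,width image grid (64 x 64 desk scale; 176 x 144 mirrors the
#'   cine protocol).
#' @param n_frames frames per cycle (8 desk scale; 25 mirrors the protocol).
#' @param contraction_amplitude peak radial displacement of the annulus (px).
#' @param translation_amplitude peak cyclic bulk translation (px).
#' @param annulus_radii inner/outer annulus radii in px (defaults scale with
#'   the grid); inner must be smaller than outer.
#' @param edge_width intensity transition width of the annulus/pool edges in
#'   px (partial-volume smoothing; keeps the scene band-limited enough for
#'   faithful bilinear resampling).
#' @param background_level,texture_level background intensity and the
#'   amplitude of its smooth texture (relative).
#' @param phase_scale peak amplitude of the static background phase (rad).
#' @param noise_sd standard deviation of additive complex Gaussian noise per
#'   real/imaginary channel (scene magnitudes are O(1); 0 disables noise).
#' @param seed RNG seed (texture, phase, noise).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(height = 64L, width = 64L, n_frames = 8L,
                           contraction_amplitude = 3,
                           translation_amplitude = 1,
                           annulus_radii = NULL, edge_width = 2.5,
                           background_level = 0.2, texture_level = 0.1,
                           phase_scale = 0.5, noise_sd = 0, seed = 1L) {
  if (is.null(annulus_radii))
    annulus_radii <- c(0.18, 0.30) * min(height, width)
  stopifnot(n_frames >= 1, contraction_amplitude >= 0,
            translation_amplitude >= 0, noise_sd >= 0)
  if (annulus_radii[1] >= annulus_radii[2])
    stop("phantom_config: annulus radii inverted (inner >= outer)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames),
                 contraction_amplitude = contraction_amplitude,
                 translation_amplitude = translation_amplitude,
                 annulus_radii = annulus_radii, edge_width = edge_width,
                 background_level = background_level,
                 texture_level = texture_level,
                 phase_scale = phase_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

smoothstep <- function(x, width = 1.2) 1 / (1 + exp(-x / (width / 4)))

smooth_random_field <- function(h, w, n_comp = 4, max_cycles = 3) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (k in seq_len(n_comp)) {
    fy <- sample.int(max_cycles, 1); fx <- sample.int(max_cycles, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::rnorm(1) * cos(2 * pi * (fy * yy + fx * xx) + ph)
  }
  f / max(abs(f))
}

#' Generate one synthetic dynamic sequence with known motion
#'
#' @param config a [phantom_config()].
#' @return a list of class `phantom` with `sequence` (a complex
#'   [dyn_sequence()]), `velocities` (ground-truth stationary velocity fields
#'   `H x W x 2 x N`, centered by construction), `template` (the undeformed
#'   scene magnitude) and `config`.
#' @export
generate_sequence <- function(config = phantom_config()) {
  h <- config$height; w <- config$width; nfr <- config$n_frames
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  r <- sqrt(yy^2 + xx^2)
  r_in <- config$annulus_radii[1]; r_out <- config$annulus_radii[2]

  with_local_seed(config$seed, {
    bg <- config$background_level *
      pmax(0, 1 + config$texture_level / max(config$background_level, 1e-6) *
             smooth_random_field(h, w))
    phase <- config$phase_scale * smooth_random_field(h, w)
    in_out <- smoothstep(r_out - r, config$edge_width)
    in_in <- smoothstep(r_in - r, config$edge_width)
    scene <- bg * (1 - in_out) + 1.0 * in_out * (1 - in_in) + 0.5 * in_in

    # prescribed stationary velocities (template -> frame n direction is -v_n)
    r_mid <- (r_in + r_out) / 2
    g <- exp(-(r - r_mid)^2 / (2 * (0.35 * r_out)^2))
    runit <- pmax(r, 1e-6)
    phase_n <- 2 * pi * (seq_len(nfr) - 1) / nfr
    v <- array(0, dim = c(h, w, 2, nfr))
    for (f in seq_len(nfr)) {
      a <- -config$contraction_amplitude * sin(phase_n[f])
      v[, , 1, f] <- a * g * yy / runit +
        config$translation_amplitude * sin(phase_n[f])
      v[, , 2, f] <- a * g * xx / runit +
        config$translation_amplitude * cos(phase_n[f]) -
        config$translation_amplitude * mean(cos(phase_n))
    }

    frames <- array(0i, dim = c(h, w, nfr))
    for (f in seq_len(nfr)) {
      tinv <- integrate_velocity(-v[, , , f], n_steps = 7)
      mag <- warp_image(scene, tinv)
      frames[, , f] <- mag * exp(1i * phase)
    }
    if (config$noise_sd > 0) {
      frames <- frames + complex(
        real = stats::rnorm(length(frames), sd = config$noise_sd),
        imaginary = stats::rnorm(length(frames), sd = config$noise_sd))
      dim(frames) <- c(h, w, nfr)
    }
    structure(list(sequence = dyn_sequence(frames), velocities = v,
                   template = scene, config = config),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d, %d frames, contraction %.1f px, noise sd %.3g\n",
    x$config$height, x$config$width, x$config$n_frames,
    x$config$contraction_amplitude, x$config$noise_sd))
  invisible(x)
}

#' Build a train/validation/test phantom dataset on disk
#'
#' Writes `train.rds`, `val.rds`, `test.rds` (lists of [generate_sequence()]
#' outputs) plus a `manifest.csv` recording every per-sequence seed and
#' geometry draw, so the dataset can be regenerated identically.
#'
#' @param n_train,n_val,n_test split sizes (>= 0).
#' @param out_dir output directory (created if missing).
#' @param base_config a [phantom_config()] supplying fixed parameters.
#' @param ranges named list of `c(min, max)` ranges randomised per sequence
#'   (defaults: contraction and translation amplitudes).
#' @param seed master seed; per-sequence seeds are drawn from it.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest data frame, invisibly.
#' @export
build_dataset <- function(n_train, n_val, n_test, out_dir,
                          base_config = phantom_config(),
                          ranges = list(contraction_amplitude = c(2, 4),
                                        translation_amplitude = c(0.5, 1.5)),
                          seed = 1L, overwrite = FALSE) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  splits <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  if (dir.exists(out_dir) &&
      length(list.files(out_dir)) > 0 && !overwrite)
    stop("build_dataset: output directory exists; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  total <- length(splits)
  manifest <- NULL
  items <- vector("list", total)
  with_local_seed(seed, {
    for (i in seq_len(total)) {
      cfg <- base_config
      row <- list(id = i, split = splits[i])
      for (nm in names(ranges)) {
        val <- stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
        cfg[[nm]] <- val
        row[[nm]] <- val
      }
      cfg$seed <- sample.int(.Machine$integer.max %/% 2L, 1)
      row$seed <- cfg$seed
      items[[i]] <- generate_sequence(cfg)
      manifest <- rbind(manifest, as.data.frame(row))
    }
  })
  for (sp in c("train", "val", "test")) {
    saveRDS(items[splits == sp], file.path(out_dir, paste0(sp, ".rds")),
            compress = FALSE)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
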
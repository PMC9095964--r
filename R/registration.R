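# Groupwise diffeomorphic registration network (GRN).
#
# The GRN maps the magnitudes of the N frames (stacked along the channel
# axis) to N two-component stationary velocity fields pointing from the
# implicit template towards the frames.  Velocities are centered so the
# template lies at the geometric center of the group; integrating +/- v gives
# the forward transforms T_n (frame -> template) and their inverses.  In the
# pairwise ablation the sequence is registered to a designated reference
# frame instead: that frame's velocity is forced to zero and no centering is
# applied.

#' Registration network configuration
#'
#' @param channels encoder-decoder convolution widths (symmetric, odd length).
#' @param activation leaky-ReLU negative slope.
#' @param mode `"groupwise"` (implicit template) or `"pairwise"` (fixed
#'   reference frame).
#' @param reference_frame_index reference frame for pairwise mode (1-based;
#'   the end-diastolic first frame by default).
#' @param integration_steps scaling-and-squaring steps.
#' @param zero_init_final_layer start from identity motion if `TRUE`.
#' @return a `reg_config` list.
#' @export
reg_config <- function(channels = c(32, 64, 128, 256, 128, 64, 32),
                       activation = 0.01,
                       mode = c("groupwise", "pairwise"),
                       reference_frame_index = 1L,
                       integration_steps = 7L,
                       zero_init_final_layer = TRUE) {
  mode <- match.arg(mode)
  check_channels(channels)
  stopifnot(reference_frame_index >= 1, integration_steps >= 1)
  structure(list(channels = channels, kernel = c(3, 3),
                 activation = activation, mode = mode,
                 reference_frame_index = as.integer(reference_frame_index),
                 integration_steps = as.integer(integration_steps),
                 zero_init_final_layer = isTRUE(zero_init_final_layer)),
            class = "reg_config")
}

#' Initialise a groupwise registration network
#'
#' The frame count is a build-time constant of the network: it fixes the
#' input (N) and output (2N) channel counts of the first and last layers.
#'
#' @param config a [reg_config()].
#' @param n_frames number of dynamic frames N.
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `grn` holding the parameters and config.
#' @export
grn_init <- function(config = reg_config(), n_frames, seed = NULL) {
  with_local_seed(seed, {
    params <- unet_init(n_frames, 2L * n_frames, config$channels,
                        kernel_nd = 2,
                        zero_init_final = config$zero_init_final_layer)
  })
  structure(list(params = params, config = config,
                 n_frames = as.integer(n_frames)),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %s registration, %d frames, %s trainable parameters\n",
              x$config$mode, x$n_frames,
              format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

# tape forward: magnitude node (H, W, N) -> velocity set node (H, W, 2, N)
grn_predict_node <- function(tape, pnodes, mag_node, grn) {
  d <- dim(mag_node$value)
  n <- grn$n_frames
  if (d[3] != n)
    stop("predict_velocities: frame count does not match the configured N")
  out <- unet_forward(tape, pnodes, mag_node, kernel_nd = 2,
                      slope = grn$config$activation)
  v <- ad_reshape(tape, out, c(d[1], d[2], 2L, n))
  if (grn$config$mode == "groupwise") {
    ad_center_frames(tape, v)
  } else {
    ref <- grn$config$reference_frame_index
    if (ref > n) stop("reference_frame_index exceeds frame count")
    m <- array(1, dim = c(d[1], d[2], 2L, n)); m[, , , ref] <- 0
    ad_mul(tape, v, ad_const(tape, m))
  }
}

#' Predict stationary velocity fields for a dynamic sequence
#'
#' Runs the registration network on the frame magnitudes.  In groupwise mode
#' the output is centered so the per-pixel sum over frames is zero; in
#' pairwise mode the reference frame's field is forced to zero.
#'
#' @param grn a [grn_init()] object.
#' @param magnitudes real nonnegative array `H x W x N`.
#' @return velocity field set, array `H x W x 2 x N`.
#' @export
predict_velocities <- function(grn, magnitudes) {
  stopifnot(inherits(grn, "grn"), length(dim(magnitudes)) == 3)
  tape <- ad_tape()
  pn <- params_to_nodes(tape, grn$params)
  v <- grn_predict_node(tape, pn$nodes, ad_const(tape, magnitudes), grn)
  v$value
}

#' Implicit template: average of forward-warped frames
#'
#' @param frames real array `H x W x N` of frame magnitudes.
#' @param forward forward displacement fields `H x W x 2 x N`.
#' @return real `H x W` matrix (the template image).
#' @export
compute_template <- function(frames, forward) {
  stopifnot(length(dim(frames)) == 3)
  if (!all(dim(frames)[1:2] == dim(forward)[1:2]) ||
      dim(frames)[3] != dim(forward)[4])
    stop("compute_template: shape mismatch")
  n <- dim(frames)[3]
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (f in seq_len(n))
    acc <- acc + warp_image(frames[, , f], forward[, , , f])
  acc / n
}

#' Select the registration reference
#'
#' Groupwise mode returns the implicit template ([compute_template()]);
#' pairwise mode returns the designated reference frame unwarped.
#'
#' @param mode `"groupwise"` or `"pairwise"`.
#' @param frames real array `H x W x N`.
#' @param forward forward displacement fields (groupwise mode).
#' @param reference_frame_index 1-based frame index (pairwise mode).
#' @return real `H x W` matrix.
#' @export
select_reference <- function(mode = c("groupwise", "pairwise"), frames,
                             forward = NULL, reference_frame_index = 1L) {
  mode <- match.arg(mode)
  if (mode == "groupwise") return(compute_template(frames, forward))
  if (reference_frame_index < 1 || reference_frame_index > dim(frames)[3])
    stop("select_reference: invalid reference_frame_index")
  frames[, , reference_frame_index]
}

#' Groupwise registration loss
#'
#' Intensity similarity plus smoothness:
#' \deqn{L = \frac1N \sum_n \|\bar X - T_n \circ X_n\|^2
#'       + \frac1N \sum_n \|X_n - T_n^{-1} \circ \bar X\|^2
#'       + \alpha\,\frac1N \sum_n \|\nabla v_n\|^2,}
#' where the template \eqn{\bar X} is recomputed from the supplied frames and
#' forward fields (or is the reference frame in pairwise mode) and all squared
#' norms are per-pixel means, making `alpha` resolution-independent.
#'
#' @param gt_magnitudes real array `H x W x N` (fully sampled magnitudes).
#' @param deformations a `deformation_set` from [invert_by_negation()].
#' @param velocities the velocity fields `H x W x 2 x N` (smoothness term).
#' @param alpha smoothness weight (>= 0, default 0.05).
#' @param mode,reference_frame_index see [select_reference()].
#' @return nonnegative scalar.
#' @export
registration_loss <- function(gt_magnitudes, deformations, velocities,
                              alpha = 0.05, mode = "groupwise",
                              reference_frame_index = 1L) {
  if (alpha < 0) stop("registration_loss: alpha must be >= 0")
  stopifnot(inherits(deformations, "deformation_set"))
  n <- dim(gt_magnitudes)[3]
  fwd <- deformations$forward; bwd <- deformations$backward
  tmpl <- select_reference(mode, gt_magnitudes, fwd, reference_frame_index)
  t1 <- 0; t2 <- 0
  for (f in seq_len(n)) {
    t1 <- t1 + mean((tmpl - warp_image(gt_magnitudes[, , f], fwd[, , , f]))^2)
    t2 <- t2 + mean((gt_magnitudes[, , f] - warp_image(tmpl, bwd[, , , f]))^2)
  }
  t1 / n + t2 / n + alpha * smoothness_penalty(velocities)
}

# tape version of Eq-1-style loss given prebuilt fwd/bwd displacement nodes
registration_loss_node <- function(tape, gt_mag_nodes, fwd_nodes, bwd_nodes,
                                   v_node, alpha, mode = "groupwise",
                                   reference_frame_index = 1L) {
  n <- length(gt_mag_nodes)
  if (mode == "groupwise") {
    warped <- lapply(seq_len(n), function(f)
      ad_warp(tape, gt_mag_nodes[[f]], fwd_nodes[[f]]))
    tmpl <- ad_smul(tape, ad_sum_list(tape, warped), 1 / n)
  } else {
    tmpl <- gt_mag_nodes[[reference_frame_index]]
    warped <- lapply(seq_len(n), function(f)
      ad_warp(tape, gt_mag_nodes[[f]], fwd_nodes[[f]]))
  }
  t1 <- lapply(seq_len(n), function(f)
    ad_mean_sq(tape, ad_sub(tape, tmpl, warped[[f]])))
  t2 <- lapply(seq_len(n), function(f)
    ad_mean_sq(tape, ad_sub(tape, gt_mag_nodes[[f]],
                            ad_warp(tape, tmpl, bwd_nodes[[f]]))))
  sm <- ad_smoothness(tape, v_node)
  ad_wsum(tape, c(t1, t2, list(sm)),
          c(rep(1 / n, n), rep(1 / n, n), alpha))
}
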
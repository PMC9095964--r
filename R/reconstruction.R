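# The unrolled motion-augmented reconstruction cascade.
#
# Per iteration k: the GRN predicts velocities from |X^{k-1}|; the implicit
# template (mean of forward-warped frames) is warped back to each frame and
# data consistency re-injects the acquired measurements, giving the
# motion-augmented sequence G^{k-1}; the residual 3D dealiasing network maps
# (G^{k-1}, G^0, X^{k-1}) to Z^k = H(.) + X^{k-1}; X^k = DC(Z^k).  Parameters
# of both networks are shared across iterations.

complex_to_ri <- function(x) {         # (H,W,N) complex -> (H,W,2,N) double
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], 2L, d[3]))
  out[, , 1, ] <- Re(x); out[, , 2, ] <- Im(x)
  out
}

ri_to_complex <- function(x) {         # (H,W,2,N) double -> (H,W,N) complex
  d <- dim(x)
  array(complex(real = x[, , 1, ], imaginary = x[, , 2, ]),
        dim = c(d[1], d[2], d[4]))
}

#' Reconstruction cascade configuration
#'
#' @param channels dealiasing network convolution widths.
#' @param iterations number of unrolled iterations K (default 4).
#' @param motion_mode `"full"` (motion-augmented inputs) or `"none"` (the
#'   plain dealiasing + data-consistency cascade, no registration).
#' @param shared_weights share network parameters across iterations.
#' @param use_zero_fill_input also feed the motion-augmented sequence built
#'   from the zero-filled images (G^0) to the dealiasing network.
#' @param template_phase phase given to the real warped template before data
#'   consistency: `"zero"` (default) or `"previous"` (borrow the phase of
#'   X^{k-1}, treated as fixed).
#' @param activation leaky-ReLU negative slope.
#' @param zero_init_final_layer start as the identity residual if `TRUE`.
#' @return a `recon_config` list.
#' @export
recon_config <- function(channels = c(32, 64, 128, 256, 128, 64, 32),
                         iterations = 4L,
                         motion_mode = c("full", "none"),
                         shared_weights = TRUE,
                         use_zero_fill_input = TRUE,
                         template_phase = c("zero", "previous"),
                         activation = 0.01,
                         zero_init_final_layer = TRUE) {
  motion_mode <- match.arg(motion_mode)
  template_phase <- match.arg(template_phase)
  check_channels(channels)
  stopifnot(iterations >= 1)
  structure(list(channels = channels, kernel = c(3, 3, 3),
                 iterations = as.integer(iterations),
                 motion_mode = motion_mode,
                 shared_weights = isTRUE(shared_weights),
                 use_zero_fill_input = isTRUE(use_zero_fill_input),
                 template_phase = template_phase,
                 activation = activation,
                 zero_init_final_layer = isTRUE(zero_init_final_layer)),
            class = "recon_config")
}

recon_in_channels <- function(config) {
  if (config$motion_mode == "none") 2L
  else if (config$use_zero_fill_input) 6L else 4L
}

#' Initialise the dealiasing network
#'
#' A 3D (two spatial axes + frame axis) encoder-decoder over real/imaginary
#' channel pairs; input channels depend on `motion_mode`.
#'
#' @param config a [recon_config()].
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `recon_net`.
#' @export
recon_init <- function(config = recon_config(), seed = NULL) {
  with_local_seed(seed, {
    params <- unet_init(recon_in_channels(config), 2L, config$channels,
                        kernel_nd = 3,
                        zero_init_final = config$zero_init_final_layer)
  })
  structure(list(params = params, config = config), class = "recon_net")
}

#' @export
print.recon_net <- function(x, ...) {
  cat(sprintf("<recon_net> motion %s, K = %d, %s trainable parameters\n",
              x$config$motion_mode, x$config$iterations,
              format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Full joint model: registration + reconstruction networks
#'
#' @param n_frames number of dynamic frames (build-time constant).
#' @param reg a [reg_config()].
#' @param recon a [recon_config()].
#' @param seed RNG seed for weight initialisation of both networks.
#' @return an object of class `grd_model`.
#' @export
grd_model <- function(n_frames, reg = reg_config(), recon = recon_config(),
                      seed = NULL) {
  grn <- if (recon$motion_mode == "full")
    grn_init(reg, n_frames, seed = if (is.null(seed)) NULL else seed) else NULL
  net <- recon_init(recon, seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(grn = grn, recon = net, n_frames = as.integer(n_frames)),
            class = "grd_model")
}

#' @export
print.grd_model <- function(x, ...) {
  np <- n_params(x$recon$params) +
    if (!is.null(x$grn)) n_params(x$grn$params) else 0L
  cat(sprintf(
    "<grd_model> %d frames, K = %d, motion %s, %s trainable parameters\n",
    x$n_frames, x$recon$config$iterations, x$recon$config$motion_mode,
    format(np, big.mark = ",")))
  invisible(x)
}

#' Motion-augmented sequence generation
#'
#' Warps the (real) template back to each frame's anatomy with the backward
#' transforms, lifts to a complex frame, and enforces data consistency, so
#' every generated frame matches the acquired measurements exactly on the
#' sampled support while fusing all frames' information off-support.
#'
#' @param template real `H x W` matrix.
#' @param backward backward displacement fields `H x W x 2 x N`.
#' @param acquired a [kspace_sequence()] of acquired data.
#' @param mask a [sampling_mask()].
#' @return complex array `H x W x N`.
#' @export
motion_augment <- function(template, backward, acquired, mask) {
  stopifnot(inherits(acquired, "kspace_sequence"),
            inherits(mask, "sampling_mask"))
  n <- dim(backward)[4]
  if (!all(dim(template) == dim(backward)[1:2]) ||
      n != acquired$frame_count)
    stop("motion_augment: shape mismatch")
  out <- array(0i, dim = c(dim(template), n))
  for (f in seq_len(n)) {
    w <- warp_image(template, backward[, , , f])
    out[, , f] <- data_consistency(matrix(as.complex(w), nrow(template)),
                                   acquired$spectra[, , f],
                                   mask$masks[, , f])
  }
  out
}

#' One residual dealiasing step
#'
#' `Z = H(G_prev, G_zero, X_prev) + X_prev` with real/imaginary parts stacked
#' along the channel axis of the 3D network.  In `motion_mode = "none"` the
#' motion-augmented inputs are omitted and must be `NULL`.
#'
#' @param recon a [recon_init()] object.
#' @param G_prev,G_zero complex arrays `H x W x N` (or `NULL` when unused).
#' @param X_prev complex array `H x W x N`.
#' @return complex array `H x W x N`.
#' @export
dealias_step <- function(recon, G_prev, G_zero, X_prev) {
  stopifnot(inherits(recon, "recon_net"))
  cfg <- recon$config
  if (cfg$motion_mode == "none" && (!is.null(G_prev) || !is.null(G_zero)))
    stop("dealias_step: motion inputs supplied but motion_mode is 'none'")
  if (cfg$motion_mode == "full" &&
      (is.null(G_prev) || (cfg$use_zero_fill_input && is.null(G_zero))))
    stop("dealias_step: missing motion-augmented inputs")
  tape <- ad_tape()
  pn <- params_to_nodes(tape, recon$params)
  xs <- list(X_prev = X_prev)
  if (cfg$motion_mode == "full") {
    xs <- c(list(G_prev = G_prev), if (cfg$use_zero_fill_input)
      list(G_zero = G_zero), xs)
  }
  nodes <- lapply(xs, function(a)
    ad_const(tape, aperm(complex_to_ri(a), c(1, 2, 4, 3))))
  z <- dealias_node(tape, pn$nodes, nodes, ad_const(tape, complex_to_ri(X_prev)),
                    cfg)
  ri_to_complex(z$value)
}

# inputs: list of (H, W, N, 2) nodes; x_prev_ri: (H, W, 2, N) node
dealias_node <- function(tape, pnodes, input_nodes, x_prev_ri, cfg) {
  x <- if (length(input_nodes) > 1)
    ad_concat_last(tape, input_nodes) else input_nodes[[1]]
  out <- unet_forward(tape, pnodes, x, kernel_nd = 3, slope = cfg$activation)
  out <- ad_aperm(tape, out, c(1, 2, 4, 3))   # (H, W, 2, N)
  ad_add(tape, out, x_prev_ri)
}

# ---------------------------------------------------------------------------
# the unrolled cascade on the tape
# ---------------------------------------------------------------------------

# Returns list(states = per-iteration node bundles, x0 = (H,W,2,N) array).
# When `gt_mag_nodes` is non-NULL, per-iteration registration-loss nodes are
# attached (evaluated against the fully sampled ground-truth magnitudes).
grd_forward_node <- function(tape, model, grn_nodes, rec_nodes, acq, masks,
                             gt_mag_nodes = NULL, alpha = 0.05) {
  cfg <- model$recon$config
  K <- cfg$iterations
  nfr <- model$n_frames
  d <- dim(acq)
  x0c <- array(0i, dim = d)
  for (f in seq_len(nfr)) x0c[, , f] <- inverse_fft(acq[, , f])
  x0 <- complex_to_ri(x0c)
  x_prev <- ad_const(tape, x0)
  g0_node <- NULL
  states <- vector("list", K)
  for (k in seq_len(K)) {
    st <- list()
    if (cfg$motion_mode == "full") {
      mag <- ad_mag(tape, x_prev)
      v <- grn_predict_node(tape, grn_nodes, mag, model$grn)
      steps <- model$grn$config$integration_steps
      fwd <- vector("list", nfr); bwd <- vector("list", nfr)
      for (f in seq_len(nfr)) {
        vf <- ad_slice_last(tape, v, f)
        fwd[[f]] <- ad_integrate(tape, vf, steps)
        bwd[[f]] <- ad_integrate(tape, ad_smul(tape, vf, -1), steps)
      }
      if (model$grn$config$mode == "groupwise") {
        warped <- lapply(seq_len(nfr), function(f) {
          fr <- ad_reshape(tape, ad_slice_last(tape, mag, f),
                           c(d[1], d[2], 1L))
          ad_warp(tape, fr, fwd[[f]])
        })
        tmpl <- ad_smul(tape, ad_sum_list(tape, warped), 1 / nfr)
      } else {
        ref <- model$grn$config$reference_frame_index
        tmpl <- ad_reshape(tape, ad_slice_last(tape, mag, ref),
                           c(d[1], d[2], 1L))
      }
      g_re <- ad_concat_last(tape, lapply(seq_len(nfr), function(f)
        ad_warp(tape, tmpl, bwd[[f]])))
      g_lift <- if (cfg$template_phase == "zero") {
        ad_lift_real(tape, g_re)
      } else {
        # borrow the (detached) phase of X^{k-1}; magnitude stays differentiable
        ph <- atan2(x_prev$value[, , 2, ], x_prev$value[, , 1, ])
        ad_phase_lift(tape, g_re, ph)
      }
      g_k <- ad_dc(tape, g_lift, acq, masks)
      if (k == 1L) g0_node <- g_k
      st$v <- v; st$fwd <- fwd; st$bwd <- bwd; st$template <- tmpl
      st$g <- g_k
      inputs <- c(list(ad_aperm(tape, g_k, c(1, 2, 4, 3))),
                  if (cfg$use_zero_fill_input)
                    list(ad_aperm(tape, g0_node, c(1, 2, 4, 3))),
                  list(ad_aperm(tape, x_prev, c(1, 2, 4, 3))))
      if (!is.null(gt_mag_nodes))
        st$reg_loss <- registration_loss_node(
          tape, gt_mag_nodes, fwd, bwd, v, alpha,
          mode = model$grn$config$mode,
          reference_frame_index = model$grn$config$reference_frame_index)
    } else {
      inputs <- list(ad_aperm(tape, x_prev, c(1, 2, 4, 3)))
    }
    z <- dealias_node(tape, rec_nodes, inputs, x_prev, cfg)
    xk <- ad_dc(tape, z, acq, masks)
    st$z <- z; st$x <- xk
    states[[k]] <- st
    x_prev <- xk
  }
  list(states = states, x0 = x0)
}

#' Run the unrolled reconstruction cascade
#'
#' Starting from the zero-filled images \eqn{X^0}, performs K iterations of
#' register / generate / dealias / data-consistency and returns the
#' per-iteration artifacts.  Every \eqn{X^k} satisfies data consistency
#' exactly on the sampled support.
#'
#' @param model a [grd_model()].
#' @param under_kspace an undersampled [kspace_sequence()].
#' @param mask the matching [sampling_mask()].
#' @return list of K `iteration_state` lists with elements `x`, `z`, `g`
#'   (complex `H x W x N` arrays; `g` absent in motion-free mode),
#'   `velocities`, `deformations`, `template`, plus attribute `x0`
#'   (the zero-filled sequence).
#' @export
unrolled_forward <- function(model, under_kspace, mask) {
  stopifnot(inherits(model, "grd_model"),
            inherits(under_kspace, "kspace_sequence"),
            inherits(mask, "sampling_mask"))
  if (under_kspace$frame_count != model$n_frames)
    stop("unrolled_forward: frame count does not match the model")
  if (!all(dim(under_kspace$spectra) == dim(mask$masks)))
    stop("unrolled_forward: k-space / mask shape mismatch")
  tape <- ad_tape()
  gn <- if (!is.null(model$grn)) params_to_nodes(tape, model$grn$params)$nodes
  rn <- params_to_nodes(tape, model$recon$params)$nodes
  fw <- grd_forward_node(tape, model, gn, rn, under_kspace$spectra,
                         mask$masks)
  out <- lapply(fw$states, function(st) {
    s <- list(x = ri_to_complex(st$x$value), z = ri_to_complex(st$z$value))
    if (!is.null(st$g)) {
      s$g <- ri_to_complex(st$g$value)
      s$velocities <- st$v$value
      nfr <- length(st$fwd)
      dd <- dim(st$v$value)
      fwdA <- array(0, dd); bwdA <- array(0, dd)
      for (f in seq_len(nfr)) {
        fwdA[, , , f] <- st$fwd[[f]]$value
        bwdA[, , , f] <- st$bwd[[f]]$value
      }
      s$deformations <- structure(list(forward = fwdA, backward = bwdA),
                                  class = "deformation_set")
      s$template <- st$template$value[, , 1]
    }
    class(s) <- "iteration_state"
    s
  })
  attr(out, "x0") <- ri_to_complex(fw$x0)
  out
}
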
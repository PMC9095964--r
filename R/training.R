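# End-to-end optimisation of the registration and reconstruction networks
# under the composite per-iteration loss
#   sum_k exp(k - K) * ( L_rec^k + lambda * L_reg^k ),
# where L_rec^k is the complex MSE of X^k against the fully sampled ground
# truth and L_reg^k the registration loss evaluated on the ground-truth
# magnitudes with the iteration's transforms.  Undersampling masks are drawn
# on the fly; training samples are shuffled every epoch; the Adam learning
# rate halves every 20 epochs.

#' Training configuration
#'
#' @param alpha velocity smoothness weight in the registration loss.
#' @param lambda weight of the registration loss in the composite loss.
#' @param accelerations acceleration factors cycled over when drawing masks
#'   (subset of `c(8, 12, 16)` in the reference protocol).
#' @param epochs number of epochs.
#' @param batch_size sequences per gradient step (the reference protocol
#'   uses 1).
#' @param learning_rate initial Adam learning rate.
#' @param lr_halve_every halve the learning rate every this many epochs.
#' @param seed master seed controlling shuffling, masks and initialisation.
#' @return a `train_config` list; iteration weights `w_k = exp(k - K)` are
#'   computed by [iteration_weights()] at loss time.
#' @export
train_config <- function(alpha = 0.05, lambda = 1, accelerations = 8,
                         epochs = 60L, batch_size = 1L,
                         learning_rate = 1e-4, lr_halve_every = 20L,
                         seed = 1L) {
  stopifnot(alpha >= 0, lambda >= 0, all(accelerations >= 1),
            epochs >= 1, learning_rate > 0)
  structure(list(alpha = alpha, lambda = lambda,
                 accelerations = accelerations,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_halve_every = as.integer(lr_halve_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Per-iteration loss weights
#'
#' `w_k = exp(k - K)` for `k = 1..K`: strictly increasing with `w_K = 1`, so
#' later iterations dominate the composite loss.
#'
#' @param K number of unrolled iterations.
#' @return numeric vector of length K.
#' @export
iteration_weights <- function(K) exp(seq_len(K) - K)

#' Learning rate at a given epoch
#' @param config a [train_config()].
#' @param epoch 1-based epoch index.
#' @return the Adam learning rate for that epoch.
#' @export
learning_rate_at <- function(config, epoch) {
  config$learning_rate * 0.5^((epoch - 1) %/% config$lr_halve_every)
}

#' Composite loss over the unrolled iterations
#'
#' Recomputes, from the per-iteration states of [unrolled_forward()],
#' \eqn{\sum_k e^{k-K} ( L_{rec}^k + \lambda L_{reg}^k )} against the fully
#' sampled ground truth.  The reconstruction MSE is the per-pixel mean
#' squared modulus of the complex difference; the registration loss uses the
#' ground-truth magnitudes with the iteration's deformations.
#'
#' @param states list of iteration states from [unrolled_forward()].
#' @param gt a [dyn_sequence()] of fully sampled ground truth.
#' @param config a [train_config()].
#' @param mode registration mode used by the model (for the template choice).
#' @param reference_frame_index pairwise reference frame.
#' @return scalar loss; per-iteration components in attribute `"parts"`.
#' @export
composite_loss <- function(states, gt, config = train_config(),
                           mode = "groupwise", reference_frame_index = 1L) {
  stopifnot(inherits(gt, "dyn_sequence"))
  K <- length(states)
  w <- iteration_weights(K)
  gt_mag <- abs(gt$frames)
  parts <- data.frame(k = seq_len(K), w = w, rec = NA_real_, reg = NA_real_)
  total <- 0
  for (k in seq_len(K)) {
    st <- states[[k]]
    if (!all(dim(st$x) == dim(gt$frames)))
      stop("composite_loss: state/ground-truth shape mismatch")
    rec <- mean(Mod(gt$frames - st$x)^2)
    reg <- if (!is.null(st$velocities)) {
      registration_loss(gt_mag, st$deformations, st$velocities,
                        alpha = config$alpha, mode = mode,
                        reference_frame_index = reference_frame_index)
    } else {
      if (config$lambda > 0)
        stop("composite_loss: lambda > 0 but states carry no motion ",
             "(motion_mode 'none' requires lambda = 0)")
      0
    }
    parts$rec[k] <- rec; parts$reg[k] <- reg
    total <- total + w[k] * (rec + config$lambda * reg)
  }
  structure(total, parts = parts)
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# ---------------------------------------------------------------------------
# training loop
# ---------------------------------------------------------------------------

# one gradient evaluation: returns list(loss, grads (named), parts)
grd_loss_and_grads <- function(model, gt_frames, acq, masks, config) {
  tape <- ad_tape()
  gflat <- list(); gnodes <- NULL
  if (!is.null(model$grn)) {
    pg <- params_to_nodes(tape, model$grn$params, prefix = "grn")
    gnodes <- pg$nodes; gflat <- pg$flat
  }
  pr <- params_to_nodes(tape, model$recon$params, prefix = "rec")
  d <- dim(gt_frames)
  gt_ri <- complex_to_ri(gt_frames)
  gt_node <- ad_const(tape, gt_ri)
  gt_mag_nodes <- if (!is.null(model$grn)) {
    gm <- abs(gt_frames)
    lapply(seq_len(d[3]), function(f)
      ad_const(tape, array(gm[, , f], dim = c(d[1], d[2], 1L))))
  }
  fw <- grd_forward_node(tape, model, gnodes, pr$nodes, acq, masks,
                         gt_mag_nodes = gt_mag_nodes, alpha = config$alpha)
  K <- length(fw$states)
  w <- iteration_weights(K)
  terms <- list(); weights <- numeric(0)
  parts <- data.frame(k = seq_len(K), rec = NA_real_, reg = NA_real_)
  for (k in seq_len(K)) {
    st <- fw$states[[k]]
    rec_k <- ad_smul(tape, ad_mean_sq(tape, ad_sub(tape, st$x, gt_node)), 2)
    terms <- c(terms, list(rec_k)); weights <- c(weights, w[k])
    parts$rec[k] <- rec_k$value
    if (!is.null(st$reg_loss) && config$lambda > 0) {
      terms <- c(terms, list(st$reg_loss))
      weights <- c(weights, w[k] * config$lambda)
      parts$reg[k] <- st$reg_loss$value
    }
  }
  loss <- ad_wsum(tape, terms, weights)
  ad_backward(tape, loss)
  grads <- lapply(c(gflat, pr$flat), function(nd)
    if (is.null(nd$grad)) NULL else nd$grad)
  list(loss = loss$value, grads = grads, parts = parts,
       final_x = ri_to_complex(fw$states[[K]]$x$value),
       x0 = ri_to_complex(fw$x0))
}

model_flat_params <- function(model) {
  c(if (!is.null(model$grn)) flatten_params(model$grn$params, "grn"),
    flatten_params(model$recon$params, "rec"))
}

model_set_flat <- function(model, flat) {
  if (!is.null(model$grn))
    model$grn$params <- unflatten_params(model$grn$params, flat, "grn")
  model$recon$params <- unflatten_params(model$recon$params, flat, "rec")
  model
}

#' Train the joint registration-reconstruction model
#'
#' Each step draws a training sequence and a fresh undersampling mask
#' (seeded stream, acceleration cycling over `config$accelerations`),
#' simulates the acquisition from the ground-truth k-space, runs the unrolled
#' cascade, and applies one Adam update to both networks jointly.  Runs are
#' fully reproducible given `config$seed`.
#'
#' @param dataset list of ground-truth [dyn_sequence()] objects (or of lists
#'   with element `sequence`).
#' @param config a [train_config()].
#' @param model a [grd_model()]; initialised from `config$seed` when `NULL`.
#' @param validation optional list of sequences for checkpoint selection by
#'   mean final-iteration PSNR (fixed seeded masks).
#' @param verbose print per-epoch progress.
#' @return list with elements `model` (best validation checkpoint if a
#'   validation set was given, else the final model), `final_model`,
#'   `history` (per-epoch data frame), `config`.
#' @export
train_model <- function(dataset, config = train_config(), model = NULL,
                        validation = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("train_model: empty dataset")
  get_seq <- function(item) {
    s <- if (inherits(item, "dyn_sequence")) item else item$sequence
    stopifnot(inherits(s, "dyn_sequence"))
    s
  }
  dataset <- lapply(dataset, get_seq)
  if (!is.null(validation) && length(validation) == 0) validation <- NULL
  if (!is.null(validation)) validation <- lapply(validation, get_seq)
  d1 <- dim(dataset[[1]]$frames)
  if (is.null(model))
    model <- grd_model(d1[3], seed = config$seed)
  flat <- model_flat_params(model)
  opt <- adam_init(flat)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), val_psnr = numeric(0))
  best <- list(psnr = -Inf, model = model)
  kspaces <- lapply(dataset, sequence_to_kspace)
  val_masks <- NULL
  with_local_seed(config$seed, {
    if (!is.null(validation)) {
      val_masks <- lapply(seq_along(validation), function(i) {
        dv <- dim(validation[[i]]$frames)
        generate_mask(dv[2], dv[1], dv[3], config$accelerations[1])
      })
    }
    acc_cycle <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- learning_rate_at(config, epoch)
      order_ <- sample.int(length(dataset))
      ep_loss <- 0
      for (i in order_) {
        acc_cycle <- acc_cycle + 1L
        acc <- config$accelerations[
          ((acc_cycle - 1L) %% length(config$accelerations)) + 1L]
        dv <- dim(dataset[[i]]$frames)
        mask <- generate_mask(dv[2], dv[1], dv[3], acc)
        und <- undersample(kspaces[[i]], mask)
        r <- grd_loss_and_grads(model, dataset[[i]]$frames,
                                und$spectra, mask$masks, config)
        if (!is.finite(r$loss))
          stop("train_model: loss diverged (non-finite) at epoch ", epoch)
        upd <- adam_step(flat, r$grads, opt, lr)
        flat <- upd$flat; opt <- upd$state
        model <- model_set_flat(model, flat)
        ep_loss <- ep_loss + r$loss
      }
      ep_loss <- ep_loss / length(dataset)
      vp <- NA_real_
      if (!is.null(validation)) {
        vp <- mean(vapply(seq_along(validation), function(i) {
          kv <- sequence_to_kspace(validation[[i]])
          und <- undersample(kv, val_masks[[i]])
          states <- unrolled_forward(model, und, val_masks[[i]])
          psnr(abs(validation[[i]]$frames), abs(states[[length(states)]]$x))
        }, 0))
        if (vp > best$psnr) best <- list(psnr = vp, model = model)
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           lr = lr, val_psnr = vp))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5g  lr %.2g  val PSNR %s",
                        epoch, ep_loss, lr,
                        if (is.na(vp)) "-" else sprintf("%.2f dB", vp)))
    }
  })
  list(model = if (is.finite(best$psnr)) best$model else model,
       final_model = model, history = history, config = config)
}
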
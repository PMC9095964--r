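# Reconstruction and registration quality metrics: PSNR, windowed SSIM, and
# the forward-then-backward warping protocol for registration quality.

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(peak^2 / MSE)` with `peak` the maximum of the reference
#' sequence and the MSE pooled over all frames.  Identical inputs return
#' `Inf` (a sentinel, not an error).
#'
#' @param reference,test real (magnitude) arrays of identical shape,
#'   `H x W` or `H x W x N`.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test) {
  if (!all(dim(reference) == dim(test))) stop("psnr: shape mismatch")
  peak <- max(reference)
  if (peak <= 0) stop("psnr: reference is identically zero")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# valid-region separable windowed filtering: out is (H-size+1) x (W-size+1)
win_filter <- function(m, w) {
  n <- length(w)
  h <- nrow(m); wd <- ncol(m)
  Wr <- matrix(0, h - n + 1, h)
  for (i in seq_len(h - n + 1)) Wr[i, i:(i + n - 1)] <- w
  Wc <- matrix(0, wd - n + 1, wd)
  for (j in seq_len(wd - n + 1)) Wc[j, j:(j + n - 1)] <- w
  Wr %*% m %*% t(Wc)
}

#' Structural similarity index (SSIM)
#'
#' Standard windowed SSIM with a Gaussian window (`sigma = 1.5`, 11 x 11),
#' constants `k1 = 0.01`, `k2 = 0.03`, averaged over all valid windows (and
#' over frames for sequences).  The dynamic range defaults to the reference
#' peak; fix it externally for a symmetric comparison.
#'
#' @param reference,test real arrays `H x W` or `H x W x N`.
#' @param dynamic_range data range L; default `max(reference)`.
#' @param sigma,size Gaussian window parameters.
#' @param k1,k2 stabilisation constants.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, dynamic_range = NULL,
                 sigma = 1.5, size = 11L, k1 = 0.01, k2 = 0.03) {
  if (!all(dim(reference) == dim(test))) stop("ssim: shape mismatch")
  d <- dim(reference)
  if (size > d[1] || size > d[2]) stop("ssim: window larger than image")
  if (is.null(dynamic_range)) dynamic_range <- max(reference)
  C1 <- (k1 * dynamic_range)^2
  C2 <- (k2 * dynamic_range)^2
  w <- gaussian_window(size, sigma)
  one_frame <- function(x, y) {
    mu1 <- win_filter(x, w); mu2 <- win_filter(y, w)
    s1 <- win_filter(x * x, w) - mu1^2
    s2 <- win_filter(y * y, w) - mu2^2
    s12 <- win_filter(x * y, w) - mu1 * mu2
    mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
           ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
  }
  if (length(d) == 2) return(one_frame(reference, test))
  mean(vapply(seq_len(d[3]), function(f)
    one_frame(reference[, , f], test[, , f]), 0))
}

#' Registration quality by forward-then-backward warping
#'
#' Integrates the velocity fields, warps the fully sampled magnitudes with
#' the forward fields to build the reference (implicit template in groupwise
#' mode, the designated frame in pairwise mode), regenerates the sequence by
#' warping that reference back with the backward fields, and reports
#' PSNR/SSIM of the regenerated against the original magnitudes.
#'
#' @param gt a [dyn_sequence()] of fully sampled ground truth.
#' @param velocities velocity field set `H x W x 2 x N` on the same grid.
#' @param mode `"groupwise"` or `"pairwise"`.
#' @param reference_frame_index pairwise reference frame (1-based).
#' @param n_steps integration steps.
#' @param method optional method tag recorded in the report.
#' @return a `metrics_report` list: `psnr`, `ssim`, `per_frame_psnr`,
#'   `regenerated` (the regenerated magnitude sequence), `mode`, `method`.
#' @export
evaluate_registration <- function(gt, velocities,
                                  mode = c("groupwise", "pairwise"),
                                  reference_frame_index = 1L, n_steps = 7,
                                  method = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "dyn_sequence"))
  velocities <- as_vfield_set(velocities)
  if (!all(dim(velocities)[c(1, 2, 4)] ==
           c(gt$height, gt$width, gt$frame_count)))
    stop("evaluate_registration: velocities do not match the sequence grid")
  mags <- abs(gt$frames)
  defs <- invert_by_negation(velocities, n_steps)
  ref <- select_reference(mode, mags, defs$forward, reference_frame_index)
  regen <- mags
  for (f in seq_len(gt$frame_count))
    regen[, , f] <- warp_image(ref, defs$backward[, , , f])
  per_frame <- vapply(seq_len(gt$frame_count), function(f) {
    m <- mean((mags[, , f] - regen[, , f])^2)
    if (m == 0) Inf else 10 * log10(max(mags)^2 / m)
  }, 0)
  structure(list(psnr = psnr(mags, regen),
                 ssim = ssim(mags, regen),
                 per_frame_psnr = per_frame,
                 regenerated = regen, reference = ref,
                 mode = mode,
                 method = if (is.null(method)) mode else method),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s: PSNR %.2f dB, SSIM %.4f\n",
              x$method, x$psnr, x$ssim))
  invisible(x)
}

#' Assemble a per-sequence metrics table
#'
#' One row per sequence x method x acceleration, mirroring a box-plot-style
#' comparison as CSV.
#'
#' @param rows list of lists/data frames with fields `sequence`, `method`,
#'   `acceleration`, `psnr`, `ssim`.
#' @param path optional CSV output path.
#' @return the combined data frame.
#' @export
metrics_table <- function(rows, path = NULL) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
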
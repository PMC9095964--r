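#' @useDynLib cinerecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# domain containers
# ---------------------------------------------------------------------------

#' Dynamic image sequence
#'
#' A thin container for an ordered set of complex-valued 2D frames
#' \eqn{X = \{X_1, \ldots, X_N\}} sharing a common grid.  By convention rows
#' are the frequency-encode axis and columns the phase-encode axis.
#'
#' @param frames complex (or numeric) array of dimension `H x W x N`, or a
#'   list of `H x W` matrices.
#' @return an object of class `dyn_sequence` with elements `frames`
#'   (complex `H x W x N` array), `frame_count`, `height`, `width`.
#' @export
dyn_sequence <- function(frames) {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1)
    frames <- array(unlist(lapply(frames, as.complex)),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3)
  storage.mode(frames) <- "complex"
  if (!all(is.finite(Re(frames))) || !all(is.finite(Im(frames))))
    stop("dyn_sequence: frames must be finite")
  structure(list(frames = frames,
                 frame_count = dim(frames)[3],
                 height = dim(frames)[1],
                 width = dim(frames)[2]),
            class = "dyn_sequence")
}

#' @export
print.dyn_sequence <- function(x, ...) {
  cat(sprintf("<dyn_sequence> %d frames of %d x %d (complex)\n",
              x$frame_count, x$height, x$width))
  invisible(x)
}

#' k-space sequence
#'
#' Per-frame 2D spectra matching a companion [dyn_sequence()].  When
#' `is_undersampled`, unacquired entries are exactly zero.
#'
#' @param spectra complex array `H x W x N`.
#' @param is_undersampled logical flag.
#' @return an object of class `kspace_sequence`.
#' @export
kspace_sequence <- function(spectra, is_undersampled = FALSE) {
  if (length(dim(spectra)) == 2) dim(spectra) <- c(dim(spectra), 1L)
  stopifnot(length(dim(spectra)) == 3)
  storage.mode(spectra) <- "complex"
  structure(list(spectra = spectra,
                 is_undersampled = isTRUE(is_undersampled),
                 frame_count = dim(spectra)[3],
                 height = dim(spectra)[1],
                 width = dim(spectra)[2]),
            class = "kspace_sequence")
}

#' Cartesian sampling mask
#'
#' Binary per-frame masks over the k-space grid.  Each sampled phase-encode
#' line (a mask column) is fully sampled along the frequency-encode axis, so
#' every mask column is constant.
#'
#' @param masks numeric/integer array `H x W x N` with entries in {0, 1}.
#' @param acceleration the target acceleration factor R.
#' @return an object of class `sampling_mask`.
#' @export
sampling_mask <- function(masks, acceleration = NA_real_) {
  if (length(dim(masks)) == 2) dim(masks) <- c(dim(masks), 1L)
  stopifnot(length(dim(masks)) == 3)
  storage.mode(masks) <- "double"
  if (!all(masks %in% c(0, 1))) stop("sampling_mask: entries must be 0/1")
  cc <- apply(masks, c(2, 3), function(col) length(unique(col)) == 1L)
  if (!all(cc))
    stop("sampling_mask: each phase-encode line must be fully sampled")
  structure(list(masks = masks, acceleration = acceleration,
                 frame_count = dim(masks)[3],
                 height = dim(masks)[1], width = dim(masks)[2]),
            class = "sampling_mask")
}

# ---------------------------------------------------------------------------
# centered orthonormal Fourier operators
# ---------------------------------------------------------------------------

# circular shift helpers: fftshift moves the DC sample (index 1) to the array
# center floor(n/2)+1; ifftshift undoes it (they differ for odd sizes).
shift_idx <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1

fftshift2 <- function(m) m[shift_idx(nrow(m), nrow(m) %/% 2),
                           shift_idx(ncol(m), ncol(m) %/% 2), drop = FALSE]
ifftshift2 <- function(m) m[shift_idx(nrow(m), -(nrow(m) %/% 2)),
                            shift_idx(ncol(m), -(ncol(m) %/% 2)), drop = FALSE]

#' Centered orthonormal 2D Fourier transform
#'
#' Forward transform of a single complex frame with the DC component at the
#' array center (`(H %/% 2 + 1, W %/% 2 + 1)`) and orthonormal `1/sqrt(HW)`
#' scaling, so that the pair conserves energy (Parseval) and
#' `inverse_fft(forward_fft(x)) == x` to machine precision.
#'
#' @param frame complex or numeric 2D matrix.
#' @return complex matrix of the same size.
#' @export
forward_fft <- function(frame) {
  if (is.null(dim(frame)) || length(dim(frame)) != 2)
    stop("forward_fft: input must be a 2D matrix")
  fftshift2(stats::fft(ifftshift2(as.matrix(frame)))) / sqrt(length(frame))
}

#' Centered orthonormal 2D inverse Fourier transform
#' @param spectrum complex 2D matrix.
#' @return complex matrix of the same size.
#' @rdname forward_fft
#' @export
inverse_fft <- function(spectrum) {
  if (is.null(dim(spectrum)) || length(dim(spectrum)) != 2)
    stop("inverse_fft: input must be a 2D matrix")
  fftshift2(stats::fft(ifftshift2(as.matrix(spectrum)), inverse = TRUE)) /
    sqrt(length(spectrum))
}

#' Fourier transform of every frame of a dynamic sequence
#' @param seq a [dyn_sequence()].
#' @return a [kspace_sequence()] with `is_undersampled = FALSE`.
#' @export
sequence_to_kspace <- function(seq) {
  stopifnot(inherits(seq, "dyn_sequence"))
  k <- seq$frames
  for (n in seq_len(seq$frame_count)) k[, , n] <- forward_fft(seq$frames[, , n])
  kspace_sequence(k, is_undersampled = FALSE)
}

# ---------------------------------------------------------------------------
# Gaussian-density Cartesian undersampling
# ---------------------------------------------------------------------------

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

central_lines <- function(n_pe) {
  c0 <- n_pe %/% 2 + 1L            # 1-based center line
  (c0 - 2L):(c0 + 2L)
}

#' Generate Gaussian-density Cartesian undersampling masks
#'
#' Per frame, `round(n_pe / acceleration)` distinct phase-encode lines are
#' sampled without replacement with probability proportional to a zero-mean
#' Gaussian over the line offset from the central line; the 5 central lines
#' are always sampled.  Masks are drawn independently per frame unless
#' `shared = TRUE`.
#'
#' @param n_pe number of phase-encode lines (mask columns); must be >= 5.
#' @param n_fe number of frequency-encode samples (mask rows).
#' @param n_frames number of temporal frames.
#' @param acceleration target acceleration factor R (>= 1).
#' @param rng_seed optional integer seed; the global RNG state is restored.
#' @param sigma Gaussian density standard deviation in lines
#'   (default `n_pe / 6`, covering the line range at three sigma).
#' @param shared if `TRUE`, one mask is drawn and reused for all frames.
#' @return a [sampling_mask()].
#' @export
generate_mask <- function(n_pe, n_fe, n_frames, acceleration,
                          rng_seed = NULL, sigma = NULL, shared = FALSE) {
  if (acceleration < 1) stop("generate_mask: acceleration must be >= 1")
  if (n_pe < 5) stop("generate_mask: n_pe must be >= 5")
  if (is.null(sigma)) sigma <- n_pe / 6
  n_keep <- round(n_pe / acceleration)
  if (n_keep < 5) {
    warning("generate_mask: round(n_pe/acceleration) < 5; ",
            "sampling only the 5 central lines")
    n_keep <- 5
  }
  centre <- central_lines(n_pe)
  offs <- seq_len(n_pe) - (n_pe %/% 2 + 1L)
  w <- exp(-offs^2 / (2 * sigma^2))
  cand <- setdiff(seq_len(n_pe), centre)
  draw_lines <- function() {
    extra <- n_keep - 5L
    picked <- if (extra > 0)
      sample(cand, extra, replace = FALSE, prob = w[cand]) else integer(0)
    sort(c(centre, picked))
  }
  masks <- array(0, dim = c(n_fe, n_pe, n_frames))
  with_local_seed(rng_seed, {
    lines1 <- draw_lines()
    for (f in seq_len(n_frames)) {
      ln <- if (shared) lines1 else if (f == 1L) lines1 else draw_lines()
      masks[, ln, f] <- 1
    }
  })
  sampling_mask(masks, acceleration = acceleration)
}

#' Apply a sampling mask to fully sampled k-space
#' @param full_kspace a [kspace_sequence()].
#' @param mask a [sampling_mask()] of matching dimensions.
#' @return an undersampled [kspace_sequence()].
#' @export
undersample <- function(full_kspace, mask) {
  stopifnot(inherits(full_kspace, "kspace_sequence"),
            inherits(mask, "sampling_mask"))
  if (!all(dim(full_kspace$spectra) == dim(mask$masks)))
    stop("undersample: shape mismatch between k-space and mask")
  kspace_sequence(full_kspace$spectra * mask$masks, is_undersampled = TRUE)
}

#' Zero-filled reconstruction
#'
#' Per-frame inverse centered orthonormal FFT of (possibly undersampled)
#' k-space; this is the aliased starting point \eqn{X^0} of the cascade.
#'
#' @param under_kspace a [kspace_sequence()].
#' @return a [dyn_sequence()].
#' @export
zero_fill_recon <- function(under_kspace) {
  stopifnot(inherits(under_kspace, "kspace_sequence"))
  x <- under_kspace$spectra
  for (n in seq_len(under_kspace$frame_count))
    x[, , n] <- inverse_fft(under_kspace$spectra[, , n])
  dyn_sequence(x)
}

#' Data-consistency enforcement for one frame
#'
#' Replaces the candidate image's spectrum by the acquired measurements on
#' the sampled support:
#' `inverse_fft(mask * acquired + (1 - mask) * forward_fft(image))`.
#' Sampled coefficients of the output equal `acquired` exactly; unsampled
#' coefficients are those of the input image.  The operation is idempotent.
#'
#' @param image complex 2D frame (candidate reconstruction).
#' @param acquired complex 2D spectrum of acquired data (zero off-support).
#' @param mask binary 2D matrix (1 = acquired).
#' @return complex 2D frame.
#' @export
data_consistency <- function(image, acquired, mask) {
  if (!all(dim(image) == dim(acquired)) || !all(dim(image) == dim(mask)))
    stop("data_consistency: shape mismatch")
  if (!all(mask %in% c(0, 1))) stop("data_consistency: mask must be binary")
  inverse_fft(mask * acquired + (1 - mask) * forward_fft(image))
}
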
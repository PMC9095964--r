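# Stationary-velocity-field machinery.  A velocity field set is an
# H x W x 2 x N array (component 1 = row displacement, 2 = column, in pixels
# per unit time); a single field is H x W x 2.  Unit-time integration by
# scaling and squaring yields invertible displacement fields; integrating the
# negated field gives the inverse transform.

as_vfield_set <- function(v) {
  if (length(dim(v)) == 3) dim(v) <- c(dim(v), 1L)
  stopifnot(length(dim(v)) == 4, dim(v)[3] == 2)
  if (!all(is.finite(v))) stop("velocity fields must be finite")
  v
}

#' Center a set of stationary velocity fields
#'
#' Subtracts the across-frame mean field from each field so that the implicit
#' template lies at the geometric center of the group: the per-pixel,
#' per-component sum of the centered fields is zero.
#'
#' @param v velocity field set, array `H x W x 2 x N`.
#' @return centered array of the same shape.
#' @export
center_velocities <- function(v) {
  v <- as_vfield_set(v)
  n <- dim(v)[4]
  m <- apply(v, c(1, 2, 3), mean)
  sweep(v, c(1, 2, 3), m, "-")
}

#' Integrate a stationary velocity field over unit time
#'
#' Scaling and squaring: the field is scaled by `2^-n_steps` and the
#' resulting small displacement is self-composed `n_steps` times,
#' `phi <- phi + warp(phi, phi)`, using the same bilinear backward-mapping
#' warp as [warp_image()].  The result approximates the flow
#' \eqn{\exp(v)} of the stationary ODE \eqn{\dot x = v(x)}.
#'
#' @param v single velocity field, array `H x W x 2` (pixels per unit time).
#' @param n_steps number of squaring steps (default 7).
#' @return displacement field `H x W x 2` in pixels.
#' @export
integrate_velocity <- function(v, n_steps = 7) {
  stopifnot(length(dim(v)) == 3, dim(v)[3] == 2, n_steps >= 1)
  if (!all(is.finite(v))) stop("integrate_velocity: non-finite field")
  phi <- v / 2^n_steps
  for (s in seq_len(n_steps)) phi <- phi + cpp_warp_fwd(phi, phi)
  phi
}

#' Forward and inverse transforms from velocity fields
#'
#' Integrates `+v_n` to the forward displacement `T_n` (frame n to template)
#' and `-v_n` to the backward displacement `T_n^{-1}` for every frame.
#'
#' @param v velocity field set `H x W x 2 x N`.
#' @param n_steps squaring steps, see [integrate_velocity()].
#' @return a `deformation_set`: list with `forward` and `backward` arrays of
#'   shape `H x W x 2 x N`.
#' @export
invert_by_negation <- function(v, n_steps = 7) {
  v <- as_vfield_set(v)
  fwd <- v; bwd <- v
  for (n in seq_len(dim(v)[4])) {
    fwd[, , , n] <- integrate_velocity(v[, , , n], n_steps)
    bwd[, , , n] <- integrate_velocity(-v[, , , n], n_steps)
  }
  structure(list(forward = fwd, backward = bwd), class = "deformation_set")
}

#' Warp a frame with a displacement field
#'
#' Backward-mapping resampling `out(x) = image(x + d(x))` with bilinear
#' interpolation and border replication.  Complex frames are warped by
#' interpolating real and imaginary parts independently.  The operation is
#' exactly linear in the image argument.
#'
#' @param image real or complex 2D matrix.
#' @param displacement array `H x W x 2` in pixels (row, column).
#' @return warped frame of the same type and size.
#' @export
warp_image <- function(image, displacement) {
  if (!all(dim(image)[1:2] == dim(displacement)[1:2]))
    stop("warp_image: shape mismatch")
  d <- dim(image)[1:2]
  if (is.complex(image)) {
    x <- array(c(Re(image), Im(image)), dim = c(d, 2L))
    w <- cpp_warp_fwd(x, displacement)
    matrix(complex(real = w[, , 1], imaginary = w[, , 2]), d[1], d[2])
  } else {
    x <- array(as.double(image), dim = c(d, 1L))
    cpp_warp_fwd(x, displacement)[, , 1]
  }
}

#' Velocity-field smoothness penalty
#'
#' Mean over frames of the summed mean-squared forward-difference spatial
#' gradients of both velocity components: per frame,
#' `sum_c mean((d_row v_c)^2) + mean((d_col v_c)^2)`, each mean over its own
#' valid (interior) positions, so a single linear ramp of slope `s` in one
#' component scores `s^2`.
#'
#' @param v velocity field set `H x W x 2 x N`.
#' @return nonnegative scalar.
#' @export
smoothness_penalty <- function(v) {
  v <- as_vfield_set(v)
  n <- dim(v)[4]
  tot <- 0
  for (f in seq_len(n)) tot <- tot + field_grad_sq(v[, , , f])
  tot / n
}

field_grad_sq <- function(field) {
  h <- dim(field)[1]; w <- dim(field)[2]
  s <- 0
  for (c in 1:2) {
    m <- field[, , c]
    if (h > 1) s <- s + mean((m[-1, , drop = FALSE] - m[-h, , drop = FALSE])^2)
    if (w > 1) s <- s + mean((m[, -1, drop = FALSE] - m[, -w, drop = FALSE])^2)
  }
  s
}

#' Compose two displacement fields
#'
#' Returns the displacement of the composed map `x -> x + d2(x) + d1(x + d2(x))`,
#' i.e. applying `d2` first and `d1` second; used for inverse-consistency
#' checks `T o T^{-1}`.
#'
#' @param d1,d2 displacement fields `H x W x 2`.
#' @return displacement field `H x W x 2`.
#' @export
compose_displacements <- function(d1, d2) {
  stopifnot(all(dim(d1) == dim(d2)))
  d2 + cpp_warp_fwd(d1, d2)
}
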
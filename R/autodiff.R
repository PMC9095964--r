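# A minimal reverse-mode automatic-differentiation tape over R arrays.
# Every operation records its parents and a backward closure; gradients are
# propagated in reverse creation order (parents are always created before
# children, so creation order is a topological order).  The heavy operators
# (convolutions, pooling, transposed convolution, bilinear warping) call the
# compiled kernels in src/kernels.cpp.  This exists because no deep-learning
# runtime is available to R in this environment; the tape is deliberately
# small and single-threaded, which also makes runs bit-reproducible.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_node <- function(tape, value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, v) ad_node(tape, v)

ad_value <- function(x) x$value

# Accumulate gradients from `loss` (a scalar node) back to every leaf.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL  # free as we go
  }
  invisible(NULL)
}

# -- elementwise / algebraic ------------------------------------------------

ad_add <- function(tape, a, b)
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))

ad_sub <- function(tape, a, b)
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))

ad_smul <- function(tape, a, s)
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_lrelu <- function(tape, a, slope = 0.01) {
  scale <- (a$value > 0) + slope * (a$value <= 0)
  ad_node(tape, a$value * scale, list(a), function(g) list(g * scale))
}

# mean of squared entries -> scalar
ad_mean_sq <- function(tape, a) {
  av <- a$value; n <- length(av)
  ad_node(tape, mean(av^2), list(a), function(g) list(g * 2 * av / n))
}

# weighted sum of scalar nodes -> scalar
ad_wsum <- function(tape, nodes, weights) {
  v <- sum(mapply(function(nd, w) nd$value * w, nodes, weights))
  ad_node(tape, v, nodes,
          function(g) lapply(weights, function(w) g * w))
}

# elementwise sum of a list of same-shaped nodes
ad_sum_list <- function(tape, nodes) {
  v <- Reduce(`+`, lapply(nodes, ad_value))
  ad_node(tape, v, nodes, function(g) rep(list(g), length(nodes)))
}

ad_reshape <- function(tape, a, dims) {
  old <- dim(a$value)
  v <- a$value; dim(v) <- dims
  ad_node(tape, v, list(a), function(g) { dim(g) <- old; list(g) })
}

ad_aperm <- function(tape, a, perm) {
  inv <- order(perm)
  ad_node(tape, aperm(a$value, perm), list(a),
          function(g) list(aperm(g, inv)))
}

# concatenate along the last dimension
ad_concat_last <- function(tape, nodes) {
  vals <- lapply(nodes, ad_value)
  d <- dim(vals[[1]])
  nd_ <- length(d)
  sizes <- vapply(vals, function(v) dim(v)[nd_], 0)
  v <- array(0, dim = c(d[-nd_], sum(sizes)))
  ix <- cumsum(c(0, sizes))
  flat <- prod(d[-nd_])
  vv <- unlist(vals, use.names = FALSE)
  v[] <- vv
  ad_node(tape, v, nodes, function(g) {
    gm <- g; dim(gm) <- c(flat, sum(sizes))
    out <- vector("list", length(nodes))
    for (k in seq_along(nodes)) {
      gk <- gm[, (ix[k] + 1):ix[k + 1], drop = FALSE]
      dim(gk) <- c(d[-nd_], sizes[k])
      out[[k]] <- gk
    }
    out
  })
}

# take one index of the last dimension, dropping it
ad_slice_last <- function(tape, a, idx) {
  d <- dim(a$value)
  nd_ <- length(d)
  flat <- prod(d[-nd_])
  v <- a$value; dim(v) <- c(flat, d[nd_])
  v <- v[, idx]
  dim(v) <- if (nd_ > 2) d[-nd_] else NULL
  ad_node(tape, v, list(a), function(g) {
    gz <- array(0, dim = c(flat, d[nd_]))
    gz[, idx] <- g
    dim(gz) <- d
    list(gz)
  })
}

# stack along a new trailing dimension
ad_stack_last <- function(tape, nodes) {
  vals <- lapply(nodes, ad_value)
  d <- dim(vals[[1]])
  if (is.null(d)) d <- length(vals[[1]])
  v <- array(unlist(vals, use.names = FALSE), dim = c(d, length(nodes)))
  flat <- prod(d)
  ad_node(tape, v, nodes, function(g) {
    dim(g) <- c(flat, length(nodes))
    lapply(seq_along(nodes), function(k) {
      gk <- g[, k]; dim(gk) <- d; gk
    })
  })
}

# subtract the across-frame (last-dim) mean: the velocity centering step.
# The Jacobian (I - P) is symmetric and idempotent, so backward = forward.
ad_center_frames <- function(tape, a) {
  d <- dim(a$value)
  nf <- d[length(d)]
  ctr <- function(x) {
    dim(x) <- c(prod(d) / nf, nf)
    x <- x - rowMeans(x)
    dim(x) <- d
    x
  }
  ad_node(tape, ctr(a$value), list(a), function(g) list(ctr(g)))
}

# magnitude of a complex sequence stored as (H, W, 2, N) -> (H, W, N)
ad_mag <- function(tape, a, eps = 1e-12) {
  d <- dim(a$value)
  re <- a$value[, , 1, , drop = FALSE]
  im <- a$value[, , 2, , drop = FALSE]
  m <- sqrt(re^2 + im^2 + eps)
  v <- m; dim(v) <- d[-3]
  ad_node(tape, v, list(a), function(g) {
    gz <- array(0, dim = d)
    dim(g) <- dim(m)
    gz[, , 1, ] <- g * re / m
    gz[, , 2, ] <- g * im / m
    list(gz)
  })
}

# embed a real sequence (H, W, N) as complex (H, W, 2, N) with zero imaginary
ad_lift_real <- function(tape, a) {
  d <- dim(a$value)
  v <- array(0, dim = c(d[1], d[2], 2, d[3]))
  v[, , 1, ] <- a$value
  ad_node(tape, v, list(a), function(g) {
    gr <- g[, , 1, , drop = FALSE]; dim(gr) <- d
    list(gr)
  })
}

# lift a real sequence (H, W, N) to complex (H, W, 2, N) with a fixed
# (non-differentiated) phase map `ph` (H, W, N)
ad_phase_lift <- function(tape, a, ph) {
  d <- dim(a$value)
  cs <- cos(ph); sn <- sin(ph)
  v <- array(0, dim = c(d[1], d[2], 2, d[3]))
  v[, , 1, ] <- a$value * cs
  v[, , 2, ] <- a$value * sn
  ad_node(tape, v, list(a), function(g) {
    gr <- g[, , 1, , drop = FALSE]; gi <- g[, , 2, , drop = FALSE]
    dim(gr) <- d; dim(gi) <- d
    list(gr * cs + gi * sn)
  })
}

# -- neural-network layers --------------------------------------------------

ad_conv2d <- function(tape, x, w, b) {
  xv <- x$value; wv <- w$value
  ad_node(tape, cpp_conv2d_fwd(xv, wv, b$value), list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

# The 3D convolution runs in float32 by default (it dominates a training
# step and is GEMM/bandwidth bound); set
# options(cinerecon.conv_precision = "double") for the exact reference path.
ad_conv3d <- function(tape, x, w, b) {
  wv <- w$value
  dx <- dim(x$value)
  if (identical(getOption("cinerecon.conv_precision", "single"), "double")) {
    xv <- x$value
    return(ad_node(tape, cpp_conv3d_fwd(xv, wv, b$value), list(x, w, b),
                   function(g) {
                     r <- cpp_conv3d_bwd(xv, wv, g)
                     list(r$gx, r$gw, r$gb)
                   }))
  }
  fw <- cpp_conv3d_fwd_cached(x$value, wv, b$value)
  ad_node(tape, fw$out, list(x, w, b), function(g) {
    r <- cpp_conv3d_bwd_cached(fw$cache, wv, g, dx)
    list(r$gx, r$gw, r$gb)
  })
}

ad_pool2d <- function(tape, x) {
  r <- cpp_maxpool2d_fwd(x$value)
  n_in <- length(x$value); din <- dim(x$value)
  ad_node(tape, r$out, list(x), function(g) {
    gx <- cpp_maxpool_bwd(r$idx, g, n_in)
    dim(gx) <- din
    list(gx)
  })
}

ad_pool3d <- function(tape, x) {
  r <- cpp_maxpool3d_fwd(x$value)
  n_in <- length(x$value); din <- dim(x$value)
  ad_node(tape, r$out, list(x), function(g) {
    gx <- cpp_maxpool_bwd(r$idx, g, n_in)
    dim(gx) <- din
    list(gx)
  })
}

ad_upconv2d <- function(tape, x, w, b) {
  xv <- x$value; wv <- w$value
  ad_node(tape, cpp_upconv2d_fwd(xv, wv, b$value), list(x, w, b), function(g) {
    r <- cpp_upconv2d_bwd(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

ad_upconv3d <- function(tape, x, w, b) {
  xv <- x$value; wv <- w$value
  ad_node(tape, cpp_upconv3d_fwd(xv, wv, b$value), list(x, w, b), function(g) {
    r <- cpp_upconv3d_bwd(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

# bilinear warp of (H, W, C) by displacement (H, W, 2); differentiable in both
ad_warp <- function(tape, img, disp) {
  iv <- img$value; dv <- disp$value
  ad_node(tape, cpp_warp_fwd(iv, dv), list(img, disp), function(g) {
    r <- cpp_warp_bwd(iv, dv, g)
    list(r$gimg, r$gdisp)
  })
}

# scaling-and-squaring integration of one (H, W, 2) velocity node
ad_integrate <- function(tape, v, n_steps = 7) {
  phi <- ad_smul(tape, v, 1 / 2^n_steps)
  for (s in seq_len(n_steps))
    phi <- ad_add(tape, phi, ad_warp(tape, phi, phi))
  phi
}

# smoothness penalty of a velocity set node (H, W, 2, N) -> scalar;
# same normalization as smoothness_penalty().
ad_smoothness <- function(tape, v) {
  d <- dim(v$value)
  h <- d[1]; w <- d[2]; nf <- d[4]
  val <- 0
  for (f in seq_len(nf)) val <- val + field_grad_sq(v$value[, , , f])
  val <- val / nf
  vv <- v$value
  ad_node(tape, val, list(v), function(g) {
    gz <- array(0, dim = d)
    for (f in seq_len(nf)) for (c in 1:2) {
      m <- vv[, , c, f]
      if (h > 1) {
        dr <- m[-1, , drop = FALSE] - m[-h, , drop = FALSE]
        s <- g * 2 / (length(dr) * nf)
        gz[-1, , c, f] <- gz[-1, , c, f] + s * dr
        gz[-h, , c, f] <- gz[-h, , c, f] - s * dr
      }
      if (w > 1) {
        dc <- m[, -1, drop = FALSE] - m[, -w, drop = FALSE]
        s <- g * 2 / (length(dc) * nf)
        gz[, -1, c, f] <- gz[, -1, c, f] + s * dc
        gz[, -w, c, f] <- gz[, -w, c, f] - s * dc
      }
    }
    list(gz)
  })
}

# data-consistency layer on a complex sequence node (H, W, 2, N).
# Forward: per frame, ifft(mask * acquired + (1-mask) * fft(z)).  The map is
# C-linear with unitary F and a real diagonal mask, so the adjoint has the
# same form with acquired = 0.
ad_dc <- function(tape, z, acquired, masks) {
  d <- dim(z$value)
  nf <- d[4]
  apply_dc <- function(arr, acq) {
    out <- array(0, dim = d)
    for (n in seq_len(nf)) {
      zc <- matrix(complex(real = arr[, , 1, n], imaginary = arr[, , 2, n]),
                   d[1], d[2])
      m <- masks[, , n]
      res <- inverse_fft(m * acq[, , n] + (1 - m) * forward_fft(zc))
      out[, , 1, n] <- Re(res)
      out[, , 2, n] <- Im(res)
    }
    out
  }
  zero_acq <- array(0i, dim = c(d[1], d[2], nf))
  ad_node(tape, apply_dc(z$value, acquired), list(z),
          function(g) list(apply_dc(g, zero_acq)))
}
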
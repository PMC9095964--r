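# Encoder-decoder (UNet) parameter initialisation and tape-based forward
# passes.  The channel list names the convolution layers, e.g.
# c(32, 64, 128, 256, 128, 64, 32): the first half are encoder convolutions
# (each followed by leaky ReLU and 2x max pooling), the middle entry is the
# bottleneck, the second half decoder convolutions preceded by a transposed
# convolution and skip concatenation.  A final 3x3 prediction layer with no
# activation maps to the requested output channels; it can be zero-initialised
# so the network starts as the zero map (identity motion / identity residual).

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

check_channels <- function(channels) {
  L <- (length(channels) - 1) / 2
  if (L != round(L)) stop("channel list must have odd length")
  if (!all(channels == rev(channels))) stop("channel list must be symmetric")
  as.integer(L)
}

#' @keywords internal
unet_init <- function(in_ch, out_ch, channels, kernel_nd = 2,
                      zero_init_final = TRUE) {
  L <- check_channels(channels)
  k <- if (kernel_nd == 2) c(3, 3) else c(3, 3, 3)
  kv <- prod(k)
  conv_par <- function(ci, co, zero = FALSE) {
    w <- if (zero) array(0, dim = c(k, ci, co)) else
      he_init(c(k, ci, co), kv * ci)
    list(w = w, b = numeric(co))
  }
  up_par <- function(ci, co) {
    list(w = he_init(c(2, 2, ci, co), 4 * ci), b = numeric(co))
  }
  p <- list(enc = list(), dec = list())
  ci <- in_ch
  for (i in seq_len(L)) {
    p$enc[[i]] <- conv_par(ci, channels[i])
    ci <- channels[i]
  }
  p$mid <- conv_par(ci, channels[L + 1])
  ci <- channels[L + 1]
  for (j in seq_len(L)) {
    co <- channels[L + 1 + j]
    p$dec[[j]] <- list(up = up_par(ci, co), conv = conv_par(2 * co, co))
    ci <- co
  }
  p$final <- conv_par(ci, out_ch, zero = zero_init_final)
  attr(p, "in_ch") <- in_ch
  attr(p, "out_ch") <- out_ch
  attr(p, "channels") <- channels
  attr(p, "kernel_nd") <- kernel_nd
  p
}

# Build tape nodes for a parameter structure; returns the node structure plus
# a flat list of (name, node) pairs used by the optimizer.
params_to_nodes <- function(tape, params, prefix = "") {
  flat <- list()
  wrap <- function(p, path) {
    if (is.list(p) && !is.null(p$w)) {
      nw <- ad_node(tape, p$w); nb <- ad_node(tape, p$b)
      flat[[paste0(path, ".w")]] <<- nw
      flat[[paste0(path, ".b")]] <<- nb
      list(w = nw, b = nb)
    } else if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) {
        nm <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
        wrap(p[[i]], paste0(path, ".", nm))
      })
      names(out) <- names(p)
      out
    } else p
  }
  nodes <- wrap(params, prefix)
  list(nodes = nodes, flat = flat)
}

# Flatten a parameter structure into a named list of arrays (for Adam).
flatten_params <- function(params, prefix = "") {
  flat <- list()
  walk <- function(p, path) {
    if (is.list(p) && !is.null(p$w)) {
      flat[[paste0(path, ".w")]] <<- p$w
      flat[[paste0(path, ".b")]] <<- p$b
    } else if (is.list(p)) {
      for (i in seq_along(p)) {
        nm <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
        walk(p[[i]], paste0(path, ".", nm))
      }
    }
  }
  walk(params, prefix)
  flat
}

# Write a named flat list of arrays back into the nested structure.
unflatten_params <- function(params, flat, prefix = "") {
  walk <- function(p, path) {
    if (is.list(p) && !is.null(p$w)) {
      p$w <- array(flat[[paste0(path, ".w")]], dim = dim(p$w))
      p$b <- as.numeric(flat[[paste0(path, ".b")]])
      p
    } else if (is.list(p)) {
      for (i in seq_along(p)) {
        nm <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
        p[[i]] <- walk(p[[i]], paste0(path, ".", nm))
      }
      p
    } else p
  }
  walk(params, prefix)
}

n_params <- function(params) sum(vapply(flatten_params(params), length, 0L))

# UNet forward pass on the tape.  `x` is a node: (H, W, C) for 2D nets,
# (H, W, D, C) for 3D nets (D = frames; pooling is spatial-only in 3D so the
# temporal axis keeps its resolution and odd frame counts are allowed).
unet_forward <- function(tape, pn, x, kernel_nd = 2, slope = 0.01) {
  conv <- if (kernel_nd == 2) ad_conv2d else ad_conv3d
  pool <- if (kernel_nd == 2) ad_pool2d else ad_pool3d
  upcv <- if (kernel_nd == 2) ad_upconv2d else ad_upconv3d
  L <- length(pn$enc)
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    x <- ad_lrelu(tape, conv(tape, x, pn$enc[[i]]$w, pn$enc[[i]]$b), slope)
    skips[[i]] <- x
    x <- pool(tape, x)
  }
  x <- ad_lrelu(tape, conv(tape, x, pn$mid$w, pn$mid$b), slope)
  for (j in seq_len(L)) {
    x <- upcv(tape, x, pn$dec[[j]]$up$w, pn$dec[[j]]$up$b)
    x <- ad_concat_last(tape, list(x, skips[[L + 1 - j]]))
    x <- ad_lrelu(tape, conv(tape, x, pn$dec[[j]]$conv$w, pn$dec[[j]]$conv$b),
                  slope)
  }
  conv(tape, x, pn$final$w, pn$final$b)   # no activation on the last layer
}
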
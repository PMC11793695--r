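# Differentiable operations on (H, W, C, N) arrays, built on the C++ kernels.

# coerce a matrix / 3d array to (H, W, C, N)
#' @keywords internal
hf_as4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

.ch_expand <- function(a, d) {
  # replicate a length-C vector across an (H, W, C, N) shape
  array(rep(rep(a, each = d[1] * d[2]), times = d[4]), dim = d)
}

op_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_hf_tensor(x)
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, stride, pad)
  hf_tensor(y, parents = list(x, w, b), backward = function(g) {
    bw <- cpp_conv2d_bwd(x$value, w$value, g, stride, pad)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_deconv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  # transposed convolution; w has dim (kh, kw, Cout, Cin)
  x <- as_hf_tensor(x)
  y <- cpp_deconv2d_fwd(x$value, w$value, b$value, stride, pad)
  zeros_cin <- numeric(dim(x$value)[3])
  hf_tensor(y, parents = list(x, w, b), backward = function(g) {
    gx <- cpp_conv2d_fwd(g, w$value, zeros_cin, stride, pad)
    gw <- cpp_conv2d_bwd(g, w$value, x$value, stride, pad)$gw
    dg <- dim(g)
    cs <- .colSums(g, dg[1] * dg[2], dg[3] * dg[4])
    gb <- .rowSums(matrix(cs, dg[3], dg[4]), dg[3], dg[4])
    list(gx, gw, gb)
  })
}

op_prelu <- function(x, a) {
  # per-channel parametric ReLU; a is a length-C parameter tensor
  d <- dim(x$value)
  af <- .ch_expand(a$value, d)
  neg <- pmin(x$value, 0)
  y <- pmax(x$value, 0) + af * neg
  hf_tensor(y, parents = list(x, a), backward = function(g) {
    slope <- af
    slope[x$value > 0] <- 1
    gx <- g * slope
    # per-channel sum of g * neg over (H, W, N)
    cs <- .colSums(g * neg, d[1] * d[2], d[3] * d[4])
    ga <- .rowSums(matrix(cs, d[3], d[4]), d[3], d[4])
    list(gx, ga)
  })
}

op_sigmoid <- function(x) {
  x <- as_hf_tensor(x)
  y <- 1 / (1 + exp(-x$value))
  hf_tensor(y, parents = list(x), backward = function(g) list(g * y * (1 - y)))
}

op_add <- function(x, y) {
  x <- as_hf_tensor(x); y <- as_hf_tensor(y)
  hf_tensor(x$value + y$value, parents = list(x, y),
            backward = function(g) list(g, g))
}

op_sub <- function(x, y) {
  x <- as_hf_tensor(x); y <- as_hf_tensor(y)
  hf_tensor(x$value - y$value, parents = list(x, y),
            backward = function(g) list(g, -g))
}

op_cmul <- function(x, y) {
  x <- as_hf_tensor(x); y <- as_hf_tensor(y)
  hf_tensor(x$value * y$value, parents = list(x, y),
            backward = function(g) list(g * y$value, g * x$value))
}

op_scale <- function(x, k) {
  x <- as_hf_tensor(x)
  hf_tensor(x$value * k, parents = list(x), backward = function(g) list(g * k))
}

op_concat_c <- function(xs) {
  xs <- lapply(xs, as_hf_tensor)
  ds <- lapply(xs, function(t) dim(t$value))
  cs <- vapply(ds, `[`, integer(1), 3L)
  d <- ds[[1]]
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  hf_tensor(out, parents = xs, backward = function(g) {
    at <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <<- at + cs[i]
      gi
    })
  })
}

op_slice_c <- function(x, channels) {
  d <- dim(x$value)
  y <- x$value[, , channels, , drop = FALSE]
  hf_tensor(y, parents = list(x), backward = function(g) {
    gx <- array(0, dim = d)
    gx[, , channels, ] <- g
    list(gx)
  })
}

op_resize <- function(x, oh, ow) {
  x <- as_hf_tensor(x)
  d <- dim(x$value)
  if (d[1] == oh && d[2] == ow) return(x)
  y <- cpp_resize_fwd(x$value, as.integer(oh), as.integer(ow))
  hf_tensor(y, parents = list(x),
            backward = function(g) list(cpp_resize_bwd(g, d[1], d[2])))
}

op_warp <- function(img, flow) {
  img <- as_hf_tensor(img); flow <- as_hf_tensor(flow)
  y <- cpp_warp_fwd(img$value, flow$value)
  hf_tensor(y, parents = list(img, flow), backward = function(g) {
    bw <- cpp_warp_bwd(img$value, flow$value, g)
    list(bw$gimg, bw$gflow)
  })
}

op_gap <- function(x) {
  # global average pooling over the spatial dims -> (1, 1, C, N)
  d <- dim(x$value)
  y <- .colMeans(x$value, d[1] * d[2], d[3] * d[4])
  dim(y) <- c(1L, 1L, d[3], d[4])
  hf_tensor(y, parents = list(x), backward = function(g) {
    gx <- array(rep(as.vector(g), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
    list(gx)
  })
}

op_linear <- function(x, w, b) {
  # x: (1, 1, Cin, N); w: (Cout, Cin); b: length Cout -> (1, 1, Cout, N)
  d <- dim(x$value)
  xm <- matrix(x$value, nrow = d[3], ncol = d[4])
  ym <- w$value %*% xm + b$value
  y <- array(ym, dim = c(1L, 1L, nrow(w$value), d[4]))
  hf_tensor(y, parents = list(x, w, b), backward = function(g) {
    gm <- matrix(g, nrow = nrow(w$value), ncol = d[4])
    gx <- array(t(w$value) %*% gm, dim = d)
    gw <- gm %*% t(xm)
    gb <- rowSums(gm)
    list(gx, gw, gb)
  })
}

op_l1 <- function(x, y) {
  x <- as_hf_tensor(x); y <- as_hf_tensor(y)
  diff <- x$value - y$value
  n <- length(diff)
  hf_tensor(mean(abs(diff)), parents = list(x, y), backward = function(g) {
    gx <- g * sign(diff) / n
    list(gx, -gx)
  })
}

op_mse <- function(x, y) {
  x <- as_hf_tensor(x); y <- as_hf_tensor(y)
  diff <- x$value - y$value
  n <- length(diff)
  hf_tensor(mean(diff^2), parents = list(x, y), backward = function(g) {
    gx <- g * 2 * diff / n
    list(gx, -gx)
  })
}

# weighted sum of scalar loss tensors
op_weighted_sum <- function(xs, weights) {
  vals <- vapply(xs, function(t) t$value, numeric(1))
  hf_tensor(sum(vals * weights), parents = xs,
            backward = function(g) as.list(g * weights))
}

# Straight-through Bernoulli gate: forward emits the sampled 0/1 values,
# backward passes the gradient to the routing probabilities unchanged.
op_straight_through <- function(w_tilde, v) {
  hf_tensor(v, parents = list(w_tilde), backward = function(g) list(g))
}

# state' = g * new + (1 - g) * old with a per-sample scalar gate g of dim
# (1, 1, 1, N) broadcast over an (H, W, C, N) state.
op_gate_mix <- function(new, old, gate) {
  d <- dim(new$value)
  gfull <- array(rep(as.vector(gate$value), each = d[1] * d[2] * d[3]), dim = d)
  y <- gfull * new$value + (1 - gfull) * old$value
  hf_tensor(y, parents = list(new, old, gate), backward = function(g) {
    ggate <- .colSums(g * (new$value - old$value), d[1] * d[2] * d[3], d[4])
    dim(ggate) <- c(1L, 1L, 1L, d[4])
    list(g * gfull, g * (1 - gfull), ggate)
  })
}
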
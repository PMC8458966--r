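# Reverse-mode automatic differentiation over volumetric tensors.
#
# A tensor is a numeric matrix with N = dx*dy*dz rows (voxels, column-major,
# x fastest) and one column per channel, carrying its grid dimensions in the
# "vdim" attribute.  Each differentiable operation appends a node (an
# environment holding the value, the gradient accumulator, and a backward
# closure) to a tape; tape_backward() replays the tape in reverse.  Creation
# order is a valid topological order because ops can only consume
# already-created nodes.

tape_new <- function(record = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp$record <- isTRUE(record)
  class(tp) <- "ls_tape"
  tp
}

tp_node <- function(tape, v, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$grad <- NULL
  nd$bw <- bw
  if (tape$record && !is.null(bw)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tape_backward <- function(tape, loss) {
  stopifnot(tape$record)
  loss$grad <- 1
  if (tape$n > 0L) {
    for (i in seq(tape$n, 1L)) {
      nd <- tape$nodes[[i]]
      if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
    }
  }
  invisible(NULL)
}

vdim <- function(x) attr(x, "vdim")

`vdim<-` <- function(x, value) {
  attr(x, "vdim") <- as.integer(value)
  x
}

# Trainable leaf (weight matrix or bias vector) with Adam state.
new_leaf <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$grad <- NULL
  p$frozen <- FALSE
  p$m <- NULL
  p$u <- NULL
  p
}

conv_out_dim <- function(dim_in, k, stride, plo, phi) {
  as.integer((dim_in + plo + phi - k) %/% stride + 1L)
}

rep_row <- function(x, n) matrix(x, nrow = n, ncol = length(x), byrow = TRUE)

# 3D convolution via im2col + BLAS matrix product.  W: (k^3*Cin) x Cout,
# b: length-Cout.  The patch matrix is retained by the backward closure.
op_conv3 <- function(tape, x, W, b, k, stride = 1L, plo = 1L, phi = 1L) {
  dim_in <- vdim(x$v)
  cols <- im2col3(x$v, dim_in, k, stride, plo, phi)
  out <- cols %*% W$v
  out <- out + rep_row(b$v, nrow(out))
  vdim(out) <- conv_out_dim(dim_in, k, stride, plo, phi)
  if (!tape$record) return(tp_node(tape, out))
  cin <- ncol(x$v)
  tp_node(tape, out, bw = function(nd) {
    g <- nd$grad
    if (!isTRUE(W$frozen)) {
      gw <- crossprod(cols, g)
      W$grad <- if (is.null(W$grad)) gw else W$grad + gw
      gb <- colSums(g)
      b$grad <- if (is.null(b$grad)) gb else b$grad + gb
    }
    gx <- col2im3(g %*% t(W$v), dim_in, cin, k, stride, plo, phi)
    acc_grad(x, gx)
  })
}

op_maxpool <- function(tape, x) {
  dim_in <- vdim(x$v)
  fw <- maxpool3_fwd(x$v, dim_in)
  out <- fw$out
  vdim(out) <- dim_in %/% 2L
  if (!tape$record) return(tp_node(tape, out))
  idx <- fw$idx
  nin <- nrow(x$v)
  tp_node(tape, out, bw = function(nd) {
    acc_grad(x, maxpool3_bwd(nd$grad, idx, nin))
  })
}

op_upnn <- function(tape, x) {
  dim_in <- vdim(x$v)
  out <- upnn3_fwd(x$v, dim_in)
  vdim(out) <- dim_in * 2L
  if (!tape$record) return(tp_node(tape, out))
  tp_node(tape, out, bw = function(nd) {
    acc_grad(x, upnn3_bwd(nd$grad, dim_in))
  })
}

# Instance normalization without learned affine parameters: each channel is
# centred and scaled to unit variance over the spatial grid.  With a single
# spatial sample the statistics are degenerate (the output would be
# identically zero, destroying all information and gradient flow), so the
# op falls back to the identity there.
op_inorm <- function(tape, x, eps = 1e-5) {
  v <- x$v
  n <- nrow(v)
  cc <- ncol(v)
  if (n == 1L) {
    out <- v
    if (!tape$record) return(tp_node(tape, out))
    return(tp_node(tape, out, bw = function(nd) acc_grad(x, nd$grad)))
  }
  mu <- .colMeans(v, n, cc)
  xc <- v - rep_row(mu, n)
  sd <- sqrt(.colMeans(xc * xc, n, cc) + eps)
  xh <- xc / rep_row(sd, n)
  vdim(xh) <- vdim(v)
  if (!tape$record) return(tp_node(tape, xh))
  tp_node(tape, xh, bw = function(nd) {
    g <- nd$grad
    cmg <- .colMeans(g, n, cc)
    cmgx <- .colMeans(g * xh, n, cc)
    gx <- (g - rep_row(cmg, n) - xh * rep_row(cmgx, n)) / rep_row(sd, n)
    acc_grad(x, gx)
  })
}

op_act <- function(tape, x, act, slope = 0.2) {
  v <- x$v
  out <- switch(act,
    relu = v * (v > 0),
    lrelu = v * (v > 0) + (slope * v) * (v <= 0),
    tanh = tanh(v),
    sigmoid = 1 / (1 + exp(-v)),
    stop("unknown activation: ", act)
  )
  vdim(out) <- vdim(v)
  if (!tape$record) return(tp_node(tape, out))
  tp_node(tape, out, bw = function(nd) {
    g <- nd$grad
    gx <- switch(act,
      relu = g * (v > 0),
      lrelu = g * ((v > 0) + slope * (v <= 0)),
      tanh = g * (1 - out * out),
      sigmoid = g * out * (1 - out)
    )
    acc_grad(x, gx)
  })
}

op_concat <- function(tape, a, b) {
  out <- cbind(a$v, b$v)
  vdim(out) <- vdim(a$v)
  if (!tape$record) return(tp_node(tape, out))
  ca <- ncol(a$v)
  cb <- ncol(b$v)
  tp_node(tape, out, bw = function(nd) {
    g <- nd$grad
    acc_grad(a, g[, seq_len(ca), drop = FALSE])
    acc_grad(b, g[, ca + seq_len(cb), drop = FALSE])
  })
}

# Scalar loss nodes -----------------------------------------------------

# mean(|x - target|); target is a plain numeric matrix/vector.
op_l1_mean <- function(tape, x, target) {
  d <- x$v - target
  out <- mean(abs(d))
  if (!tape$record) return(tp_node(tape, out))
  n <- length(d)
  tp_node(tape, out, bw = function(nd) {
    acc_grad(x, (sign(d) / n) * nd$grad)
  })
}

# mean((x - center)^2)
op_mean_sq <- function(tape, x, center = 0) {
  d <- x$v - center
  out <- mean(d * d)
  if (!tape$record) return(tp_node(tape, out))
  n <- length(d)
  tp_node(tape, out, bw = function(nd) {
    acc_grad(x, (2 / n) * d * nd$grad)
  })
}

# Weighted sum of scalar nodes.
op_wsum <- function(tape, nodes, weights) {
  out <- sum(vapply(nodes, function(nd) nd$v, numeric(1)) * weights)
  if (!tape$record) return(tp_node(tape, out))
  tp_node(tape, out, bw = function(nd) {
    for (i in seq_along(nodes)) acc_grad(nodes[[i]], weights[i] * nd$grad)
  })
}

# Optimizer -------------------------------------------------------------

# One Adam update over a list of leaves; leaves with no accumulated gradient
# or with frozen = TRUE are skipped.  Gradients are cleared afterwards.
adam_step <- function(params, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (isTRUE(p$frozen) || is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) {
      p$m <- g * 0
      p$u <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$u <- beta2 * p$u + (1 - beta2) * (g * g)
    mhat <- p$m / (1 - beta1^t)
    uhat <- p$u / (1 - beta2^t)
    p$v <- p$v - lr * mhat / (sqrt(uhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
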
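# Minimal tape-based reverse-mode automatic differentiation over (C,H,W)
# arrays.  Nodes are environments recorded on a tape in creation order;
# backward() walks the tape in reverse.  Parameters live outside the tape
# (environments with $value/$grad plus Adam state) so one parameter can be
# used at several tape positions and across iterations.
#
# All ops accept either tape = NULL (pure forward, plain arrays in and out,
# used at inference time) or a tape (nodes in and out).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

ag_is_node <- function(x) is.environment(x) && !is.null(x$ag_value)

ag_val <- function(x) if (ag_is_node(x)) x$ag_value else x

ag_node <- function(tape, value, parents = list(), backfn = NULL, param = NULL) {
  if (is.null(tape)) return(value)
  nd <- new.env(parent = emptyenv())
  nd$ag_value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_accum <- function(nd, g) {
  if (!ag_is_node(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run backward from a scalar root; parameter gradients are accumulated into
# each parameter environment's $grad.
ag_backward <- function(tape, root) {
  stopifnot(ag_is_node(root))
  root$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backfn)) nd$backfn(nd)
    if (!is.null(nd$param)) {
      nd$param$grad <- if (is.null(nd$param$grad)) nd$grad else nd$param$grad + nd$grad
    }
  }
  invisible(NULL)
}

# -- parameters ---------------------------------------------------------------

ag_parameter <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- 0
  p$v <- 0
  class(p) <- "ag_parameter"
  p
}

ag_use <- function(tape, param) {
  if (is.null(tape)) return(param$value)
  ag_node(tape, param$value, param = param)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# One Adam update over a flat list of parameters.
ag_adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         t = 1) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# -- ops ----------------------------------------------------------------------

ag_conv2d <- function(tape, x, w, b, stride = 1L, pad = 0L) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  out <- cpp_conv2d(xv, wv, bv, as.integer(stride), as.integer(pad),
                    as.integer(pad))
  ag_node(tape, out, parents = list(x, w, b), backfn = function(nd) {
    gr <- cpp_conv2d_bwd(xv, wv, nd$grad, as.integer(stride),
                         as.integer(pad), as.integer(pad))
    ag_accum(nd$parents[[1]], gr$gx)
    ag_accum(nd$parents[[2]], gr$gw)
    ag_accum(nd$parents[[3]], gr$gb)
  })
}

ag_snake <- function(tape, x, w, b, off, axis = 1L) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b); ov <- ag_val(off)
  out <- cpp_snake(xv, wv, bv, ov, as.integer(axis))
  ag_node(tape, out, parents = list(x, w, b, off), backfn = function(nd) {
    gr <- cpp_snake_bwd(xv, wv, ov, as.integer(axis), nd$grad)
    ag_accum(nd$parents[[1]], gr$gx)
    ag_accum(nd$parents[[2]], gr$gw)
    ag_accum(nd$parents[[3]], gr$gb)
    ag_accum(nd$parents[[4]], gr$goff)
  })
}

ag_silu <- function(tape, x) {
  xv <- ag_val(x)
  s <- 1 / (1 + exp(-xv))
  out <- xv * s
  ag_node(tape, out, parents = list(x), backfn = function(nd) {
    ag_accum(nd$parents[[1]], nd$grad * (s * (1 + xv * (1 - s))))
  })
}

ag_add <- function(tape, a, b) {
  out <- ag_val(a) + ag_val(b)
  ag_node(tape, out, parents = list(a, b), backfn = function(nd) {
    ag_accum(nd$parents[[1]], nd$grad)
    ag_accum(nd$parents[[2]], nd$grad)
  })
}

# Concatenate along the channel dimension.
ag_concat <- function(tape, xs) {
  vals <- lapply(xs, ag_val)
  dims <- vapply(vals, function(v) dim(v)[1], integer(1))
  H <- dim(vals[[1]])[2]; W <- dim(vals[[1]])[3]
  out <- array(0, dim = c(sum(dims), H, W))
  at <- 0L
  for (v in vals) {
    out[at + seq_len(dim(v)[1]), , ] <- v
    at <- at + dim(v)[1]
  }
  ag_node(tape, out, parents = xs, backfn = function(nd) {
    at <- 0L
    for (j in seq_along(nd$parents)) {
      ag_accum(nd$parents[[j]], nd$grad[at + seq_len(dims[j]), , , drop = FALSE])
      at <- at + dims[j]
    }
  })
}

ag_slice_channels <- function(tape, x, idx) {
  xv <- ag_val(x)
  out <- xv[idx, , , drop = FALSE]
  ag_node(tape, out, parents = list(x), backfn = function(nd) {
    g <- array(0, dim = dim(xv))
    g[idx, , ] <- nd$grad
    ag_accum(nd$parents[[1]], g)
  })
}

ag_upsample2x <- function(tape, x) {
  out <- cpp_upsample2x(ag_val(x))
  ag_node(tape, out, parents = list(x), backfn = function(nd) {
    ag_accum(nd$parents[[1]], cpp_upsample2x_bwd(nd$grad))
  })
}

# Scalar node carrying an externally computed loss value together with its
# (already evaluated) gradient with respect to `x`.  Lets the detection-loss
# layer, which works on decoded grid values, plug into the tape.
ag_adjoint <- function(tape, x, value, grad_wrt_x) {
  force(grad_wrt_x)  # promises must not outlive the caller's loop iteration
  ag_node(tape, value, parents = list(x), backfn = function(nd) {
    ag_accum(nd$parents[[1]], nd$grad * grad_wrt_x)
  })
}

ag_sum_scalars <- function(tape, xs) {
  out <- sum(vapply(xs, function(x) as.numeric(ag_val(x)), numeric(1)))
  ag_node(tape, out, parents = xs, backfn = function(nd) {
    for (p in nd$parents) ag_accum(p, nd$grad)
  })
}
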
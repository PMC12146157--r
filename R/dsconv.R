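# Dynamic snake convolution: vector-quantized kernels with fitted
# distribution shifts (KDS per weight block, CDS per output channel),
# serpentine sampling with learnable per-tap offsets, and the C2f blocks
# built from them.

#' Feature map container
#'
#' A 3-D real-valued grid indexed (channel, row, column) together with its
#' stride relative to the input image.
#'
#' @param values Numeric array with \code{dim = c(channels, height, width)}.
#' @param stride Integer power of two; spatial downscaling factor relative to
#'   the network input.
#' @return A \code{feature_map} object.
#' @export
feature_map <- function(values, stride = 1L) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3-D array (channel, row, column)")
  if (any(dim(values) < 1)) stop("all feature-map dimensions must be >= 1")
  if (!all(is.finite(values))) stop("feature map contains non-finite values")
  structure(list(values = values, stride = as.integer(stride)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map %d x %d x %d, stride %d>\n", d[1], d[2], d[3],
              x$stride))
  invisible(x)
}

as_fm_values <- function(x) {
  if (inherits(x, "feature_map")) x$values else x
}

#' Quantization specification for vector-quantized kernels
#'
#' @param bits Integer bit width \code{b >= 2}; quantized values are integers
#'   in \code{[-2^(b-1), 2^(b-1) - 1]}.
#' @param block_size Block length BLK over which the kernel distribution
#'   shift (scale and bias) is fitted; default 64.
#' @return A \code{quant_spec} object.
#' @export
quant_spec <- function(bits = 8L, block_size = 64L) {
  bits <- as.integer(bits); block_size <- as.integer(block_size)
  if (bits < 2L) stop("bits must be >= 2")
  if (block_size < 1L) stop("block_size must be >= 1")
  structure(list(bits = bits, block_size = block_size), class = "quant_spec")
}

round_half_even <- function(x) round(x)  # base R rounds half to even

#' Quantize weights onto a signed integer grid
#'
#' Linearly maps the weight range onto the signed \code{bits}-bit integer
#' grid \code{[-2^(b-1), 2^(b-1) - 1]} and rounds half to even.  The step is
#' chosen so the largest-magnitude weight maps to the edge of the grid; an
#' all-zero block falls back to a step of 1.
#'
#' @param weights Finite numeric vector.
#' @param spec A \code{\link{quant_spec}} (or integer bit count).
#' @param step Optional explicit quantization step; overrides the automatic
#'   range fit.
#' @return Integer vector of quantized values with attribute \code{"step"}.
#' @export
quantize_vqk <- function(weights, spec = quant_spec(), step = NULL) {
  if (is.numeric(spec)) spec <- quant_spec(bits = spec)
  if (!all(is.finite(weights))) stop("weights must be finite")
  b <- spec$bits
  qlo <- -2^(b - 1); qhi <- 2^(b - 1) - 1
  if (is.null(step)) {
    m <- max(abs(weights))
    step <- if (m == 0) 1 else m / qhi
  }
  wq <- round_half_even(weights / step)
  wq <- pmin(pmax(wq, qlo), qhi)
  structure(as.integer(wq), step = step)
}

#' Admissible integer range at a given bit width
#' @param bits Integer bit count.
#' @return \code{c(lo, hi)} = \code{c(-2^(b-1), 2^(b-1) - 1)}.
#' @export
quant_range <- function(bits) c(-2^(bits - 1), 2^(bits - 1) - 1)

#' Fit the kernel distribution shift (KDS)
#'
#' Per block of \code{block_size} weights, the scale \eqn{\xi} is the
#' closed-form least-squares minimizer of
#' \eqn{\sum_i (w_{q,i}\,\hat\xi - w_i)^2}, i.e.
#' \eqn{\xi = \sum w_q w / \sum w_q^2}, and the bias \eqn{\xi_s} is the mean
#' residual \eqn{\overline{w - \xi w_q}}.  A block with
#' \eqn{\sum w_q^2 = 0} uses \eqn{\xi = 1}, \eqn{\xi_s = \bar w}.
#'
#' @param original Numeric vector of original weights.
#' @param quantized Integer vector from \code{\link{quantize_vqk}}, same
#'   length.
#' @param block_size Block length BLK (last block may be shorter).
#' @return List with per-block \code{scale}, \code{bias}, and
#'   \code{block_size}.
#' @export
fit_kds <- function(original, quantized, block_size = 64L) {
  if (length(original) != length(quantized))
    stop("original and quantized must have the same length")
  n <- length(original)
  nb <- ceiling(n / block_size)
  scale <- numeric(nb); bias <- numeric(nb)
  for (j in seq_len(nb)) {
    idx <- ((j - 1) * block_size + 1):min(j * block_size, n)
    w <- original[idx]; wq <- as.numeric(quantized[idx])
    ss <- sum(wq^2)
    if (ss == 0) {
      scale[j] <- 1; bias[j] <- mean(w)
    } else {
      scale[j] <- sum(wq * w) / ss
      bias[j] <- mean(w - scale[j] * wq)
    }
  }
  list(scale = scale, bias = bias, block_size = as.integer(block_size))
}

#' Dequantize with a fitted KDS
#'
#' @param quantized Integer vector of quantized weights.
#' @param kds Fit from \code{\link{fit_kds}}.
#' @return Numeric vector \eqn{\xi w_q + \xi_s} applied blockwise.
#' @export
dequantize_kds <- function(quantized, kds) {
  n <- length(quantized)
  out <- numeric(n)
  for (j in seq_along(kds$scale)) {
    idx <- ((j - 1) * kds$block_size + 1):min(j * kds$block_size, n)
    out[idx] <- kds$scale[j] * as.numeric(quantized[idx]) + kds$bias[j]
  }
  out
}

#' Snake kernel specification
#'
#' A snake (serpentine) kernel has \code{kernel_size} taps marching along one
#' image axis while a learnable fractional offset displaces each tap along
#' the perpendicular axis; offsets are clamped to
#' \code{[-offset_clamp, offset_clamp]}.
#'
#' @param kernel_size Odd integer number of taps.
#' @param offsets Numeric vector of per-tap offsets (recycled scalar 0 by
#'   default); clamped on construction.
#' @param axis \code{"horizontal"} (taps step in x, offsets in y) or
#'   \code{"vertical"} (roles swapped).
#' @param offset_clamp Nonnegative clamp bound, default 1.
#' @return A \code{snake_kernel_spec} object.
#' @export
snake_kernel_spec <- function(kernel_size = 3L, offsets = 0,
                              axis = c("horizontal", "vertical"),
                              offset_clamp = 1) {
  axis <- match.arg(axis)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be a positive odd integer")
  if (offset_clamp < 0) stop("offset_clamp must be >= 0")
  offsets <- rep_len(offsets, kernel_size)
  offsets <- pmin(pmax(offsets, -offset_clamp), offset_clamp)
  structure(list(kernel_size = kernel_size, offsets = offsets, axis = axis,
                 offset_clamp = offset_clamp),
            class = "snake_kernel_spec")
}

#' Sample positions of a snake kernel centered at a point
#'
#' Tap \eqn{c \in \{-(k-1)/2, \dots, (k-1)/2\}} of a horizontal kernel
#' centered at \eqn{(x_i, y_i)} samples at \eqn{(x_i + c,\; y_i + \Delta y_c)};
#' a vertical kernel swaps the roles of x and y.  Positions may be
#' fractional.
#'
#' @param center Numeric \code{c(x, y)}.
#' @param spec A \code{\link{snake_kernel_spec}}.
#' @return Data frame with columns \code{tap}, \code{x}, \code{y}.
#' @export
snake_sample_positions <- function(center, spec) {
  stopifnot(inherits(spec, "snake_kernel_spec"))
  k <- spec$kernel_size
  cs <- seq_len(k) - 1L - (k - 1L) %/% 2L
  if (spec$axis == "horizontal") {
    data.frame(tap = cs, x = center[1] + cs, y = center[2] + spec$offsets)
  } else {
    data.frame(tap = cs, x = center[1] + spec$offsets, y = center[2] + cs)
  }
}

#' Apply a snake convolution to a feature map
#'
#' Each tap samples the input at its serpentine position by linear
#' interpolation (zero padding outside the grid), multiplies by the kernel
#' weight and accumulates.  When a \code{\link{quant_spec}} is given, the
#' weights are first vector-quantized, reconstructed through the fitted
#' kernel distribution shift (KDS, per block) and then corrected by a
#' channel distribution shift (CDS): a per-output-channel affine fit of the
#' reconstructed weights against the originals by the same least-squares
#' recipe.
#'
#' @param input A \code{\link{feature_map}} (or 3-D array).
#' @param weights Numeric array \code{dim = c(out_channels, in_channels, k)}.
#' @param spec A \code{\link{snake_kernel_spec}} with \code{kernel_size = k}.
#' @param bias Optional per-output-channel bias (default zeros).
#' @param quant Optional \code{\link{quant_spec}} activating the quantized
#'   path.
#' @return A \code{feature_map} at the input stride and spatial size.
#' @export
dsconv_apply <- function(input, weights, spec, bias = NULL, quant = NULL) {
  x <- as_fm_values(input)
  stride <- if (inherits(input, "feature_map")) input$stride else 1L
  if (!is.array(weights) || length(dim(weights)) != 3)
    stop("weights must be a 3-D array (out, in, taps)")
  d <- dim(weights)
  if (d[2] != dim(x)[1])
    stop(sprintf("shape mismatch: input has %d channels, weights expect %d",
                 dim(x)[1], d[2]))
  if (d[3] != spec$kernel_size)
    stop("weights tap count does not match kernel_size")
  if (is.null(bias)) bias <- numeric(d[1])
  w <- weights
  if (!is.null(quant)) {
    flat <- as.numeric(w)
    wq <- quantize_vqk(flat, quant)
    kds <- fit_kds(flat, wq, quant$block_size)
    deq <- dequantize_kds(wq, kds)
    w <- array(deq, dim = d)
    # CDS: per-output-channel affine correction against the original weights
    for (o in seq_len(d[1])) {
      wo <- as.numeric(weights[o, , ]); dq <- as.numeric(w[o, , ])
      ss <- sum(dq^2)
      phi <- if (ss == 0) 1 else sum(dq * wo) / ss
      phis <- mean(wo - phi * dq)
      w[o, , ] <- phi * w[o, , ] + phis
    }
  }
  axis <- if (spec$axis == "horizontal") 1L else 2L
  out <- cpp_snake(x, w, bias, spec$offsets, axis)
  feature_map(out, stride = stride)
}

# -- trainable layers ---------------------------------------------------------

# A conv layer descriptor: mode "dense" (kh x kw, stride, SAME padding) or
# "snake" (k taps, stride 1, learnable offsets).  act = TRUE appends SiLU.
new_conv_layer <- function(cin, cout, k = 3L, stride = 1L,
                           mode = c("dense", "snake"), axis = 1L, act = TRUE,
                           offset_clamp = 1) {
  mode <- match.arg(mode)
  fan_in <- if (mode == "dense") cin * k * k else cin * k
  sd <- sqrt(2 / fan_in)
  if (mode == "dense") {
    w <- ag_parameter(array(stats::rnorm(cout * cin * k * k, sd = sd),
                            dim = c(cout, cin, k, k)))
  } else {
    w <- ag_parameter(array(stats::rnorm(cout * cin * k, sd = sd),
                            dim = c(cout, cin, k)))
  }
  b <- ag_parameter(numeric(cout))
  off <- if (mode == "snake") ag_parameter(numeric(k)) else NULL
  list(mode = mode, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), axis = as.integer(axis), act = act,
       offset_clamp = offset_clamp, w = w, b = b, off = off)
}

layer_forward <- function(tape, layer, x) {
  if (layer$mode == "dense") {
    out <- ag_conv2d(tape, x, ag_use(tape, layer$w), ag_use(tape, layer$b),
                     stride = layer$stride, pad = (layer$k - 1L) %/% 2L)
  } else {
    out <- ag_snake(tape, x, ag_use(tape, layer$w), ag_use(tape, layer$b),
                    ag_use(tape, layer$off), axis = layer$axis)
  }
  if (layer$act) out <- ag_silu(tape, out) else out
}

layer_params <- function(layer) {
  ps <- list(layer$w, layer$b)
  if (!is.null(layer$off)) ps <- c(ps, list(layer$off))
  ps
}

# Clamp snake offsets in place after an optimizer step.
clamp_layer_offsets <- function(layer) {
  if (!is.null(layer$off)) {
    cl <- layer$offset_clamp
    layer$off$value <- pmin(pmax(layer$off$value, -cl), cl)
  }
  invisible(NULL)
}

#' Build a C2f block (optionally with snake convolutions)
#'
#' The C2f topology: a channel-expanding convolution, a split into two
#' halves, \code{n} bottlenecks applied sequentially to the second half
#' (each bottleneck = two convolutions with a residual connection, their
#' outputs all retained), concatenation of every intermediate, and a final
#' projection convolution.  With \code{dsconv = TRUE} every convolution in
#' the block — the pre/post channel-adjust convolutions and both bottleneck
#' convolutions — is a snake convolution, with horizontal and vertical axes
#' alternating across the two bottleneck convolutions.
#'
#' @param c_in,c_out Input and output channel counts.
#' @param n Number of bottlenecks.
#' @param dsconv Use snake convolutions throughout (the C2f-DSConv variant).
#' @param k Tap count / kernel size for the bottleneck convolutions.
#' @return A \code{c2f_block} list of layers; apply with
#'   \code{\link{c2f_dsconv_forward}}.
#' @export
c2f_block <- function(c_in, c_out, n = 1L, dsconv = TRUE, k = 3L) {
  h <- max(1L, c_out %/% 2L)
  mode <- if (dsconv) "snake" else "dense"
  k1 <- if (dsconv) k else 1L  # channel-adjust convs: 1x1 dense or k-tap snake
  cv1 <- new_conv_layer(c_in, 2L * h, k = k1, mode = mode, axis = 1L)
  bns <- vector("list", n)
  for (i in seq_len(n)) {
    bns[[i]] <- list(
      a = new_conv_layer(h, h, k = k, mode = mode, axis = 1L),
      b = new_conv_layer(h, h, k = k, mode = mode, axis = 2L))
  }
  cv2 <- new_conv_layer((2L + n) * h, c_out, k = k1, mode = mode, axis = 2L)
  structure(list(cv1 = cv1, bottlenecks = bns, cv2 = cv2, hidden = h,
                 c_in = c_in, c_out = c_out, n = as.integer(n),
                 dsconv = dsconv),
            class = "c2f_block")
}

c2f_forward_node <- function(tape, block, x) {
  y <- layer_forward(tape, block$cv1, x)
  h <- block$hidden
  a <- ag_slice_channels(tape, y, seq_len(h))
  b <- ag_slice_channels(tape, y, h + seq_len(h))
  parts <- list(a, b)
  cur <- b
  for (bn in block$bottlenecks) {
    t1 <- layer_forward(tape, bn$a, cur)
    t2 <- layer_forward(tape, bn$b, t1)
    cur <- ag_add(tape, cur, t2)
    parts <- c(parts, list(cur))
  }
  cat_out <- ag_concat(tape, parts)
  layer_forward(tape, block$cv2, cat_out)
}

#' Apply a C2f block to a feature map
#'
#' Spatial size is preserved (all convolutions are stride 1 with SAME
#' padding).
#'
#' @param input A \code{\link{feature_map}} or 3-D array.
#' @param block A \code{\link{c2f_block}}.
#' @return A \code{feature_map} at the input stride.
#' @export
c2f_dsconv_forward <- function(input, block) {
  stopifnot(inherits(block, "c2f_block"))
  x <- as_fm_values(input)
  if (dim(x)[1] != block$c_in)
    stop(sprintf("channel mismatch: input has %d channels, block expects %d",
                 dim(x)[1], block$c_in))
  stride <- if (inherits(input, "feature_map")) input$stride else 1L
  feature_map(c2f_forward_node(NULL, block, x), stride = stride)
}

c2f_params <- function(block) {
  ps <- c(layer_params(block$cv1), layer_params(block$cv2))
  for (bn in block$bottlenecks) ps <- c(ps, layer_params(bn$a), layer_params(bn$b))
  ps
}

#' Count trainable parameters
#'
#' @param x A \code{c2f_block} or \code{vb_detector}.
#' @return Total number of scalar trainable parameters.
#' @export
n_params <- function(x) {
  ps <- if (inherits(x, "c2f_block")) c2f_params(x)
        else if (inherits(x, "vb_detector")) detector_params(x)
        else stop("unsupported object")
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}
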
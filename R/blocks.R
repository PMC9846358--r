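# Reusable network building blocks: Hard-Swish / ReLU6 activations, channel
# shuffle, the shuffle block and inverted shuffle block, CBAM attention and
# the SPPF pyramid-pooling unit.
#
# Feature maps are numeric arrays with dim = c(height, width, channels);
# blocks never modify their inputs in place.

#' ReLU6 activation
#'
#' `min(max(x, 0), 6)`, applied element-wise.
#'
#' @param x numeric vector or array.
#' @return object of the same shape.
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' Hard-Swish activation
#'
#' `x * ReLU6(x + 3) / 6`, applied element-wise: a piecewise-polynomial
#' approximation of SiLU that is cheap on embedded hardware. It equals the
#' identity for `x >= 3`, is zero for `x <= -3`, and is bounded below by
#' -0.375.
#'
#' @param x numeric vector or array.
#' @return object of the same shape.
#' @examples
#' hard_swish(c(-3, 0, 1, 3))   # 0, 0, 2/3, 3
#' @export
hard_swish <- function(x) x * relu6(x + 3) / 6

#' Interleave channel groups (channel shuffle)
#'
#' Reshapes the channel axis to (groups, C/groups), transposes, and
#' flattens, so consecutive grouped convolutions exchange information
#' between groups. Output channel `j * g + i` (0-based) is input channel
#' `i * (C/g) + j`. Spatial values are untouched; the operation is a
#' bijection on channel indices.
#'
#' @param x feature map, array with dim = c(H, W, C).
#' @param groups positive integer dividing C.
#' @return shuffled feature map of identical shape.
#' @export
channel_shuffle <- function(x, groups) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (d[3] %% groups != 0)
    stop("invalid configuration: channels (", d[3],
         ") not divisible by groups (", groups, ")")
  x[, , shuffle_perm(d[3], groups), drop = FALSE]
}

# the permutation applied by channel_shuffle: out position -> in channel
# (reshape channels to (groups, C/groups), transpose, flatten)
shuffle_perm <- function(C, groups) {
  as.vector(t(matrix(seq_len(C), ncol = groups)))
}

#' Conv + BatchNorm + Hard-Swish unit (CBH)
#'
#' The basic convolution unit of the backbone and neck. Padding is
#' `kernel %/% 2` (same-size convention); spatial size divides by the
#' stride exactly or the forward pass errors.
#'
#' @param in_channels,out_channels positive integers.
#' @param kernel odd positive integer.
#' @param stride 1 or 2.
#' @param act activation name ("hardswish", "silu", "relu", "linear").
#' @return a module; apply with [block_forward()].
#' @export
cbh <- function(in_channels, out_channels, kernel = 3, stride = 1,
                act = "hardswish") {
  stopifnot(kernel %% 2 == 1)
  pn_conv(in_channels, out_channels, k = kernel, s = stride, act = act)
}

# depthwise 3x3 (BN, no nonlinearity — ShuffleNet convention) followed
# nowhere; pointwise convs carry the block's activation.
dwconv <- function(c, stride) {
  pn_conv(c, c, k = 3, s = stride, groups = c, act = "linear")
}

#' Shuffle block
#'
#' The shallow-stage unit. With stride 1 the input is split into two channel
#' halves: one half passes 1x1 conv -> 3x3 depthwise conv -> 1x1 conv, the
#' other passes through untouched; the halves are concatenated and channel-
#' shuffled (groups = 2). With stride 2 there is no split: the main branch is
#' as above with a stride-2 depthwise conv, the second branch is a stride-2
#' 3x3 depthwise conv followed by a 1x1 conv, and the concatenation doubles
#' the channel count while the spatial size halves.
#'
#' @param in_channels input channel count (even when stride = 1).
#' @param stride 1 or 2.
#' @param act activation for the pointwise convolutions.
#' @return a module.
#' @export
shuffle_block <- function(in_channels, stride = 1, act = "hardswish") {
  stopifnot(stride %in% c(1, 2))
  m <- new_module("shuffle_block")
  m$stride <- stride
  m$cin <- in_channels
  if (stride == 1) {
    if (in_channels %% 2 != 0)
      stop("invalid configuration: stride-1 shuffle block needs even channels")
    h <- in_channels %/% 2
    m$children$pw1 <- pn_conv(h, h, k = 1, act = act)
    m$children$dw <- dwconv(h, 1)
    m$children$pw2 <- pn_conv(h, h, k = 1, act = act)
    m$cout <- in_channels
  } else {
    c <- in_channels
    m$children$pw1 <- pn_conv(c, c, k = 1, act = act)
    m$children$dw <- dwconv(c, 2)
    m$children$pw2 <- pn_conv(c, c, k = 1, act = act)
    m$children$dw_b <- dwconv(c, 2)
    m$children$pw_b <- pn_conv(c, c, k = 1, act = act)
    m$cout <- 2 * in_channels
  }
  m$call <- function(x) {
    ch <- m$children
    if (m$stride == 1) {
      h <- m$cin %/% 2
      keep <- op_take_channels(x, seq_len(h))
      main <- pn_call(ch$pw2, pn_call(ch$dw, pn_call(ch$pw1,
        op_take_channels(x, (h + 1):m$cin))))
      out <- op_concat(list(keep, main))
    } else {
      main <- pn_call(ch$pw2, pn_call(ch$dw, pn_call(ch$pw1, x)))
      side <- pn_call(ch$pw_b, pn_call(ch$dw_b, x))
      out <- op_concat(list(side, main))
    }
    op_shuffle2(out)
  }
  m
}

op_shuffle2 <- function(x) {
  if (is_shape(x)) return(x)
  ag_permute_c(x, shuffle_perm(dim(as_value(x))[3], 2))
}

#' Inverted shuffle block
#'
#' The deep-stage unit. Structured like [shuffle_block()], but the processing
#' branch is an inverted residual bottleneck: a 1x1 pointwise convolution
#' first *reduces* the width by the ratio `t`, a 3x3 depthwise convolution
#' filters it, and a final 1x1 convolution restores the width. Every branch's
#' final projection uses a linear activation so the narrow representation is
#' not clipped. The stride-2 variant adds a 3x3 depthwise + linear pointwise
#' conv on the second branch, and the concatenation is channel-shuffled.
#'
#' @param in_channels input channel count.
#' @param stride 1 or 2.
#' @param expansion bottleneck ratio t > 1; the branch narrows to
#'   `channels / t` before being restored.
#' @param act activation for the non-linear pointwise convolutions.
#' @return a module.
#' @export
inverted_shuffle_block <- function(in_channels, stride = 1, expansion = 2,
                                   act = "hardswish") {
  stopifnot(stride %in% c(1, 2), expansion > 1)
  m <- new_module("inverted_shuffle_block")
  m$stride <- stride
  m$cin <- in_channels
  mid <- function(c) max(1L, as.integer(round(c / expansion)))
  if (stride == 1) {
    if (in_channels %% 2 != 0)
      stop("invalid configuration: stride-1 block needs even channels")
    h <- in_channels %/% 2
    m$children$pw1 <- pn_conv(h, mid(h), k = 1, act = act)
    m$children$dw <- dwconv(mid(h), 1)
    m$children$pw2 <- pn_conv(mid(h), h, k = 1, act = "linear")
    m$cout <- in_channels
  } else {
    c <- in_channels
    m$children$pw1 <- pn_conv(c, mid(c), k = 1, act = act)
    m$children$dw <- dwconv(mid(c), 2)
    m$children$pw2 <- pn_conv(mid(c), c, k = 1, act = "linear")
    m$children$dw_b <- dwconv(c, 2)
    m$children$pw_b <- pn_conv(c, c, k = 1, act = "linear")
    m$cout <- 2 * in_channels
  }
  m$call <- function(x) {
    ch <- m$children
    if (m$stride == 1) {
      h <- m$cin %/% 2
      keep <- op_take_channels(x, seq_len(h))
      main <- pn_call(ch$pw2, pn_call(ch$dw, pn_call(ch$pw1,
        op_take_channels(x, (h + 1):m$cin))))
      out <- op_concat(list(keep, main))
    } else {
      main <- pn_call(ch$pw2, pn_call(ch$dw, pn_call(ch$pw1, x)))
      side <- pn_call(ch$pw_b, pn_call(ch$dw_b, x))
      out <- op_concat(list(side, main))
    }
    op_shuffle2(out)
  }
  m
}

#' Convolutional block attention module (CBAM)
#'
#' Channel attention first: global average and global max pooling produce two
#' C-vectors that pass through one shared two-layer perceptron (reduction
#' ratio `reduction`), are summed and squashed by a sigmoid into channel
#' weights. Spatial attention second: per-pixel mean and max over channels
#' form a 2-channel map, a 7x7 convolution and sigmoid produce a spatial
#' mask. The attention-refined map is added back onto the input (residual).
#'
#' @param channels input/output channel count.
#' @param reduction perceptron bottleneck ratio (default 16).
#' @return a module; output shape equals input shape.
#' @export
cbam <- function(channels, reduction = 16) {
  m <- new_module("cbam")
  hidden <- max(1L, channels %/% reduction)
  m$children$fc1 <- pn_conv(channels, hidden, k = 1, act = "relu",
                            bn = FALSE, bias = TRUE)
  m$children$fc2 <- pn_conv(hidden, channels, k = 1, act = "linear",
                            bn = FALSE, bias = TRUE)
  m$children$spatial <- pn_conv(2, 1, k = 7, act = "linear",
                                bn = FALSE, bias = TRUE)
  m$call <- function(x) {
    ch <- m$children
    if (is_shape(x)) {
      # attention convs still count toward FLOPs (at their own tiny sizes)
      s1 <- make_shape(x$c, 1, 1, x$tally)
      pn_call(ch$fc2, pn_call(ch$fc1, s1))
      pn_call(ch$spatial, make_shape(2, x$h, x$w, x$tally))
      return(x)
    }
    mlp <- function(v) pn_call(ch$fc2, pn_call(ch$fc1, v))
    wc <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
    xc <- ag_scale_channels(x, wc)
    sm <- ag_sigmoid(pn_call(ch$spatial,
                             ag_concat_c(list(ag_chan_mean(xc), ag_chan_max(xc)))))
    refined <- ag_scale_spatial(xc, sm)
    ag_add(x, refined)
  }
  m
}

#' Spatial pyramid pooling, fast variant (SPPF)
#'
#' A 1x1 convolution halves the channel width, three chained 5x5 stride-1
#' max-pools widen the receptive field, the four stages are concatenated
#' (4 x C/2 channels) and a final 1x1 convolution maps to the output width.
#' Spatial size is preserved.
#'
#' @param in_channels,out_channels channel counts.
#' @param act activation of the two convolutions.
#' @return a module.
#' @export
sppf <- function(in_channels, out_channels, act = "hardswish") {
  m <- new_module("sppf")
  half <- in_channels %/% 2
  m$children$cv1 <- pn_conv(in_channels, half, k = 1, act = act)
  m$children$pool <- pn_maxpool(5, 1, 2)
  m$children$cv2 <- pn_conv(4 * half, out_channels, k = 1, act = act)
  m$call <- function(x) {
    ch <- m$children
    a <- pn_call(ch$cv1, x)
    b <- pn_call(ch$pool, a)
    c <- pn_call(ch$pool, b)
    d <- pn_call(ch$pool, c)
    pn_call(ch$cv2, op_concat(list(a, b, c, d)))
  }
  m
}

#' Run a block on a feature-map array
#'
#' Convenience wrapper for applying a single module outside a training loop:
#' wraps the array, runs the module in evaluation mode without gradient
#' recording, and returns a plain array.
#'
#' @param module a module built by [cbh()], [shuffle_block()], etc.
#' @param x numeric array with dim = c(H, W, C).
#' @return numeric array.
#' @export
block_forward <- function(module, x) {
  stopifnot(length(dim(x)) == 3)
  no_grad(as_value(pn_call(module, ag_const(x))))
}

#' Shape contract of a block
#'
#' Propagates a (channels, height, width) shape through a module without
#' computing values and returns the output shape plus the per-convolution
#' MAC tally used by [count_flops()].
#'
#' @param module a module.
#' @param channels,height,width input shape.
#' @return list with `channels`, `height`, `width`, and a `layers` data frame.
#' @export
block_shape <- function(module, channels, height, width) {
  s <- pn_call(module, make_shape(channels, height, width))
  list(channels = s$c, height = s$h, width = s$w,
       layers = do.call(rbind, s$tally$rows))
}
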
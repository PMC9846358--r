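# Neural-network module protocol.
#
# A module is an environment with named parameter tensors in `$params`,
# child modules in `$children`, and a `$call(x)` closure. `x` is either a
# `pn_tensor` feature map (dim = H, W, C) or a `pn_shape`, in which case the
# module propagates shapes only and logs every convolution into the shape's
# tally — this single code path feeds both the forward pass and the
# FLOPs/parameter accounting.

.pn$training <- FALSE
.pn$bn_frozen <- FALSE

set_training <- function(on) {
  old <- .pn$training
  .pn$training <- on
  invisible(old)
}

is_training <- function() .pn$training

# When frozen, batch norm uses its running statistics in the training
# forward pass too (and stops updating them). With single-image batches the
# batch statistics differ per illumination regime while evaluation sees one
# pooled running estimate; freezing partway through training removes that
# train/eval gap — the usual small-batch measure in detection training.
set_bn_frozen <- function(on) {
  old <- .pn$bn_frozen
  .pn$bn_frozen <- on
  invisible(old)
}

bn_frozen <- function() .pn$bn_frozen

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("pn_", type), "pn_module")
  m
}

pn_call <- function(m, x) m$call(x)

#' @export
print.pn_module <- function(x, ...) {
  cat("<pn_module:", x$type, "> params:", n_params(x), "\n")
  invisible(x)
}

# ---- shape tracing ----------------------------------------------------------

make_shape <- function(c, h, w, tally = NULL) {
  if (is.null(tally)) {
    tally <- new.env(parent = emptyenv())
    tally$rows <- list()
  }
  structure(list(c = c, h = h, w = w, tally = tally), class = "pn_shape")
}

is_shape <- function(x) inherits(x, "pn_shape")

tally_conv <- function(shape_out, k, cin, cout, groups) {
  t <- shape_out$tally
  cin_eff <- cin / groups          # depthwise/grouped: C_{i-1} per group
  t$rows[[length(t$rows) + 1L]] <- data.frame(
    L = shape_out$h, K = k, C_out = cout, C_in = cin_eff,
    macs = shape_out$h^2 * k^2 * cout * cin_eff)
  invisible(shape_out)
}

# ---- parameter bookkeeping --------------------------------------------------

collect_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children))
    out <- c(out, collect_params(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive modules ------------------------------------------------------

# Conv -> BatchNorm -> activation unit (CBH when act = "hardswish",
# CBS when act = "silu"). bias defaults to on only when BN is absent.
pn_conv <- function(cin, cout, k = 1, s = 1, p = k %/% 2, groups = 1,
                    act = "hardswish", bn = TRUE, bias = !bn) {
  m <- new_module("conv")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$s <- s; m$p <- p
  m$groups <- groups; m$act <- act; m$bn <- bn
  cpg <- cin / groups
  stopifnot(cpg == round(cpg), cout %% groups == 0)
  fan_in <- k * k * cpg
  m$params$w <- ag_param(array(stats::rnorm(k * k * cpg * cout, 0,
                                            sqrt(2 / fan_in)),
                               dim = c(k, k, cpg, cout)))
  if (bias) m$params$b <- ag_param(numeric(cout))
  if (bn) {
    m$params$gamma <- ag_param(rep(1, cout))
    m$params$beta <- ag_param(numeric(cout))
    m$running <- new.env(parent = emptyenv())
    m$running$mean <- numeric(cout)
    m$running$var <- rep(1, cout)
    m$bn_eps <- 1e-3
    m$bn_momentum <- 0.03
  }
  m$call <- function(x) {
    if (is_shape(x)) {
      stopifnot(x$c == cin)
      if (s > 1 && (x$h %% s != 0 || x$w %% s != 0))
        stop("invalid configuration: non-integer output size (",
             x$h, "x", x$w, " not divisible by stride ", s, ")")
      ho <- (x$h + 2 * p - k) %/% s + 1
      wo <- (x$w + 2 * p - k) %/% s + 1
      if (ho <= 0 || wo <= 0)
        stop("invalid configuration: non-positive output size")
      out <- make_shape(cout, ho, wo, x$tally)
      return(tally_conv(out, k, cin, cout, groups))
    }
    y <- ag_conv2d(x, m$params$w, m$params$b, s, p, groups)
    if (bn)
      y <- ag_batchnorm(y, m$params$gamma, m$params$beta, m$running,
                        m$bn_eps, m$bn_momentum,
                        is_training() && !bn_frozen())
    ag_act(y, act)
  }
  m
}

pn_maxpool <- function(k = 5, s = 1, p = k %/% 2) {
  m <- new_module("maxpool")
  m$call <- function(x) {
    if (is_shape(x))
      return(make_shape(x$c, (x$h + 2 * p - k) %/% s + 1,
                        (x$w + 2 * p - k) %/% s + 1, x$tally))
    ag_maxpool(x, k, s, p)
  }
  m
}

pn_upsample2 <- function() {
  m <- new_module("upsample")
  m$call <- function(x) {
    if (is_shape(x)) return(make_shape(x$c, 2 * x$h, 2 * x$w, x$tally))
    ag_upsample2(x)
  }
  m
}

# shape-aware helpers used inside composite blocks
op_concat <- function(xs) {
  if (is_shape(xs[[1]])) {
    return(make_shape(sum(vapply(xs, function(s) s$c, numeric(1))),
                      xs[[1]]$h, xs[[1]]$w, xs[[1]]$tally))
  }
  ag_concat_c(xs)
}

op_take_channels <- function(x, channels) {
  if (is_shape(x)) return(make_shape(length(channels), x$h, x$w, x$tally))
  ag_take_c(x, channels)
}

op_add <- function(a, b) if (is_shape(a)) a else ag_add(a, b)
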
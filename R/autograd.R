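# Reverse-mode automatic differentiation on plain numeric arrays.
#
# A tensor is an environment holding a value (`v`), an accumulated gradient
# (`grad`), the parent tensors it was computed from, and a backward closure
# mapping the incoming gradient to per-parent gradients. Feature maps use the
# package-wide dim = c(H, W, C) layout. Gradient recording can be switched off
# globally (evaluation mode) so inference builds no tape.

.pn <- new.env(parent = emptyenv())
.pn$grad_enabled <- TRUE
.pn$id <- 0L

#' Evaluate an expression with gradient recording disabled
#'
#' Used by all inference paths (detection, validation AP) so that forward
#' passes allocate no tape.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
no_grad <- function(expr) {
  old <- .pn$grad_enabled
  .pn$grad_enabled <- FALSE
  on.exit(.pn$grad_enabled <- old)
  force(expr)
}

grad_enabled <- function() .pn$grad_enabled

new_tensor <- function(v, parents = list(), bw = NULL, is_param = FALSE) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$grad <- NULL
  t$parents <- if (grad_enabled() || is_param) parents else list()
  t$bw <- if (grad_enabled() || is_param) bw else NULL
  t$is_param <- is_param
  .pn$id <- .pn$id + 1L
  t$id <- .pn$id
  t$visited <- 0L
  t$pos <- 0L
  class(t) <- "pn_tensor"
  t
}

#' @export
print.pn_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<pn_tensor",
      if (is.null(d)) paste0("len=", length(x$v)) else paste(d, collapse = "x"),
      if (x$is_param) "param" else "", ">\n")
  invisible(x)
}

ag_param <- function(v) new_tensor(v, is_param = TRUE)
ag_const <- function(v) new_tensor(v)

as_value <- function(x) if (inherits(x, "pn_tensor")) x$v else x

# Wrap an op. `bw(g)` must return a list of gradients aligned with `inputs`
# (NULL entries allowed); non-tensor inputs are dropped from the tape and the
# returned gradients are re-aligned with the surviving parents.
ag_op <- function(value, inputs, bw) {
  pos <- which(vapply(inputs, inherits, logical(1), what = "pn_tensor"))
  if (!grad_enabled() || length(pos) == 0L) return(new_tensor(value))
  new_tensor(value, parents = inputs[pos],
             bw = function(g) bw(g)[pos])
}

# Accumulate gradient g into tensor t.
acc_grad <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

#' Backpropagate from a scalar loss tensor
#'
#' Topologically orders the tape reachable from `loss` and accumulates
#' gradients into every parameter tensor's `$grad` (summed, so batch
#' accumulation works by calling backward once per sample).
#'
#' @param loss a `pn_tensor` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "pn_tensor"), length(loss$v) == 1L)
  # visit stamps and positional gradient slots: no per-tensor names are
  # interned anywhere (symbols are never collected by R's GC)
  visit <- .pn$visit <- (.pn$visit %||% 0L) + 1L
  order <- vector("list", 256L)
  n_ord <- 0L
  stack <- list(list(t = loss, stage = 1L))
  # iterative DFS post-order (recursion would overflow on deep nets)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$stage == 1L) {
      if (top$t$visited == visit) next
      top$t$visited <- visit
      stack[[length(stack) + 1L]] <- list(t = top$t, stage = 2L)
      for (p in top$t$parents)
        if (p$visited != visit)
          stack[[length(stack) + 1L]] <- list(t = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", n_ord))
      order[[n_ord]] <- top$t
      top$t$pos <- n_ord
    }
  }
  grads <- vector("list", n_ord)
  grads[[loss$pos]] <- 1
  for (i in n_ord:1) {
    t <- order[[i]]
    g <- grads[[i]]
    grads[i] <- list(NULL)   # release as we go
    if (is.null(g)) next
    if (t$is_param) { acc_grad(t, g); next }
    if (is.null(t$bw)) next
    pg <- t$bw(g)
    parents <- t$parents
    for (j in seq_along(parents)) {
      if (is.null(pg[[j]])) next
      p <- parents[[j]]
      cur <- grads[[p$pos]]
      grads[[p$pos]] <- if (is.null(cur)) pg[[j]] else cur + pg[[j]]
    }
  }
  invisible(loss)
}

# ---- elementwise arithmetic -------------------------------------------------

ag_add <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  ag_op(av + bv, list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) reduce_like(g, av) else NULL,
         if (inherits(b, "pn_tensor")) reduce_like(g, bv) else NULL)
  })
}

ag_sub <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  ag_op(av - bv, list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) reduce_like(g, av) else NULL,
         if (inherits(b, "pn_tensor")) reduce_like(-g, bv) else NULL)
  })
}

ag_mul <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  ag_op(av * bv, list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) reduce_like(g * bv, av) else NULL,
         if (inherits(b, "pn_tensor")) reduce_like(g * av, bv) else NULL)
  })
}

ag_div <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  ag_op(av / bv, list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) reduce_like(g / bv, av) else NULL,
         if (inherits(b, "pn_tensor")) reduce_like(-g * av / bv^2, bv) else NULL)
  })
}

# collapse a broadcast gradient back to the shape of the operand (only the
# scalar-vs-vector case is ever produced by the ops above)
reduce_like <- function(g, v) {
  if (length(v) == 1L && length(g) > 1L) return(sum(g))
  g
}

ag_neg <- function(a) ag_op(-as_value(a), list(a), function(g) list(-g))

ag_square <- function(a) {
  av <- as_value(a)
  ag_op(av^2, list(a), function(g) list(2 * g * av))
}

ag_sqrt <- function(a) {
  av <- as_value(a); y <- sqrt(av)
  ag_op(y, list(a), function(g) list(g / (2 * y)))
}

ag_exp <- function(a) {
  y <- exp(as_value(a))
  ag_op(y, list(a), function(g) list(g * y))
}

ag_log <- function(a) {
  av <- as_value(a)
  ag_op(log(av), list(a), function(g) list(g / av))
}

ag_atan <- function(a) {
  av <- as_value(a)
  ag_op(atan(av), list(a), function(g) list(g / (1 + av^2)))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-as_value(a)))
  ag_op(y, list(a), function(g) list(g * y * (1 - y)))
}

# elementwise max of two same-shaped operands (ties route to the first)
ag_max2 <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  m <- av >= bv
  ag_op(pmax(av, bv), list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) g * m else NULL,
         if (inherits(b, "pn_tensor")) g * !m else NULL)
  })
}

ag_min2 <- function(a, b) {
  av <- as_value(a); bv <- as_value(b)
  m <- av <= bv
  ag_op(pmin(av, bv), list(a, b), function(g) {
    list(if (inherits(a, "pn_tensor")) g * m else NULL,
         if (inherits(b, "pn_tensor")) g * !m else NULL)
  })
}

ag_clamp <- function(a, lo, hi) {
  av <- as_value(a)
  inside <- av >= lo & av <= hi
  ag_op(pmin(pmax(av, lo), hi), list(a), function(g) list(g * inside))
}

ag_sum <- function(a) {
  av <- as_value(a)
  ag_op(sum(av), list(a), function(g) list(array(g, dim = dim(av) %||% length(av))))
}

ag_mean <- function(a) {
  av <- as_value(a); n <- length(av)
  ag_op(mean(av), list(a), function(g)
    list(array(g / n, dim = dim(av) %||% length(av))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- activations ------------------------------------------------------------

ag_hardswish <- function(a) {
  av <- as_value(a)
  r6 <- pmin(pmax(av + 3, 0), 6)
  ag_op(av * r6 / 6, list(a), function(g) {
    inner <- av > -3 & av < 3
    d <- ((2 * av + 3) / 6) * inner + (av >= 3)
    list(g * d)
  })
}

ag_silu <- function(a) {
  av <- as_value(a)
  s <- 1 / (1 + exp(-av))
  ag_op(av * s, list(a), function(g) list(g * (s * (1 + av * (1 - s)))))
}

ag_relu <- function(a) {
  av <- as_value(a)
  ag_op(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ag_act <- function(a, act) {
  switch(act,
         hardswish = ag_hardswish(a),
         silu = ag_silu(a),
         relu = ag_relu(a),
         linear = a,
         stop("unknown activation: ", act))
}

# ---- structural ops on (H, W, C) feature maps -------------------------------

ag_concat_c <- function(xs) {
  vals <- lapply(xs, as_value)
  dims <- lapply(vals, dim)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  y <- array(unlist(vals, use.names = FALSE), dim = c(H, W, sum(cs)))
  ag_op(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      n <- H * W * cs[i]
      out[[i]] <- array(g[(off + 1):(off + n)], dim = c(H, W, cs[i]))
      off <- off + n
    }
    out
  })
}

ag_take_c <- function(x, channels) {
  xv <- as_value(x)
  d <- dim(xv)
  y <- xv[, , channels, drop = FALSE]
  ag_op(y, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, , channels] <- g
    list(gx)
  })
}

# fixed permutation of channels (used by channel shuffle)
ag_permute_c <- function(x, perm) {
  xv <- as_value(x)
  y <- xv[, , perm, drop = FALSE]
  inv <- order(perm)
  ag_op(y, list(x), function(g) list(g[, , inv, drop = FALSE]))
}

ag_upsample2 <- function(x) {
  xv <- as_value(x)
  d <- dim(xv)
  y <- xv[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
  ag_op(y, list(x), function(g) {
    io <- seq(1, 2 * d[1], by = 2); jo <- seq(1, 2 * d[2], by = 2)
    list(g[io, jo, , drop = FALSE] + g[io + 1, jo, , drop = FALSE] +
           g[io, jo + 1, , drop = FALSE] + g[io + 1, jo + 1, , drop = FALSE])
  })
}

# global average pool -> 1x1xC map
ag_gap <- function(x) {
  xv <- as_value(x)
  d <- dim(xv); m <- d[1] * d[2]
  y <- array(colMeans(matrix(xv, m, d[3])), dim = c(1, 1, d[3]))
  ag_op(y, list(x), function(g) {
    list(array(rep(as.vector(g) / m, each = m), dim = d))
  })
}

# global max pool -> 1x1xC map (gradient to first argmax per channel)
ag_gmp <- function(x) {
  xv <- as_value(x)
  d <- dim(xv); m <- d[1] * d[2]
  xm <- matrix(xv, m, d[3])
  wm <- max.col(t(xm), ties.method = "first")
  y <- array(xm[cbind(wm, seq_len(d[3]))], dim = c(1, 1, d[3]))
  ag_op(y, list(x), function(g) {
    gx <- matrix(0, m, d[3])
    gx[cbind(wm, seq_len(d[3]))] <- as.vector(g)
    list(array(gx, dim = d))
  })
}

# per-pixel mean over channels -> HxWx1
ag_chan_mean <- function(x) {
  xv <- as_value(x)
  d <- dim(xv)
  y <- array(rowMeans(matrix(xv, d[1] * d[2], d[3])), dim = c(d[1], d[2], 1))
  ag_op(y, list(x), function(g)
    list(array(rep(as.vector(g) / d[3], d[3]), dim = d)))
}

# per-pixel max over channels -> HxWx1 (deterministic first-tie argmax)
ag_chan_max <- function(x) {
  xv <- as_value(x)
  d <- dim(xv); m <- d[1] * d[2]
  xm <- matrix(xv, m, d[3])
  wc <- max.col(xm, ties.method = "first")
  y <- array(xm[cbind(seq_len(m), wc)], dim = c(d[1], d[2], 1))
  ag_op(y, list(x), function(g) {
    gx <- matrix(0, m, d[3])
    gx[cbind(seq_len(m), wc)] <- as.vector(g)
    list(array(gx, dim = d))
  })
}

# multiply map by per-channel weights (CAM): w is a 1x1xC tensor
ag_scale_channels <- function(x, w) {
  xv <- as_value(x); wv <- as.vector(as_value(w))
  d <- dim(xv); m <- d[1] * d[2]
  wexp <- rep(wv, each = m)
  ag_op(array(as.vector(xv) * wexp, dim = d), list(x, w), function(g) {
    gw <- colSums(matrix(as.vector(g) * as.vector(xv), m, d[3]))
    list(array(as.vector(g) * wexp, dim = d), array(gw, dim = c(1, 1, d[3])))
  })
}

# multiply map by a spatial mask (SAM): mask is HxWx1, recycled over channels
ag_scale_spatial <- function(x, mask) {
  xv <- as_value(x); mv <- as.vector(as_value(mask))
  d <- dim(xv)
  ag_op(array(as.vector(xv) * mv, dim = d), list(x, mask), function(g) {
    gm <- rowSums(matrix(as.vector(g) * as.vector(xv), d[1] * d[2], d[3]))
    list(array(as.vector(g) * mv, dim = d), array(gm, dim = c(d[1], d[2], 1)))
  })
}

# gather elements of an array by linear index -> flat vector
ag_gather <- function(x, idx) {
  xv <- as_value(x)
  d <- dim(xv) %||% length(xv)
  ag_op(as.vector(xv)[idx], list(x), function(g) {
    gx <- numeric(length(xv))
    # indices may repeat; accumulate
    acc <- rowsum(g, idx)
    gx[as.integer(rownames(acc))] <- acc[, 1]
    list(array(gx, dim = d))
  })
}

# mean binary cross-entropy on logits against constant targets in [0,1]
ag_bce_logits <- function(logits, targets) {
  lv <- as_value(logits); tv <- as.vector(targets)
  n <- length(lv)
  s <- 1 / (1 + exp(-lv))
  # numerically stable: log(sigma) = -log1p(exp(-x)); log(1-sigma) = -x - log1p(exp(-x))
  lse <- ifelse(lv > 0, lv + log1p(exp(-lv)), log1p(exp(lv)))
  loss <- mean(lse - tv * lv)
  ag_op(loss, list(logits), function(g) list(g * (s - tv) / n))
}

# ---- convolution / pooling / batch norm -------------------------------------

ag_conv2d <- function(x, w, b, stride, pad, groups) {
  xv <- as_value(x); wv <- as_value(w)
  bv <- if (is.null(b)) NULL else as_value(b)
  y <- conv2d_fw(xv, wv, bv, stride, pad, groups)
  inputs <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(y, inputs, function(g) {
    bk <- conv2d_bw(xv, wv, g, stride, pad, groups, !is.null(b))
    if (is.null(b)) list(bk$gx, bk$gw) else list(bk$gx, bk$gw, bk$gb)
  })
}

ag_maxpool <- function(x, k, stride, pad) {
  xv <- as_value(x)
  r <- maxpool_fw(xv, k, stride, pad)
  d <- dim(xv)
  ag_op(r$y, list(x), function(g) list(maxpool_bw(g, r$idx, d)))
}

# Batch normalization over the spatial dimensions of one (H, W, C) map.
# training = TRUE uses batch statistics and updates running estimates.
ag_batchnorm <- function(x, gamma, beta, running, eps, momentum, training) {
  xv <- as_value(x)
  d <- dim(xv); m <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, m, C)
  if (training) {
    mu <- colMeans(xm)
    var <- colMeans(xm^2) - mu^2
    var[var < 0] <- 0
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    # unbiased estimate for the running variance (matches torch semantics)
    ub <- if (m > 1) var * m / (m - 1) else var
    running$var <- (1 - momentum) * running$var + momentum * ub
  } else {
    mu <- running$mean
    var <- running$var
  }
  ivar <- 1 / sqrt(var + eps)
  # column-recycled arithmetic (rep(each = m)) is much faster than sweep()
  ex <- function(v) rep(v, each = m)
  xhat <- (xm - ex(mu)) * ex(ivar)
  gv <- as.vector(as_value(gamma)); bv <- as.vector(as_value(beta))
  y <- array(xhat * ex(gv) + ex(bv), dim = d)
  ag_op(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, m, C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    if (training) {
      dxhat <- gm * ex(gv)
      gx <- (dxhat - ex(colMeans(dxhat)) -
               xhat * ex(colMeans(dxhat * xhat))) * ex(ivar)
    } else {
      gx <- gm * ex(gv * ivar)
    }
    list(array(gx, dim = d), ggamma, gbeta)
  })
}
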
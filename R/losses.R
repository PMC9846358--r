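# Training objective: per-scale binary cross-entropy confidence loss with
# IoU-valued soft targets, scale weighting (small targets are hardest, so the
# high-resolution head carries weight 6.0), CIoU location loss, and the
# YOLOv5-style shape-ratio target assignment.

# normalize box input to a matrix with columns cx, cy, w, h
as_box_matrix <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b[, c("cx", "cy", "w", "h")])
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = FALSE)
  stopifnot(ncol(b) == 4)
  colnames(b) <- c("cx", "cy", "w", "h")
  b
}

box_corners <- function(b) {
  cbind(x1 = b[, 1] - b[, 3] / 2, y1 = b[, 2] - b[, 4] / 2,
        x2 = b[, 1] + b[, 3] / 2, y2 = b[, 2] + b[, 4] / 2)
}

#' Intersection over union of axis-aligned boxes
#'
#' Boxes are given in center form (cx, cy, w, h); inputs are recycled
#' row-wise, so one box against many works.
#'
#' @param a,b length-4 vectors, 4-column matrices, or data frames with
#'   columns cx, cy, w, h.
#' @return numeric vector of IoU values in [0, 1].
#' @export
iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  ca <- box_corners(a); cb <- box_corners(b)
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  unname(ifelse(union > 0, inter / union, 0))
}

# CIoU similarity: IoU - d^2/c^2 - alpha*v  (the quantity whose complement is
# the loss; also used, clamped to [0,1], as the objectness soft target)
ciou_value <- function(pred, gt) {
  p <- as_box_matrix(pred); g <- as_box_matrix(gt)
  n <- max(nrow(p), nrow(g))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  g <- g[rep_len(seq_len(nrow(g)), n), , drop = FALSE]
  if (any(p[, 3] <= 0 | p[, 4] <= 0 | g[, 3] <= 0 | g[, 4] <= 0))
    stop("degenerate (zero-area) box")
  i <- iou(p, g)
  cp <- box_corners(p); cg <- box_corners(g)
  d2 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  cw <- pmax(cp[, 3], cg[, 3]) - pmin(cp[, 1], cg[, 1])
  chh <- pmax(cp[, 4], cg[, 4]) - pmin(cp[, 2], cg[, 2])
  c2 <- cw^2 + chh^2
  v <- (4 / pi^2) * (atan(g[, 3] / g[, 4]) - atan(p[, 3] / p[, 4]))^2
  denom <- (1 - i) + v
  alpha <- ifelse(denom > 0, v / denom, 0)   # 0/0 guard at IoU = 1, v = 0
  unname(i - ifelse(c2 > 0, d2 / c2, 0) - alpha * v)
}

#' Complete-IoU (CIoU) loss
#'
#' `1 - (IoU - d^2/c^2 - alpha*v)` where `d` is the center distance, `c` the
#' diagonal of the smallest enclosing box, `v = (4/pi^2) (atan(w_gt/h_gt) -
#' atan(w_p/h_p))^2` the aspect-ratio penalty and `alpha = v / ((1 - IoU) + v)`
#' (set to 0 at the 0/0 point where the boxes coincide). Zero iff the boxes
#' are identical; translation- and scale-invariant.
#'
#' @param pred,gt boxes in center form (see [iou()]).
#' @return numeric vector of non-negative losses.
#' @export
ciou_loss <- function(pred, gt) 1 - ciou_value(pred, gt)

#' Confidence (objectness) loss
#'
#' Mean binary cross-entropy of the sigmoid-squashed raw scores against
#' IoU-valued soft labels: `-sum(t*ln(s) + (1-t)*ln(1-s)) / n` with
#' `s = sigmoid(logit)`. Negatives carry target 0.
#'
#' @param logits raw (pre-sigmoid) confidence scores.
#' @param targets soft labels in [0, 1], same length.
#' @param n normalizing sample count (defaults to `length(logits)`).
#' @return non-negative scalar.
#' @export
confidence_loss <- function(logits, targets, n = length(logits)) {
  if (n < 1) stop("confidence_loss: sample count must be >= 1")
  stopifnot(length(logits) == length(targets), all(targets >= 0 & targets <= 1))
  lse <- ifelse(logits > 0, logits + log1p(exp(-logits)), log1p(exp(logits)))
  sum(lse - targets * logits) / n
}

#' Scale weights for the confidence loss
#'
#' @param k_small,k_medium,k_large non-negative weights for the
#'   high- (stride 8), mid- and low-resolution heads. Defaults 6.0 / 1.0 /
#'   0.5: distant pears are small on the image and hardest to detect, so the
#'   small-object head is up-weighted.
#' @return list with class "loss_weights".
#' @export
loss_weights <- function(k_small = 6.0, k_medium = 1.0, k_large = 0.5) {
  stopifnot(k_small >= 0, k_medium >= 0, k_large >= 0)
  structure(list(k_small = k_small, k_medium = k_medium, k_large = k_large),
            class = "loss_weights")
}

#' Weighted confidence loss across the three scales
#'
#' `k_small * L_small + k_medium * L_medium + k_large * L_large`; "small"
#' refers to the highest-resolution (stride 8) head.
#'
#' @param per_scale numeric vector of three per-scale confidence losses
#'   (small, medium, large).
#' @param weights a [loss_weights()] object.
#' @return scalar.
#' @export
weighted_confidence_loss <- function(per_scale, weights = loss_weights()) {
  stopifnot(length(per_scale) == 3, all(per_scale >= 0))
  weights$k_small * per_scale[1] + weights$k_medium * per_scale[2] +
    weights$k_large * per_scale[3]
}

#' Assemble the total detection loss
#'
#' `total = weighted confidence + location`; the detector is single-class and
#' has no classification term.
#'
#' @param conf_small,conf_medium,conf_large per-scale confidence losses.
#' @param loc location (CIoU) loss.
#' @param weights a [loss_weights()] object.
#' @return a `LossBreakdown` list: per-scale confidence losses, the weighted
#'   confidence total, the location loss and the grand total.
#' @export
total_loss <- function(conf_small, conf_medium, conf_large, loc,
                       weights = loss_weights()) {
  conf_w <- weighted_confidence_loss(c(conf_small, conf_medium, conf_large),
                                     weights)
  structure(list(conf_small = conf_small, conf_medium = conf_medium,
                 conf_large = conf_large, conf_weighted = conf_w,
                 loc = loc, total = conf_w + loc),
            class = "loss_breakdown")
}

#' Assign ground-truth boxes to anchors and grid cells
#'
#' YOLOv5-style shape matching: a ground truth is assigned to every anchor
#' whose width and height ratios satisfy `max(r, 1/r) < ratio_thresh`
#' (default 4) at the cell containing its center plus the two nearest
#' neighbor cells (by the fractional offset of the center). All other cells
#' are negatives. An empty ground-truth list yields a zero-row assignment.
#'
#' @param gts data frame with columns cx, cy, w, h (pixels).
#' @param model a model object (provides anchors, strides, input size).
#' @param input_size image side in pixels.
#' @param ratio_thresh anchor shape-ratio gate.
#' @return data frame with columns scale, anchor, cell_i (row), cell_j
#'   (column), gt (index into `gts`), all 1-based.
#' @export
assign_targets <- function(gts, model, input_size = model$input_size,
                           ratio_thresh = 4) {
  empty <- data.frame(scale = integer(), anchor = integer(),
                      cell_i = integer(), cell_j = integer(), gt = integer())
  if (is.null(gts) || nrow(gts) == 0) return(empty)
  out <- list(empty)
  for (s in 1:3) {
    stride <- model$strides[s]
    ng <- input_size / stride
    anc <- model$anchors[[s]]
    rw <- outer(gts$w, anc[, 1], "/")
    rh <- outer(gts$h, anc[, 2], "/")
    ok <- pmax(pmax(rw, 1 / rw), pmax(rh, 1 / rh)) < ratio_thresh
    pairs <- which(ok, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    gi <- pairs[, 1]; a <- pairs[, 2]
    gx <- gts$cx[gi] / stride
    gy <- gts$cy[gi] / stride
    j0 <- floor(gx); i0 <- floor(gy)
    jn <- j0 + ifelse(gx - j0 < 0.5, -1, 1)
    in_ <- i0 + ifelse(gy - i0 < 0.5, -1, 1)
    ci <- c(i0, i0, in_); cj <- c(j0, jn, j0)
    aa <- rep(a, 3); gg <- rep(gi, 3)
    valid <- ci >= 0 & ci < ng & cj >= 0 & cj < ng
    if (!any(valid)) next
    out[[length(out) + 1L]] <- data.frame(
      scale = s, anchor = aa[valid], cell_i = as.integer(ci[valid]) + 1L,
      cell_j = as.integer(cj[valid]) + 1L, gt = gg[valid])
  }
  res <- do.call(rbind, out)
  res[!duplicated(res), , drop = FALSE]
}

# ---- differentiable loss over one image -------------------------------------

# CIoU loss composed from tape ops so gradients flow to the decoded boxes;
# alpha is differentiated through as well (an epsilon guards its 0/0 point at
# coinciding boxes), so autodiff agrees with finite differences everywhere.
# Returns the loss tensor and the detached CIoU similarity used as the
# objectness soft target.
ag_ciou <- function(bx, by, bw, bh, g) {
  half <- function(t) ag_mul(t, 0.5)
  px1 <- ag_sub(bx, half(bw)); px2 <- ag_add(bx, half(bw))
  py1 <- ag_sub(by, half(bh)); py2 <- ag_add(by, half(bh))
  gx1 <- g[, 1] - g[, 3] / 2; gx2 <- g[, 1] + g[, 3] / 2
  gy1 <- g[, 2] - g[, 4] / 2; gy2 <- g[, 2] + g[, 4] / 2
  iw <- ag_clamp(ag_sub(ag_min2(px2, gx2), ag_max2(px1, gx1)), 0, Inf)
  ih <- ag_clamp(ag_sub(ag_min2(py2, gy2), ag_max2(py1, gy1)), 0, Inf)
  inter <- ag_mul(iw, ih)
  union <- ag_sub(ag_add(ag_mul(bw, bh), g[, 3] * g[, 4]), inter)
  i <- ag_div(inter, union)
  cw <- ag_sub(ag_max2(px2, gx2), ag_min2(px1, gx1))
  chh <- ag_sub(ag_max2(py2, gy2), ag_min2(py1, gy1))
  c2 <- ag_add(ag_add(ag_square(cw), ag_square(chh)), 1e-9)
  d2 <- ag_add(ag_square(ag_sub(bx, g[, 1])), ag_square(ag_sub(by, g[, 2])))
  v <- ag_mul(ag_square(ag_sub(atan(g[, 3] / g[, 4]),
                               ag_atan(ag_div(bw, bh)))), 4 / pi^2)
  alpha <- ag_div(v, ag_add(ag_add(ag_sub(1, i), v), 1e-12))
  ciou <- ag_sub(i, ag_add(ag_div(d2, c2), ag_mul(v, alpha)))
  list(loss = ag_sub(1, ciou), ciou = as_value(ciou))
}

# linear indices of channel `ch` (1-based) in an (H, W, C) array
chan_idx <- function(H, W, ch) ((ch - 1) * H * W) + seq_len(H * W)

cell_chan_idx <- function(H, W, ch, i, j) (ch - 1) * H * W + (j - 1) * H + i

#' Differentiable loss of one image
#'
#' Runs the model forward (recording the tape when gradients are enabled),
#' assigns targets, decodes the predicted boxes at the matched cells with the
#' YOLOv5 transform (`xy = (2*sigmoid - 0.5 + cell) * stride`,
#' `wh = (2*sigmoid)^2 * anchor`), and evaluates the combined objective. The
#' objectness soft target of a matched prediction is its CIoU with the ground
#' truth, clamped to [0, 1] and detached.
#'
#' @param model a model object.
#' @param image numeric array (S, S, 3).
#' @param gts data frame with columns cx, cy, w, h (pixels); may be empty.
#' @param weights a [loss_weights()] object.
#' @param ratio_thresh anchor shape-ratio gate for assignment.
#' @return list: `loss` (scalar tensor for backward), `breakdown` (a
#'   `LossBreakdown` of plain numbers), `n_pos` (positive assignments).
#' @export
compute_loss <- function(model, image, gts, weights = loss_weights(),
                         ratio_thresh = 4) {
  heads <- pn_call(model, ag_const(image))
  S <- dim(image)[1]
  asg <- assign_targets(gts, model, input_size = S,
                        ratio_thresh = ratio_thresh)
  conf <- vector("list", 3)
  loc_terms <- list()
  n_pos <- 0
  for (s in 1:3) {
    h <- heads[[s]]
    d <- dim(as_value(h))
    H <- d[1]; W <- d[2]
    stride <- S / H
    obj_targets <- numeric(H * W * model$na)
    rows <- asg[asg$scale == s, , drop = FALSE]
    if (nrow(rows) > 0) {
      a <- rows$anchor; i <- rows$cell_i; j <- rows$cell_j
      base <- (a - 1) * 5
      g <- as_box_matrix(gts[rows$gt, c("cx", "cy", "w", "h")])
      tx <- ag_gather(h, cell_chan_idx(H, W, base + 1, i, j))
      ty <- ag_gather(h, cell_chan_idx(H, W, base + 2, i, j))
      tw <- ag_gather(h, cell_chan_idx(H, W, base + 3, i, j))
      th <- ag_gather(h, cell_chan_idx(H, W, base + 4, i, j))
      anc <- model$anchors[[s]][a, , drop = FALSE]
      bx <- ag_mul(ag_add(ag_sub(ag_mul(ag_sigmoid(tx), 2), 0.5), j - 1), stride)
      by <- ag_mul(ag_add(ag_sub(ag_mul(ag_sigmoid(ty), 2), 0.5), i - 1), stride)
      bw <- ag_mul(ag_square(ag_mul(ag_sigmoid(tw), 2)), anc[, 1])
      bh <- ag_mul(ag_square(ag_mul(ag_sigmoid(th), 2)), anc[, 2])
      ci <- ag_ciou(bx, by, bw, bh, g)
      loc_terms[[length(loc_terms) + 1L]] <- ci$loss
      n_pos <- n_pos + nrow(rows)
      # objectness soft target: detached CIoU clamped to [0, 1]; the target
      # vector is ordered anchor-major to match the gather below
      obj_in_scale <- (a - 1) * H * W + (j - 1) * H + i
      obj_targets[obj_in_scale] <- pmin(pmax(ci$ciou, 0), 1)
    }
    all_obj_idx <- unlist(lapply(seq_len(model$na), function(a)
      chan_idx(H, W, (a - 1) * 5 + 5)))
    logits <- ag_gather(h, all_obj_idx)
    conf[[s]] <- ag_bce_logits(logits, obj_targets)
  }
  loc <- if (length(loc_terms) == 0) ag_const(0) else {
    total <- NULL
    n <- 0
    for (t in loc_terms) {
      total <- if (is.null(total)) ag_sum(t) else ag_add(total, ag_sum(t))
      n <- n + length(as_value(t))
    }
    ag_div(total, n)
  }
  conf_w <- ag_add(ag_add(ag_mul(conf[[1]], weights$k_small),
                          ag_mul(conf[[2]], weights$k_medium)),
                   ag_mul(conf[[3]], weights$k_large))
  loss <- ag_add(conf_w, loc)
  breakdown <- total_loss(as_value(conf[[1]]), as_value(conf[[2]]),
                          as_value(conf[[3]]), as_value(loc), weights)
  list(loss = loss, breakdown = breakdown, n_pos = n_pos)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss %.4f = conf %.4f (S %.4f M %.4f L %.4f, weighted) + loc %.4f\n",
    x$total, x$conf_weighted, x$conf_small, x$conf_medium, x$conf_large,
    x$loc))
  invisible(x)
}
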
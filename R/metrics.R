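# Detection post-processing and the evaluation protocol: decoding, NMS,
# greedy matching at a confidence gate of 0.4 and IoU 0.5, precision /
# recall / F1, all-point-interpolated AP@0.5, and stratified reporting by
# shade degree, background complexity and day/night.

#' Decode raw head maps into detections
#'
#' Applies the YOLOv5 box transform to every anchor at every cell and
#' returns detections above a (low) confidence floor.
#'
#' @param heads list of three (H, W, 15) arrays from [model_forward()].
#' @param model the model that produced them (anchors, strides).
#' @param input_size image side in pixels.
#' @param conf_floor discard predictions below this sigmoid confidence.
#' @return data frame with columns cx, cy, w, h, confidence (pixel units).
#' @export
decode_detections <- function(heads, model, input_size = model$input_size,
                              conf_floor = 0.001) {
  sig <- function(x) 1 / (1 + exp(-x))
  out <- list()
  for (s in 1:3) {
    arr <- heads[[s]]
    d <- dim(arr)
    H <- d[1]; W <- d[2]
    stride <- input_size / H
    anc <- model$anchors[[s]]
    for (a in seq_len(model$na)) {
      base <- (a - 1) * 5
      conf <- sig(arr[, , base + 5])
      keep <- which(conf >= conf_floor)
      if (length(keep) == 0) next
      jj <- (keep - 1) %/% H      # 0-based column (x cell)
      ii <- (keep - 1) %% H       # 0-based row (y cell)
      tx <- arr[, , base + 1][keep]; ty <- arr[, , base + 2][keep]
      tw <- arr[, , base + 3][keep]; th <- arr[, , base + 4][keep]
      out[[length(out) + 1L]] <- data.frame(
        cx = (2 * sig(tx) - 0.5 + jj) * stride,
        cy = (2 * sig(ty) - 0.5 + ii) * stride,
        w = (2 * sig(tw))^2 * anc[a, 1],
        h = (2 * sig(th))^2 * anc[a, 2],
        confidence = conf[keep])
    }
  }
  if (length(out) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), confidence = numeric()))
  do.call(rbind, out)
}

#' Non-maximum suppression
#'
#' Greedy suppression by descending confidence: the highest-confidence box is
#' kept and every remaining box overlapping it with IoU above the threshold
#' is removed; ties break on confidence first, then on smaller original
#' index, making the result deterministic.
#'
#' @param dets data frame with columns cx, cy, w, h, confidence.
#' @param iou_thresh suppression threshold in (0, 1).
#' @return the surviving rows of `dets`, ordered by descending confidence.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(nrow(d)) > i)
    if (length(rest) == 0) break
    ov <- iou(d[rest, c("cx", "cy", "w", "h")],
              d[i, c("cx", "cy", "w", "h")])
    alive[rest[ov > iou_thresh]] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' End-to-end detection on one image
#'
#' Forward pass, decode, confidence gate, NMS.
#'
#' @param model a model object.
#' @param image numeric array (S, S, 3).
#' @param conf_thresh report detections above this confidence (default 0.4,
#'   the deployment operating point).
#' @param nms_thresh NMS IoU threshold (default 0.45).
#' @return data frame of detections (cx, cy, w, h, confidence).
#' @export
detect <- function(model, image, conf_thresh = 0.4, nms_thresh = 0.45) {
  heads <- model_forward(model, image)
  dets <- decode_detections(heads, model, input_size = dim(image)[1],
                            conf_floor = min(conf_thresh, 0.001))
  dets <- nms(dets, nms_thresh)
  dets[dets$confidence >= conf_thresh, , drop = FALSE]
}

#' Match detections to ground truths on one image
#'
#' Detections below the confidence gate are discarded; the rest are matched
#' greedily in order of descending confidence to the unmatched ground truth
#' of highest IoU, requiring IoU >= `iou_thresh`. Unmatched detections are
#' false positives; unmatched ground truths are false negatives.
#'
#' @param dets data frame with cx, cy, w, h, confidence.
#' @param gts data frame with cx, cy, w, h.
#' @param conf_thresh confidence gate (default 0.4).
#' @param iou_thresh match threshold (default 0.5).
#' @return named vector c(tp, fp, fn).
#' @export
match_detections <- function(dets, gts, conf_thresh = 0.4, iou_thresh = 0.5) {
  stopifnot(conf_thresh > 0, conf_thresh < 1, iou_thresh > 0, iou_thresh < 1)
  kept <- dets[dets$confidence >= conf_thresh, , drop = FALSE]
  m <- match_greedy(kept, gts, iou_thresh)
  c(tp = sum(m > 0), fp = sum(m == 0), fn = nrow(gts) - sum(m > 0))
}

# greedy matcher: returns, per detection (sorted by its own order), the index
# of the matched gt or 0; detections must already be confidence-filtered.
# Processing order: descending confidence, then original index.
match_greedy <- function(dets, gts, iou_thresh) {
  if (nrow(dets) == 0) return(integer(0))
  res <- integer(nrow(dets))
  if (is.null(gts) || nrow(gts) == 0) return(res)
  taken <- logical(nrow(gts))
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  for (i in ord) {
    ov <- iou(gts[, c("cx", "cy", "w", "h")],
              dets[i, c("cx", "cy", "w", "h")])
    ov[taken] <- -1
    best <- which.max(ov)
    if (ov[best] >= iou_thresh) {
      res[i] <- best
      taken[best] <- TRUE
    }
  }
  res
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any quantity with a
#' zero denominator is reported as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named vector c(precision, recall, f1).
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision at a fixed IoU threshold (AP@0.5)
#'
#' Sweeps the precision-recall curve over detection confidence (detections
#' pooled across images, matched greedily per image) and integrates it with
#' all-point interpolation (the precision envelope). With a single class,
#' AP equals mAP.
#'
#' @param dets data frame with image_id, cx, cy, w, h, confidence.
#' @param gts data frame with image_id, cx, cy, w, h; must be non-empty.
#' @param iou_thresh match threshold (default 0.5).
#' @param interpolation "all_point" (default) or "eleven_point" (classic VOC).
#' @return AP in [0, 1].
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5,
                              interpolation = c("all_point", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  if (is.null(gts) || nrow(gts) == 0) stop("average_precision: no ground truths")
  n_gt <- nrow(gts)
  if (nrow(dets) == 0) return(0)
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  is_tp <- logical(nrow(d))
  for (img in unique(d$image_id)) {
    di <- which(d$image_id == img)
    gi <- gts[gts$image_id == img, , drop = FALSE]
    m <- match_greedy(d[di, , drop = FALSE], gi, iou_thresh)
    is_tp[di] <- m > 0
  }
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  if (interpolation == "all_point") {
    # precision envelope, integrated over recall increments
    env <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    sum((recall - r_prev) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r0) {
      sel <- recall >= r0
      if (!any(sel)) 0 else max(precision[sel])
    }, numeric(1)))
  }
}

#' Stratified evaluation report
#'
#' Pools TP/FP/FN counters per stratum (shade category x background
#' complexity tier x illumination) and reports precision/recall/F1 per
#' stratum and per axis. Objects lacking metadata are pooled into an
#' "untagged" stratum with a warning.
#'
#' @param per_image list of per-image results; each element has `dets`
#'   (data frame with cx, cy, w, h, confidence) and `gts` (data frame with
#'   cx, cy, w, h and optional ks, shade_category columns).
#' @param manifest data frame with one row per image: image_id, tier,
#'   illumination.
#' @param conf_thresh,iou_thresh matching thresholds (0.4 / 0.5 defaults).
#' @param drop_beyond_scope exclude objects with shade degree >= 0.6 from the
#'   stratified counters (they are beyond the detector's design envelope).
#' @return an `eval_result` list: overall counters/metrics, `strata` (data
#'   frame of per-stratum counters and F1), and per-axis summaries.
#' @export
stratified_report <- function(per_image, manifest, conf_thresh = 0.4,
                              iou_thresh = 0.5, drop_beyond_scope = TRUE) {
  rows <- list()
  untagged <- 0L
  for (k in seq_along(per_image)) {
    ri <- per_image[[k]]
    img <- manifest[k, , drop = FALSE]
    gts <- ri$gts
    kept <- ri$dets[ri$dets$confidence >= conf_thresh, , drop = FALSE]
    m <- match_greedy(kept, gts, iou_thresh)
    shade <- if (!is.null(gts$shade_category)) as.character(gts$shade_category)
             else rep(NA_character_, nrow(gts))
    tier <- if (!is.null(img$tier)) as.character(img$tier) else NA_character_
    illum <- if (!is.null(img$illumination)) as.character(img$illumination)
             else NA_character_
    # per-gt outcome: matched (tp) or missed (fn)
    for (gi in seq_len(nrow(gts))) {
      sc <- shade[gi]
      if (is.na(sc) || is.na(tier) || is.na(illum)) untagged <- untagged + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        shade = ifelse(is.na(sc), "untagged", sc),
        tier = ifelse(is.na(tier), "untagged", tier),
        illumination = ifelse(is.na(illum), "untagged", illum),
        tp = as.integer(gi %in% m), fp = 0L,
        fn = as.integer(!gi %in% m))
    }
    # false positives carry image-level tags only; shade is not defined
    n_fp <- sum(m == 0)
    if (n_fp > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        shade = "any", tier = ifelse(is.na(tier), "untagged", tier),
        illumination = ifelse(is.na(illum), "untagged", illum),
        tp = 0L, fp = n_fp, fn = 0L)
  }
  if (untagged > 0)
    warning(untagged, " object(s) lacked stratum metadata; ",
            "pooled into an 'untagged' stratum")
  tab <- do.call(rbind, rows)
  if (drop_beyond_scope)
    tab <- tab[tab$shade != "beyond_scope", , drop = FALSE]
  agg <- function(by) {
    counts <- stats::aggregate(tab[, c("tp", "fp", "fn")], by = by, FUN = sum)
    met <- t(apply(counts[, c("tp", "fp", "fn")], 1, function(r)
      precision_recall_f1(r[1], r[2], r[3])))
    cbind(counts, met)
  }
  overall <- c(tp = sum(tab$tp), fp = sum(tab$fp), fn = sum(tab$fn))
  structure(list(
    tp = overall["tp"], fp = overall["fp"], fn = overall["fn"],
    metrics = precision_recall_f1(overall["tp"], overall["fp"], overall["fn"]),
    strata = agg(list(shade = tab$shade, tier = tab$tier,
                      illumination = tab$illumination)),
    by_shade = agg(list(shade = tab$shade)),
    by_tier = agg(list(tier = tab$tier)),
    by_illumination = agg(list(illumination = tab$illumination))),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | P %.3f R %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$metrics["precision"], x$metrics["recall"],
              x$metrics["f1"]))
  cat("\nBy shade category:\n"); print(x$by_shade)
  cat("\nBy background complexity:\n"); print(x$by_tier)
  cat("\nBy illumination:\n"); print(x$by_illumination)
  invisible(x)
}
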
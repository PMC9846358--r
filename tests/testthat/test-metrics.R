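# NMS, greedy matching, precision/recall/F1, AP@0.5 and the stratified report.

det_df <- function(cx, cy, w, h, conf, image_id = NULL) {
  d <- data.frame(cx = cx, cy = cy, w = w, h = h, confidence = conf)
  if (!is.null(image_id)) d$image_id <- image_id
  d
}

test_that("nms keeps the strongest box of each overlapping cluster", {
  one <- det_df(5, 5, 10, 10, 0.7)
  expect_equal(nms(one, 0.5), one)
  # two identical boxes: only the stronger survives
  two <- det_df(c(5, 5), c(5, 5), 10, 10, c(0.9, 0.8))
  expect_equal(nrow(nms(two, 0.5)), 1)
  expect_equal(nms(two, 0.5)$confidence, 0.9)
  # chain: A~B above threshold, B~C above, A~C below -> {A, C}
  chain <- det_df(c(5, 8, 11), 5, 10, 10, c(0.9, 0.8, 0.7))
  expect_gt(iou(chain[1, 1:4], chain[2, 1:4]), 0.5)
  expect_gt(iou(chain[2, 1:4], chain[3, 1:4]), 0.5)
  expect_lt(iou(chain[1, 1:4], chain[3, 1:4]), 0.5)
  kept <- nms(chain, 0.5)
  expect_equal(sort(kept$confidence), c(0.7, 0.9))
  # brute-force greedy oracle agrees on random sets
  greedy_oracle <- function(d, th) {
    ord <- order(-d$confidence, seq_len(nrow(d)))
    alive <- rep(TRUE, nrow(d)); keep <- integer(0)
    for (i in ord) {
      if (!alive[i]) next
      keep <- c(keep, i)
      for (j in ord) if (alive[j] && j != i &&
                         iou(d[i, 1:4], d[j, 1:4]) > th) alive[j] <- FALSE
      alive[i] <- FALSE
    }
    sort(keep)
  }
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    d <- det_df(runif(n, 0, 30), runif(n, 0, 30), runif(n, 4, 14),
                runif(n, 4, 14), runif(n))
    got <- nms(d, 0.45)
    want <- d[greedy_oracle(d, 0.45), ]
    expect_setequal(got$confidence, want$confidence)
  }
})

test_that("match_detections applies the 0.4 gate and greedy IoU matching", {
  gts <- data.frame(cx = c(10, 30, 50), cy = 10, w = 8, h = 8)
  perfect <- det_df(c(10, 30, 50), 10, 8, 8, c(0.9, 0.8, 0.7))
  expect_equal(match_detections(perfect, gts), c(tp = 3, fp = 0, fn = 0))
  # duplicate detections of one gt: second counts as FP
  dup <- det_df(c(10, 10.5), c(10, 10), 8, 8, c(0.9, 0.8))
  expect_equal(match_detections(dup, gts[1, ]), c(tp = 1, fp = 1, fn = 0))
  # conf 0.3 hit is discarded by the 0.4 gate
  three <- det_df(c(10, 30, 50), 10, 8, 8, c(0.9, 0.5, 0.3))
  expect_equal(match_detections(three, gts), c(tp = 2, fp = 0, fn = 1))
})

test_that("match counters conserve totals over random sets", {
  set.seed(42)
  for (rep in 1:15) {
    ng <- sample(0:6, 1); nd <- sample(0:8, 1)
    gts <- data.frame(cx = runif(ng, 0, 60), cy = runif(ng, 0, 60),
                      w = runif(ng, 5, 15), h = runif(ng, 5, 15))
    dets <- det_df(runif(nd, 0, 60), runif(nd, 0, 60), runif(nd, 5, 15),
                   runif(nd, 5, 15), runif(nd))
    m <- match_detections(dets, gts)
    expect_equal(m["tp"] + m["fn"], c(tp = ng))
    expect_equal(m["tp"] + m["fp"],
                 c(tp = sum(dets$confidence >= 0.4)))
  }
})

test_that("precision_recall_f1 matches hand arithmetic and conventions", {
  r <- precision_recall_f1(9, 1, 2)
  expect_equal(r[["precision"]], 0.9)
  expect_equal(r[["recall"]], 9 / 11, tolerance = 1e-4)
  expect_equal(r[["f1"]], 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11),
               tolerance = 1e-12)
  expect_equal(round(r[["recall"]], 4), 0.8182)
  expect_equal(round(r[["f1"]], 4), 0.8571)
  expect_equal(precision_recall_f1(0, 0, 0),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(5, 0, 0),
               c(precision = 1, recall = 1, f1 = 1))
})

test_that("average_precision integrates the envelope and hits worked values", {
  gts <- data.frame(image_id = 1, cx = c(10, 30, 50), cy = 10, w = 8, h = 8)
  # all gts hit before any FP
  hits <- det_df(c(10, 30, 50), 10, 8, 8, c(0.9, 0.8, 0.7), image_id = 1)
  expect_equal(average_precision(hits, gts), 1)
  # ranked TP, TP, FP, TP over 3 gts -> 1/3 + 1/3 + 1/4 = 0.9167
  seq4 <- det_df(c(10, 30, 200, 50), 10, 8, 8, c(0.9, 0.8, 0.7, 0.6),
                 image_id = 1)
  expect_equal(average_precision(seq4, gts), 1 / 3 + 1 / 3 + 1 / 4,
               tolerance = 1e-12)
  expect_equal(round(average_precision(seq4, gts), 4), 0.9167)
  # no detections -> 0; no gts -> error
  expect_equal(average_precision(seq4[0, ], gts), 0)
  expect_error(average_precision(seq4, gts[0, ]), "ground truths")
})

test_that("average_precision agrees with a dense P(R)-integration oracle", {
  # oracle: evaluate the interpolated precision max_{recall >= r} P on a
  # dense recall grid and average (Riemann approximation of the integral)
  ap_oracle <- function(dets, gts) {
    ord <- order(-dets$confidence, seq_len(nrow(dets)))
    d <- dets[ord, , drop = FALSE]
    is_tp <- logical(nrow(d))
    pn <- pn_internal()
    for (img in unique(d$image_id)) {
      di <- which(d$image_id == img)
      m <- pn$match_greedy(d[di, , drop = FALSE],
                           gts[gts$image_id == img, , drop = FALSE], 0.5)
      is_tp[di] <- m > 0
    }
    rec <- cumsum(is_tp) / nrow(gts)
    prec <- cumsum(is_tp) / seq_along(is_tp)
    grid <- seq(1e-6, 1, length.out = 20000)
    mean(vapply(grid, function(r0) {
      sel <- rec >= r0
      if (!any(sel)) 0 else max(prec[sel])
    }, numeric(1)))
  }
  set.seed(43)
  for (rep in 1:6) {
    ng <- sample(2:5, 1)
    gts <- data.frame(image_id = sample(1:2, ng, TRUE),
                      cx = runif(ng, 10, 50), cy = runif(ng, 10, 50),
                      w = 8, h = 8)
    nd <- sample(3:10, 1)
    pick <- sample(ng, nd, replace = TRUE)
    dets <- det_df(gts$cx[pick] + runif(nd, -6, 6), gts$cy[pick],
                   8, 8, runif(nd), image_id = gts$image_id[pick])
    expect_equal(average_precision(dets, gts), ap_oracle(dets, gts),
                 tolerance = 5e-4)
  }
})

test_that("AP is invariant to image order and monotone confidence transforms", {
  set.seed(44)
  gts <- data.frame(image_id = rep(1:3, each = 2),
                    cx = runif(6, 10, 50), cy = runif(6, 10, 50), w = 8, h = 8)
  dets <- det_df(gts$cx + runif(6, -5, 5), gts$cy, 8, 8,
                 runif(6), image_id = gts$image_id)
  extra <- det_df(runif(3, 60, 90), runif(3, 60, 90), 8, 8, runif(3),
                  image_id = 1:3)
  dets <- rbind(dets, extra)
  ap <- average_precision(dets, gts)
  # permute image ids consistently
  perm <- c(2, 3, 1)
  d2 <- dets; d2$image_id <- perm[d2$image_id]
  g2 <- gts; g2$image_id <- perm[g2$image_id]
  expect_equal(average_precision(d2, g2), ap)
  # strictly monotone transform of confidences
  d3 <- dets; d3$confidence <- plogis(5 * d3$confidence - 1)
  expect_equal(average_precision(d3, gts), ap)
  d4 <- dets; d4$confidence <- d4$confidence^3
  expect_equal(average_precision(d4, gts), ap)
})

test_that("recall never decreases when the confidence gate is lowered", {
  set.seed(45)
  for (rep in 1:8) {
    ng <- sample(2:6, 1)
    gts <- data.frame(cx = runif(ng, 10, 50), cy = runif(ng, 10, 50),
                      w = 10, h = 10)
    nd <- sample(2:10, 1)
    dets <- det_df(runif(nd, 10, 50), runif(nd, 10, 50), 10, 10, runif(nd))
    last_recall <- -1
    for (th in c(0.8, 0.6, 0.4, 0.2, 0.05)) {
      m <- match_detections(dets, gts, conf_thresh = th)
      rec <- precision_recall_f1(m["tp"], m["fp"], m["fn"])[["recall"]]
      expect_gte(rec, last_recall)
      last_recall <- rec
    }
  }
})

test_that("stratified_report reproduces hand-computed per-stratum F1", {
  # engineered fixture: 2 day images (uncomplicated) + 1 night (extreme)
  # image 1: 2 gts (not_or_slight, medium), both detected + 1 FP
  g1 <- data.frame(cx = c(10, 30), cy = 10, w = 8, h = 8,
                   shade_category = c("not_or_slight", "medium"))
  d1 <- det_df(c(10, 30, 60), 10, 8, 8, c(0.9, 0.8, 0.7))
  # image 2: 1 gt (serious), missed
  g2 <- data.frame(cx = 20, cy = 20, w = 8, h = 8,
                   shade_category = "serious")
  d2 <- det_df(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
  # image 3 (night): 1 gt (medium) detected, 1 gt beyond_scope missed
  g3 <- data.frame(cx = c(12, 40), cy = 12, w = 8, h = 8,
                   shade_category = c("medium", "beyond_scope"))
  d3 <- det_df(12, 12, 8, 8, 0.95)
  manifest <- data.frame(image_id = 1:3,
                         tier = c("uncomplicated", "uncomplicated", "extreme"),
                         illumination = c("day", "day", "night"))
  rep_ <- stratified_report(list(list(dets = d1, gts = g1),
                                 list(dets = d2, gts = g2),
                                 list(dets = d3, gts = g3)), manifest)
  # beyond_scope gt excluded: totals tp 3, fp 1, fn 1
  expect_equal(unname(rep_$tp), 3)
  expect_equal(unname(rep_$fp), 1)
  expect_equal(unname(rep_$fn), 1)
  expect_equal(unname(rep_$metrics["precision"]), 3 / 4)
  expect_equal(unname(rep_$metrics["recall"]), 3 / 4)
  expect_equal(unname(rep_$metrics["f1"]), 0.75)
  by_shade <- rep_$by_shade
  expect_equal(by_shade$f1[by_shade$shade == "medium"], 1)  # 2/2 detected
  expect_equal(by_shade$f1[by_shade$shade == "serious"], 0) # missed
  expect_false("beyond_scope" %in% by_shade$shade)
  by_ill <- rep_$by_illumination
  # day: tp 2, fp 1, fn 1 -> P 2/3, R 2/3, F1 2/3
  f1_day <- by_ill$f1[by_ill$illumination == "day"]
  expect_equal(f1_day, 2 / 3, tolerance = 1e-12)
  expect_equal(by_ill$f1[by_ill$illumination == "night"], 1)
  # single stratum: stratum F1 equals overall F1
  rep1 <- stratified_report(list(list(dets = d1, gts = g1)),
                            manifest[1, , drop = FALSE])
  expect_equal(rep1$by_illumination$f1[1], unname(rep1$metrics["f1"]))
})
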
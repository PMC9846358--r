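# IoU / CIoU geometry, the confidence objective, target assignment, and the
# differentiable loss path.

test_that("iou handles identity, disjoint and the worked offset pair", {
  a <- c(cx = 1, cy = 1, w = 2, h = 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 2, 2)), 0)
  # 2x2 squares offset by (1, 0): intersection 2, union 6
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  # vectorized: one against many
  many <- data.frame(cx = c(1, 5), cy = c(1, 5), w = 2, h = 2)
  expect_equal(iou(a, many), c(1, 0))
})

# scalar CIoU oracle written independently from the vectorized implementation
ciou_oracle <- function(p, g) {
  corners <- function(b) c(b[1] - b[3] / 2, b[2] - b[4] / 2,
                           b[1] + b[3] / 2, b[2] + b[4] / 2)
  cp <- corners(p); cg <- corners(g)
  iw <- max(0, min(cp[3], cg[3]) - max(cp[1], cg[1]))
  ih <- max(0, min(cp[4], cg[4]) - max(cp[2], cg[2]))
  inter <- iw * ih
  i <- inter / (p[3] * p[4] + g[3] * g[4] - inter)
  d2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  c2 <- (max(cp[3], cg[3]) - min(cp[1], cg[1]))^2 +
    (max(cp[4], cg[4]) - min(cp[2], cg[2]))^2
  v <- 4 / pi^2 * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
  alpha <- if (i == 1 && v == 0) 0 else v / ((1 - i) + v)
  1 - (i - (d2 / c2 + alpha * v))
}

test_that("ciou_loss reproduces hand-worked values and the scalar oracle", {
  b <- c(1, 1, 2, 2)
  expect_equal(ciou_loss(b, b), 0)
  # disjoint 2x2 squares at (1,1) and (5,5): IoU 0, d2 = 32, c2 = 72, v = 0
  expect_equal(ciou_loss(c(1, 1, 2, 2), c(5, 5, 2, 2)), 1 + 32 / 72,
               tolerance = 1e-12)
  expect_equal(1 + 32 / 72, 1.4444, tolerance = 1e-4)
  # same center, same area, transposed aspect: aspect penalty is active
  p <- c(0, 0, 4, 2); g <- c(0, 0, 2, 4)
  expect_equal(ciou_loss(p, g), ciou_oracle(p, g), tolerance = 1e-12)
  expect_gt(ciou_loss(p, g), 1 - iou(p, g))
  # random cross-check against the oracle
  set.seed(31)
  for (i in 1:25) {
    p <- c(runif(2, -5, 5), runif(2, 0.2, 6))
    g <- c(runif(2, -5, 5), runif(2, 0.2, 6))
    expect_equal(ciou_loss(p, g), ciou_oracle(p, g), tolerance = 1e-10)
  }
  expect_error(ciou_loss(c(0, 0, 0, 2), b), "degenerate")
})

test_that("ciou_loss is non-negative, zero iff identical, and invariant to
           translation and scaling", {
  set.seed(32)
  for (i in 1:25) {
    p <- c(runif(2, -5, 5), runif(2, 0.2, 6))
    g <- c(runif(2, -5, 5), runif(2, 0.2, 6))
    l <- ciou_loss(p, g)
    expect_gte(l, 0)
    shift <- runif(2, -10, 10)
    expect_equal(ciou_loss(p + c(shift, 0, 0), g + c(shift, 0, 0)), l,
                 tolerance = 1e-9)
    s <- runif(1, 0.1, 8)
    expect_equal(ciou_loss(p * s, g * s), l, tolerance = 1e-9)
    expect_gt(l, 0)  # p != g almost surely
  }
  expect_equal(ciou_loss(c(2, 3, 1, 4), c(2, 3, 1, 4)), 0)
})

test_that("confidence_loss is mean BCE with soft labels", {
  # target 0.5 at sigmoid(0) = 0.5 gives ln 2
  expect_equal(confidence_loss(0, 0.5), log(2), tolerance = 1e-12)
  # perfect-prediction limit
  expect_lt(confidence_loss(20, 1), 1e-8)
  # order invariance
  set.seed(33)
  lg <- rnorm(50); tg <- runif(50)
  p <- sample(50)
  expect_equal(confidence_loss(lg, tg), confidence_loss(lg[p], tg[p]))
  # agrees with an independent scalar oracle on 100 random pairs
  lg <- rnorm(100); tg <- runif(100)
  s <- plogis(lg)
  oracle <- mean(-(tg * log(s) + (1 - tg) * log(1 - s)))
  expect_equal(confidence_loss(lg, tg), oracle, tolerance = 1e-9)
  expect_error(confidence_loss(numeric(0), numeric(0)), "sample count")
})

test_that("weighted confidence loss applies the 6.0/1.0/0.5 scale weights", {
  expect_equal(weighted_confidence_loss(c(1, 1, 1)), 7.5)
  expect_equal(weighted_confidence_loss(c(0, 0, 0)), 0)
  expect_equal(weighted_confidence_loss(c(0.3, 0.7, 0.9),
                                        loss_weights(1, 1, 1)),
               0.3 + 0.7 + 0.9)
  expect_equal(weighted_confidence_loss(c(2, 3, 4)),
               6 * 2 + 1 * 3 + 0.5 * 4)
})

test_that("total_loss sums weighted confidence and location, nothing else", {
  lb <- total_loss(0.2, 0.1, 0.05, 0.4)
  expect_s3_class(lb, "loss_breakdown")
  expect_equal(lb$conf_weighted, 6 * 0.2 + 1 * 0.1 + 0.5 * 0.05)
  expect_equal(lb$total, lb$conf_weighted + lb$loc)
  # no class term exists anywhere in the breakdown
  expect_named(lb, c("conf_small", "conf_medium", "conf_large",
                     "conf_weighted", "loc", "total"))
  lb0 <- total_loss(0.3, 0.2, 0.1, 0)
  expect_equal(lb0$total, lb0$conf_weighted)
  expect_gte(lb$total, max(lb$conf_weighted, lb$loc))
})

test_that("assign_targets implements the shape-ratio gate and neighbor cells", {
  m <- tiny_model(seed = 34)
  # no objects -> zero positives
  empty <- assign_targets(data.frame(cx = numeric(), cy = numeric(),
                                     w = numeric(), h = numeric()), m,
                          input_size = 64)
  expect_equal(nrow(empty), 0)
  # one gt exactly matching the first P3 anchor, centered off the cell center
  gt <- data.frame(cx = 28, cy = 28, w = 16, h = 16)
  asg <- assign_targets(gt, m, input_size = 64)
  expect_gte(sum(asg$scale == 1 & asg$anchor == 1), 3)  # center + 2 neighbors
  expect_true(all(asg$gt == 1))
  # a gt 10x larger than every anchor at scale 1 fails the ratio gate there
  big <- data.frame(cx = 32, cy = 32, w = 320, h = 320)
  asg2 <- assign_targets(big, m, input_size = 64)
  expect_equal(sum(asg2$scale == 1), 0)
  # every assignment lies on the grid
  expect_true(all(asg$cell_i >= 1 & asg$cell_i <= 8))
})

test_that("loss gradients on a 2-box toy batch match finite differences", {
  pn <- pn_internal()
  set.seed(35)
  g <- matrix(c(20, 24, 22, 26, 44, 40, 30, 34), ncol = 4, byrow = TRUE)
  targets <- c(0.7, 0.4)
  anc <- c(24, 28)
  raw <- rnorm(10)
  lf <- function(v) {
    ts <- lapply(1:5, function(k) pn$ag_param(v[(2 * k - 1):(2 * k)]))
    bx <- pn$ag_mul(pn$ag_add(pn$ag_sub(pn$ag_mul(pn$ag_sigmoid(ts[[1]]), 2),
                                        0.5), c(2, 5)), 8)
    by <- pn$ag_mul(pn$ag_add(pn$ag_sub(pn$ag_mul(pn$ag_sigmoid(ts[[2]]), 2),
                                        0.5), c(3, 4)), 8)
    bw <- pn$ag_mul(pn$ag_square(pn$ag_mul(pn$ag_sigmoid(ts[[3]]), 2)), anc)
    bh <- pn$ag_mul(pn$ag_square(pn$ag_mul(pn$ag_sigmoid(ts[[4]]), 2)), anc)
    ci <- pn$ag_ciou(bx, by, bw, bh, g)
    loss <- pn$ag_add(pn$ag_mean(ci$loss),
                      pn$ag_bce_logits(ts[[5]], targets))
    list(loss = loss, leaves = ts)
  }
  r <- lf(raw)
  pn$ag_backward(r$loss)
  auto <- unlist(lapply(r$leaves, function(t) t$grad))
  for (i in seq_along(raw)) {
    fd <- fd_grad(function(v) pn$as_value(lf(v)$loss), raw, i)
    expect_equal(auto[i], fd, tolerance = 1e-4)
  }
})

test_that("compute_loss produces a consistent breakdown and empty scenes work", {
  m <- tiny_model(seed = 36)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  gts <- data.frame(cx = c(20, 44), cy = c(24, 40), w = c(22, 30),
                    h = c(26, 30))
  r <- compute_loss(m, img, gts)
  lb <- r$breakdown
  expect_gt(r$n_pos, 0)
  expect_equal(lb$total, lb$conf_weighted + lb$loc, tolerance = 1e-12)
  expect_equal(lb$conf_weighted,
               6 * lb$conf_small + 1 * lb$conf_medium + 0.5 * lb$conf_large,
               tolerance = 1e-12)
  # image with no objects: all-negative assignment, zero location loss
  r0 <- compute_loss(m, img, gts[0, ])
  expect_equal(r0$n_pos, 0)
  expect_equal(r0$breakdown$loc, 0)
  expect_gt(r0$breakdown$total, 0)
})

test_that("one small optimizer step on a single image decreases the loss", {
  pn <- pn_internal()
  m <- tiny_model(seed = 37)
  sc <- tiny_scene(1)
  params <- pn$collect_params(m)
  old_mode <- pn$set_training(TRUE)
  on.exit(pn$set_training(old_mode))
  losses <- numeric(11)
  for (step in 1:11) {
    pn$zero_grads(params)
    r <- compute_loss(m, sc$image, sc$gts)
    losses[step] <- r$breakdown$total
    pn$ag_backward(r$loss)
    for (p in params) if (!is.null(p$grad)) p$v <- p$v - 1e-3 * p$grad
  }
  expect_lt(losses[2], losses[1])       # first step already descends
  expect_lt(losses[11], losses[1])      # and the first 10 steps make progress
})
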
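# Training loop: Adam with decoupled weight decay, linear warmup + cosine
# learning-rate annealing, per-epoch validation AP@0.5, best-checkpoint
# tracking and early stopping on AP patience. Fully seeded.

#' Training configuration
#'
#' Defaults mirror the published schedule: 500 epochs, batch size 32,
#' initial learning rate 0.01 with cosine annealing, momentum 0.9
#' (Adam beta1), weight decay 0.0005, three warmup epochs with warmup
#' momentum 0.8, early stop after 50 epochs without validation-AP
#' improvement.
#'
#' @param epochs,batch_size,initial_lr,momentum,weight_decay,warmup_epochs,warmup_momentum,patience schedule parameters.
#' @param final_lr_fraction cosine floor as a fraction of `initial_lr`.
#' @param warmup_floor_fraction warmup start as a fraction of `initial_lr`.
#' @param optimizer only "adam" is implemented.
#' @param seed RNG seed governing shuffling and any stochastic parts.
#' @param eval_every evaluate validation AP every this many epochs.
#' @param bn_freeze_fraction after this fraction of the epochs, batch norm
#'   switches from per-batch statistics to its accumulated running
#'   statistics for the remaining epochs (and stops updating them). With
#'   single-image batches the per-batch statistics differ by illumination
#'   regime while evaluation sees one pooled estimate; freezing removes the
#'   train/eval normalization gap. Set to 1 to disable.
#' @param weights a [loss_weights()] object.
#' @param ratio_thresh anchor shape-ratio gate for target assignment.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 500, batch_size = 32, initial_lr = 0.01,
                         final_lr_fraction = 0.01,
                         warmup_floor_fraction = 0.1, momentum = 0.9,
                         weight_decay = 5e-4, warmup_epochs = 3,
                         warmup_momentum = 0.8, patience = 50,
                         optimizer = "adam", seed = 1, eval_every = 1,
                         bn_freeze_fraction = 0.5,
                         weights = loss_weights(), ratio_thresh = 4) {
  stopifnot(epochs >= 1, batch_size >= 1, patience <= epochs,
            optimizer == "adam", bn_freeze_fraction >= 0,
            bn_freeze_fraction <= 1)
  structure(list(epochs = epochs, batch_size = batch_size,
                 initial_lr = initial_lr,
                 final_lr_fraction = final_lr_fraction,
                 warmup_floor_fraction = warmup_floor_fraction,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs,
                 warmup_momentum = warmup_momentum, patience = patience,
                 optimizer = optimizer, seed = seed,
                 eval_every = eval_every,
                 bn_freeze_fraction = bn_freeze_fraction,
                 weights = weights, ratio_thresh = ratio_thresh),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warmup from `warmup_floor_fraction * initial_lr` to `initial_lr`
#' over the first `warmup_epochs` epochs, then cosine decay down to
#' `final_lr_fraction * initial_lr` at the last epoch. Non-increasing after
#' warmup.
#'
#' @param epoch 1-based epoch index in `[1, epochs]`.
#' @param config a [train_config()].
#' @return learning rate (numeric).
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch < 1 || epoch > config$epochs) stop("epoch out of range")
  lr0 <- config$initial_lr
  wu <- config$warmup_epochs
  if (epoch <= wu && wu > 0) {
    floor_lr <- config$warmup_floor_fraction * lr0
    return(floor_lr + (lr0 - floor_lr) * epoch / wu)
  }
  lrf <- config$final_lr_fraction * lr0
  span <- max(config$epochs - wu, 1)
  t <- (epoch - wu) / span
  lrf + (lr0 - lrf) * (1 + cos(pi * t)) / 2
}

# Adam beta1 during warmup ramps from warmup_momentum to momentum
beta1_schedule <- function(epoch, config) {
  wu <- config$warmup_epochs
  if (epoch > wu || wu == 0) return(config$momentum)
  config$warmup_momentum +
    (config$momentum - config$warmup_momentum) * (epoch - 1) / wu
}

adam_state <- function(params) {
  lapply(params, function(p)
    list(m = array(0, dim = dim(p$v) %||% length(p$v)),
         v = array(0, dim = dim(p$v) %||% length(p$v)), t = 0))
}

adam_step <- function(params, state, lr, beta1, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0, scale = 1) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    st <- state[[nm]]
    st$t <- st$t + 1
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^st$t)
    vhat <- st$v / (1 - beta2^st$t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    # decoupled weight decay on convolution weights only
    if (weight_decay > 0 && endsWith(nm, ".w"))
      upd <- upd + lr * weight_decay * p$v
    p$v <- p$v - upd
    state[[nm]] <- st
  }
  state
}

#' Validation AP@0.5 over a sample list
#'
#' @param model a model object.
#' @param samples list of samples (`image`, `gts`), as from
#'   [load_dataset()].
#' @param conf_floor decode confidence floor.
#' @param nms_thresh NMS IoU threshold.
#' @param iou_thresh AP match threshold.
#' @return AP in [0, 1] (0 when the set holds no ground truths is an error).
#' @export
evaluate_ap <- function(model, samples, conf_floor = 0.001,
                        nms_thresh = 0.45, iou_thresh = 0.5) {
  dets <- list(); gts <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    heads <- model_forward(model, s$image)
    d <- decode_detections(heads, model, input_size = dim(s$image)[1],
                           conf_floor = conf_floor)
    d <- nms(d, nms_thresh)
    if (nrow(d) > 0) d$image_id <- i
    dets[[i]] <- d
    g <- s$gts
    if (nrow(g) > 0) g$image_id <- i
    gts[[i]] <- g
  }
  dets <- do.call(rbind, Filter(function(d) nrow(d) > 0, dets))
  gts <- do.call(rbind, Filter(function(g) nrow(g) > 0, gts))
  if (is.null(dets)) return(0)
  average_precision(dets, gts, iou_thresh)
}

#' Train a detection model
#'
#' Iterates mini-batches of single-image losses (gradients accumulate across
#' the batch, then one Adam step), evaluates validation AP@0.5 every
#' `eval_every` epochs, tracks the best checkpoint and early-stops when the
#' best AP has not improved for `patience` epochs. A NaN loss aborts with a
#' diagnostic naming the epoch and batch. History is returned and, when
#' `out_dir` is given, persisted as CSV next to `best.ckpt` / `last.ckpt`.
#'
#' @param model a model object (modified in place; also returned).
#' @param dataset list with `train` and `val` sample lists (see
#'   [load_dataset()]), or a single list of samples used for both.
#' @param config a [train_config()].
#' @param out_dir optional output directory.
#' @param verbose print one line per evaluation.
#' @param eval_fn function(model, samples) returning the validation metric;
#'   defaults to [evaluate_ap()]. Injection point for custom early-stop
#'   metrics.
#' @return list: `model`, `history` (data frame epoch/lr/loss/ap),
#'   `best_ap`, `best_epoch`.
#' @export
train <- function(model, dataset, config = train_config(), out_dir = NULL,
                  verbose = FALSE, eval_fn = evaluate_ap) {
  if (!is.null(dataset$train)) {
    train_set <- dataset$train
    val_set <- dataset$val %||% dataset$train
  } else {
    train_set <- dataset
    val_set <- dataset
  }
  if (length(train_set) == 0) stop("empty training set")
  params <- collect_params(model)
  state <- adam_state(params)
  set.seed(config$seed)
  history <- list()
  best_ap <- -Inf; best_epoch <- 0L
  best_weights <- NULL
  freeze_at <- ceiling(config$bn_freeze_fraction * config$epochs)
  old_frozen <- set_bn_frozen(FALSE)
  on.exit(set_bn_frozen(old_frozen), add = TRUE)
  for (epoch in seq_len(config$epochs)) {
    if (epoch > freeze_at) set_bn_frozen(TRUE)
    lr <- lr_schedule(epoch, config)
    b1 <- beta1_schedule(epoch, config)
    ord <- sample.int(length(train_set))
    set_training(TRUE)
    epoch_loss <- 0; n_seen <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in seq_along(batches)) {
      zero_grads(params)
      nb <- length(batches[[bi]])
      for (si in batches[[bi]]) {
        s <- train_set[[si]]
        res <- compute_loss(model, s$image, s$gts, config$weights,
                            config$ratio_thresh)
        if (!is.finite(as_value(res$loss)))
          stop("NaN/Inf loss at epoch ", epoch, ", batch ", bi,
               " (sample index ", si, ")")
        ag_backward(res$loss)
        epoch_loss <- epoch_loss + res$breakdown$total
        n_seen <- n_seen + 1
      }
      state <- adam_step(params, state, lr, b1,
                         weight_decay = config$weight_decay, scale = 1 / nb)
    }
    set_training(FALSE)
    ap <- NA_real_
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      ap <- eval_fn(model, val_set)
      if (ap > best_ap + 1e-9) {
        best_ap <- ap
        best_epoch <- epoch
        best_weights <- list(
          params = lapply(params, function(p) p$v),
          running = lapply(collect_running(model), function(r)
            list(mean = r$mean, var = r$var)))
      }
      if (verbose)
        cat(sprintf("epoch %4d lr %.5f loss %.4f AP %.4f\n",
                    epoch, lr, epoch_loss / n_seen, ap))
    }
    history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                   loss = epoch_loss / n_seen, ap = ap)
    if (best_epoch > 0 && epoch - best_epoch >= config$patience) break
  }
  history <- do.call(rbind, history)
  if (!is.null(best_weights)) {
    for (nm in names(params)) params[[nm]]$v <- best_weights$params[[nm]]
    rn <- collect_running(model)
    for (nm in names(rn)) {
      rn[[nm]]$mean <- best_weights$running[[nm]]$mean
      rn[[nm]]$var <- best_weights$running[[nm]]$var
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "best.ckpt"))
  }
  list(model = model, history = history, best_ap = best_ap,
       best_epoch = best_epoch)
}

# ---- full-precision checkpoints ---------------------------------------------

# batch-norm running statistics live outside the parameter list but must
# round-trip for evaluation to be reproducible
collect_running <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$running)) out[[paste0(prefix, "running")]] <- m$running
  for (nm in names(m$children))
    out <- c(out, collect_running(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

#' Save a full-precision checkpoint
#'
#' Parameters and batch-norm running statistics as a flat double-precision
#' binary with a JSON sidecar of names and shapes.
#'
#' @param model a model object.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  rn <- collect_running(model)
  con <- file(path, "wb")
  on.exit(close(con))
  sidecar <- list()
  for (nm in names(ps)) {
    writeBin(as.vector(ps[[nm]]$v), con)
    sidecar[[nm]] <- as.integer(dim(ps[[nm]]$v) %||% length(ps[[nm]]$v))
  }
  for (nm in names(rn)) {
    writeBin(c(rn[[nm]]$mean, rn[[nm]]$var), con)
    sidecar[[paste0(nm, ".stats")]] <- 2L * length(rn[[nm]]$mean)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a full-precision checkpoint
#'
#' @param model a model object with matching architecture.
#' @param path checkpoint written by [save_checkpoint()].
#' @export
load_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  rn <- collect_running(model)
  con <- file(path, "rb")
  on.exit(close(con))
  for (nm in names(ps)) {
    n <- length(ps[[nm]]$v)
    vals <- readBin(con, "double", n)
    d <- dim(ps[[nm]]$v)
    ps[[nm]]$v <- if (is.null(d)) vals else array(vals, dim = d)
  }
  for (nm in names(rn)) {
    n <- length(rn[[nm]]$mean)
    vals <- readBin(con, "double", 2 * n)
    rn[[nm]]$mean <- vals[seq_len(n)]
    rn[[nm]]$var <- vals[n + seq_len(n)]
  }
  invisible(model)
}
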
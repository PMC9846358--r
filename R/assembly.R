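# Model assembly: the pear detector (reconstructed shuffle / inverted-shuffle
# backbone with CBAM), the YOLOv5s baseline, and the T1-T4 ablation variants,
# plus architecture accounting (FLOPs per the conv-layer product formula,
# parameter counts, half-precision serialized volume).

# Stage repeats and bottleneck ratio frozen by scripts/calibrate_arch.R so the
# 640x640 build lands on the published 10.1 GFLOPs / 8.3 MB operating point.
YOLOP_REPEATS <- c(15L, 3L, 2L)
YOLOP_EXPANSION <- 2

default_anchors <- function(input_size = 640) {
  s <- input_size / 640
  lapply(list(
    matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
    matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
    matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE)
  ), function(a) a * s)
}

new_model <- function(variant, input_size, anchors, width = 1) {
  m <- new_module("model")
  m$variant <- variant
  m$input_size <- input_size
  m$strides <- c(8, 16, 32)
  m$anchors <- anchors
  m$na <- nrow(anchors[[1]])
  m$width <- width
  m
}

# YOLOv5-style C3 fusion block (CSP bottleneck with 3 convolutions)
pn_c3 <- function(c1, c2, n = 1, shortcut = TRUE, act = "silu") {
  m <- new_module("c3")
  ch <- c2 %/% 2
  m$children$cv1 <- pn_conv(c1, ch, k = 1, act = act)
  m$children$cv2 <- pn_conv(c1, ch, k = 1, act = act)
  m$children$cv3 <- pn_conv(2 * ch, c2, k = 1, act = act)
  for (i in seq_len(n)) {
    m$children[[paste0("b", i, "a")]] <- pn_conv(ch, ch, k = 1, act = act)
    m$children[[paste0("b", i, "b")]] <- pn_conv(ch, ch, k = 3, act = act)
  }
  m$n <- n
  m$shortcut <- shortcut
  m$call <- function(x) {
    ch_ <- m$children
    y1 <- pn_call(ch_$cv1, x)
    for (i in seq_len(m$n)) {
      z <- pn_call(ch_[[paste0("b", i, "b")]],
                   pn_call(ch_[[paste0("b", i, "a")]], y1))
      y1 <- if (m$shortcut) op_add(y1, z) else z
    }
    pn_call(ch_$cv3, op_concat(list(y1, pn_call(ch_$cv2, x))))
  }
  m
}

# FPN + PAN neck (YOLOv5 release-6 layout) over taps with 128/256/512
# channels, plus the three 1x1 detection heads (anchors x 5 outputs: box 4 +
# objectness 1 — the detector is single-class and carries no class channel).
add_neck_head <- function(m, act, na) {
  ch <- m$children
  m$children$n_cv5 <- pn_conv(512, 256, k = 1, act = act)
  m$children$n_up <- pn_upsample2()
  m$children$n_c3a <- pn_c3(512, 256, 1, FALSE, act)
  m$children$n_cv4 <- pn_conv(256, 128, k = 1, act = act)
  m$children$n_c3b <- pn_c3(256, 128, 1, FALSE, act)
  m$children$n_d3 <- pn_conv(128, 128, k = 3, s = 2, act = act)
  m$children$n_c3c <- pn_c3(256, 256, 1, FALSE, act)
  m$children$n_d4 <- pn_conv(256, 256, k = 3, s = 2, act = act)
  m$children$n_c3d <- pn_c3(512, 512, 1, FALSE, act)
  m$children$head3 <- pn_conv(128, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  m$children$head4 <- pn_conv(256, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  m$children$head5 <- pn_conv(512, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  invisible(m)
}

run_neck_head <- function(m, p3, p4, p5) {
  ch <- m$children
  t5 <- pn_call(ch$n_cv5, p5)                                   # 256 @ /32
  f4 <- pn_call(ch$n_c3a, op_concat(list(pn_call(ch$n_up, t5), p4)))
  t4 <- pn_call(ch$n_cv4, f4)                                   # 128 @ /16
  f3 <- pn_call(ch$n_c3b, op_concat(list(pn_call(ch$n_up, t4), p3)))
  o3 <- f3                                                      # 128 @ /8
  o4 <- pn_call(ch$n_c3c, op_concat(list(pn_call(ch$n_d3, o3), t4)))
  o5 <- pn_call(ch$n_c3d, op_concat(list(pn_call(ch$n_d4, o4), t5)))
  list(pn_call(ch$head3, o3), pn_call(ch$head4, o4), pn_call(ch$head5, o5))
}

#' Build the lightweight pear-detection network
#'
#' Assembles the full detector: stage 1 is two stride-2 CBH convolutions
#' (3 -> 32 -> 64 channels), stages 2-3 are shuffle-block stages (one stride-2
#' entry followed by `stage_repeats[i]` stride-1 blocks, reaching 128 then 256
#' channels), stage 4 is an inverted-shuffle-block stage (512 channels), and
#' stage 5 is SPPF. A CBAM sits at the end of stages 2, 3 and 4; the neck
#' (FPN + PAN, all activations Hard-Swish) consumes the stage-2 and stage-3
#' CBAM outputs and the SPPF output, and the head emits 5 channels per anchor
#' at strides 8, 16 and 32.
#'
#' @param input_size input side in pixels, divisible by 32.
#' @param stage_repeats integer vector (n2, n3, n4) of stride-1 block counts.
#' @param expansion bottleneck ratio of the inverted shuffle blocks.
#' @param use_cbam insert CBAM attention (disable for the T3/T4 ablations).
#' @param cbam_reduction CBAM perceptron reduction ratio.
#' @param act activation of all CBH units.
#' @param anchors list of three 3x2 (w, h) anchor matrices in pixels.
#' @param width channel width multiplier (1 reproduces the published model;
#'   smaller values give desk-scale variants for training experiments).
#' @return a model object; see [count_flops()], [detect()], [train()].
#' @export
build_yolop <- function(input_size = 640, stage_repeats = YOLOP_REPEATS,
                        expansion = YOLOP_EXPANSION, use_cbam = TRUE,
                        cbam_reduction = 16, act = "hardswish",
                        anchors = default_anchors(input_size), width = 1) {
  if (input_size %% 32 != 0)
    stop("invalid configuration: input size must be divisible by 32")
  w <- function(c) max(8L, as.integer(round(c * width)))
  m <- new_model("yolop", input_size, anchors, width)
  m$widths <- vapply(c(32, 64, 128, 256, 512), w, integer(1))
  cw <- m$widths
  m$children$stem1 <- cbh(3, cw[1], 3, 2, act)
  m$children$stem2 <- cbh(cw[1], cw[2], 3, 2, act)
  add_stage <- function(name, maker, cin, n) {
    m$children[[paste0(name, "_d")]] <- maker(cin, 2)
    for (i in seq_len(n))
      m$children[[paste0(name, "_", i)]] <- maker(2 * cin, 1)
  }
  sb <- function(cin, s) shuffle_block(cin, s, act)
  isb <- function(cin, s) inverted_shuffle_block(cin, s, expansion, act)
  add_stage("s2", sb, cw[2], stage_repeats[1])
  add_stage("s3", sb, cw[3], stage_repeats[2])
  add_stage("s4", isb, cw[4], stage_repeats[3])
  if (use_cbam) {
    m$children$cbam2 <- cbam(cw[3], cbam_reduction)
    m$children$cbam3 <- cbam(cw[4], cbam_reduction)
    m$children$cbam4 <- cbam(cw[5], cbam_reduction)
  }
  m$children$sppf <- sppf(cw[5], cw[5], act)
  m$use_cbam <- use_cbam
  m$repeats <- stage_repeats
  # neck assumes the published 128/256/512 tap widths; scale via pn_conv taps
  if (width == 1) add_neck_head(m, act, m$na) else add_neck_head_scaled(m, act, m$na, cw)
  m$call <- function(x) {
    ch <- m$children
    run_stage <- function(x, name, n) {
      x <- pn_call(ch[[paste0(name, "_d")]], x)
      for (i in seq_len(n)) x <- pn_call(ch[[paste0(name, "_", i)]], x)
      x
    }
    x <- pn_call(ch$stem2, pn_call(ch$stem1, x))
    x <- run_stage(x, "s2", m$repeats[1])
    if (m$use_cbam) x <- pn_call(ch$cbam2, x)
    p3 <- x
    x <- run_stage(x, "s3", m$repeats[2])
    if (m$use_cbam) x <- pn_call(ch$cbam3, x)
    p4 <- x
    x <- run_stage(x, "s4", m$repeats[3])
    if (m$use_cbam) x <- pn_call(ch$cbam4, x)
    p5 <- pn_call(ch$sppf, x)
    run_neck_head(m, p3, p4, p5)
  }
  m
}

# width-scaled neck for desk-scale models (tap widths cw[3:5])
add_neck_head_scaled <- function(m, act, na, cw) {
  c3 <- cw[3]; c4 <- cw[4]; c5 <- cw[5]
  m$children$n_cv5 <- pn_conv(c5, c4, k = 1, act = act)
  m$children$n_up <- pn_upsample2()
  m$children$n_c3a <- pn_c3(2 * c4, c4, 1, FALSE, act)
  m$children$n_cv4 <- pn_conv(c4, c3, k = 1, act = act)
  m$children$n_c3b <- pn_c3(2 * c3, c3, 1, FALSE, act)
  m$children$n_d3 <- pn_conv(c3, c3, k = 3, s = 2, act = act)
  m$children$n_c3c <- pn_c3(2 * c3, c4, 1, FALSE, act)
  m$children$n_d4 <- pn_conv(c4, c4, k = 3, s = 2, act = act)
  m$children$n_c3d <- pn_c3(2 * c4, c5, 1, FALSE, act)
  m$children$head3 <- pn_conv(c3, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  m$children$head4 <- pn_conv(c4, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  m$children$head5 <- pn_conv(c5, na * 5, k = 1, act = "linear",
                              bn = FALSE, bias = TRUE)
  invisible(m)
}

# reference YOLOv5s backbone (CSP-DarkNet53, width 0.50 / depth 0.33)
build_yolov5s <- function(input_size, anchors) {
  act <- "silu"
  m <- new_model("yolov5s", input_size, anchors)
  m$children$stem <- pn_conv(3, 32, k = 6, s = 2, p = 2, act = act)
  m$children$cv1 <- pn_conv(32, 64, k = 3, s = 2, act = act)
  m$children$c3_1 <- pn_c3(64, 64, 1, TRUE, act)
  m$children$cv2 <- pn_conv(64, 128, k = 3, s = 2, act = act)
  m$children$c3_2 <- pn_c3(128, 128, 2, TRUE, act)
  m$children$cv3 <- pn_conv(128, 256, k = 3, s = 2, act = act)
  m$children$c3_3 <- pn_c3(256, 256, 3, TRUE, act)
  m$children$cv4 <- pn_conv(256, 512, k = 3, s = 2, act = act)
  m$children$c3_4 <- pn_c3(512, 512, 1, TRUE, act)
  m$children$sppf <- sppf(512, 512, act)
  add_neck_head(m, act, m$na)
  m$call <- function(x) {
    ch <- m$children
    x <- pn_call(ch$c3_1, pn_call(ch$cv1, pn_call(ch$stem, x)))
    p3 <- pn_call(ch$c3_2, pn_call(ch$cv2, x))
    p4 <- pn_call(ch$c3_3, pn_call(ch$cv3, p3))
    p5 <- pn_call(ch$sppf, pn_call(ch$c3_4, pn_call(ch$cv4, p4)))
    run_neck_head(m, p3, p4, p5)
  }
  m
}

# T1/T2 ablations: the YOLOv5s stem is kept, the four downsample + C3 groups
# are replaced wholesale by shuffle (T1) or inverted shuffle (T2) stages.
build_all_block_variant <- function(variant, input_size, anchors,
                                    stage_repeats, expansion) {
  act <- "silu"
  maker <- if (variant == "T1") {
    function(cin, s) shuffle_block(cin, s, act)
  } else {
    function(cin, s) inverted_shuffle_block(cin, s, expansion, act)
  }
  m <- new_model(variant, input_size, anchors)
  m$children$stem <- pn_conv(3, 32, k = 6, s = 2, p = 2, act = act)
  reps <- c(1L, stage_repeats)
  cins <- c(32, 64, 128, 256)
  for (k in seq_len(4)) {
    m$children[[paste0("g", k, "_d")]] <- maker(cins[k], 2)
    for (i in seq_len(reps[k]))
      m$children[[paste0("g", k, "_", i)]] <- maker(2 * cins[k], 1)
  }
  m$children$sppf <- sppf(512, 512, act)
  add_neck_head(m, act, m$na)
  m$repeats <- reps
  m$call <- function(x) {
    ch <- m$children
    x <- pn_call(ch$stem, x)
    outs <- list()
    for (k in seq_len(4)) {
      x <- pn_call(ch[[paste0("g", k, "_d")]], x)
      for (i in seq_len(m$repeats[k]))
        x <- pn_call(ch[[paste0("g", k, "_", i)]], x)
      outs[[k]] <- x
    }
    p5 <- pn_call(ch$sppf, outs[[4]])
    run_neck_head(m, outs[[2]], outs[[3]], p5)
  }
  m
}

#' Build a baseline or ablation variant
#'
#' * `yolov5s` — the reference CSP-DarkNet53 + PANet single-class baseline
#'   with SiLU activations.
#' * `T1` / `T2` — all four backbone stage groups replaced by shuffle /
#'   inverted shuffle blocks (SiLU, no attention).
#' * `T3` — the mixed shuffle + inverted-shuffle backbone with SiLU retained
#'   and no CBAM.
#' * `T4` — T3 with Hard-Swish activations (parameter count identical to T3).
#' * `yolop` — T4 plus CBAM (the full model; equivalent to [build_yolop()]).
#'
#' @param name one of "yolov5s", "T1", "T2", "T3", "T4", "yolop".
#' @param input_size input side in pixels.
#' @param stage_repeats,expansion backbone configuration (see
#'   [build_yolop()]); T1/T2 reuse the same repeats for their stages.
#' @param anchors anchor list (defaults to the stock three-scale set).
#' @return a model object.
#' @export
build_variant <- function(name, input_size = 640,
                          stage_repeats = YOLOP_REPEATS,
                          expansion = YOLOP_EXPANSION,
                          anchors = default_anchors(input_size)) {
  valid <- c("yolov5s", "T1", "T2", "T3", "T4", "yolop")
  if (!name %in% valid)
    stop("unknown variant '", name, "'; valid variants: ",
         paste(valid, collapse = ", "))
  switch(name,
    yolov5s = build_yolov5s(input_size, anchors),
    T1 = build_all_block_variant("T1", input_size, anchors, stage_repeats,
                                 expansion),
    T2 = build_all_block_variant("T2", input_size, anchors, stage_repeats,
                                 expansion),
    T3 = build_yolop(input_size, stage_repeats, expansion, use_cbam = FALSE,
                     act = "silu", anchors = anchors),
    T4 = build_yolop(input_size, stage_repeats, expansion, use_cbam = FALSE,
                     act = "hardswish", anchors = anchors),
    yolop = build_yolop(input_size, stage_repeats, expansion,
                        anchors = anchors))
}

#' Forward pass of a detection model
#'
#' Runs the model in evaluation mode (batch-norm running statistics, no
#' gradient tape) and returns the three raw head maps.
#'
#' @param model a model object.
#' @param image numeric array, dim = c(S, S, 3), values in any real range.
#' @return list of three arrays with dims (S/8, S/8, 15), (S/16, ...), (S/32, ...).
#' @export
model_forward <- function(model, image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  no_grad(lapply(pn_call(model, ag_const(image)), as_value))
}

#' Count FLOPs of a model by the conv-layer product formula
#'
#' For every convolutional layer the multiply-accumulate count is
#' `L^2 * K^2 * C_out * C_in`, with `L` the output spatial side, `K` the
#' kernel side, and `C_in` the per-group input width (so depthwise layers
#' contribute with `C_in = 1`). Non-convolutional layers contribute nothing.
#' A multiply-accumulate is two floating-point operations, so the reported
#' total is `ops_per_mac` (default 2) times the summed products — the
#' convention under which the published model-accounting tables are stated.
#'
#' @param model a model object.
#' @param input_size input side in pixels (default: the model's build size).
#' @param ops_per_mac floating-point operations counted per MAC; set to 1 to
#'   obtain the raw product sum.
#' @return total FLOPs (numeric); the per-layer table, in MAC units, is
#'   attached as attribute `layers`.
#' @export
count_flops <- function(model, input_size = model$input_size,
                        ops_per_mac = 2) {
  s <- pn_call(model, make_shape(3, input_size, input_size))
  layers <- do.call(rbind, s[[1]]$tally$rows)
  total <- ops_per_mac * sum(layers$macs)
  attr(total, "layers") <- layers
  total
}

#' Count learnable parameters of a model
#'
#' Convolution weights and biases plus batch-norm scale/shift; running
#' statistics are not learnable and are excluded.
#'
#' @param model a model object.
#' @return integer-valued numeric.
#' @export
count_params <- function(model) n_params(model)

# ---- half-precision weight archive ------------------------------------------

WEIGHT_MAGIC <- "PNWF"

#' Serialize model weights at half precision
#'
#' Writes every learnable parameter as IEEE-754 binary16 into a flat archive
#' (4-byte magic + 4-byte tensor count header) and a JSON sidecar with layer
#' names and shapes. The loader validates the sidecar against the model.
#'
#' @param model a model object.
#' @param path output file; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
serialize_weights <- function(model, path) {
  ps <- collect_params(model)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(WEIGHT_MAGIC), con)
  writeBin(as.integer(length(ps)), con, size = 4, endian = "little")
  for (p in ps) writeBin(double_to_half(as.vector(p$v)), con)
  sidecar <- list(
    magic = WEIGHT_MAGIC,
    tensors = lapply(ps, function(p) as.integer(dim(p$v) %||% length(p$v))))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load half-precision weights into a model
#'
#' @param model a model object whose architecture matches the archive.
#' @param path archive written by [serialize_weights()].
#' @return the model, invisibly.
#' @export
load_weights <- function(model, path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  ps <- collect_params(model)
  if (length(sidecar$tensors) != length(ps))
    stop("weight archive does not match model: tensor count differs")
  for (nm in names(ps)) {
    want <- as.integer(dim(ps[[nm]]$v) %||% length(ps[[nm]]$v))
    got <- as.integer(unlist(sidecar$tensors[[nm]]))
    if (!identical(want, got))
      stop("shape mismatch for ", nm)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != WEIGHT_MAGIC) stop("not a weight archive")
  readBin(con, "integer", 1, size = 4, endian = "little")
  for (nm in names(ps)) {
    n <- length(ps[[nm]]$v)
    vals <- half_to_double(readBin(con, "raw", 2 * n))
    d <- dim(ps[[nm]]$v)
    ps[[nm]]$v <- if (is.null(d)) vals else array(vals, dim = d)
  }
  invisible(model)
}

#' Serialized model volume in megabytes
#'
#' Size of the half-precision weight archive, in MB (10^6 bytes): two bytes
#' per learnable parameter plus an 8-byte header.
#'
#' @param model a model object.
#' @param path optional path to keep the archive; defaults to a tempfile
#'   removed afterwards.
#' @return megabytes (numeric).
#' @export
serialized_volume <- function(model, path = NULL) {
  keep <- !is.null(path)
  if (!keep) path <- tempfile(fileext = ".pnw")
  serialize_weights(model, path)
  mb <- file.size(path) / 1e6
  if (!keep) {
    unlink(path)
    unlink(paste0(path, ".json"))
  }
  mb
}

#' Architecture summary
#'
#' @param model a model object.
#' @param input_size input side for the FLOPs count.
#' @return list with `parameter_count`, `flops`, `gflops`,
#'   `serialized_megabytes`.
#' @export
model_summary <- function(model, input_size = model$input_size) {
  fl <- count_flops(model, input_size)
  list(parameter_count = count_params(model),
       flops = as.numeric(fl),
       gflops = as.numeric(fl) / 1e9,
       serialized_megabytes = serialized_volume(model))
}
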
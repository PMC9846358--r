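# Synthetic orchard scenes with exact ground truth.
#
# The generator emulates the structure of an orchard detection dataset:
# pear-like elliptical targets whose on-image size encodes camera distance
# (background-complexity tiers), leaf-like occluders placed to achieve a
# requested shade degree Ks (measured exactly on pixel masks, never assumed),
# day/night illumination, a six-strategy augmentation menu, and an 80:20
# train/validation split. Everything is reproducible from a single seed.

# on-image pear diameter bands (pixels at a 640 canvas) per complexity tier;
# closer camera = larger fruit = less cluttered background
TIER_BANDS <- list(uncomplicated = c(120, 200),
                   moderate = c(60, 120),
                   extreme = c(20, 60))
TIER_CLUTTER <- c(uncomplicated = 6, moderate = 14, extreme = 30)

#' Parameters of one synthetic scene
#'
#' @param image_size canvas side in pixels.
#' @param complexity_tier "uncomplicated", "moderate" or "extreme"; controls
#'   the pear size band (decreasing with tier) and clutter density.
#' @param n_pears number of pears.
#' @param ks_targets requested shade degree per pear (0 = unoccluded); values
#'   must be < 1. Recycled to `n_pears`.
#' @param illumination "day" or "night".
#' @param rng_seed integer seed; the same spec renders bit-identical scenes.
#' @param size_band optional c(min, max) pear diameter in pixels, overriding
#'   the tier band (used by desk-scale training experiments).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 640,
                       complexity_tier = c("uncomplicated", "moderate",
                                           "extreme"),
                       n_pears = 4, ks_targets = 0,
                       illumination = c("day", "night"), rng_seed = 1,
                       size_band = NULL) {
  complexity_tier <- match.arg(complexity_tier)
  illumination <- match.arg(illumination)
  ks_targets <- rep_len(ks_targets, max(n_pears, 1))
  if (n_pears > 0 && any(ks_targets >= 1))
    stop("requested Ks must be < 1")
  structure(list(image_size = image_size, complexity_tier = complexity_tier,
                 n_pears = n_pears, ks_targets = ks_targets,
                 illumination = illumination, rng_seed = rng_seed,
                 size_band = size_band),
            class = "scene_spec")
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# bilinear upscale of a coarse grid to an S x S field (low-frequency noise)
smooth_field <- function(coarse, S) {
  K <- nrow(coarse)
  pos <- (seq_len(S) - 0.5) / S * (K - 1) + 1
  i0 <- pmin(floor(pos), K - 1); f <- pos - i0
  a <- coarse[i0, i0]
  b <- coarse[i0 + 1, i0]
  c <- coarse[i0, i0 + 1]
  d <- coarse[i0 + 1, i0 + 1]
  fr <- matrix(f, S, S); fc <- matrix(f, S, S, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + c * (1 - fr) * fc +
    d * fr * fc
}

# logical mask of an axis-aligned ellipse on an S x S canvas
ellipse_mask <- function(S, cx, cy, ax, ay) {
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
}

paint_rgb <- function(img, mask, col) {
  for (k in 1:3) {
    ch <- img[, , k]
    val <- if (is.matrix(col[[k]])) col[[k]][mask] else col[[k]]
    ch[mask] <- val
    img[, , k] <- ch
  }
  img
}

#' Shade degree from pixel masks
#'
#' `Ks = |total & (union of occluders)| / |total|` — the fraction of the
#' fruit's area hidden by occluders — and the corresponding category:
#' not_or_slight (Ks <= 0.2), medium (0.2 < Ks <= 0.4), serious
#' (0.4 < Ks < 0.6), and beyond_scope (Ks >= 0.6; such targets sit outside
#' the detector's design envelope and are excluded from stratified
#' evaluation by default).
#'
#' @param total_mask logical matrix, the full (amodal) fruit mask; must be
#'   non-empty.
#' @param occluder_masks list of logical matrices of the same size.
#' @return list with `ks` and `shade_category`.
#' @export
compute_shade_degree <- function(total_mask, occluder_masks) {
  if (!any(total_mask)) stop("empty total mask")
  occ <- Reduce(`|`, occluder_masks, init = array(FALSE, dim(total_mask)))
  ks <- sum(total_mask & occ) / sum(total_mask)
  list(ks = ks, shade_category = shade_category(ks))
}

shade_category <- function(ks) {
  ifelse(ks >= 0.6, "beyond_scope",
         ifelse(ks > 0.4, "serious",
                ifelse(ks > 0.2, "medium", "not_or_slight")))
}

#' Render one synthetic orchard scene
#'
#' Background: a low-frequency green-brown field with tier-scaled clutter
#' (leaf-like ellipses and branch-like strokes). Pears: yellow-green
#' ellipses with radial shading and a specular highlight, sized by the tier
#' band and placed without mutual overlap. Occluders: leaf ellipses whose
#' offset from the fruit center is found by bisection so the measured cover
#' fraction hits the requested Ks within +/- 0.02; the recorded Ks is always
#' re-measured from the final masks. Night mode multiplies luminance by a
#' directional gradient and a cast-shadow band. Boxes are exact amodal
#' ellipse bounds.
#'
#' @param spec a [scene_spec()].
#' @return list: `image` (S x S x 3 array in [0, 1]) and `gts` (data frame
#'   with cx, cy, w, h in pixels, ks, shade_category, visible_area,
#'   total_area).
#' @export
generate_scene <- function(spec) {
  with_seed(spec$rng_seed, render_scene(spec))
}

render_scene <- function(spec) {
  S <- spec$image_size
  band <- spec$size_band %||% (TIER_BANDS[[spec$complexity_tier]] * S / 640)
  n_clutter <- ceiling(TIER_CLUTTER[[spec$complexity_tier]] * (S / 640)^0.5)

  img <- array(0, dim = c(S, S, 3))
  K <- 8
  base_col <- c(0.30, 0.42, 0.18)
  for (k in 1:3)
    img[, , k] <- smooth_field(matrix(stats::runif(K * K, base_col[k] * 0.6,
                                                   base_col[k] * 1.5), K, K), S)

  # clutter: leaf ellipses and branch strokes
  for (q in seq_len(n_clutter)) {
    cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
    if (stats::runif(1) < 0.7) {
      ax <- stats::runif(1, 0.015, 0.05) * S
      mk <- ellipse_mask(S, cx, cy, ax, ax * stats::runif(1, 0.4, 0.8))
      col <- c(stats::runif(1, 0.05, 0.25), stats::runif(1, 0.25, 0.55),
               stats::runif(1, 0.05, 0.2))
    } else {
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 0.1, 0.3) * S
      x <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
      y <- matrix(seq_len(S), S, S) - cy
      along <- x * cos(ang) + y * sin(ang)
      across <- -x * sin(ang) + y * cos(ang)
      mk <- abs(along) <= len / 2 & abs(across) <= stats::runif(1, 1, 3)
      col <- c(stats::runif(1, 0.25, 0.4), stats::runif(1, 0.15, 0.3),
               stats::runif(1, 0.05, 0.15))
    }
    img <- paint_rgb(img, mk, as.list(col))
  }

  # pears: rejection placement, no mutual overlap, fully inside the frame
  pears <- list()
  for (p in seq_len(spec$n_pears)) {
    placed <- FALSE
    for (try in 1:200) {
      d <- stats::runif(1, band[1], band[2])
      ay <- d / 2
      ax <- ay * stats::runif(1, 0.8, 0.95)
      cx <- stats::runif(1, ax + 2, S - ax - 1)
      cy <- stats::runif(1, ay + 2, S - ay - 1)
      ok <- TRUE
      for (q in pears) {
        if ((cx - q$cx)^2 + (cy - q$cy)^2 <
            (1.1 * (max(ax, ay) + max(q$ax, q$ay)))^2) { ok <- FALSE; break }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place pear ", p, " without overlap; reduce n_pears")
    pears[[p]] <- list(cx = cx, cy = cy, ax = ax, ay = ay,
                       mask = ellipse_mask(S, cx, cy, ax, ay))
  }

  # paint pears with radial shading + highlight
  for (p in pears) {
    x <- matrix(seq_len(S), S, S, byrow = TRUE)
    y <- matrix(seq_len(S), S, S)
    r2 <- ((x - p$cx) / p$ax)^2 + ((y - p$cy) / p$ay)^2
    shade <- 1 - 0.45 * pmin(r2, 1)
    hx <- p$cx - 0.35 * p$ax; hy <- p$cy - 0.35 * p$ay
    hl <- 0.25 * exp(-(((x - hx) / (0.45 * p$ax))^2 +
                         ((y - hy) / (0.45 * p$ay))^2))
    base <- c(stats::runif(1, 0.6, 0.75), stats::runif(1, 0.68, 0.85),
              stats::runif(1, 0.2, 0.32))
    col <- lapply(base, function(b) pmin(b * shade + hl, 1))
    img <- paint_rgb(img, p$mask, col)
  }

  # occluders: bisect the leaf offset until the measured cover hits Ks
  occ_masks <- list()
  for (p in seq_along(pears)) {
    ks_t <- spec$ks_targets[p]
    if (ks_t <= 0) next
    pear <- pears[[p]]
    area <- sum(pear$mask)
    # approach from the side away from the nearest other pear: keeps the
    # leaf from accidentally shading a neighbour
    others <- pears[-p]
    theta0 <- if (length(others) == 0) stats::runif(1, 0, 2 * pi) else {
      nb <- others[[which.min(vapply(others, function(q)
        (q$cx - pear$cx)^2 + (q$cy - pear$cy)^2, numeric(1)))]]
      atan2(pear$cy - nb$cy, pear$cx - nb$cx)
    }
    res <- NULL
    # mask quantization can make the cover fraction jump past the target;
    # retry with a fresh leaf geometry when bisection cannot land inside the
    # +/- 0.02 window
    for (attempt in 1:8) {
      lax <- pear$ax * stats::runif(1, 0.9, 1.3)
      lay <- pear$ay * stats::runif(1, 0.9, 1.3)
      theta <- if (attempt == 1) theta0
               else theta0 + (attempt - 1) * stats::runif(1, 0.2, 0.6)
      cover_at <- function(delta) {
        mk <- ellipse_mask(S, pear$cx + delta * cos(theta),
                           pear$cy + delta * sin(theta), lax, lay)
        list(mask = mk, ks = sum(mk & pear$mask) / area)
      }
      if (cover_at(0)$ks < ks_t) next
      lo <- 0; hi <- max(pear$ax + lax, pear$ay + lay) + 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        r <- cover_at(mid)
        if (abs(r$ks - ks_t) <= 0.02) { res <- r; break }
        if (r$ks > ks_t) lo <- mid else hi <- mid
      }
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("unattainable Ks for object ", p,
           " (search did not converge within +/- 0.02)")
    occ_masks[[length(occ_masks) + 1L]] <- res$mask
    leaf_col <- c(stats::runif(1, 0.05, 0.2), stats::runif(1, 0.3, 0.5),
                  stats::runif(1, 0.05, 0.18))
    img <- paint_rgb(img, res$mask, as.list(leaf_col))
  }

  if (spec$illumination == "night") {
    ang <- stats::runif(1, 0, 2 * pi)
    x <- matrix(seq_len(S), S, S, byrow = TRUE) / S - 0.5
    y <- matrix(seq_len(S), S, S) / S - 0.5
    along <- x * cos(ang) + y * sin(ang)
    lum <- 0.25 + 0.45 * (along - min(along)) / (max(along) - min(along))
    band_c <- stats::runif(1, -0.2, 0.2)
    shadow <- abs(-x * sin(ang) + y * cos(ang) - band_c) <
      stats::runif(1, 0.05, 0.12)
    lum[shadow] <- lum[shadow] * 0.5
    for (k in 1:3) img[, , k] <- img[, , k] * lum
  }
  img <- pmin(pmax(img, 0), 1)

  occ_union <- Reduce(`|`, occ_masks,
                      init = array(FALSE, dim = c(S, S)))
  gts <- do.call(rbind, lapply(seq_along(pears), function(p) {
    pe <- pears[[p]]
    total <- sum(pe$mask)
    hidden <- sum(pe$mask & occ_union)
    ks <- hidden / total
    data.frame(cx = pe$cx, cy = pe$cy, w = 2 * pe$ax, h = 2 * pe$ay,
               ks = ks, shade_category = shade_category(ks),
               visible_area = total - hidden, total_area = total,
               stringsAsFactors = FALSE)
  }))
  if (is.null(gts))
    gts <- data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), ks = numeric(),
                      shade_category = character(),
                      visible_area = integer(), total_area = integer())
  list(image = img, gts = gts)
}

# ---- augmentation -----------------------------------------------------------

AUGMENT_STRATEGIES <- c("hflip", "vflip", "scale", "brightness", "blur",
                        "noise")

#' Randomized augmentation (three of six strategies)
#'
#' Draws exactly 3 distinct strategies from {horizontal flip, vertical flip,
#' scaling, brightness, Gaussian blur, Gaussian noise} and applies each with
#' its own parameters: flips fire with probability 0.5; scaling shrinks the
#' content by a factor in [0.80, 0.95] (canvas-padded, centered); brightness
#' multiplies by a factor in [0.35, 1.50]; blur and noise draw their kernel
#' width / variance at random. Geometric strategies transform the boxes;
#' photometric ones leave them untouched. Boxes whose in-canvas remainder
#' falls below 10% of their area are dropped (`n_dropped` reports how many).
#'
#' @param image S x S x 3 array.
#' @param labels data frame with cx, cy, w, h in pixels.
#' @param seed integer; fixing it reproduces the same strategy triple and
#'   parameters.
#' @return list: `image`, `labels`, `applied` (character vector),
#'   `n_dropped`.
#' @export
augment <- function(image, labels, seed = 1) {
  with_seed(seed, {
    S <- dim(image)[1]
    chosen <- sample(AUGMENT_STRATEGIES, 3)
    applied <- character(0)
    for (strat in AUGMENT_STRATEGIES) {   # canonical order, geometric first
      if (!strat %in% chosen) next
      if (strat == "hflip") {
        if (stats::runif(1) < 0.5) {
          image <- image[, dim(image)[2]:1, , drop = FALSE]
          labels$cx <- S - labels$cx
          applied <- c(applied, "hflip")
        }
      } else if (strat == "vflip") {
        if (stats::runif(1) < 0.5) {
          image <- image[dim(image)[1]:1, , , drop = FALSE]
          labels$cy <- S - labels$cy
          applied <- c(applied, "vflip")
        }
      } else if (strat == "scale") {
        f <- stats::runif(1, 0.80, 0.95)
        Sf <- max(2L, round(S * f))
        src <- pmin(S, pmax(1L, round(seq_len(Sf) / Sf * S)))
        off <- floor((S - Sf) / 2)
        canvas <- array(0, dim = dim(image))
        canvas[off + seq_len(Sf), off + seq_len(Sf), ] <-
          image[src, src, , drop = FALSE]
        image <- canvas
        fs <- Sf / S
        labels$cx <- labels$cx * fs + off
        labels$cy <- labels$cy * fs + off
        labels$w <- labels$w * fs
        labels$h <- labels$h * fs
        applied <- c(applied, sprintf("scale(%.3f)", f))
      } else if (strat == "brightness") {
        f <- stats::runif(1, 0.35, 1.50)
        image <- pmin(pmax(image * f, 0), 1)
        applied <- c(applied, sprintf("brightness(%.2f)", f))
      } else if (strat == "blur") {
        sd <- stats::runif(1, 0.5, 1.5)
        image <- gaussian_blur(image, sd)
        applied <- c(applied, sprintf("blur(%.2f)", sd))
      } else if (strat == "noise") {
        sd <- stats::runif(1, 0.01, 0.05)
        image <- pmin(pmax(image +
          array(stats::rnorm(length(image), 0, sd), dim = dim(image)), 0), 1)
        applied <- c(applied, sprintf("noise(%.3f)", sd))
      }
    }
    # clip boxes to the canvas; drop those with < 10% of their area left
    n0 <- nrow(labels)
    if (n0 > 0) {
      x1 <- pmax(labels$cx - labels$w / 2, 0)
      x2 <- pmin(labels$cx + labels$w / 2, S)
      y1 <- pmax(labels$cy - labels$h / 2, 0)
      y2 <- pmin(labels$cy + labels$h / 2, S)
      vis <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
      keep <- vis >= 0.1 * labels$w * labels$h
      labels <- labels[keep, , drop = FALSE]
    }
    list(image = image, labels = labels, applied = applied,
         n_dropped = n0 - nrow(labels))
  })
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(image, sd, radius = 2) {
  ker <- stats::dnorm(-radius:radius, sd = sd)
  ker <- ker / sum(ker)
  S1 <- dim(image)[1]; S2 <- dim(image)[2]
  pad_idx <- function(i, n) pmin(pmax(i, 1), n)
  for (k in seq_len(dim(image)[3])) {
    ch <- image[, , k]
    acc <- matrix(0, S1, S2)
    for (t in -radius:radius)
      acc <- acc + ker[t + radius + 1] * ch[pad_idx(seq_len(S1) + t, S1), ]
    ch <- acc
    acc <- matrix(0, S1, S2)
    for (t in -radius:radius)
      acc <- acc + ker[t + radius + 1] * ch[, pad_idx(seq_len(S2) + t, S2)]
    image[, , k] <- acc
  }
  image
}

# ---- label and manifest I/O -------------------------------------------------

#' Write labels in single-class YOLO txt format
#'
#' One line per object: `0 cx cy w h`, center coordinates and sides
#' normalized to [0, 1] with 8 decimal places.
#'
#' @param labels data frame with cx, cy, w, h in pixels.
#' @param path output file.
#' @param image_size canvas side in pixels.
#' @export
write_yolo_labels <- function(labels, path, image_size) {
  lines <- sprintf("0 %.8f %.8f %.8f %.8f",
                   labels$cx / image_size, labels$cy / image_size,
                   labels$w / image_size, labels$h / image_size)
  writeLines(lines, path)
  invisible(path)
}

#' Read single-class YOLO txt labels
#'
#' @param path label file written by [write_yolo_labels()].
#' @param image_size canvas side used to de-normalize.
#' @return data frame with cx, cy, w, h in pixels.
#' @export
read_yolo_labels <- function(path, image_size) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric()))
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  data.frame(cx = m[, 2] * image_size, cy = m[, 3] * image_size,
             w = m[, 4] * image_size, h = m[, 5] * image_size)
}

#' Generate a synthetic detection dataset on disk
#'
#' Renders `n_images` scenes (PNG), writes YOLO txt labels, applies the
#' 80:20 split and saves a YAML manifest with per-image tier/illumination
#' tags and per-object shade metadata. Tier and night proportions default to
#' the composition of the emulated orchard dataset (23/31/46% of images per
#' complexity tier, 30% night).
#'
#' @param n_images number of scenes.
#' @param dir output directory (created if needed).
#' @param image_size canvas side.
#' @param seed master seed; per-image seeds are derived from it.
#' @param tier_probs probabilities of the three tiers.
#' @param night_fraction fraction of night scenes.
#' @param ks_menu function(n) returning n requested Ks values; the default
#'   mixes unoccluded fruit with light, medium and serious shade.
#' @param split_ratio train fraction (default 0.8).
#' @return the manifest (invisibly also written to `dir/manifest.yaml`).
#' @export
generate_dataset <- function(n_images, dir, image_size = 640, seed = 1,
                             tier_probs = c(0.23, 0.31, 0.46),
                             night_fraction = 0.30,
                             ks_menu = default_ks_menu,
                             split_ratio = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiers <- names(TIER_BANDS)
  records <- list()
  with_seed(seed, {
    tier_draw <- sample(tiers, n_images, replace = TRUE, prob = tier_probs)
    night_draw <- stats::runif(n_images) < night_fraction
    seeds <- sample.int(.Machine$integer.max, n_images)
    for (i in seq_len(n_images)) {
      n_pears <- switch(tier_draw[i], uncomplicated = sample(1:3, 1),
                        moderate = sample(2:4, 1), extreme = sample(3:6, 1))
      # a draw can be unrenderable (e.g. a shade target on a fruit too small
      # for +/- 0.02 mask control); redraw the scene with a derived seed
      sc <- NULL
      for (try in 0:9) {
        spec <- scene_spec(image_size = image_size,
                           complexity_tier = tier_draw[i],
                           n_pears = n_pears, ks_targets = ks_menu(n_pears),
                           illumination = if (night_draw[i]) "night"
                                          else "day",
                           rng_seed = (seeds[i] + try * 7919L) %%
                             .Machine$integer.max)
        sc <- tryCatch(generate_scene(spec), error = function(e) NULL)
        if (!is.null(sc)) break
      }
      if (is.null(sc))
        stop("could not render scene ", i, " after 10 attempts")
      img_file <- sprintf("img_%04d.png", i)
      lab_file <- sprintf("img_%04d.txt", i)
      png::writePNG(sc$image, file.path(dir, img_file))
      write_yolo_labels(sc$gts, file.path(dir, lab_file), image_size)
      records[[i]] <- list(image = img_file, label = lab_file,
                           tier = tier_draw[i],
                           illumination = if (night_draw[i]) "night" else "day",
                           objects = lapply(seq_len(nrow(sc$gts)), function(r)
                             list(ks = sc$gts$ks[r],
                                  shade_category = sc$gts$shade_category[r])))
    }
  })
  manifest <- list(image_size = image_size, records = records)
  manifest <- split_dataset(manifest, ratio = split_ratio, seed = seed + 1L)
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param n number of values to draw.
#' @export
default_ks_menu <- function(n) {
  ks <- numeric(n)
  u <- stats::runif(n)
  ks[u >= 0.4 & u < 0.6] <- stats::runif(sum(u >= 0.4 & u < 0.6), 0.02, 0.2)
  ks[u >= 0.6 & u < 0.8] <- stats::runif(sum(u >= 0.6 & u < 0.8), 0.22, 0.4)
  ks[u >= 0.8] <- stats::runif(sum(u >= 0.8), 0.42, 0.55)
  ks
}

#' Split a dataset manifest 80:20
#'
#' Shuffles the records with the given seed and assigns the first
#' `round(ratio * n)` to the training split, the rest to validation; no
#' record lands in both.
#'
#' @param manifest manifest list with a `records` element.
#' @param ratio train fraction in (0, 1).
#' @param seed shuffle seed.
#' @return the manifest with a `split` element (`train` / `val` index
#'   vectors).
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(manifest$records)
  if (n == 0) stop("cannot split an empty manifest")
  with_seed(seed, {
    ord <- sample.int(n)
    n_train <- round(ratio * n)
    manifest$split <- list(train = sort(ord[seq_len(n_train)]),
                           val = sort(ord[setdiff(seq_len(n), seq_len(n_train))]))
  })
  manifest
}

#' @rdname generate_dataset
#' @param manifest manifest list.
#' @param path YAML file path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname generate_dataset
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' Load a generated dataset into memory
#'
#' @param manifest manifest list (with split).
#' @param dir directory holding the images and labels.
#' @param split "train" or "val".
#' @return list of samples, each with `image`, `gts`, `tier`,
#'   `illumination`.
#' @export
load_dataset <- function(manifest, dir, split = c("train", "val")) {
  split <- match.arg(split)
  idx <- manifest$split[[split]]
  lapply(idx, function(i) {
    rec <- manifest$records[[i]]
    img <- png::readPNG(file.path(dir, rec$image))
    gts <- read_yolo_labels(file.path(dir, rec$label), manifest$image_size)
    if (nrow(gts) > 0 && length(rec$objects) == nrow(gts)) {
      gts$ks <- vapply(rec$objects, function(o) o$ks, numeric(1))
      gts$shade_category <- vapply(rec$objects, function(o) o$shade_category,
                                   character(1))
    }
    list(image = img, gts = gts, tier = rec$tier,
         illumination = rec$illumination)
  })
}
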
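# The scene generator: determinism, exact shade-degree bookkeeping, tier
# size bands, augmentation, label IO and the 80:20 split.

test_that("generate_scene is reproducible and honours the pear count", {
  sp <- scene_spec(image_size = 96, n_pears = 2, ks_targets = c(0, 0.3),
                   rng_seed = 7, size_band = c(20, 32))
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$gts, b$gts)
  expect_equal(nrow(a$gts), 2)
  expect_true(all(a$image >= 0 & a$image <= 1))
  # empty scene
  empty <- generate_scene(scene_spec(image_size = 64, n_pears = 0))
  expect_equal(nrow(empty$gts), 0)
  expect_equal(dim(empty$image), c(64, 64, 3))
})

test_that("requested shade degree is achieved within 0.02 and categorized", {
  sp <- scene_spec(image_size = 128, n_pears = 1, ks_targets = 0.25,
                   rng_seed = 3, size_band = c(40, 60))
  sc <- generate_scene(sp)
  expect_gte(sc$gts$ks, 0.23)
  expect_lte(sc$gts$ks, 0.27)
  expect_equal(sc$gts$shade_category, "medium")
  # heavier shade request lands in 'serious'
  sp2 <- scene_spec(image_size = 128, n_pears = 1, ks_targets = 0.5,
                    rng_seed = 5, size_band = c(40, 60))
  sc2 <- generate_scene(sp2)
  expect_gte(sc2$gts$ks, 0.48)
  expect_lte(sc2$gts$ks, 0.52)
  expect_equal(sc2$gts$shade_category, "serious")
  # recorded ks is exact by construction: ks = 1 - visible/total
  expect_equal(sc2$gts$ks, 1 - sc2$gts$visible_area / sc2$gts$total_area)
})

test_that("compute_shade_degree measures mask overlap and applies the bounds", {
  total <- matrix(FALSE, 50, 50); total[1:40, 1:25] <- TRUE   # 1000 px
  none <- compute_shade_degree(total, list())
  expect_equal(none$ks, 0)
  expect_equal(none$shade_category, "not_or_slight")
  occ <- matrix(FALSE, 50, 50); occ[1:10, 1:25] <- TRUE       # 250 px cover
  r <- compute_shade_degree(total, list(occ))
  expect_equal(r$ks, 0.25)
  expect_equal(r$shade_category, "medium")
  occ2 <- matrix(FALSE, 50, 50); occ2[1:26, 1:25] <- TRUE     # 650 px cover
  r2 <- compute_shade_degree(total, list(occ2))
  expect_equal(r2$ks, 0.65)
  expect_equal(r2$shade_category, "beyond_scope")
  expect_error(compute_shade_degree(matrix(FALSE, 5, 5), list()), "empty")
  # category boundaries
  pn <- pn_internal()
  expect_equal(pn$shade_category(c(0, 0.2, 0.21, 0.4, 0.41, 0.59, 0.6, 0.9)),
               c("not_or_slight", "not_or_slight", "medium", "medium",
                 "serious", "serious", "beyond_scope", "beyond_scope"))
})

test_that("tier size bands are disjoint and monotone decreasing", {
  pn <- pn_internal()
  bands <- pn$TIER_BANDS
  expect_lt(max(bands$extreme), min(bands$moderate) + 1e-9)
  expect_lt(max(bands$moderate), min(bands$uncomplicated) + 1e-9)
  set.seed(9)
  unc <- generate_scene(scene_spec(640, "uncomplicated", 2, rng_seed = 10))
  ext <- generate_scene(scene_spec(640, "extreme", 2, rng_seed = 11))
  expect_gt(min(unc$gts$w), max(ext$gts$w))
})

test_that("augmentation picks three strategies and transforms boxes correctly", {
  sp <- scene_spec(image_size = 96, n_pears = 2, rng_seed = 12,
                   size_band = c(18, 30))
  sc <- generate_scene(sp)
  # fixed seed reproduces the same triple and parameters
  a1 <- augment(sc$image, sc$gts, seed = 5)
  a2 <- augment(sc$image, sc$gts, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$applied, a2$applied)
  # scan seeds for specific strategies and verify their geometry
  found_flip <- FALSE; found_scale <- FALSE
  for (s in 1:60) {
    a <- augment(sc$image, sc$gts, seed = s)
    expect_lte(length(a$applied), 3)
    if ("hflip" %in% a$applied && !any(grepl("scale|vflip", a$applied)) &&
        !found_flip) {
      expect_equal(a$labels$cx, 96 - sc$gts$cx)
      expect_equal(a$labels$cy, sc$gts$cy)
      found_flip <- TRUE
    }
    sc_par <- grep("^scale", a$applied, value = TRUE)
    if (length(sc_par) == 1 && !any(grepl("flip", a$applied)) &&
        !found_scale) {
      f <- as.numeric(sub("scale\\((.*)\\)", "\\1", sc_par))
      expect_gte(f, 0.80); expect_lte(f, 0.95)
      fs <- max(2L, round(96 * f)) / 96   # realized integer-grid factor
      expect_equal(a$labels$w, sc$gts$w * fs, tolerance = 1e-9)
      found_scale <- TRUE
    }
    # boxes always stay on the canvas
    if (nrow(a$labels) > 0) {
      expect_true(all(a$labels$cx - a$labels$w / 2 >= -a$labels$w * 0.9))
      expect_true(all(a$labels$cx <= 96 & a$labels$cy <= 96))
    }
  }
  expect_true(found_flip)
  expect_true(found_scale)
})

test_that("yolo label files round-trip within 1e-6", {
  labs <- data.frame(cx = c(12.345, 500.1), cy = c(33.3, 22.2),
                     w = c(45.6, 120.9), h = c(67.8, 88.8))
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(labs, f, image_size = 640)
  back <- read_yolo_labels(f, image_size = 640)
  expect_equal(as.matrix(back), as.matrix(labs), tolerance = 1e-6)
  # class column is the single class 0
  expect_true(all(startsWith(readLines(f), "0 ")))
  # empty file reads as zero rows
  writeLines(character(0), f)
  expect_equal(nrow(read_yolo_labels(f, 640)), 0)
  unlink(f)
})

test_that("split_dataset reproduces the 80:20 arithmetic", {
  fake <- list(records = lapply(seq_len(5257), function(i) list(image = i)))
  sp <- split_dataset(fake, ratio = 0.8, seed = 2)
  expect_equal(length(sp$split$train), 4206)
  expect_equal(length(sp$split$val), 1051)
  expect_equal(length(intersect(sp$split$train, sp$split$val)), 0)
  # determinism
  sp2 <- split_dataset(fake, ratio = 0.8, seed = 2)
  expect_identical(sp$split, sp2$split)
  small <- list(records = lapply(1:10, function(i) list(image = i)))
  s <- split_dataset(small, 0.8, seed = 1)
  expect_equal(lengths(s$split), c(train = 8L, val = 2L))
  expect_error(split_dataset(list(records = list()), 0.8, 1), "empty")
})

test_that("generate_dataset writes images, labels and a loadable manifest", {
  dir <- file.path(tempdir(), "pearnet-ds")
  on.exit(unlink(dir, recursive = TRUE))
  # at the study canvas (640): smaller canvases shrink extreme-tier fruit
  # below what the +/- 0.02 shade-degree contract can control
  man <- generate_dataset(6, dir, image_size = 640, seed = 4)
  expect_equal(length(man$records), 6)
  expect_equal(length(man$split$train), round(0.8 * 6))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  man2 <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(length(man2$records), 6)
  train <- load_dataset(man2, dir, "train")
  expect_equal(length(train), round(0.8 * 6))
  s <- train[[1]]
  expect_equal(dim(s$image), c(640, 640, 3))
  expect_true(all(c("cx", "cy", "w", "h") %in% names(s$gts)))
  expect_true(all(vapply(train, function(x)
    all(x$gts$ks >= 0 & x$gts$ks < 1), logical(1))))
})
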
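# Desk-scale fixtures: a width-0.25 model on 64x64 canvases with anchors
# sized for 16-28 px pears. This is the configuration used by the training
# smoke experiment; scenes are rendered by the package's own generator.

tiny_anchors <- function() {
  list(matrix(c(16, 16, 24, 24, 32, 32), ncol = 2, byrow = TRUE),
       matrix(c(32, 32, 40, 40, 48, 48), ncol = 2, byrow = TRUE),
       matrix(c(48, 48, 56, 56, 64, 64), ncol = 2, byrow = TRUE))
}

tiny_model <- function(seed = 11) {
  set.seed(seed)
  build_yolop(input_size = 64, width = 0.25, stage_repeats = c(1, 1, 1),
              cbam_reduction = 4, anchors = tiny_anchors())
}

tiny_scene <- function(i, seed = 100) {
  sp <- scene_spec(image_size = 64, complexity_tier = "uncomplicated",
                   n_pears = 1 + i %% 2,
                   ks_targets = if (i %% 3 == 0) 0.3 else 0,
                   illumination = if (i %% 4 == 0) "night" else "day",
                   rng_seed = seed + i, size_band = c(16, 28))
  sc <- generate_scene(sp)
  list(image = sc$image, gts = sc$gts, tier = sp$complexity_tier,
       illumination = sp$illumination)
}

tiny_scenes <- function(n = 16, seed = 100) lapply(seq_len(n), tiny_scene,
                                                   seed = seed)

# finite-difference derivative of f at x[i]
fd_grad <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

pn_internal <- function() asNamespace("pearnet")
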
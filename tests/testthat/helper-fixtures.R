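# Shared fixtures: tiny configurations that keep unit tests fast, plus a
# lazily trained desk-profile model reused by the acceptance tests.

# Tiny model: 32x32 images, 4 channels, 2 slots, 8^3 grid.  Small enough
# that a forward pass takes milliseconds.
tiny_model_config <- function(...) {
  model_config("desk",
               image_px = 32L, d = 4L, channels = c(4L, 8L, 8L, 8L),
               N = 2L, S = 4L, alpha = 4L, topk = 2L, r = 4L,
               fe_layers = 1L, fe_heads = 2L, fe_hidden = 8L,
               fe_downsample = 4L,
               sce_hidden = 8L, head3d_channels = 4L,
               grid_extent_mm = 64, grid_n = 8L,
               spp_scales = c(1L, 2L), ...)
}

# Matching small phantom world (fits the 32-px detector comfortably).
tiny_phantom_config <- function(...) {
  base <- phantom_config(image_px = 32, vol_dims = 32, vol_spacing = 2,
                         n_vertebrae = c(2, 2), body_radius_xy = c(5, 7),
                         body_radius_z = c(4, 5), gap_mm = c(2, 4),
                         curve_amp_mm = c(0, 2), noise_sd = 0,
                         detector_size_m = 0.12)
  dots <- list(...)
  base[names(dots)] <- dots
  base
}

tiny_sample <- function(seed = 1L) {
  simulate_biplanar_sample(tiny_phantom_config(), seed = seed)
}

# Geometry round-trip oracle shared by the unit and acceptance tests:
# project random in-volume points into both views as Gaussian point splats
# (sigma = one voxel footprint at the object plane), unproject, soft-argmax,
# and return the recovery errors (mm).
roundtrip_error <- function(cameras_px, detector_m, grid_n, grid_extent,
                            n_points, box_frac = 0.3) {
  cams <- make_biplanar_cameras(detector_m, cameras_px, 1100, 700)
  cameras <- list(lat = cams$lat, ap = cams$ap)
  grid <- volume_grid_cube(grid_extent, grid_n)
  pitch_obj <- cams$pitch_mm[1] * cams$sod_mm / cams$sdd_mm
  sigma_px <- max(1, grid$spacing[1] / pitch_obj)
  xs <- seq_len(cameras_px) - 1
  vapply(seq_len(n_points), function(i) {
    pt <- runif(3, -box_frac * grid_extent, box_frac * grid_extent)
    fm <- lapply(cameras, function(cam) {
      uv <- project_points(cam, pt)
      img <- exp(-(outer((xs - uv[2])^2, (xs - uv[1])^2, "+")) / (2 * sigma_px^2))
      array(img, c(cameras_px, cameras_px, 1))
    })
    vol <- unproject_features(fm, cameras, grid)
    rec <- soft_argmax3d(vol[, , , 1], grid, temperature = 0.02)
    sqrt(sum((rec - pt)^2))
  }, numeric(1))
}

# Finite-difference gradient check for a scalar-valued tape computation.
# build(g, x_node) must return the root node; x0 is the input array.
fd_gradcheck <- function(build, x0, eps = 1e-6) {
  g <- ad_tape_t()
  xn <- ad_const_t(g, x0)
  root <- build(g, xn)
  spineloc:::ad_backward(g, root)
  analytic <- xn$grad
  idx <- sample(length(x0), min(8, length(x0)))
  numeric_g <- vapply(idx, function(i) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    gp <- ad_tape_t(); vp <- build(gp, ad_const_t(gp, xp))$value
    gm <- ad_tape_t(); vm <- build(gm, ad_const_t(gm, xm))$value
    (sum(vp) - sum(vm)) / (2 * eps)
  }, numeric(1))
  max(abs(numeric_g - analytic[idx]))
}

ad_tape_t <- function() spineloc:::ad_tape()
ad_const_t <- function(g, v) spineloc:::ad_const(g, v)

# The desk-profile acceptance model is expensive to train (minutes), so the
# acceptance tests share one fit through this memoized accessor.
acceptance_env <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (is.null(acceptance_env$world)) {
    cfg <- model_config("desk")
    pcfg <- phantom_config()
    acceptance_env$world <- list(
      cfg = cfg, pcfg = pcfg, grid = config_grid(cfg),
      train = lapply(1:50, function(i)
        simulate_biplanar_sample(pcfg, seed = 1000 + i)),
      val = lapply(1:4, function(i)
        simulate_biplanar_sample(pcfg, seed = 3000 + i)),
      test = lapply(1:10, function(i)
        simulate_biplanar_sample(pcfg, seed = 2000 + i)))
  }
  acceptance_env$world
}

acceptance_fit <- function() {
  if (is.null(acceptance_env$fit)) {
    w <- acceptance_world()
    ## 12 epochs keeps the whole suite inside its runtime budget (the
    ## criterion allows up to 30; accuracy plateaus near this point)
    acceptance_env$fit <- train_model(
      w$train, w$cfg, train_config(epochs = 12L, seed = 7L),
      val_samples = w$val)
  }
  acceptance_env$fit
}
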
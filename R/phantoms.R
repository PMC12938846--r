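## Synthetic biplanar spine phantoms.
##
## The generator emulates, at desk scale, the construction of a synthetic
## biplanar radiograph benchmark: procedural vertebra-chain attenuation
## volumes stand in for CT, perspective ray-integral projections onto a
## virtual detector stand in for the DRR renderer, random rigid rotations
## emulate pose variation, and the exact projected landmarks provide
## pixel-perfect 2D annotations.  Attenuation is in arbitrary units per mm;
## only relative contrast matters because every rendered image is min-max
## normalized.

#' Default phantom configuration
#'
#' The stated world of the generator: a ~19 cm cubic field of view imaged by
#' an orthogonal biplanar rig. Vertebral bodies are ellipsoids threaded on a
#' smooth vertical curve; optional high-attenuation blobs emulate metal
#' implants and an exaggerated lateral curve emulates scoliotic deformity.
#'
#' @param image_px rendered image size (pixels, square)
#' @param vol_dims attenuation grid voxels per edge
#' @param vol_spacing attenuation voxel size (mm)
#' @param n_vertebrae integer range `c(min, max)`
#' @param body_radius_xy,body_radius_z semi-axis ranges (mm)
#' @param gap_mm inter-body gap range (mm)
#' @param curve_amp_mm lateral curve amplitude range (mm)
#' @param bone_mu bone attenuation range (per mm, arbitrary units)
#' @param tissue_mu soft-tissue cylinder attenuation
#' @param implant_prob,deformity_prob per-phantom probabilities
#' @param noise_sd additive Gaussian image noise (after normalization)
#' @param rot_z_deg,rot_xy_deg pose perturbation half-ranges (degrees) about
#'   the vertical axis and the two horizontal axes
#' @param detector_size_m,source_to_detector_mm,source_to_object_mm rig
#'   geometry passed to [make_biplanar_cameras()]
#' @export
phantom_config <- function(image_px = 128,
                           vol_dims = 96,
                           vol_spacing = 2,
                           n_vertebrae = c(3, 5),
                           body_radius_xy = c(9, 13),
                           body_radius_z = c(7, 10),
                           gap_mm = c(3, 6),
                           curve_amp_mm = c(0, 6),
                           bone_mu = c(0.8, 1.2),
                           tissue_mu = 0.03,
                           implant_prob = 0.15,
                           deformity_prob = 0.15,
                           noise_sd = 0.01,
                           rot_z_deg = 15,
                           rot_xy_deg = 5,
                           detector_size_m = 0.36,
                           source_to_detector_mm = 1100,
                           source_to_object_mm = 700) {
  as.list(environment())
}

## rotation matrix from Euler angles (degrees) about z, then y, then x
rotation_from_angles <- function(az, ay, ax) {
  r <- pi / 180
  cz <- cos(az * r); sz <- sin(az * r)
  cy <- cos(ay * r); sy <- sin(ay * r)
  cx <- cos(ax * r); sx <- sin(ax * r)
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rx %*% Ry %*% Rz
}

## fill one ellipsoid (additively) into a volume, world-frame center/semiaxes
fill_ellipsoid <- function(vol, grid, center, semi, value) {
  d <- grid$dims
  lo <- pmax(1, floor((center - semi - grid$origin) / grid$spacing) + 1)
  hi <- pmin(d, ceiling((center + semi - grid$origin) / grid$spacing) + 1)
  if (any(lo > hi)) return(vol)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  wx <- (grid$origin[1] + (ix - 1) * grid$spacing[1] - center[1]) / semi[1]
  wy <- (grid$origin[2] + (iy - 1) * grid$spacing[2] - center[2]) / semi[2]
  wz <- (grid$origin[3] + (iz - 1) * grid$spacing[3] - center[3]) / semi[3]
  m <- outer(outer(wx^2, wy^2, "+"), wz^2, "+") <= 1
  vol[ix, iy, iz] <- vol[ix, iy, iz] + value * m
  vol
}

#' Generate a procedural spine phantom
#'
#' A chain of ellipsoidal vertebral bodies placed superior to inferior along
#' a smooth vertical curve with positive inter-body gaps, inside a
#' soft-tissue cylinder. Deterministic for a fixed seed.
#'
#' @param config from [phantom_config()]
#' @param seed integer seed
#' @return An object of class `spine_phantom`: list with `volume`
#'   (attenuation array), `grid` ([volume_grid()]), `landmarks` (data.frame
#'   `level, slot, x_mm, y_mm, z_mm`, ordered superior to inferior), `meta`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  rng <- local_rng(seed)
  cfg <- config
  grid <- volume_grid_cube(cfg$vol_dims * cfg$vol_spacing, cfg$vol_dims)
  half <- cfg$vol_dims * cfg$vol_spacing / 2
  n <- as.integer(cfg$n_vertebrae[1]) +
    sample.int(as.integer(cfg$n_vertebrae[2] - cfg$n_vertebrae[1]) + 1L, 1) - 1L
  rz <- runif(n, cfg$body_radius_z[1], cfg$body_radius_z[2])
  rxy <- runif(n, cfg$body_radius_xy[1], cfg$body_radius_xy[2])
  gaps <- runif(n - 1, cfg$gap_mm[1], cfg$gap_mm[2])
  chain_len <- 2 * sum(rz) + sum(gaps)
  margin <- max(rxy) + 4
  if (chain_len > 2 * (half - margin))
    stop("config error: vertebral chain does not fit in the volume")
  deformity <- runif(1) < cfg$deformity_prob
  amp <- if (deformity) runif(1, 8, 15) else runif(1, cfg$curve_amp_mm[1], cfg$curve_amp_mm[2])
  phase <- runif(1, 0, 2 * pi)
  freq <- runif(1, 0.5, 1.5)
  ## z decreasing from superior to inferior, chain centered vertically
  z0 <- chain_len / 2 - rz[1]
  zc <- numeric(n)
  zc[1] <- z0
  if (n > 1) for (i in 2:n) zc[i] <- zc[i - 1] - (rz[i - 1] + gaps[i - 1] + rz[i])
  tt <- (zc - min(zc)) / max(1e-9, diff(range(zc)))
  xc <- amp * sin(2 * pi * freq * tt + phase)
  yc <- 0.4 * amp * cos(2 * pi * freq * tt + phase)
  mu <- runif(n, cfg$bone_mu[1], cfg$bone_mu[2])
  implant <- runif(1) < cfg$implant_prob
  vol <- array(0, dim = grid$dims)
  ## soft-tissue cylinder along z
  cc <- voxel_centers(grid)
  r2 <- (cc[, 1]^2 + cc[, 2]^2)
  tis <- cfg$tissue_mu * (r2 <= (0.75 * half)^2)
  dim(tis) <- grid$dims
  vol <- vol + tis
  for (i in seq_len(n)) {
    vol <- fill_ellipsoid(vol, grid, c(xc[i], yc[i], zc[i]),
                          c(rxy[i], rxy[i], rz[i]), mu[i])
    ## a low-attenuation "canal" notch behind the body, for texture
    vol <- fill_ellipsoid(vol, grid, c(xc[i], yc[i] + 0.8 * rxy[i], zc[i]),
                          c(0.35 * rxy[i], 0.35 * rxy[i], 0.8 * rz[i]), -0.5 * mu[i])
  }
  if (implant) {
    j <- sample.int(n, 1)
    off <- runif(3, -4, 4)
    vol <- fill_ellipsoid(vol, grid, c(xc[j], yc[j], zc[j]) + off,
                          c(4, 4, 4), 10 * max(mu))
  }
  vol[vol < 0] <- 0
  landmarks <- data.frame(
    level = paste0("V", seq_len(n)), slot = seq_len(n) - 1L,
    x_mm = xc, y_mm = yc, z_mm = zc)
  structure(list(volume = vol, grid = grid, landmarks = landmarks,
                 meta = list(seed = seed, n_vertebrae = n,
                             implant = implant, deformity = deformity)),
            class = "spine_phantom")
}

#' Rigidly rotate a phantom (pose perturbation)
#'
#' Samples Euler angles uniformly inside the configured ranges, rotates the
#' landmark chain exactly and resamples the attenuation volume with
#' trilinear interpolation about the volume center.
#'
#' @param phantom a `spine_phantom`
#' @param seed integer seed
#' @param config for the rotation ranges (defaults to the phantom's scales)
#' @return rotated `spine_phantom`; `meta$angles_deg` records the draw
#' @export
perturb_pose <- function(phantom, seed = 1L, config = phantom_config()) {
  rng <- local_rng(seed)
  ang <- sample_pose_angles(config)
  R <- rotation_from_angles(ang[1], ang[2], ang[3])
  grid <- phantom$grid
  ## vol'(p) = vol(R^T p) about the world origin (grid center)
  cc <- voxel_centers(grid)
  src <- cc %*% R  # == t(R^T %*% t(cc))
  newvol <- cpp_trilerp(as.vector(phantom$volume), as.integer(grid$dims),
                        grid$origin, grid$spacing, src)
  dim(newvol) <- grid$dims
  lm <- phantom$landmarks
  rot <- as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
  lm$x_mm <- rot[, 1]; lm$y_mm <- rot[, 2]; lm$z_mm <- rot[, 3]
  out <- phantom
  out$volume <- newvol
  out$landmarks <- lm
  out$meta$angles_deg <- ang
  out
}

#' Sample pose perturbation angles (degrees)
#'
#' Uniform in `[-rot_z_deg, rot_z_deg]` about the vertical axis and
#' `[-rot_xy_deg, rot_xy_deg]` about the two horizontal axes. Uses the
#' current RNG stream.
#' @param config from [phantom_config()]
#' @return length-3 vector `(about_z, about_y, about_x)`
#' @export
sample_pose_angles <- function(config = phantom_config()) {
  c(runif(1, -config$rot_z_deg, config$rot_z_deg),
    runif(1, -config$rot_xy_deg, config$rot_xy_deg),
    runif(1, -config$rot_xy_deg, config$rot_xy_deg))
}

#' Render a ray-integral radiograph of a phantom
#'
#' Each pixel value is the line integral of attenuation along the ray from
#' the source through that pixel center (fixed world step, trilinear volume
#' sampling), min-max normalized to `[0, 1]` per image. The integral is
#' linear in attenuation before normalization, so scaling the phantom leaves
#' the image unchanged.
#'
#' @param phantom a `spine_phantom`
#' @param camera a [projection_matrix()]
#' @param image_px image size, length-1 or 2 `(width, height)`
#' @param step_mm ray-marching step (mm)
#' @param normalize min-max normalize to `[0,1]` (default TRUE)
#' @return `h x w` matrix (rows = image rows)
#' @export
render_drr <- function(phantom, camera, image_px = c(128, 128), step_mm = 1,
                       normalize = TRUE) {
  image_px <- rep(as.integer(image_px), length.out = 2)
  w <- image_px[1]; h <- image_px[2]
  src <- camera_center(camera)
  M <- camera$P[, 1:3]
  Minv <- solve(M)
  u <- rep(seq_len(w) - 1, each = h)
  v <- rep(seq_len(h) - 1, w)
  dirs <- cbind(u, v, 1) %*% t(Minv)
  ## orient rays to positive projective depth: depth of src + d is
  ## row3 . (src + d) + p34 = (row3 . d) since P src~ = 0; det(M) sign fixes it
  sgn <- sign(as.numeric(camera$P[3, 1:3] %*% dirs[1, ]))
  if (sgn == 0) stop("camera error: degenerate ray")
  dirs <- dirs * sgn
  img <- cpp_drr(as.vector(phantom$volume), as.integer(phantom$grid$dims),
                 phantom$grid$origin, phantom$grid$spacing,
                 src, dirs, step_mm)
  dim(img) <- c(h, w)
  if (normalize) {
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1]) else img[] <- 0
  }
  img
}

#' Simulate one calibrated biplanar sample
#'
#' Generates a phantom, perturbs its pose, renders LAT and AP views, and
#' stores the exact projected 2D landmarks and the prompts (the projected
#' center of the top-most vertebral body in each view).
#'
#' @param config from [phantom_config()]
#' @param seed integer seed
#' @return list with `images` (named list of h x w matrices), `cameras`,
#'   `landmarks_3d` (data.frame), `landmarks_2d` (named list of n x 2
#'   matrices), `prompt` (named list of length-2 pixel vectors), `meta`
#' @export
simulate_biplanar_sample <- function(config = phantom_config(), seed = 1L) {
  ph <- generate_phantom(config, seed = seed)
  ph <- perturb_pose(ph, seed = seed + 500000L, config = config)
  cams <- make_biplanar_cameras(config$detector_size_m,
                                config$image_px,
                                config$source_to_detector_mm,
                                config$source_to_object_mm)
  cameras <- list(lat = cams$lat, ap = cams$ap)
  images <- list()
  lm3 <- as.matrix(ph$landmarks[, c("x_mm", "y_mm", "z_mm")])
  landmarks_2d <- list()
  rng <- local_rng(seed + 900000L)
  for (v in c("lat", "ap")) {
    img <- render_drr(ph, cameras[[v]], image_px = config$image_px)
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, config$noise_sd), nrow(img))
      img <- pmin(pmax(img, 0), 1)
    }
    images[[v]] <- img
    landmarks_2d[[v]] <- project_points(cameras[[v]], lm3)
  }
  prompt <- list(lat = landmarks_2d$lat[1, ], ap = landmarks_2d$ap[1, ])
  list(images = images, cameras = cameras,
       landmarks_3d = ph$landmarks, landmarks_2d = landmarks_2d,
       prompt = prompt,
       meta = c(ph$meta, list(sample_seed = seed)))
}

## ---- on-disk dataset ----------------------------------------------------

## Plain-text 16-bit PGM (P2) image IO: a standard, text-only raster format.
write_pgm <- function(img, path, maxval = 65535L) {
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = 16)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("not an ASCII PGM (P2) file")
  w <- as.integer(txt[2]); h <- as.integer(txt[3]); maxval <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a synthetic biplanar dataset to disk
#'
#' Generates `n_samples` biplanar samples, splits them deterministically
#' into train/val/test, and writes per-sample images (ASCII PGM), cameras
#' (JSON), landmarks and prompts (CSV), plus a JSON manifest. The split
#' mirrors an 80-20 train-test partition with 5% of the training set
#' reserved for validation: `(0.76, 0.04, 0.20)`.
#'
#' @param n_samples number of samples
#' @param seed integer master seed (sample i uses `seed * 1000 + i`)
#' @param out_dir output directory
#' @param split fractions `(train, val, test)`, must sum to 1
#' @param config from [phantom_config()]
#' @param force overwrite an existing non-empty directory
#' @return the manifest (invisibly)
#' @export
make_dataset <- function(n_samples, seed = 1L, out_dir,
                         split = c(0.76, 0.04, 0.20),
                         config = phantom_config(), force = FALSE) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- round(n_samples * split[1])
  n_val <- round(n_samples * split[2])
  n_test <- n_samples - n_train - n_val
  assign_split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  ids <- sprintf("sample_%04d", seq_len(n_samples))
  manifest <- list(n_samples = n_samples, seed = seed, split = as.list(
    stats::setNames(as.numeric(split), c("train", "val", "test"))),
    samples = list())
  for (i in seq_len(n_samples)) {
    s <- simulate_biplanar_sample(config, seed = seed * 1000L + i)
    sdir <- file.path(out_dir, ids[i])
    dir.create(sdir, showWarnings = FALSE)
    for (v in c("lat", "ap"))
      write_pgm(s$images[[v]], file.path(sdir, paste0(v, ".pgm")))
    write_cameras(s$cameras, file.path(sdir, "cameras.json"))
    utils::write.csv(s$landmarks_3d, file.path(sdir, "landmarks_3d.csv"),
                     row.names = FALSE)
    for (v in c("lat", "ap")) {
      lm2 <- as.data.frame(s$landmarks_2d[[v]])
      lm2$slot <- s$landmarks_3d$slot
      utils::write.csv(lm2, file.path(sdir, paste0("landmarks_2d_", v, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(lapply(s$prompt, as.numeric),
                         file.path(sdir, "prompt.json"), digits = NA)
    manifest$samples[[i]] <- list(id = ids[i], split = assign_split[i],
                                  seed = seed * 1000L + i,
                                  n_vertebrae = s$meta$n_vertebrae)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load one sample from a dataset directory
#' @param dir sample directory written by [make_dataset()]
#' @export
read_sample <- function(dir) {
  images <- list(lat = read_pgm(file.path(dir, "lat.pgm")),
                 ap = read_pgm(file.path(dir, "ap.pgm")))
  cameras <- read_cameras(file.path(dir, "cameras.json"))
  lm3 <- utils::read.csv(file.path(dir, "landmarks_3d.csv"))
  lm2 <- list()
  for (v in c("lat", "ap")) {
    d <- utils::read.csv(file.path(dir, paste0("landmarks_2d_", v, ".csv")))
    lm2[[v]] <- as.matrix(d[, c("x", "y")])
  }
  pr <- jsonlite::read_json(file.path(dir, "prompt.json"), simplifyVector = TRUE)
  list(images = images, cameras = cameras, landmarks_3d = lm3,
       landmarks_2d = lm2, prompt = lapply(pr, as.numeric))
}

## Seed scoping: set a deterministic stream for the calling function and
## restore the caller's RNG state when that function exits.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
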
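test_that("generate_phantom is deterministic and respects its geometry contract", {
  cfg <- tiny_phantom_config()
  a <- generate_phantom(cfg, seed = 12)
  b <- generate_phantom(cfg, seed = 12)
  expect_identical(a$volume, b$volume)
  expect_identical(a$landmarks, b$landmarks)
  expect_true(all(a$volume >= 0))
  ## centroids ordered superior -> inferior, all inside the volume
  expect_true(all(diff(a$landmarks$z_mm) < 0))
  half <- cfg$vol_dims * cfg$vol_spacing / 2
  expect_true(all(abs(as.matrix(a$landmarks[, c("x_mm", "y_mm", "z_mm")])) < half))
})

test_that("zero curvature amplitude gives a straight vertical chain", {
  cfg <- tiny_phantom_config(curve_amp_mm = c(0, 0), deformity_prob = 0)
  ph <- generate_phantom(cfg, seed = 3)
  expect_equal(ph$landmarks$x_mm, rep(0, nrow(ph$landmarks)))
  expect_equal(ph$landmarks$y_mm, rep(0, nrow(ph$landmarks)))
})

test_that("consecutive centroid gaps respect the configured minimum over many seeds", {
  cfg <- phantom_config(vol_dims = 32, vol_spacing = 4, n_vertebrae = c(3, 5),
                        body_radius_xy = c(6, 8), body_radius_z = c(5, 6),
                        gap_mm = c(3, 6))
  for (seed in 1:200) {
    ph <- generate_phantom(cfg, seed = seed)
    lm <- as.matrix(ph$landmarks[, c("x_mm", "y_mm", "z_mm")])
    if (nrow(lm) < 2) next
    gaps <- sqrt(rowSums(diff(lm)^2))
    ## consecutive centroids are at least 2*min(rz) + min gap apart
    expect_true(all(gaps >= 2 * cfg$body_radius_z[1] + cfg$gap_mm[1] - 1e-9))
  }
})

test_that("vertebra counts cover the configured range across seeds", {
  cfg <- tiny_phantom_config(n_vertebrae = c(2, 3))
  counts <- vapply(1:40, function(s) generate_phantom(cfg, s)$meta$n_vertebrae,
                   integer(1))
  expect_setequal(unique(counts), 2:3)
})

test_that("infeasible chain geometry is rejected", {
  cfg <- tiny_phantom_config(n_vertebrae = c(12, 12))
  expect_error(generate_phantom(cfg, 1), "config error")
})

test_that("render_drr: empty volume, attenuation-scale invariance, peak location", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, seed = 2)
  cams <- make_biplanar_cameras(cfg$detector_size_m, cfg$image_px,
                                cfg$source_to_detector_mm,
                                cfg$source_to_object_mm)
  ## all-zero phantom -> all-zero image
  empty <- ph; empty$volume[] <- 0
  expect_true(all(render_drr(empty, cams$lat, cfg$image_px) == 0))
  ## doubling attenuation leaves the normalized image unchanged
  img1 <- render_drr(ph, cams$lat, cfg$image_px)
  dbl <- ph; dbl$volume <- ph$volume * 2
  expect_equal(render_drr(dbl, cams$lat, cfg$image_px), img1, tolerance = 1e-12)
  expect_true(all(img1 >= 0 & img1 <= 1) && all(is.finite(img1)))
  expect_gt(stats::sd(img1), 0)  # nonconstant for a nonempty phantom
  ## a single bright voxel peaks within 1 px of its projected center
  ## (rendered at a resolution where the ray spacing at the object plane
  ## is finer than the voxel, otherwise rays can miss it entirely)
  cfg64 <- tiny_phantom_config(image_px = 64)
  cams64 <- make_biplanar_cameras(cfg64$detector_size_m, 64,
                                  cfg64$source_to_detector_mm,
                                  cfg64$source_to_object_mm)
  single <- generate_phantom(cfg64, seed = 2)
  single$volume[] <- 0
  single$volume[20, 12, 25] <- 100
  ctr <- single$grid$origin + c(19, 11, 24) * single$grid$spacing
  for (v in c("lat", "ap")) {
    img <- render_drr(single, cams64[[v]], 64)
    pk <- which(img == max(img), arr.ind = TRUE)[1, ]
    uv <- project_points(cams64[[v]], ctr)
    expect_lt(abs(pk["col"] - 1 - uv[1]), 1)
    expect_lt(abs(pk["row"] - 1 - uv[2]), 1)
  }
})

test_that("perturb_pose is rigid on landmarks and bounded in angle", {
  cfg <- tiny_phantom_config()
  ph <- generate_phantom(cfg, seed = 4)
  ## zero ranges -> identity
  cfg0 <- tiny_phantom_config(rot_z_deg = 0, rot_xy_deg = 0)
  p0 <- perturb_pose(ph, seed = 1, config = cfg0)
  expect_equal(p0$landmarks, ph$landmarks, tolerance = 1e-12)
  ## pairwise distances invariant (isometry)
  pp <- perturb_pose(ph, seed = 5, config = cfg)
  d0 <- dist(as.matrix(ph$landmarks[, c("x_mm", "y_mm", "z_mm")]))
  d1 <- dist(as.matrix(pp$landmarks[, c("x_mm", "y_mm", "z_mm")]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  ## sampled angles stay within the configured bounds over many draws
  set.seed(100)
  ang <- t(replicate(10000, sample_pose_angles(cfg)))
  expect_true(all(abs(ang[, 1]) <= cfg$rot_z_deg))
  expect_true(all(abs(ang[, 2:3]) <= cfg$rot_xy_deg))
  ## the range is actually exercised
  expect_gt(max(abs(ang[, 1])), 0.9 * cfg$rot_z_deg)
})

test_that("simulated samples have exactly consistent projections and prompts", {
  cfg <- tiny_phantom_config()
  s <- tiny_sample(seed = 21)
  for (v in c("lat", "ap")) {
    proj <- project_points(s$cameras[[v]],
                           as.matrix(s$landmarks_3d[, c("x_mm", "y_mm", "z_mm")]))
    expect_lt(max(abs(proj - s$landmarks_2d[[v]])), 1e-9)
    expect_equal(as.numeric(s$prompt[[v]]), as.numeric(s$landmarks_2d[[v]][1, ]))
    expect_true(all(s$images[[v]] >= 0 & s$images[[v]] <= 1))
  }
  ## bit-exact reproducibility
  s2 <- tiny_sample(seed = 21)
  expect_identical(s$images, s2$images)
  expect_identical(s$landmarks_3d, s2$landmarks_3d)
})

test_that("make_dataset writes deterministic, disjoint splits and round-trips", {
  dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- tiny_phantom_config()
  m1 <- make_dataset(10, seed = 5, out_dir = dir1,
                     split = c(0.6, 0.2, 0.2), config = cfg)
  ids <- vapply(m1$samples, `[[`, character(1), "id")
  splits <- vapply(m1$samples, `[[`, character(1), "split")
  expect_equal(unname(table(splits)[c("train", "val", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(ids), 0L)
  ## refuse to clobber without force
  expect_error(make_dataset(2, seed = 5, out_dir = dir1, config = cfg),
               "force")
  ## deterministic manifests
  m2 <- make_dataset(10, seed = 5, out_dir = dir2,
                     split = c(0.6, 0.2, 0.2), config = cfg)
  expect_identical(m1$samples, m2$samples)
  expect_error(make_dataset(4, 1, tempfile(), split = c(0.5, 0.5, 0.5)),
               "sum to 1")
  ## the 80-20 + 5%-of-train scheme: n = 100 -> 76 / 4 / 20
  n <- 100; sp <- c(0.76, 0.04, 0.20)
  expect_equal(c(round(n * sp[1]), round(n * sp[2]),
                 n - round(n * sp[1]) - round(n * sp[2])), c(76, 4, 20))
  ## on-disk sample round-trips through the readers
  back <- read_sample(file.path(dir1, ids[1]))
  orig <- simulate_biplanar_sample(cfg, seed = m1$samples[[1]]$seed)
  expect_lt(max(abs(back$images$lat - orig$images$lat)), 1 / 65535)
  expect_equal(back$cameras$lat$P, orig$cameras$lat$P)
  expect_equal(as.numeric(back$prompt$lat), as.numeric(orig$prompt$lat),
               tolerance = 1e-9)
  expect_equal(back$landmarks_3d$z_mm, orig$landmarks_3d$z_mm, tolerance = 1e-9)
  ## loader groups by split
  ds <- load_dataset(dir1)
  expect_equal(lengths(ds)[c("train", "val", "test")], c(train = 6L, val = 2L, test = 2L))
  unlink(c(dir1, dir2), recursive = TRUE)
})
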
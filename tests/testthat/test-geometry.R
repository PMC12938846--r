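test_that("project_points follows the pinhole model and rejects points behind the source", {
  ## identity-like camera: P = [I3 | 0], point (0, 0, 1) -> (0, 0)
  P <- cbind(diag(3), 0)
  cam <- projection_matrix(P, "lat")
  expect_equal(as.numeric(project_points(cam, c(0, 0, 1))), c(0, 0))
  expect_error(project_points(cam, c(0, 0, -1)), "behind camera")
  expect_error(project_points(cam, c(1, 1, 0)), "behind camera")
})

test_that("projection is invariant to homogeneous scaling (100 random cases)", {
  set.seed(42)
  for (i in 1:100) {
    P <- matrix(rnorm(12), 3, 4)
    if (qr(P[, 1:3])$rank < 3) next
    pt <- rnorm(3) * 10
    depth <- sum(P[3, ] * c(pt, 1))
    if (depth <= 0) P <- -P  # flip so the point is in front
    cam <- projection_matrix(P, "ap")
    s <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    cam2 <- projection_matrix(s * P, "ap")
    if (s < 0) next  # sign flip moves the point behind the camera by convention
    expect_equal(project_points(cam2, pt), project_points(cam, pt),
                 tolerance = 1e-9)
  }
})

test_that("make_biplanar_cameras matches the stated detector geometry", {
  cams <- make_biplanar_cameras(c(0.6, 0.6), c(2048, 2048), 1100, 700)
  ## 600 mm over 2048 px
  expect_equal(cams$pitch_mm, rep(600 / 2048, 2), tolerance = 1e-12)
  expect_equal(cams$pitch_mm[1], 0.29297, tolerance = 1e-4)
  ## optical axes orthogonal: LAT along +x, AP along +y
  axis_of <- function(cam) {
    a <- cam$P[3, 1:3]
    a / sqrt(sum(a^2))
  }
  expect_equal(sum(axis_of(cams$lat) * axis_of(cams$ap)), 0)
  ## world origin lands on the detector center pixel in both views
  ctr <- (2048 - 1) / 2
  expect_equal(as.numeric(project_points(cams$lat, c(0, 0, 0))), c(ctr, ctr))
  expect_equal(as.numeric(project_points(cams$ap, c(0, 0, 0))), c(ctr, ctr))
  expect_error(make_biplanar_cameras(0.6, 2048, -1, 700), "invalid rig")
  expect_error(make_biplanar_cameras(0.6, 2048, 500, 700), "invalid rig")
})

test_that("camera_center recovers the source position", {
  cams <- make_biplanar_cameras(0.36, 128, 1100, 700)
  expect_equal(camera_center(cams$lat), c(-700, 0, 0), tolerance = 1e-9)
  expect_equal(camera_center(cams$ap), c(0, -700, 0), tolerance = 1e-9)
})

test_that("volume_grid voxel centers are exact and validated", {
  g <- volume_grid(c(-10, 0, 5), c(1, 2, 3), c(2, 2, 2))
  vc <- voxel_centers(g)
  ## voxel (1,0,1): flat row 1 + 1 + 2*0 + 4*1 = 6
  expect_equal(vc[6, ], c(-10 + 1, 0, 5 + 3))
  expect_error(volume_grid(0, -1, 4), "spacing")
  expect_error(volume_grid(0, 1, 0), "dims")
})

test_that("unproject_features matches a brute-force per-voxel loop on an 8^3 grid", {
  set.seed(7)
  cams <- make_biplanar_cameras(0.36, 16, 1100, 700)
  cameras <- list(lat = cams$lat, ap = cams$ap)
  grid <- volume_grid_cube(64, 8)
  fm <- list(lat = array(rnorm(16 * 16 * 3), c(16, 16, 3)),
             ap = array(rnorm(16 * 16 * 3), c(16, 16, 3)))
  vol <- unproject_features(fm, cameras, grid)

  bilin <- function(img, x, y) {
    h <- nrow(img); w <- ncol(img)
    x0 <- floor(x); y0 <- floor(y)
    acc <- 0
    for (dy in 0:1) for (dx in 0:1) {
      xx <- x0 + dx; yy <- y0 + dy
      if (xx < 0 || xx >= w || yy < 0 || yy >= h) next
      wt <- (if (dx) x - x0 else 1 - (x - x0)) * (if (dy) y - y0 else 1 - (y - y0))
      acc <- acc + wt * img[yy + 1, xx + 1]
    }
    acc
  }
  ref <- array(0, dim = c(8, 8, 8, 3))
  for (i in 0:7) for (j in 0:7) for (k in 0:7) {
    p <- grid$origin + c(i, j, k) * grid$spacing
    for (c in 1:3) {
      acc <- 0
      for (v in c("lat", "ap")) {
        uv <- project_points(cameras[[v]], p)
        acc <- acc + bilin(fm[[v]][, , c], uv[1], uv[2])
      }
      ref[i + 1, j + 1, k + 1, c] <- acc / 2
    }
  }
  expect_equal(vol, ref, tolerance = 1e-12)
})

test_that("unprojection edge behavior: zeros, constants, channel mismatch", {
  cams <- make_biplanar_cameras(0.36, 16, 1100, 700)
  cameras <- list(lat = cams$lat, ap = cams$ap)
  grid <- volume_grid_cube(48, 6)
  z <- list(lat = array(0, c(16, 16, 2)), ap = array(0, c(16, 16, 2)))
  expect_true(all(unproject_features(z, cameras, grid) == 0))
  ## identical constant maps in both views -> constant over in-view voxels
  cst <- list(lat = array(3.5, c(16, 16, 1)), ap = array(3.5, c(16, 16, 1)))
  vol <- unproject_features(cst, cameras, grid)
  uv1 <- spineloc:::grid_pixel_coords(cameras$lat, grid)
  uv2 <- spineloc:::grid_pixel_coords(cameras$ap, grid)
  inview <- uv1[, 1] >= 0 & uv1[, 1] <= 15 & uv1[, 2] >= 0 & uv1[, 2] <= 15 &
    uv2[, 1] >= 0 & uv2[, 1] <= 15 & uv2[, 2] >= 0 & uv2[, 2] <= 15
  expect_equal(as.vector(vol)[inview], rep(3.5, sum(inview)))
  bad <- list(lat = array(0, c(16, 16, 2)), ap = array(0, c(16, 16, 3)))
  expect_error(unproject_features(bad, cameras, grid), "inconsistent")
})

test_that("soft_argmax3d: one-hot, uniform, twin peaks, hull containment", {
  grid <- volume_grid_cube(64, 8)
  vc <- voxel_centers(grid)
  ## near-zero temperature recovers the argmax voxel center
  hm <- array(0, c(8, 8, 8)); hm[3, 4, 5] <- 1
  expect_equal(soft_argmax3d(hm, grid, temperature = 1e-4),
               grid$origin + c(2, 3, 4) * grid$spacing, tolerance = 1e-9)
  ## uniform heatmap -> centroid of all voxel centers
  expect_equal(soft_argmax3d(array(1, c(8, 8, 8)), grid), colMeans(vc),
               tolerance = 1e-12)
  ## two equal peaks over a suppressed background -> midpoint at any
  ## temperature (symmetry)
  hm2 <- array(-1e6, c(8, 8, 8)); hm2[2, 2, 2] <- 7; hm2[5, 7, 3] <- 7
  a <- grid$origin + c(1, 1, 1) * grid$spacing
  b <- grid$origin + c(4, 6, 2) * grid$spacing
  for (tmp in c(0.1, 1, 10))
    expect_equal(soft_argmax3d(hm2, grid, tmp), (a + b) / 2, tolerance = 1e-9)
  ## output always inside the hull of voxel centers
  set.seed(1)
  for (i in 1:25) {
    r <- soft_argmax3d(array(rnorm(512), c(8, 8, 8)), grid,
                       temperature = runif(1, 0.05, 5))
    expect_true(all(r >= apply(vc, 2, min) - 1e-12) &&
                all(r <= apply(vc, 2, max) + 1e-12))
  }
  expect_error(soft_argmax3d(array(-Inf, c(2, 2, 2)), grid), "degenerate")
  expect_error(soft_argmax3d(array(1, c(2, 2, 2)), grid, temperature = 0),
               "temperature")
})

test_that("project -> delta image -> unproject -> soft-argmax round-trips a point", {
  ## a point rendered as a one-voxel-wide Gaussian splat in both views is
  ## recovered within one voxel spacing
  set.seed(11)
  rt <- roundtrip_error(cameras_px = 64, detector_m = 0.18, grid_n = 16,
                        grid_extent = 96, n_points = 10)
  expect_true(all(rt < 96 / 16))
})

test_that("camera JSON round-trip preserves the matrices", {
  cams <- make_biplanar_cameras(0.36, 128, 1100, 700)
  path <- tempfile(fileext = ".json")
  write_cameras(list(lat = cams$lat, ap = cams$ap), path)
  back <- read_cameras(path)
  expect_equal(back$lat$P, cams$lat$P)
  expect_equal(back$ap$P, cams$ap$P)
  expect_s3_class(back$lat, "projection_matrix")
})
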
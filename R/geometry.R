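## Projective geometry for calibrated biplanar radiographs.
##
## Conventions (stated once, used everywhere):
##   * World frame: right-handed, millimetres; the anatomical vertical axis
##     is world +z (superior), so image rows increase toward inferior.
##   * Pixels: 0-based, (x = column, y = row), pixel centers at integer
##     coordinates.
##   * A projection matrix P maps a homogeneous world point (mm) to a
##     homogeneous pixel; dehomogenization requires positive projective
##     depth (the point must lie in front of the source).

#' Construct a projection matrix
#'
#' @param P numeric 3x4 matrix mapping homogeneous world (mm) to homogeneous
#'   pixel coordinates. The left 3x3 block must have full rank.
#' @param view_id one of `"lat"`, `"ap"`.
#' @return An object of class `projection_matrix`.
#' @export
projection_matrix <- function(P, view_id = c("lat", "ap")) {
  view_id <- match.arg(view_id)
  P <- as.matrix(P)
  if (!all(dim(P) == c(3, 4))) stop("P must be a 3x4 matrix")
  if (qr(P[, 1:3])$rank < 3) stop("left 3x3 submatrix of P must have full rank")
  structure(list(P = P, view = view_id), class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("<projection_matrix view=%s>\n", x$view))
  print(x$P)
  invisible(x)
}

#' Project world points to pixel coordinates
#'
#' Dehomogenizes `P %*% c(X, Y, Z, 1)`. Points with zero or negative
#' projective depth are rejected: they lie behind (or at) the X-ray source
#' and have no image.
#'
#' @param camera a [projection_matrix()]
#' @param points numeric vector of length 3 or an n x 3 matrix of world
#'   coordinates (mm)
#' @return An n x 2 matrix of continuous 0-based pixel coordinates
#'   `(x = column, y = row)`; a single point yields a length-2 vector.
#' @export
project_points <- function(camera, points) {
  stopifnot(inherits(camera, "projection_matrix"))
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, 1, 3) else as.matrix(points)
  if (ncol(pts) != 3) stop("points must have 3 columns")
  hp <- cbind(pts, 1) %*% t(camera$P)
  if (any(hp[, 3] <= 0)) stop("point behind camera: non-positive projective depth")
  uv <- hp[, 1:2, drop = FALSE] / hp[, 3]
  colnames(uv) <- c("x", "y")
  if (single) uv[1, ] else uv
}

#' Build a calibrated biplanar rig
#'
#' Two perspective cameras with orthogonal principal axes: the LAT view
#' looks along world +x, the AP view along world +y. The principal point is
#' the detector center pixel, the pixel pitch is `detector_size / detector_px`,
#' the image x axis follows the in-plane lateral world axis and the image y
#' axis follows world -z (rows grow toward inferior). Both sources sit at
#' distance `source_to_object_mm` from the world origin, with the detector
#' `source_to_detector_mm` from the source.
#'
#' @param detector_size_m detector edge lengths in meters (length-1 or 2)
#' @param detector_px detector resolution in pixels (length-1 or 2)
#' @param source_to_detector_mm source-to-detector distance (mm)
#' @param source_to_object_mm source-to-world-origin distance (mm)
#' @return A list with elements `lat` and `ap` ([projection_matrix()]s),
#'   `pitch_mm` (mm per pixel), and the source positions (used by the
#'   renderer's oracle tests).
#' @export
make_biplanar_cameras <- function(detector_size_m = c(0.6, 0.6),
                                  detector_px = c(2048, 2048),
                                  source_to_detector_mm = 1100,
                                  source_to_object_mm = 700) {
  detector_size_m <- rep(detector_size_m, length.out = 2)
  detector_px <- rep(as.integer(detector_px), length.out = 2)
  if (any(detector_size_m <= 0) || any(detector_px < 1) ||
      source_to_detector_mm <= 0 || source_to_object_mm <= 0 ||
      source_to_detector_mm <= source_to_object_mm)
    stop("invalid rig geometry")
  pitch <- detector_size_m * 1000 / detector_px   # mm per pixel, (x, y)
  f <- source_to_detector_mm / pitch              # focal terms in pixels
  cu <- (detector_px[1] - 1) / 2
  cv <- (detector_px[2] - 1) / 2
  sod <- source_to_object_mm
  ## LAT: source at (-sod, 0, 0), axis +x, u <- +y, v <- -z
  P_lat <- rbind(c(cu, f[1], 0, cu * sod),
                 c(cv, 0, -f[2], cv * sod),
                 c(1, 0, 0, sod))
  ## AP: source at (0, -sod, 0), axis +y, u <- +x, v <- -z
  P_ap <- rbind(c(f[1], cu, 0, cu * sod),
                c(0, cv, -f[2], cv * sod),
                c(0, 1, 0, sod))
  list(lat = projection_matrix(P_lat, "lat"),
       ap = projection_matrix(P_ap, "ap"),
       pitch_mm = pitch,
       source = list(lat = c(-sod, 0, 0), ap = c(0, -sod, 0)),
       sdd_mm = source_to_detector_mm, sod_mm = source_to_object_mm,
       detector_px = detector_px)
}

#' Camera center (X-ray source position) of a projection matrix
#'
#' The right null space of P, dehomogenized.
#' @param camera a [projection_matrix()]
#' @return world mm 3-vector
#' @export
camera_center <- function(camera) {
  P <- camera$P
  c0 <- -solve(P[, 1:3], P[, 4])
  as.vector(c0)
}

#' Axis-aligned voxel grid in world coordinates
#'
#' `origin` is the center of voxel (0,0,0); voxel (i,j,k) has center
#' `origin + c(i,j,k) * spacing` exactly.
#'
#' @param origin world mm 3-vector
#' @param spacing mm, length-1 or 3, strictly positive
#' @param dims voxel counts, length-1 or 3, at least 1
#' @export
volume_grid <- function(origin, spacing, dims) {
  spacing <- rep(spacing, length.out = 3)
  dims <- rep(as.integer(dims), length.out = 3)
  origin <- rep(origin, length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(dims < 1)) stop("dims must be >= 1")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "volume_grid")
}

#' Centered cubic grid helper
#' @param extent_mm full edge length of the cube (mm)
#' @param n voxels per edge
#' @export
volume_grid_cube <- function(extent_mm, n) {
  spacing <- extent_mm / n
  volume_grid(origin = rep(-spacing * (n - 1) / 2, 3), spacing = spacing, dims = n)
}

#' Voxel centers of a grid
#' @param grid a [volume_grid()]
#' @return (prod(dims)) x 3 matrix, voxel (i,j,k) at flat row
#'   `1 + i + dims[1]*j + dims[1]*dims[2]*k` (column-major, 0-based ijk)
#' @export
voxel_centers <- function(grid) {
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  cbind(grid$origin[1] + i * grid$spacing[1],
        grid$origin[2] + j * grid$spacing[2],
        grid$origin[3] + k * grid$spacing[3])
}

## Project voxel centers with one camera; returns n_vox x 2 pixel coords,
## with NA rows for voxels at or behind the source (those sample to zero).
grid_pixel_coords <- function(camera, grid) {
  pc <- voxel_centers(grid)
  hp <- cbind(pc, 1) %*% t(camera$P)
  bad <- hp[, 3] <= 0
  uv <- hp[, 1:2, drop = FALSE] / hp[, 3]
  uv[bad, ] <- NA_real_
  uv
}

#' Unproject per-view 2D feature maps into a pseudo-3D feature volume
#'
#' Every voxel center is projected into each view with that view's
#' projection matrix and the view's feature map is sampled bilinearly at the
#' projected pixel location (zero outside the image). The per-view volumes
#' are aggregated by the elementwise mean.
#'
#' @param feature_maps named list (`lat`, `ap`) of arrays with dim
#'   `c(h, w, channels)`; channel counts must agree
#' @param cameras named list (`lat`, `ap`) of [projection_matrix()]s
#' @param grid a [volume_grid()]
#' @return array with dim `c(grid$dims, channels)`
#' @export
unproject_features <- function(feature_maps, cameras, grid) {
  views <- names(feature_maps)
  chans <- vapply(feature_maps, function(f) dim(f)[3], integer(1))
  if (length(unique(chans)) != 1) stop("inconsistent inputs: channel counts differ")
  C <- chans[[1]]
  nv <- prod(grid$dims)
  acc <- matrix(0, nv, C)
  for (v in views) {
    fm <- feature_maps[[v]]
    uv <- grid_pixel_coords(cameras[[v]], grid)
    acc <- acc + cpp_bilin_fw(fm, dim(fm)[1], dim(fm)[2], C, uv)
  }
  acc <- acc / length(views)
  dim(acc) <- c(grid$dims, C)
  acc
}

#' Differentiable 3D soft-argmax
#'
#' The softmax-weighted mean of voxel centers:
#' `sum_v softmax(heatmap / temperature)_v * center_v`. Always lies inside
#' the convex hull of the voxel centers and is differentiable in the heatmap
#' values.
#'
#' @param volume numeric array over the grid (any values; a log-heatmap or
#'   probability map)
#' @param grid a [volume_grid()]
#' @param temperature softmax temperature, > 0
#' @return world mm 3-vector
#' @export
soft_argmax3d <- function(volume, grid, temperature = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  v <- as.vector(volume) / temperature
  m <- max(v)
  if (!is.finite(m)) stop("degenerate input: heatmap has no finite maximum")
  p <- exp(v - m)
  p <- p / sum(p)
  as.vector(crossprod(voxel_centers(grid), p))
}

## JSON (de)serialization of cameras --------------------------------------

#' Write cameras to a JSON file
#' @param cameras list with `lat` and `ap` [projection_matrix()]s
#' @param path output file
#' @export
write_cameras <- function(cameras, path) {
  obj <- lapply(c("lat", "ap"), function(v)
    list(view = v, P = unclass(cameras[[v]]$P)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read cameras from a JSON file written by [write_cameras()]
#' @param path input file
#' @export
read_cameras <- function(path) {
  obj <- jsonlite::read_json(path)
  out <- list()
  for (o in obj) {
    P <- do.call(rbind, lapply(o$P, function(r) as.numeric(unlist(r))))
    out[[o$view]] <- projection_matrix(P, o$view)
  }
  out
}
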
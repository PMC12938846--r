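## Ground-truth heatmap construction and training losses.
##
## Per-view heatmap stacks are arrays with dim c(S, S, N) (rows, cols,
## vertebra slots); two-view collections are named lists (`lat`, `ap`).
## Slots beyond the number of vertebrae actually present carry all-zero
## target heatmaps, which trains their predicted maxima below the presence
## threshold.

#' Ground-truth heatmap for one 2D landmark
#'
#' An isotropic Gaussian bump centered at the landmark mapped into heatmap
#' grid coordinates, normalized so the peak cell value is exactly 1
#' (`sigma -> 0` recovers a one-hot grid). The `S x S` grid covers the full
#' image extent: image pixel `(x, y)` maps to grid coordinates
#' `((x + 0.5) * S / w - 0.5, (y + 0.5) * S / h - 0.5)`.
#'
#' @param landmark_2d length-2 pixel coordinates `(x, y)`, 0-based
#' @param image_size `c(w, h)` in pixels
#' @param grid heatmap resolution S (default 16)
#' @param sigma Gaussian width in grid cells
#' @return `S x S` matrix with values in `[0, 1]` and max exactly 1
#' @export
make_gt_heatmap <- function(landmark_2d, image_size, grid = 16L, sigma = 1.0) {
  w <- image_size[1]; h <- image_size[2]
  x <- landmark_2d[1]; y <- landmark_2d[2]
  if (x < -0.5 || x > w - 0.5 || y < -0.5 || y > h - 0.5)
    stop("invalid GT: landmark outside the image")
  gx <- (x + 0.5) * grid / w - 0.5
  gy <- (y + 0.5) * grid / h - 0.5
  cx <- seq_len(grid) - 1
  d2 <- outer((cx - gy)^2, (cx - gx)^2, "+")  # rows = y cells, cols = x cells
  if (sigma <= 0) {
    hm <- matrix(0, grid, grid)
    hm[which.min(d2)] <- 1
    return(hm)
  }
  hm <- exp(-d2 / (2 * sigma^2))
  hm / max(hm)
}

#' Build the two-view ground-truth heatmap stacks for a sample
#'
#' @param landmarks_2d named list (`lat`, `ap`) of n x 2 pixel matrices
#' @param image_size `c(w, h)`
#' @param N total slot count (slots beyond the landmarks present are zero)
#' @param grid,sigma passed to [make_gt_heatmap()]
#' @return named list of `S x S x N` arrays
#' @export
make_gt_heatmaps <- function(landmarks_2d, image_size, N, grid = 16L, sigma = 1.0) {
  out <- list()
  for (v in names(landmarks_2d)) {
    hm <- array(0, dim = c(grid, grid, N))
    lm <- landmarks_2d[[v]]
    for (n in seq_len(min(nrow(lm), N)))
      hm[, , n] <- make_gt_heatmap(lm[n, ], image_size, grid, sigma)
    out[[v]] <- hm
  }
  out
}

check_heatmap_shapes <- function(pred, gt) {
  if (!identical(sort(names(pred)), sort(names(gt))))
    stop("shape mismatch: views differ")
  for (v in names(pred))
    if (!identical(dim(pred[[v]]), dim(gt[[v]])))
      stop("shape mismatch between predicted and ground-truth heatmaps")
}

#' Mean-squared-error heatmap loss
#'
#' Squared differences summed over both views, all N slots and all `S x S`
#' cells, normalized by exactly `2 * N * S * S`.
#'
#' @param pred,gt named lists (`lat`, `ap`) of `S x S x N` heatmap arrays
#' @return scalar loss
#' @export
loss_mse_2d <- function(pred, gt) {
  check_heatmap_shapes(pred, gt)
  tot <- 0
  for (v in names(pred)) tot <- tot + sum((pred[[v]] - gt[[v]])^2)
  tot / (2 * prod(dim(pred[[1]])))
}

#' Dice heatmap loss
#'
#' `1 - (1 / 2N) * sum_views sum_n (2 * sum p * p~ + eps) /
#' (sum p^2 + sum p~^2 + eps)`; with the epsilon guard an empty predicted
#' and empty target slot contributes a perfect overlap (loss 0).
#'
#' @inheritParams loss_mse_2d
#' @param eps numerical guard added to numerator and denominator
#' @return scalar loss
#' @export
loss_dice_2d <- function(pred, gt, eps = 1e-6) {
  check_heatmap_shapes(pred, gt)
  N <- dim(pred[[1]])[3]
  acc <- 0
  for (v in names(pred)) {
    for (n in seq_len(N)) {
      p <- gt[[v]][, , n]; q <- pred[[v]][, , n]
      acc <- acc + (2 * sum(p * q) + eps) / (sum(p^2) + sum(q^2) + eps)
    }
  }
  1 - acc / (2 * N)
}

#' 3D coordinate loss
#'
#' Mean squared Euclidean distance over the `Nv` vertebrae actually
#' present; slots `> Nv` are excluded.
#'
#' @param pred n x 3 matrix of predicted coordinates (mm); rows beyond `Nv`
#'   are ignored
#' @param gt `Nv` x 3 (or larger) matrix of ground-truth coordinates (mm)
#' @param Nv number of vertebrae present
#' @return scalar loss in mm^2
#' @export
loss_3d <- function(pred, gt, Nv = nrow(gt)) {
  if (Nv < 1) stop("empty target: Nv must be >= 1")
  pred <- matrix(pred, ncol = 3)[seq_len(Nv), , drop = FALSE]
  gt <- matrix(gt, ncol = 3)[seq_len(Nv), , drop = FALSE]
  sum((pred - gt)^2) / Nv
}

#' Overall localization loss
#'
#' `w1 * LossMSE + w2 * LossDice + w3 * Loss3D` with default unit weights.
#'
#' @param pred list with `heatmaps` (named list of `S x S x N` arrays) and
#'   `coords` (n x 3 matrix, mm)
#' @param gt list with `heatmaps`, `coords` and `Nv`
#' @param weights length-3 numeric weights
#' @param eps Dice guard
#' @return scalar loss
#' @export
loss_overall <- function(pred, gt, weights = c(1, 1, 1), eps = 1e-6) {
  weights[1] * loss_mse_2d(pred$heatmaps, gt$heatmaps) +
    weights[2] * loss_dice_2d(pred$heatmaps, gt$heatmaps, eps) +
    weights[3] * loss_3d(pred$coords, gt$coords, gt$Nv)
}

## --------------------------------------------------------------------------
## Tape versions used by the training graph (same formulas, with analytic
## gradients).  pred_* are tape nodes; targets are plain arrays.
## --------------------------------------------------------------------------

ad_loss_mse_2d <- function(g, pred_node, gt_array) {
  norm <- 2 * prod(dim(gt_array))
  ad_node(g, sum((pred_node$value - gt_array)^2) / norm, list(pred_node),
          function(gr) list(as.numeric(gr) * 2 * (pred_node$value - gt_array) / norm))
}

ad_loss_dice_2d <- function(g, pred_node, gt_array, eps = 1e-6) {
  ## pred_node: (S, S, N) for one view; contributes sum_n dice_n; the 1 - /2N
  ## wrapper is applied by the caller across views.
  N <- dim(gt_array)[3]
  q <- pred_node$value
  num <- den <- numeric(N)
  for (n in seq_len(N)) {
    p <- gt_array[, , n]
    num[n] <- 2 * sum(p * q[, , n]) + eps
    den[n] <- sum(p^2) + sum(q[, , n]^2) + eps
  }
  ad_node(g, sum(num / den), list(pred_node), function(gr) {
    gq <- array(0, dim = dim(q))
    for (n in seq_len(N)) {
      p <- gt_array[, , n]
      gq[, , n] <- as.numeric(gr) * (2 * p / den[n] - num[n] * 2 * q[, , n] / den[n]^2)
    }
    list(gq)
  })
}

ad_loss_3d <- function(g, coords_node, gt, Nv) {
  ## coords_node: N x 3 coordinate matrix node; slots > Nv excluded
  diff <- coords_node$value[seq_len(Nv), , drop = FALSE] -
    gt[seq_len(Nv), , drop = FALSE]
  ad_node(g, sum(diff^2) / Nv, list(coords_node), function(gr) {
    gc <- matrix(0, nrow(coords_node$value), 3)
    gc[seq_len(Nv), ] <- as.numeric(gr) * 2 * diff / Nv
    list(gc)
  })
}
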
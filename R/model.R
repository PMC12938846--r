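## Full localization model: parameter initialization and the end-to-end
## forward pass (optionally with losses on the tape for training).

#' Initialize model parameters
#'
#' All weights are drawn from scaled Gaussians (He initialization for the
#' convolutions). The final 3D convolution head is initialized as a gated
#' pass-through of the unprojected per-slot heatmap channels: slot n's 3D
#' logit starts as a positive gain times the two-view mean of heatmap
#' channel n, so the voxel softmax is informative from the first step and
#' the 2D and 3D objectives cooperate instead of fighting. All other
#' aspects of the head remain learnable.
#'
#' @param cfg a [model_config()]
#' @param seed integer seed
#' @return named list of parameter arrays
#' @export
model_init <- function(cfg, seed = 1L) {
  local_rng(seed)
  pars <- list()
  pars <- init_vfe(pars, cfg)
  pars <- init_fe(pars, cfg)
  pars <- init_sce(pars, cfg)
  cin <- cfg$d + cfg$N
  c3 <- cfg$head3d_channels
  ## head: 1x1x1 channel mixer followed by two 3x3x3 convolutions
  pars <- init_linear(pars, "f3d.c1", cin, c3)
  pars <- init_conv3d(pars, "f3d.c2", c3, c3)
  pars <- init_conv3d(pars, "f3d.c3", c3, cfg$N)
  ## identity-like pass-through: heatmap channel d+n -> hidden n -> slot n,
  ## through the center tap of each 3x3x3 kernel, with a final gain that
  ## makes a confident two-view heatmap agreement dominate the voxel softmax
  center <- (1 + 1) * 9 + (1 + 1) * 3 + (1 + 1) + 1  # center offset in 27-block
  gain <- cfg$head3d_gain
  for (n in seq_len(min(cfg$N, c3))) {
    pars[["f3d.c1.W"]][cfg$d + n, n] <- pars[["f3d.c1.W"]][cfg$d + n, n] + 1
    pars[["f3d.c2.W"]][(n - 1) * 27 + center, n] <-
      pars[["f3d.c2.W"]][(n - 1) * 27 + center, n] + 1
    pars[["f3d.c3.W"]][(n - 1) * 27 + center, n] <-
      pars[["f3d.c3.W"]][(n - 1) * 27 + center, n] + gain
  }
  pars
}

## The 3D convolution head: fused (dims, d+N) volume node -> per-slot logits.
## Dilated taps widen the receptive field to roughly one vertebral body so
## the head can place a peak relative to both body edges.
head3d_forward <- function(g, pars, fused, grid, cfg) {
  nvox <- prod(grid$dims)
  cin <- cfg$d + cfg$N
  dl <- cfg$head3d_dilation
  xr <- ad_reshape(g, fused, c(nvox, cin))
  h1 <- ad_relu(g, linear_p(g, pars, "f3d.c1", xr))
  h1 <- ad_reshape(g, h1, c(grid$dims, cfg$head3d_channels))
  h2 <- ad_relu(g, conv3d_p(g, pars, "f3d.c2", h1, dil = dl[1]))
  conv3d_p(g, pars, "f3d.c3", h2, dil = dl[2])
}

## Precompute the per-view voxel->pixel sampling tables for a sample's
## cameras (they depend only on the rig and the grid).
make_uv_tables <- function(cameras, grid) {
  lapply(cameras, function(cam) grid_pixel_coords(cam, grid))
}

#' End-to-end forward pass
#'
#' Runs both views through feature extraction, prompt-guided enhancement,
#' the dual-attention context module, multi-view unprojection and the 3D
#' convolution head, producing per-slot 3D coordinates by soft-argmax.
#' When `gt` is supplied the overall loss (2D MSE + Dice + 3D MSE) is
#' assembled on the tape for backpropagation.
#'
#' @param pars parameters from [model_init()]
#' @param sample a biplanar sample (see [simulate_biplanar_sample()]); only
#'   `images`, `cameras`, `prompt` are required
#' @param cfg a [model_config()]
#' @param grid the localization [volume_grid()] (default [config_grid()])
#' @param gt optional list with `heatmaps` (per-view `S x S x N` arrays),
#'   `coords` (`Nv x 3` mm), `Nv`
#' @param uv_tables optional precomputed [make_uv_tables()] output
#' @return list with `result` (a `localization_result`), `loss` (tape node
#'   or NULL), `tape`
#' @export
model_forward <- function(pars, sample, cfg, grid = config_grid(cfg),
                          gt = NULL, uv_tables = NULL) {
  g <- ad_tape()
  views <- c("lat", "ap")
  if (is.null(uv_tables)) uv_tables <- make_uv_tables(sample$cameras, grid)
  fe_nodes <- list(); hm_nodes <- list(); sel <- list()
  for (v in views) {
    img <- sample$images[[v]]
    h <- nrow(img); w <- ncol(img)
    x <- ad_const(g, array(img, dim = c(h, w, 1)))
    fi <- vfe_forward(g, pars, x, cfg)
    pr <- sample$prompt[[v]]
    fp <- ad_prompt_crop(g, fi, pr, cfg$r)
    fe <- fe_forward(g, pars, fi, fp, cfg)
    Md <- distance_mask(pr, w, h)
    Mb <- (Md > 0) * 1
    Mh <- if (cfg$md_normalize) Md / h^2 else Md
    fm <- ad_mask_features(g, fe, Mb, Mh)
    out <- sce_forward(g, pars, fm, cfg)
    fe_nodes[[v]] <- fe
    hm_nodes[[v]] <- out$heatmap
    sel[[v]] <- out$selection
  }
  ## fusion: rescale heatmaps to image size, concat with fe, unproject
  vols <- list()
  for (v in views) {
    dimg <- dim(fe_nodes[[v]]$value)
    hmup <- ad_resample_sep(g, hm_nodes[[v]],
                            interp_matrix(dimg[1], cfg$S),
                            interp_matrix(dimg[2], cfg$S))
    fc <- ad_concat_ch(g, fe_nodes[[v]], hmup)
    vols[[v]] <- ad_sample_bilinear(g, fc, uv_tables[[v]])
  }
  fused <- ad_scale(g, ad_add(g, vols[[1]], vols[[2]]), 0.5)
  fused <- ad_reshape(g, fused, c(grid$dims, cfg$d + cfg$N))
  logits <- head3d_forward(g, pars, fused, grid, cfg)
  centers <- voxel_centers(grid)
  coords_node <- ad_softargmax_slots(g, logits, centers, cfg$temperature)
  coords <- coords_node$value
  pmax_view <- lapply(hm_nodes, function(hm)
    apply(hm$value, 3, max))
  result <- localization_result(coords, lapply(hm_nodes, function(n) n$value),
                                pmax_view, cfg)
  loss <- NULL
  parts <- NULL
  if (!is.null(gt)) {
    mse <- ad_add(g, ad_loss_mse_2d(g, hm_nodes$lat, gt$heatmaps$lat),
                  ad_loss_mse_2d(g, hm_nodes$ap, gt$heatmaps$ap))
    dice_sum <- ad_add(g, ad_loss_dice_2d(g, hm_nodes$lat, gt$heatmaps$lat, cfg$dice_eps),
                       ad_loss_dice_2d(g, hm_nodes$ap, gt$heatmaps$ap, cfg$dice_eps))
    dice <- ad_affine(g, dice_sum, -1 / (2 * cfg$N), 1)
    l3 <- ad_loss_3d(g, coords_node, as.matrix(gt$coords), gt$Nv)
    ## 3D term optimized in normalized grid coordinates so it stays
    ## commensurate with the unit-scale heatmap losses
    scale_mm <- if (is.null(cfg$loss3d_scale_mm)) cfg$grid_extent_mm
                else cfg$loss3d_scale_mm
    l3n <- ad_scale(g, l3, 1 / scale_mm^2)
    w <- cfg$loss_weights
    loss <- ad_add(g, ad_add(g, ad_scale(g, mse, w[1]), ad_scale(g, dice, w[2])),
                   ad_scale(g, l3n, w[3]))
    parts <- c(mse = mse$value, dice = dice$value, l3_mm2 = l3$value,
               total = loss$value)
  }
  list(result = result, loss = loss, parts = parts, tape = g,
       selection = sel)
}

#' Localization result container
#'
#' @param coords N x 3 matrix of world coordinates (mm)
#' @param heatmaps_2d named list of `S x S x N` predicted heatmaps
#' @param pmax named list of per-slot maximum heatmap probabilities
#' @param cfg the [model_config()] (for the presence rule)
#' @return object of class `localization_result` with a `valid` flag per
#'   slot
#' @export
localization_result <- function(coords, heatmaps_2d, pmax, cfg) {
  res <- structure(list(coords = coords, heatmaps_2d = heatmaps_2d,
                        pmax = pmax, valid = rep(TRUE, nrow(coords))),
                   class = "localization_result")
  validity_filter(res, threshold = cfg$presence_threshold,
                  rule = cfg$presence_rule)
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result: %d slots, %d valid>\n",
              nrow(x$coords), sum(x$valid)))
  df <- data.frame(slot = seq_len(nrow(x$coords)) - 1L,
                   x_mm = round(x$coords[, 1], 2),
                   y_mm = round(x$coords[, 2], 2),
                   z_mm = round(x$coords[, 3], 2),
                   pmax_lat = round(x$pmax$lat, 3),
                   pmax_ap = round(x$pmax$ap, 3),
                   valid = x$valid)
  print(df)
  invisible(x)
}

#' Apply the presence (pmax) validity rule
#'
#' A slot is considered present when the maximum probability of its
#' predicted 2D heatmap exceeds the threshold — in both views (default) or
#' in at least one (`rule = "any"`). Invalid slots are excluded from
#' downstream metrics.
#'
#' @param result a `localization_result`
#' @param threshold presence threshold (default 0.5)
#' @param rule `"both"` or `"any"`
#' @return the result with its `valid` flags updated
#' @export
validity_filter <- function(result, threshold = 0.5, rule = c("both", "any")) {
  rule <- match.arg(rule)
  pm <- do.call(cbind, result$pmax)
  result$valid <- if (rule == "both") apply(pm > threshold, 1, all)
                  else apply(pm > threshold, 1, any)
  result
}

#' Fuse per-view heatmaps and features into 3D coordinates
#'
#' The last stage of the pipeline as a standalone operation: rescales the
#' `S x S` heatmaps to image resolution, concatenates them with the
#' enhanced features, unprojects both views into the pseudo-3D volume
#' (elementwise mean), applies the 3D convolution head, and reads out one
#' coordinate per slot by per-slot voxel softmax + soft-argmax.
#'
#' @param heatmaps named list (`lat`, `ap`) of `S x S x N` arrays
#' @param features named list of `c(h, w, d)` enhanced feature arrays
#' @param cameras named list of [projection_matrix()]s
#' @param grid the localization [volume_grid()]
#' @param pars,cfg model parameters and configuration
#' @return a `localization_result`
#' @export
fuse_and_localize <- function(heatmaps, features, cameras, grid, pars, cfg) {
  g <- ad_tape()
  uv <- make_uv_tables(cameras, grid)
  vols <- list()
  for (v in names(features)) {
    dimg <- dim(features[[v]])
    hm <- ad_const(g, heatmaps[[v]])
    hmup <- ad_resample_sep(g, hm, interp_matrix(dimg[1], cfg$S),
                            interp_matrix(dimg[2], cfg$S))
    fc <- ad_concat_ch(g, ad_const(g, features[[v]]), hmup)
    vols[[v]] <- ad_sample_bilinear(g, fc, uv[[v]])
  }
  fused <- ad_scale(g, ad_add(g, vols[[1]], vols[[2]]), 0.5)
  fused <- ad_reshape(g, fused, c(grid$dims, cfg$d + cfg$N))
  logits <- head3d_forward(g, pars, fused, grid, cfg)
  centers <- voxel_centers(grid)
  coords <- ad_softargmax_slots(g, logits, centers, cfg$temperature)$value
  pmax_view <- lapply(heatmaps, function(hm) apply(hm, 3, max))
  localization_result(coords, heatmaps, pmax_view, cfg)
}
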
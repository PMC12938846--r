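## Visual feature extraction (a four-level U-Net with a spatial-pyramid
## bottleneck) and the prompt-guided cross-attention feature enhancement
## stage.

#' Model configuration
#'
#' Hyperparameters of the localization network. Two named presets mirror
#' the published full-scale settings; the desk profile is small enough to
#' train on a single CPU.
#'
#' @param preset `"desk"` (default), `"bispinex"` (512-pixel synthetic
#'   full-scale profile: d = 64, N = 10, alpha = 32, k = 8) or
#'   `"sheepspinex"` (N = 5, alpha = 8, k = 4)
#' @param ... overrides for any field
#' @return list of class `model_config`
#' @export
model_config <- function(preset = c("desk", "bispinex", "sheepspinex"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(
      image_px = 128L, d = 16L, channels = c(8L, 16L, 32L, 64L),
      N = 5L, S = 16L, alpha = 8L, topk = 4L, r = 16L,
      fe_layers = 4L, fe_heads = 8L, fe_hidden = 64L, fe_downsample = 8L,
      sce_hidden = 64L, head3d_channels = 8L,
      grid_extent_mm = 192, grid_n = 64L,
      ## a sharper voxel softmax measurably improves desk-scale precision
      temperature = 0.5,
      spp_scales = c(1L, 2L, 4L, 8L)),
    bispinex = list(
      image_px = 512L, d = 64L, channels = c(16L, 32L, 64L, 128L),
      temperature = 1,
      N = 10L, S = 16L, alpha = 32L, topk = 8L, r = 40L,
      fe_layers = 4L, fe_heads = 8L, fe_hidden = 64L, fe_downsample = 8L,
      sce_hidden = 64L, head3d_channels = 32L,
      grid_extent_mm = 512, grid_n = 64L,
      spp_scales = c(1L, 2L, 4L, 8L)),
    sheepspinex = list(
      image_px = 512L, d = 64L, channels = c(16L, 32L, 64L, 128L),
      temperature = 1,
      N = 5L, S = 16L, alpha = 8L, topk = 4L, r = 40L,
      fe_layers = 4L, fe_heads = 8L, fe_hidden = 64L, fe_downsample = 8L,
      sce_hidden = 64L, head3d_channels = 32L,
      grid_extent_mm = 512, grid_n = 64L,
      spp_scales = c(1L, 2L, 4L, 8L)))
  ## dice_eps guards the Dice ratio for empty-target slots; it must exceed
  ## the squared sigmoid floor summed over the S^2 heatmap cells or those
  ## slots can never reach a perfect overlap score (see the methods
  ## vignette), hence 1e-3 here rather than a token machine epsilon
  common <- list(md_normalize = TRUE, use_pe = TRUE,
                 topk_reduce = "max", presence_threshold = 0.5,
                 presence_rule = "both", sigma = 1.0, dice_eps = 1e-3,
                 head3d_gain = 10,
                 ## kernel-tap dilations of the two spatial head convolutions:
                 ## (2, 4) spans ~+/-18 mm at 3 mm voxels, about one vertebral
                 ## body, which center-finding needs
                 head3d_dilation = c(2L, 4L),
                 ## reference length for the normalized 3D coordinate loss
                 ## (defaults to the grid extent; stronger normalizations were
                 ## tried and suppress heatmap learning, see the vignette)
                 loss3d_scale_mm = NULL,
                 loss_weights = c(1, 1, 1), include_reference_slot = TRUE)
  cfg <- c(cfg, common)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "model_config")
}

#' The pseudo-3D localization grid implied by a configuration
#' @param cfg a [model_config()]
#' @export
config_grid <- function(cfg) volume_grid_cube(cfg$grid_extent_mm, cfg$grid_n)

## ---- U-Net + SPP --------------------------------------------------------

init_vfe <- function(pars, cfg) {
  ch <- cfg$channels
  pars <- init_conv2d(pars, "vfe.enc1a", 1, ch[1])
  pars <- init_conv2d(pars, "vfe.enc1b", ch[1], ch[1])
  pars <- init_conv2d(pars, "vfe.enc2a", ch[1], ch[2])
  pars <- init_conv2d(pars, "vfe.enc2b", ch[2], ch[2])
  pars <- init_conv2d(pars, "vfe.enc3a", ch[2], ch[3])
  pars <- init_conv2d(pars, "vfe.enc3b", ch[3], ch[3])
  pars <- init_conv2d(pars, "vfe.enc4a", ch[3], ch[4])
  pars <- init_conv2d(pars, "vfe.enc4b", ch[4], ch[4])
  q <- max(1L, ch[4] %/% 4L)
  for (s in cfg$spp_scales)
    pars <- init_conv2d(pars, paste0("vfe.spp", s), ch[4], q, k = 1)
  pars <- init_conv2d(pars, "vfe.sppout",
                      ch[4] + length(cfg$spp_scales) * q, ch[4], k = 1)
  pars <- init_conv2d(pars, "vfe.dec3a", ch[4] + ch[3], ch[3])
  pars <- init_conv2d(pars, "vfe.dec3b", ch[3], ch[3])
  pars <- init_conv2d(pars, "vfe.dec2a", ch[3] + ch[2], ch[2])
  pars <- init_conv2d(pars, "vfe.dec2b", ch[2], ch[2])
  pars <- init_conv2d(pars, "vfe.dec1a", ch[2] + ch[1], ch[1])
  pars <- init_conv2d(pars, "vfe.dec1b", ch[1], ch[1])
  pars <- init_conv2d(pars, "vfe.out", ch[1], cfg$d, k = 1)
  pars
}

conv_block <- function(g, pars, name, x) {
  x <- ad_relu(g, conv2d_p(g, pars, paste0(name, "a"), x))
  ad_relu(g, conv2d_p(g, pars, paste0(name, "b"), x))
}

vfe_forward <- function(g, pars, img, cfg, use_spp = TRUE) {
  d <- dim(img$value)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("size error: image dimensions must be divisible by 8")
  s1 <- conv_block(g, pars, "vfe.enc1", img)
  s2 <- conv_block(g, pars, "vfe.enc2", ad_maxpool2d(g, s1, 2))
  s3 <- conv_block(g, pars, "vfe.enc3", ad_maxpool2d(g, s2, 2))
  bt <- conv_block(g, pars, "vfe.enc4", ad_maxpool2d(g, s3, 2))
  if (use_spp) {
    hb <- dim(bt$value)[1]; wb <- dim(bt$value)[2]
    branches <- list(bt)
    for (s in cfg$spp_scales) {
      if (s > min(hb, wb)) next
      pooled <- ad_resample_sep(g, bt, avg_matrix(s, hb), avg_matrix(s, wb))
      proj <- ad_relu(g, conv2d_p(g, pars, paste0("vfe.spp", s), pooled, k = 1))
      branches <- c(branches, list(
        ad_resample_sep(g, proj, interp_matrix(hb, s), interp_matrix(wb, s))))
    }
    cat_node <- branches[[1]]
    for (i in seq_along(branches)[-1]) cat_node <- ad_concat_ch(g, cat_node, branches[[i]])
    bt <- ad_relu(g, conv2d_p(g, pars, "vfe.sppout", cat_node, k = 1))
  }
  up3 <- ad_resample_sep(g, bt, interp_matrix(dim(s3$value)[1], dim(bt$value)[1]),
                         interp_matrix(dim(s3$value)[2], dim(bt$value)[2]))
  d3 <- conv_block(g, pars, "vfe.dec3", ad_concat_ch(g, up3, s3))
  up2 <- ad_resample_sep(g, d3, interp_matrix(dim(s2$value)[1], dim(d3$value)[1]),
                         interp_matrix(dim(s2$value)[2], dim(d3$value)[2]))
  d2 <- conv_block(g, pars, "vfe.dec2", ad_concat_ch(g, up2, s2))
  up1 <- ad_resample_sep(g, d2, interp_matrix(dim(s1$value)[1], dim(d2$value)[1]),
                         interp_matrix(dim(s1$value)[2], dim(d2$value)[2]))
  d1 <- conv_block(g, pars, "vfe.dec1", ad_concat_ch(g, up1, s1))
  conv2d_p(g, pars, "vfe.out", d1, k = 1)
}

#' Extract full-resolution visual features from a grayscale image
#'
#' Runs the shared four-level encoder-decoder with the spatial-pyramid
#' bottleneck; fully convolutional, so any input size divisible by 8 works.
#'
#' @param image `h x w` matrix (grayscale, any numeric range)
#' @param pars parameter list from [model_init()]
#' @param cfg the matching [model_config()]
#' @param use_spp include the spatial-pyramid bottleneck (default TRUE;
#'   disabling it makes the extractor translation-covariant up to border
#'   effects, which the tests exploit)
#' @return array with dim `c(h, w, d)`
#' @export
extract_features <- function(image, pars, cfg, use_spp = TRUE) {
  g <- ad_tape()
  img <- ad_const(g, array(image, dim = c(nrow(image), ncol(image), 1)))
  vfe_forward(g, pars, img, cfg, use_spp = use_spp)$value
}

#' Split a tall image into sliding windows
#'
#' Consecutive non-overlapping windows from top to bottom; the final window
#' is anchored to the bottom edge (and may overlap its predecessor) so that
#' every row is covered. Row offsets allow exact reassembly of coordinates.
#'
#' @param image `h x w` matrix
#' @param window window height in rows (default 512)
#' @return list of `list(patch, row_offset)` with 0-based offsets
#' @export
sliding_window_split <- function(image, window = 512L) {
  h <- nrow(image)
  window <- as.integer(window)
  if (h <= window) return(list(list(patch = image, row_offset = 0L)))
  offsets <- as.integer(seq(0L, h - window, by = window))
  if (offsets[length(offsets)] != h - window)
    offsets <- c(offsets, h - as.integer(window))
  lapply(offsets, function(o)
    list(patch = image[(o + 1):(o + window), , drop = FALSE], row_offset = o))
}

## ---- prompt-guided feature enhancement ----------------------------------

init_fe <- function(pars, cfg) {
  for (l in seq_len(cfg$fe_layers))
    pars <- init_mha_block(pars, paste0("fe.l", l), cfg$d, cfg$fe_hidden,
                           cfg$fe_heads)
  pars
}

fe_forward <- function(g, pars, fi, fp, cfg) {
  d <- dim(fi$value)
  if (d[3] != dim(fp$value)[3])
    stop("inconsistent inputs: channel counts differ")
  ds <- cfg$fe_downsample
  h8 <- d[1] %/% ds; w8 <- d[2] %/% ds
  hp8 <- max(1L, dim(fp$value)[1] %/% ds); wp8 <- max(1L, dim(fp$value)[2] %/% ds)
  fi8 <- ad_resample_sep(g, fi, avg_matrix(h8, d[1]), avg_matrix(w8, d[2]))
  fp8 <- ad_resample_sep(g, fp, avg_matrix(hp8, dim(fp$value)[1]),
                         avg_matrix(wp8, dim(fp$value)[2]))
  qt <- ad_reshape(g, fi8, c(h8 * w8, d[3]))
  kt <- ad_reshape(g, fp8, c(hp8 * wp8, d[3]))
  pe_q <- if (cfg$use_pe) pe_2d(h8, w8, d[3]) else NULL
  pe_k <- if (cfg$use_pe) pe_2d(hp8, wp8, d[3]) else NULL
  for (l in seq_len(cfg$fe_layers))
    qt <- mha_block(g, pars, paste0("fe.l", l), qt, kt, cfg$fe_heads,
                    cfg$fe_hidden, pe_q = pe_q, pe_kv = pe_k)
  att <- ad_reshape(g, qt, c(h8, w8, d[3]))
  up <- ad_resample_sep(g, att, interp_matrix(d[1], h8), interp_matrix(d[2], w8))
  ad_add(g, fi, up)
}

#' Prompt-guided feature enhancement
#'
#' Average-pools the image features and the prompt-window features by the
#' configured factor, runs a stack of cross-attention layers in which the
#' prompt tokens serve as key and value, then bilinearly upsamples the
#' attended tokens and adds them residually to the input features.
#'
#' @param fi feature array `c(h, w, d)` from [extract_features()]
#' @param fp prompt feature crop `c(2r, 2r, d)` from [prompt_features()]
#' @param pars,cfg model parameters and configuration
#' @return enhanced features, same shape as `fi`
#' @export
enhance_features <- function(fi, fp, pars, cfg) {
  g <- ad_tape()
  fe_forward(g, pars, ad_const(g, fi), ad_const(g, fp), cfg)$value
}
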
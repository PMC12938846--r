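## Sparse dual-attention semantic context module.
##
## Learnable per-vertebra embedding grids attend to the masked features in
## two stages: a coarse attention over max-pooled (stride alpha) features
## scores every pooled cell, the top-k highest-scoring cells are expanded
## to their alpha x alpha blocks of full-resolution positions, and a fine
## attention runs only over those sparse foreground features. The
## context-enriched embeddings feed a linear+logistic head that emits one
## S x S heatmap per vertebra slot and view.
##
## Token layout: a feature array c(h, w, d) flattens column-major to an
## (h*w) x d matrix, so flat token index = y + h * x (0-based y, x).
## Embeddings are stored as an (N*S^2) x d matrix with rows grouped by
## slot, cells column-major within a slot.

#' Coarse attention scores over pooled features
#'
#' `Attn1 = softmax(e WQ1 (fm_pooled WK1)^T / sqrt(dk))` row-wise, where
#' the queries are the flattened embedding tokens and the keys the pooled
#' feature tokens.
#'
#' @param e `(N*S^2) x d` embedding token matrix
#' @param fm_pooled `(h/alpha, w/alpha, d)` max-pooled feature array, or an
#'   already-flattened token matrix
#' @param WQ,WK `d x dk` projection matrices
#' @return `(N*S^2) x (wh/alpha^2)` attention matrix; rows sum to 1
#' @export
coarse_attention <- function(e, fm_pooled, WQ, WK) {
  keys <- if (is.matrix(fm_pooled)) fm_pooled else {
    d <- dim(fm_pooled); matrix(fm_pooled, d[1] * d[2], d[3])
  }
  dk <- ncol(WQ)
  softmax_rows((e %*% WQ) %*% t(keys %*% WK) / sqrt(dk))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Select top-k foreground cells and expand to full resolution
#'
#' Each pooled cell is scored by reducing its attention column over all
#' query rows (`max` by default); cells are sorted by descending score with
#' ties broken by the smaller flat index, the top `k` kept (k is clamped to
#' the pooled size), and each kept cell is expanded to its `alpha x alpha`
#' block of full-resolution flat indices.
#'
#' @param Attn1 attention matrix from [coarse_attention()]
#' @param k number of foreground cells
#' @param alpha pooling stride
#' @param w,h full-resolution feature width and height
#' @param reduce `"max"` (default) or `"mean"` column reduction
#' @return list with `coarse_indices` (1-based pooled flat indices),
#'   `fine_indices` (1-based full-resolution flat indices, tiling the
#'   selected cells exactly, no duplicates), `scores`
#' @export
select_topk <- function(Attn1, k, alpha, w, h, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  if (k < 1) stop("k must be >= 1")
  scores <- if (reduce == "max") apply(Attn1, 2, max) else colMeans(Attn1)
  np <- length(scores)
  hp <- h %/% alpha
  k <- min(k, np)
  ord <- order(-scores, seq_len(np))
  coarse <- ord[seq_len(k)]
  fine <- integer(0)
  for (ci in coarse) {
    yc <- (ci - 1) %% hp
    xc <- (ci - 1) %/% hp
    ys <- yc * alpha + seq_len(alpha) - 1
    xs <- xc * alpha + seq_len(alpha) - 1
    fine <- c(fine, as.vector(outer(ys, xs * h, "+")) + 1L)
  }
  list(coarse_indices = coarse, fine_indices = fine,
       scores = scores[coarse])
}

#' Fine attention over the selected sparse foreground features
#'
#' `Attn2 = softmax(e WQ2 (fs WK2)^T / sqrt(dk))` and the context-enriched
#' embeddings `e_tilde = Attn2 (fs WV2)`.
#'
#' @param e `(N*S^2) x d` embedding token matrix
#' @param fs `m x d` matrix of gathered foreground features
#' @param WQ,WK `d x dk`; `WV` `d x d`
#' @param key_bias optional `m x dk`-compatible additive term for the keys
#'   (used for positional information); NULL to omit
#' @return list with `Attn2` and `e_tilde` (`(N*S^2) x d`)
#' @export
fine_attention <- function(e, fs, WQ, WK, WV, key_bias = NULL) {
  if (nrow(fs) == 0) stop("invalid selection: no foreground features")
  dk <- ncol(WQ)
  keys <- fs
  if (!is.null(key_bias)) keys <- keys + key_bias
  Attn2 <- softmax_rows((e %*% WQ) %*% t(keys %*% WK) / sqrt(dk))
  list(Attn2 = Attn2, e_tilde = Attn2 %*% (fs %*% WV))
}

#' Heatmap head
#'
#' Per-token linear map `d -> 1` followed by the logistic function, then
#' reshaped to one `S x S` heatmap per vertebra slot; values in (0, 1).
#'
#' @param e_tilde `(N*S^2) x d` context-enriched embedding tokens
#' @param W `d x 1` weights, `b` scalar bias
#' @param N,S slot count and heatmap resolution
#' @return array `c(S, S, N)`
#' @export
heatmap_heads <- function(e_tilde, W, b, N, S) {
  z <- e_tilde %*% W + b
  array(1 / (1 + exp(-z)), dim = c(S, S, N))
}

#' Attention-cost accounting: dual-attention vs vanilla
#'
#' Multiply-accumulate counts for `L` attention layers with `M = S^2 * N`
#' query tokens over a `w x h` feature map: the vanilla cost is
#' `L * w * h * M * d`; the dual-attention cost is
#' `(L/2) * ((w*h/alpha^2) * M * d + k * alpha^2 * M * d)` (coarse pass on
#' pooled features plus fine pass on the selected sparse features). With
#' `alpha = 1` and `k = w*h` the two coincide.
#'
#' @param w,h feature-map width and height
#' @param d channel count
#' @param N slot count
#' @param S embedding spatial resolution
#' @param alpha pooling stride
#' @param k selected foreground cells
#' @param L attention layers
#' @return list with `brickformer_ops` and `vanilla_ops`
#' @export
complexity_estimate <- function(w, h, d, N, S, alpha, k, L) {
  M <- S^2 * N
  vanilla <- L * w * h * M * d
  brick <- (L / 2) * ((w * h / alpha^2) * M * d + k * alpha^2 * M * d)
  list(brickformer_ops = brick, vanilla_ops = vanilla)
}

## ---- tape builder -------------------------------------------------------

init_sce <- function(pars, cfg) {
  d <- cfg$d; dk <- cfg$sce_hidden
  ## locality-biased initialization: each slot's embedding grid starts from
  ## the positional code of its own cell plus a slot-specific offset, and
  ## the query/key projections start tied, so query (n, s) initially
  ## attends to image positions near s (the attention analogue of anchor
  ## priors); everything remains fully learnable
  pe <- pe_2d(cfg$S, cfg$S, d)
  slot_off <- matrix(stats::rnorm(cfg$N * d, 0, 0.5), cfg$N, d)
  e <- do.call(rbind, lapply(seq_len(cfg$N), function(n)
    pe + matrix(slot_off[n, ], cfg$S^2, d, byrow = TRUE)))
  pars[["sce.e"]] <- e + matrix(stats::rnorm(length(e), 0, 0.05), nrow(e), d)
  ## all four projections start from one tied matrix: the coarse stage gets
  ## no gradient (hard top-k), so its scores stay meaningful only because
  ## the shared embeddings e keep evolving through the fine stage; starting
  ## coarse == fine makes the frozen selection track what the fine
  ## attention learns to look for
  Wqk <- init_mat(d, dk, sqrt(1 / d))
  pars[["sce.WQ1"]] <- Wqk
  pars[["sce.WK1"]] <- Wqk + init_mat(d, dk, 0.02)
  pars[["sce.WQ2"]] <- Wqk
  pars[["sce.WK2"]] <- Wqk + init_mat(d, dk, 0.02)
  pars[["sce.WV2"]] <- init_mat(d, d, sqrt(1 / d))
  pars <- init_linear(pars, "sce.head", d, 1)
  ## a mildly negative head bias starts background heatmap values low
  pars[["sce.head.b"]] <- -2
  pars
}

## One view's dual-attention pass on the masked features fm (tape node).
## Returns list(heatmap = (S,S,N) node in (0,1), selection).
sce_forward <- function(g, pars, fm, cfg) {
  d <- dim(fm$value)
  h <- d[1]; w <- d[2]
  alpha <- cfg$alpha
  if (h %% alpha != 0 || w %% alpha != 0)
    stop("config error: alpha must divide the feature dimensions")
  e <- ad_param(g, pars, "sce.e")
  WQ1 <- ad_param(g, pars, "sce.WQ1"); WK1 <- ad_param(g, pars, "sce.WK1")
  WQ2 <- ad_param(g, pars, "sce.WQ2"); WK2 <- ad_param(g, pars, "sce.WK2")
  WV2 <- ad_param(g, pars, "sce.WV2")
  dk <- ncol(pars[["sce.WQ1"]])
  ## coarse pass on max-pooled features
  fmp <- if (alpha > 1) ad_maxpool2d(g, fm, alpha) else fm
  hp <- h %/% alpha; wp <- w %/% alpha
  keys1 <- ad_reshape(g, fmp, c(hp * wp, d[3]))
  if (cfg$use_pe) keys1 <- ad_add_const(g, keys1, pe_2d(hp, wp, d[3]))
  Q1 <- ad_matmul(g, e, WQ1)
  K1 <- ad_matmul(g, keys1, WK1)
  Attn1 <- ad_softmax_rows(g, ad_scale(g, ad_matmul(g, Q1, ad_transpose(g, K1)),
                                       1 / sqrt(dk)))
  ## hard top-k selection (non-differentiable; gradients flow through fs)
  sel <- select_topk(Attn1$value, cfg$topk, alpha, w, h,
                     reduce = cfg$topk_reduce)
  fm_tokens <- ad_reshape(g, fm, c(h * w, d[3]))
  fs <- ad_gather_rows(g, fm_tokens, sel$fine_indices)
  keys2 <- if (cfg$use_pe)
    ad_add_const(g, fs, pe_2d(h, w, d[3])[sel$fine_indices, , drop = FALSE])
  else fs
  Q2 <- ad_matmul(g, e, WQ2)
  K2 <- ad_matmul(g, keys2, WK2)
  Attn2 <- ad_softmax_rows(g, ad_scale(g, ad_matmul(g, Q2, ad_transpose(g, K2)),
                                       1 / sqrt(dk)))
  e_tilde <- ad_matmul(g, Attn2, ad_matmul(g, fs, WV2))
  z <- linear_p(g, pars, "sce.head", e_tilde)
  hm <- ad_reshape(g, ad_sigmoid(g, z), c(cfg$S, cfg$S, cfg$N))
  list(heatmap = hm, selection = sel, Attn1 = Attn1, Attn2 = Attn2,
       e_tilde = e_tilde)
}
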
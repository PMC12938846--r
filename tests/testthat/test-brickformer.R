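test_that("coarse_attention rows are probability vectors and match a brute-force oracle", {
  set.seed(30)
  d <- 4; dk <- 6; S <- 2; N <- 3
  e <- matrix(rnorm(N * S^2 * d), N * S^2, d)
  fmp <- array(rnorm(4 * 4 * d), c(4, 4, d))
  WQ <- matrix(rnorm(d * dk), d, dk); WK <- matrix(rnorm(d * dk), d, dk)
  A <- coarse_attention(e, fmp, WQ, WK)
  expect_equal(dim(A), c(N * S^2, 16))
  expect_equal(rowSums(A), rep(1, N * S^2), tolerance = 1e-9)
  ## exhaustive oracle
  keys <- matrix(fmp, 16, d)
  Sc <- (e %*% WQ) %*% t(keys %*% WK) / sqrt(dk)
  ref <- t(apply(Sc, 1, function(r) { p <- exp(r - max(r)); p / sum(p) }))
  expect_equal(A, ref, tolerance = 1e-10)
  ## identical keys at all positions -> uniform rows
  cst <- array(1, c(4, 4, d))
  expect_equal(coarse_attention(e, cst, WQ, WK),
               matrix(1 / 16, N * S^2, 16), tolerance = 1e-12)
})

test_that("select_topk expands coarse cells exactly and matches brute-force sorting", {
  set.seed(31)
  ## k = 2, alpha = 2 on a 4x4 pooled grid -> 8 fine indices, two 2x2 blocks
  A <- matrix(runif(5 * 16), 5, 16)
  sel <- select_topk(A, k = 2, alpha = 2, w = 8, h = 8)
  expect_length(sel$fine_indices, 8)
  expect_equal(anyDuplicated(sel$fine_indices), 0L)
  ## fine indices tile the selected coarse cells exactly
  for (ci in seq_along(sel$coarse_indices)) {
    cc <- sel$coarse_indices[ci]
    yc <- (cc - 1) %% 4; xc <- (cc - 1) %/% 4
    blk <- as.vector(outer(yc * 2 + 0:1, (xc * 2 + 0:1) * 8, "+")) + 1L
    expect_setequal(sel$fine_indices[(ci - 1) * 4 + 1:4], blk)
  }
  ## brute-force score sort with smaller-index tie-break
  scores <- apply(A, 2, max)
  ord <- order(-scores, seq_along(scores))
  expect_equal(sel$coarse_indices, ord[1:2])
  ## k >= pooled size covers every full-resolution index
  sel_all <- select_topk(A, k = 99, alpha = 2, w = 8, h = 8)
  expect_setequal(sel_all$fine_indices, 1:64)
  ## deterministic tie-break on equal scores
  At <- matrix(0.5, 2, 16)
  expect_equal(select_topk(At, 3, 2, 8, 8)$coarse_indices, 1:3)
})

test_that("select_topk matches brute force over many random configurations", {
  set.seed(32)
  for (i in 1:300) {
    hp <- sample(2:6, 1); wp <- sample(2:6, 1); alpha <- sample(1:3, 1)
    h <- hp * alpha; w <- wp * alpha
    k <- sample(1:(hp * wp), 1)
    A <- matrix(runif(3 * hp * wp), 3, hp * wp)
    sel <- select_topk(A, k, alpha, w, h)
    scores <- apply(A, 2, max)
    ord <- order(-scores, seq_along(scores))
    expect_equal(sel$coarse_indices, ord[1:k])
    expect_length(sel$fine_indices, k * alpha^2)
    expect_equal(anyDuplicated(sel$fine_indices), 0L)
    ## every fine index belongs to a selected cell
    ys <- (sel$fine_indices - 1) %% h; xs <- (sel$fine_indices - 1) %/% h
    cells <- (ys %/% alpha) + hp * (xs %/% alpha) + 1
    expect_setequal(unique(cells), sel$coarse_indices)
  }
})

test_that("fine_attention matches its formula and handles the single-feature case", {
  set.seed(33)
  d <- 4; dk <- 5; n_q <- 6
  e <- matrix(rnorm(n_q * d), n_q, d)
  fs <- matrix(rnorm(7 * d), 7, d)
  WQ <- matrix(rnorm(d * dk), d, dk); WK <- matrix(rnorm(d * dk), d, dk)
  WV <- matrix(rnorm(d * d), d, d)
  out <- fine_attention(e, fs, WQ, WK, WV)
  expect_equal(rowSums(out$Attn2), rep(1, n_q), tolerance = 1e-9)
  Sc <- (e %*% WQ) %*% t(fs %*% WK) / sqrt(dk)
  ref <- t(apply(Sc, 1, function(r) { p <- exp(r - max(r)); p / sum(p) }))
  expect_equal(out$Attn2, ref, tolerance = 1e-10)
  expect_equal(out$e_tilde, ref %*% (fs %*% WV), tolerance = 1e-10)
  ## |fs| = 1: every output token equals the single value vector
  one <- fine_attention(e, fs[1, , drop = FALSE], WQ, WK, WV)
  for (i in 1:n_q)
    expect_equal(one$e_tilde[i, ], as.numeric(fs[1, , drop = FALSE] %*% WV),
                 tolerance = 1e-10)
  expect_error(fine_attention(e, fs[0, , drop = FALSE], WQ, WK, WV),
               "invalid selection")
})

test_that("with alpha = 1 and k = full, the dual pass equals vanilla attention", {
  ## the coarse stage degenerates to the identity selection, so fine
  ## attention over the gathered features must reproduce plain attention
  ## over all of fm with (WQ2, WK2, WV2)
  cfg <- tiny_model_config(alpha = 1L, topk = 64L, use_pe = FALSE)
  for (seed in 1:10) {
    set.seed(seed)
    pars <- model_init(cfg, seed = seed)
    fm <- array(rnorm(8 * 8 * cfg$d), c(8, 8, cfg$d))
    g <- ad_tape_t()
    out <- spineloc:::sce_forward(g, pars, ad_const_t(g, fm), cfg)
    expect_setequal(out$selection$fine_indices, 1:64)
    tok <- matrix(fm, 64, cfg$d)
    tok <- tok[out$selection$fine_indices, ]
    van <- fine_attention(pars[["sce.e"]], tok, pars[["sce.WQ2"]],
                          pars[["sce.WK2"]], pars[["sce.WV2"]])
    expect_equal(out$Attn2$value, van$Attn2, tolerance = 1e-5)
    expect_equal(out$e_tilde$value, van$e_tilde, tolerance = 1e-5)
    expect_equal(rowSums(out$Attn1$value), rep(1, nrow(pars[["sce.e"]])),
                 tolerance = 1e-6)
    expect_equal(rowSums(out$Attn2$value), rep(1, nrow(pars[["sce.e"]])),
                 tolerance = 1e-6)
  }
})

test_that("heatmap_heads squashes to (0,1) with the documented edge cases", {
  set.seed(34)
  et <- matrix(rnorm(2 * 16 * 4), 32, 4)
  hm <- heatmap_heads(et, matrix(rnorm(4), 4, 1), 0.2, N = 2, S = 4)
  expect_equal(dim(hm), c(4, 4, 2))
  expect_true(all(hm > 0 & hm < 1))
  ## zero weights, zero bias -> all 0.5
  expect_equal(heatmap_heads(et, matrix(0, 4, 1), 0, 2, 4),
               array(0.5, c(4, 4, 2)))
  ## max > 0.5 iff pre-activation max > 0
  W <- matrix(rnorm(4), 4, 1)
  z <- et %*% W + 0.1
  expect_equal(max(heatmap_heads(et, W, 0.1, 2, 4)) > 0.5, max(z) > 0)
})

test_that("gradients flow to the vertebral embeddings through the dual pass", {
  cfg <- tiny_model_config()
  pars <- model_init(cfg, seed = 5)
  set.seed(35)
  fm <- array(rnorm(32 * 32 * cfg$d), c(32, 32, cfg$d))
  g <- ad_tape_t()
  out <- spineloc:::sce_forward(g, pars, ad_const_t(g, fm), cfg)
  root <- spineloc:::ad_sum_all(g, out$heatmap)
  spineloc:::ad_backward(g, root)
  gr <- spineloc:::ad_grads(g)
  expect_true("sce.e" %in% names(gr))
  expect_gt(sum(abs(gr[["sce.e"]])), 0)
  expect_gt(sum(abs(gr[["sce.WQ2"]])), 0)
  expect_gt(sum(abs(gr[["sce.head.W"]])), 0)
})

test_that("complexity accounting: limits, presets, monotonicity", {
  ## alpha = 1 with full k reproduces the vanilla count exactly
  eq <- complexity_estimate(64, 64, 16, 5, 16, alpha = 1, k = 64 * 64, L = 4)
  expect_equal(eq$brickformer_ops, eq$vanilla_ops)
  ## full-scale synthetic preset: dual attention is far below vanilla
  est <- complexity_estimate(512, 512, 64, 10, 16, alpha = 32, k = 8, L = 4)
  expect_lt(est$brickformer_ops, est$vanilla_ops)
  M <- 16^2 * 10
  expect_equal(est$vanilla_ops, 4 * 512 * 512 * M * 64)
  expect_equal(est$brickformer_ops,
               2 * ((512 * 512 / 32^2) * M * 64 + 8 * 32^2 * M * 64))
  ## monotone increasing in k
  ks <- c(2, 4, 8, 16)
  ops <- vapply(ks, function(k)
    complexity_estimate(512, 512, 64, 10, 16, 32, k, 4)$brickformer_ops,
    numeric(1))
  expect_true(all(diff(ops) > 0))
})
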
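## Shared neural-network building blocks: parameter initialization,
## interpolation/pooling operators as separable matrices, fixed sinusoidal
## positional encodings, and a multi-head cross-attention tape builder.

init_mat <- function(nin, nout, sd = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
}

init_conv2d <- function(pars, name, cin, cout, k = 3) {
  pars[[paste0(name, ".W")]] <- init_mat(cin * k * k, cout)
  pars[[paste0(name, ".b")]] <- numeric(cout)
  pars
}

init_conv3d <- function(pars, name, cin, cout) {
  pars[[paste0(name, ".W")]] <- init_mat(cin * 27, cout)
  pars[[paste0(name, ".b")]] <- numeric(cout)
  pars
}

init_linear <- function(pars, name, nin, nout, sd = sqrt(1 / nin)) {
  pars[[paste0(name, ".W")]] <- init_mat(nin, nout, sd)
  pars[[paste0(name, ".b")]] <- numeric(nout)
  pars
}

conv2d_p <- function(g, pars, name, x, k = 3) {
  ad_conv2d(g, x, ad_param(g, pars, paste0(name, ".W")),
            ad_param(g, pars, paste0(name, ".b")), k = k)
}

conv3d_p <- function(g, pars, name, x, dil = 1L) {
  ad_conv3d(g, x, ad_param(g, pars, paste0(name, ".W")),
            ad_param(g, pars, paste0(name, ".b")), dil = dil)
}

linear_p <- function(g, pars, name, x) {
  ad_add_bias(g, ad_matmul(g, x, ad_param(g, pars, paste0(name, ".W"))),
              ad_param(g, pars, paste0(name, ".b")))
}

## Bilinear interpolation matrix (n_out x n_in), pixel centers aligned:
## output coordinate i maps to input coordinate (i + 0.5) * n_in / n_out - 0.5.
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    lo <- floor(s)
    f <- s - lo
    A[i, lo + 1] <- A[i, lo + 1] + (1 - f)
    if (f > 0) A[i, lo + 2] <- A[i, lo + 2] + f
  }
  A
}

## Adaptive average-pooling matrix (n_out x n_in): row i averages the input
## interval [i * n_in / n_out, (i+1) * n_in / n_out) with fractional overlap.
avg_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * r; b <- i * r
    for (j in (floor(a) + 1):min(n_in, ceiling(b))) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) A[i, j] <- ov / r
    }
  }
  A
}

## Fixed 2D sinusoidal positional encoding for an (h, w) token grid with d
## channels (d divisible by 4); rows follow column-major token flattening
## (flat = y + h * (x - 1)).
pe_2d <- function(h, w, d) {
  stopifnot(d %% 4 == 0)
  q <- d %/% 4
  freq <- 1 / (100^((seq_len(q) - 1) / max(1, q)))
  y <- rep(seq_len(h) - 1, w)
  x <- rep(seq_len(w) - 1, each = h)
  py <- outer(y, freq)
  px <- outer(x, freq)
  cbind(sin(py), cos(py), sin(px), cos(px))
}

## Multi-head cross-attention + feed-forward block.  Queries from `q`
## (n_q x d), keys/values from `kv` (n_kv x d); per-head projections, concat,
## output projection, residual connections.  Positional encodings (plain
## matrices or NULL) are added to queries and keys only.
init_mha_block <- function(pars, name, d, hidden, heads, ffn_hidden = hidden) {
  dh <- hidden %/% heads
  stopifnot(dh * heads == hidden)
  for (h in seq_len(heads)) {
    pars <- init_linear(pars, sprintf("%s.q%d", name, h), d, dh)
    pars <- init_linear(pars, sprintf("%s.k%d", name, h), d, dh)
    pars <- init_linear(pars, sprintf("%s.v%d", name, h), d, dh)
  }
  pars <- init_linear(pars, paste0(name, ".o"), hidden, d)
  pars <- init_linear(pars, paste0(name, ".f1"), d, ffn_hidden)
  pars <- init_linear(pars, paste0(name, ".f2"), ffn_hidden, d)
  pars
}

ad_cbind <- function(g, nodes) {
  ncols <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(ncols)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(g, do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(gr) lapply(seq_along(nodes), function(i)
            gr[, starts[i]:ends[i], drop = FALSE]))
}

ad_add_const <- function(g, a, const) {
  ad_node(g, a$value + const, list(a), function(gr) list(gr))
}

mha_block <- function(g, pars, name, q, kv, heads, hidden,
                      pe_q = NULL, pe_kv = NULL) {
  dh <- hidden %/% heads
  qin <- if (is.null(pe_q)) q else ad_add_const(g, q, pe_q)
  kin <- if (is.null(pe_kv)) kv else ad_add_const(g, kv, pe_kv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    Qh <- linear_p(g, pars, sprintf("%s.q%d", name, h), qin)
    Kh <- linear_p(g, pars, sprintf("%s.k%d", name, h), kin)
    Vh <- linear_p(g, pars, sprintf("%s.v%d", name, h), kv)
    S <- ad_scale(g, ad_matmul(g, Qh, ad_transpose(g, Kh)), 1 / sqrt(dh))
    A <- ad_softmax_rows(g, S)
    outs[[h]] <- ad_matmul(g, A, Vh)
  }
  o <- linear_p(g, pars, paste0(name, ".o"),
                if (heads > 1) ad_cbind(g, outs) else outs[[1]])
  x <- ad_add(g, q, o)
  f <- linear_p(g, pars, paste0(name, ".f2"),
                ad_relu(g, linear_p(g, pars, paste0(name, ".f1"), x)))
  ad_add(g, x, f)
}

ad_transpose <- function(g, a) {
  ad_node(g, t(a$value), list(a), function(gr) list(t(gr)))
}

## Masked-feature op: fm = fe * Mb + Mh, masks broadcast over channels.
ad_mask_features <- function(g, fe, Mb, Mh) {
  v <- fe$value * as.vector(Mb) + as.vector(Mh)
  ad_node(g, v, list(fe), function(gr) list(gr * as.vector(Mb)))
}

## Crop the prompt window out of a (h, w, d) node, zero-padded to 2r x 2r.
ad_prompt_crop <- function(g, fi, prompt, r) {
  d <- dim(fi$value); h <- d[1]; w <- d[2]
  x0 <- trunc(prompt[1]); y0 <- trunc(prompt[2])
  xs <- max(0, x0 - r):min(w - 1, x0 + r - 1)
  ys <- max(0, y0 - r):min(h - 1, y0 + r - 1)
  oy <- ys - (y0 - r) + 1; ox <- xs - (x0 - r) + 1
  v <- array(0, dim = c(2 * r, 2 * r, d[3]))
  v[oy, ox, ] <- fi$value[ys + 1, xs + 1, , drop = FALSE]
  ad_node(g, v, list(fi), function(gr) {
    gx <- array(0, dim = d)
    gx[ys + 1, xs + 1, ] <- gr[oy, ox, , drop = FALSE]
    list(gx)
  })
}

## Slice one channel of a (n1, n2, n3, C) node.
ad_slice_ch3d <- function(g, x, ch) {
  d <- dim(x$value)
  ad_node(g, x$value[, , , ch], list(x), function(gr) {
    gx <- array(0, dim = d)
    gx[, , , ch] <- gr
    list(gx)
  })
}

## Affine map of a node: a * mul + add (scalars).
ad_affine <- function(g, a, mul, add) {
  ad_node(g, a$value * mul + add, list(a), function(gr) list(gr * mul))
}
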
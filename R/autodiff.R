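## Minimal reverse-mode automatic differentiation over R arrays.
##
## The network graphs built here are small (a few hundred coarse-grained
## nodes), so a tape of environments with closure backward rules is cheap;
## all heavy lifting (convolutions, sampling) happens inside vectorized /
## compiled kernels.  Nodes are appended in creation order, which is a valid
## topological order, so the backward sweep simply walks the tape in reverse.

#' Create an empty autodiff tape
#'
#' @return An environment holding the node list and parameter registry.
#' @keywords internal
ad_tape <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g$params <- list()  # name -> list of leaf nodes (a shared weight may appear twice)
  g
}

ad_push <- function(g, node) {
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- node
  node
}

#' Create a tape node
#'
#' @param g tape from [ad_tape()]
#' @param value numeric array
#' @param parents list of parent nodes
#' @param backward function(grad) returning a list of gradients, one per parent
#'   (NULL entries allowed for constant parents)
#' @keywords internal
ad_node <- function(g, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  ad_push(g, node)
}

#' Register a learnable parameter leaf on the tape
#' @keywords internal
ad_param <- function(g, pars, name) {
  node <- ad_node(g, pars[[name]])
  node$param_name <- name
  g$params[[name]] <- c(g$params[[name]], list(node))
  node
}

ad_const <- function(g, value) ad_node(g, value)

ad_accum <- function(node, grad) {
  if (is.null(node$grad)) node$grad <- grad else node$grad <- node$grad + grad
}

#' Reverse sweep: accumulate gradients of `root` (summed if non-scalar)
#' @keywords internal
ad_backward <- function(g, root, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  root$grad <- seed
  for (i in seq(g$n, 1L)) {
    node <- g$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(grads[[j]])) ad_accum(node$parents[[j]], grads[[j]])
    }
  }
  invisible(NULL)
}

#' Collect parameter gradients by name (summing over shared uses)
#' @keywords internal
ad_grads <- function(g) {
  out <- list()
  for (name in names(g$params)) {
    tot <- NULL
    for (node in g$params[[name]]) {
      if (!is.null(node$grad)) tot <- if (is.null(tot)) node$grad else tot + node$grad
    }
    if (!is.null(tot)) out[[name]] <- tot
  }
  out
}

## --------------------------------------------------------------------------
## Elementwise and linear-algebra ops
## --------------------------------------------------------------------------

ad_add <- function(g, a, b) {
  ad_node(g, a$value + b$value, list(a, b), function(gr) list(gr, gr))
}

ad_sub <- function(g, a, b) {
  ad_node(g, a$value - b$value, list(a, b), function(gr) list(gr, -gr))
}

ad_mul <- function(g, a, b) {
  av <- a$value; bv <- b$value
  ad_node(g, av * bv, list(a, b), function(gr) list(gr * bv, gr * av))
}

ad_scale <- function(g, a, s) {
  ad_node(g, a$value * s, list(a), function(gr) list(gr * s))
}

## add a bias row-vector (length ncol) to every row of a matrix
ad_add_bias <- function(g, a, b) {
  ad_node(g, sweep(a$value, 2, b$value, "+"), list(a, b),
          function(gr) list(gr, colSums(gr)))
}

ad_matmul <- function(g, a, b) {
  av <- a$value; bv <- b$value
  ad_node(g, av %*% bv, list(a, b),
          function(gr) list(gr %*% t(bv), crossprod(av, gr)))
}

ad_relu <- function(g, a) {
  mask <- a$value > 0
  ad_node(g, a$value * mask, list(a), function(gr) list(gr * mask))
}

ad_sigmoid <- function(g, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(g, s, list(a), function(gr) list(gr * s * (1 - s)))
}

ad_reshape <- function(g, a, dims) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ad_node(g, v, list(a), function(gr) { dim(gr) <- old; list(gr) })
}

## softmax over rows of a matrix
ad_softmax_rows <- function(g, a) {
  v <- a$value
  m <- apply(v, 1, max)
  e <- exp(v - m)
  p <- e / rowSums(e)
  ad_node(g, p, list(a), function(gr) {
    dot <- rowSums(gr * p)
    list(p * (gr - dot))
  })
}

## concatenate two (h, w, C) arrays along the channel dimension
ad_concat_ch <- function(g, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 3L, all(da[1:2] == db[1:2]))
  ia <- seq_len(da[3]); ib <- da[3] + seq_len(db[3])
  v <- array(0, dim = c(da[1:2], da[3] + db[3]))
  v[, , ia] <- a$value
  v[, , ib] <- b$value
  ad_node(g, v, list(a, b), function(gr) {
    list(gr[, , ia, drop = FALSE], gr[, , ib, drop = FALSE])
  })
}

## gather rows of a matrix (straight-through on the selection indices)
ad_gather_rows <- function(g, a, idx) {
  n <- nrow(a$value)
  dup <- anyDuplicated(idx) > 0
  ad_node(g, a$value[idx, , drop = FALSE], list(a), function(gr) {
    out <- matrix(0, n, ncol(gr))
    if (!dup) out[idx, ] <- gr
    else for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + gr[k, ]
    list(out)
  })
}

## --------------------------------------------------------------------------
## Convolutions (C++ im2col kernels)
## --------------------------------------------------------------------------

## x: (h, w, cin); W: (cin*k*k, cout); b: cout
ad_conv2d <- function(g, x, W, b, k = 3L) {
  d <- dim(x$value); h <- d[1]; w <- d[2]; cin <- d[3]; cout <- ncol(W$value)
  cols <- cpp_im2col2d(x$value, h, w, cin, k)
  y <- sweep(cols %*% W$value, 2, b$value, "+")
  dim(y) <- c(h, w, cout)
  ad_node(g, y, list(x, W, b), function(gr) {
    grm <- gr; dim(grm) <- c(h * w, cout)
    gW <- crossprod(cols, grm)
    gb <- colSums(grm)
    gx <- cpp_col2im2d(grm %*% t(W$value), h, w, cin, k)
    dim(gx) <- c(h, w, cin)
    list(gx, gW, gb)
  })
}

## x: (n1, n2, n3, cin); W: (cin*27, cout); b: cout; dil: tap dilation
ad_conv3d <- function(g, x, W, b, dil = 1L) {
  d <- dim(x$value); dims <- d[1:3]; cin <- d[4]; cout <- ncol(W$value)
  xv <- x$value
  y <- cpp_conv3d_fw(xv, as.integer(dims), cin, W$value, b$value, as.integer(dil))
  dim(y) <- c(dims, cout)
  ad_node(g, y, list(x, W, b), function(gr) {
    bw <- cpp_conv3d_bw(xv, as.integer(dims), cin, W$value, gr, as.integer(dil))
    gx <- bw$gx; dim(gx) <- c(dims, cin)
    list(gx, bw$gW, as.vector(bw$gb))
  })
}

## --------------------------------------------------------------------------
## Pooling / resampling
## --------------------------------------------------------------------------

## separable linear resampling: y[, , c] = A %*% x[, , c] %*% t(B)
ad_resample_sep <- function(g, x, A, B) {
  d <- dim(x$value); C <- d[3]
  y <- array(0, dim = c(nrow(A), nrow(B), C))
  for (c in seq_len(C)) y[, , c] <- A %*% x$value[, , c] %*% t(B)
  ad_node(g, y, list(x), function(gr) {
    gx <- array(0, dim = d)
    for (c in seq_len(C)) gx[, , c] <- crossprod(A, gr[, , c]) %*% B
    list(gx)
  })
}

ad_maxpool2d <- function(g, x, f) {
  d <- dim(x$value); h <- d[1]; w <- d[2]; C <- d[3]
  mp <- cpp_maxpool2d(x$value, h, w, C, as.integer(f))
  y <- mp$y; dim(y) <- c(h %/% f, w %/% f, C)
  idx <- mp$idx
  ad_node(g, y, list(x), function(gr) {
    gx <- numeric(h * w * C)
    gx[idx] <- gr  # pooling windows are disjoint, so idx has no duplicates
    dim(gx) <- c(h, w, C)
    list(gx)
  })
}

## bilinear sampling of a (h, w, C) node at fixed pixel locations uv (n x 2)
ad_sample_bilinear <- function(g, x, uv) {
  d <- dim(x$value); h <- d[1]; w <- d[2]; C <- d[3]
  y <- cpp_bilin_fw(x$value, h, w, C, uv)
  ad_node(g, y, list(x), function(gr) {
    gx <- cpp_bilin_bw(h, w, C, uv, gr)
    dim(gx) <- c(h, w, C)
    list(gx)
  })
}

## --------------------------------------------------------------------------
## Softmax + soft-argmax over voxel grids
## --------------------------------------------------------------------------

## logits: vector node (flattened voxels); centers: n_vox x 3 matrix.
## Returns a node holding c(coords (3), followed by max probability).
ad_softargmax3d <- function(g, logits, centers, temperature = 1) {
  v <- as.vector(logits$value) / temperature
  m <- max(v)
  e <- exp(v - m)
  p <- e / sum(e)
  coords <- as.vector(crossprod(centers, p))
  ad_node(g, coords, list(logits), function(gr) {
    ## d coords_j / d logit_v = p_v (centers_vj - coords_j) / temperature
    w <- (centers %*% gr - sum(coords * gr)) / temperature
    list(as.vector(p * w))
  })
}

## per-voxel softmax probabilities (kept for heatmap output / losses)
ad_softmax_vec <- function(g, logits, temperature = 1) {
  v <- as.vector(logits$value) / temperature
  e <- exp(v - max(v))
  p <- e / sum(e)
  ad_node(g, p, list(logits), function(gr) {
    dot <- sum(gr * p)
    list((p * (gr - dot)) / temperature)
  })
}

## fused per-slot voxel softmax + soft-argmax: logits (n1,n2,n3,N) -> N x 3
## coordinate matrix (mm); the per-slot probability stack is kept for the
## backward pass and for heatmap inspection.
ad_softargmax_slots <- function(g, logits, centers, temperature = 1) {
  d <- dim(logits$value)
  N <- d[4]
  nvox <- prod(d[1:3])
  res <- cpp_softargmax_slots(logits$value, nvox, N, centers, temperature)
  node <- ad_node(g, res$coords, list(logits), function(gr) {
    gx <- cpp_softargmax_slots_bw(res$P, centers, res$coords, gr, temperature)
    dim(gx) <- d
    list(gx)
  })
  node$P <- res$P
  node
}

## mean over all elements -> scalar node
ad_mean_all <- function(g, a) {
  n <- length(a$value)
  ad_node(g, sum(a$value) / n, list(a), function(gr) {
    list(array(as.numeric(gr) / n, dim = dim(a$value)))
  })
}

ad_sum_all <- function(g, a) {
  ad_node(g, sum(a$value), list(a), function(gr) {
    list(array(as.numeric(gr), dim = dim(a$value)))
  })
}
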
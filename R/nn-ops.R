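# Low-level tensor engine for the segmentation networks.
#
# A batch of 2-D feature maps is stored as a plain numeric matrix with
# H*W*N rows (row index h fastest, then w, then sample n) and one column per
# channel.  In this layout a 3x3 convolution is an im2col gather followed by
# one BLAS GEMM, a 1x1 convolution is a GEMM, batch normalisation is
# column-wise arithmetic, and global average pooling is a grouped row sum —
# so the whole network runs on vectorised base R.
#
# Gradients come from a minimal reverse-mode tape: every op appends a node
# holding its value and a closure that maps the node's gradient to its
# parents' gradients.  Nodes are created in execution order, so reverse
# creation order is a valid topological order for backpropagation.

# ---- tape -------------------------------------------------------------

tp_new <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

tp_node <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tp_leaf <- function(tape, val) tp_node(tape, val)

tp_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Backpropagate from `loss` (a scalar node) through every node on the tape.
tp_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) tp_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(tape)
}

# ---- shape / index-map helpers ----------------------------------------

# Index maps for a 3x3 same-padding convolution on an (H, W, N) batch,
# cached per shape.  `pad_idx` places interior rows into the zero-padded
# grid; `maps[[k]]` reads the k-th kernel tap (dh fastest, dw outer).
.nn_cache <- new.env(parent = emptyenv())

conv3_maps <- function(H, W, N) {
  key <- paste0("c3_", H, "_", W, "_", N)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  hh <- rep.int(seq_len(H), W * N)
  ww <- rep.int(rep(seq_len(W), each = H), N)
  nn <- rep(seq_len(N), each = H * W)
  base_n <- Hp * Wp * (nn - 1L)
  pad_idx <- (hh + 1L) + Hp * ww + base_n
  maps <- vector("list", 9L)
  k <- 0L
  for (dw in -1L:1L) {
    for (dh in -1L:1L) {
      k <- k + 1L
      maps[[k]] <- (hh + dh + 1L) + Hp * (ww + dw) + base_n
    }
  }
  # translate padded-grid indices into input rows; padding taps hit the
  # appended all-zero row n_out + 1
  n_out <- H * W * N
  inv <- rep.int(n_out + 1L, Hp * Wp * N)
  inv[pad_idx] <- seq_len(n_out)
  out <- list(allmap = inv[unlist(maps)], n_out = n_out)
  .nn_cache[[key]] <- out
  out
}

pool2_maps <- function(H, W, N) {
  key <- paste0("p2_", H, "_", W, "_", N)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  hh <- rep.int(seq_len(Ho), Wo * N)
  ww <- rep.int(rep(seq_len(Wo), each = Ho), N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  base <- H * W * (nn - 1L)
  at <- function(dh, dw) (2L * hh - 1L + dh) + H * (2L * ww - 2L + dw) + base
  out <- list(idx = list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L)),
              n_out = Ho * Wo * N)
  .nn_cache[[key]] <- out
  out
}

upnearest2_map <- function(H, W, N) {
  key <- paste0("u2_", H, "_", W, "_", N)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- 2L * H; Wo <- 2L * W
  hh <- rep.int(seq_len(Ho), Wo * N)
  ww <- rep.int(rep(seq_len(Wo), each = Ho), N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  map <- ((hh + 1L) %/% 2L) + H * (((ww + 1L) %/% 2L) - 1L) + H * W * (nn - 1L)
  .nn_cache[[key]] <- map
  map
}

# 1-D bilinear interpolation matrix (half-pixel centre convention).
bilinear_mat1d <- function(n_in, n_out) {
  if (n_in == n_out) return(Matrix::Diagonal(n_in))
  src <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  Matrix::sparseMatrix(
    i = c(seq_len(n_out), seq_len(n_out)),
    j = c(i0 + 1, i1 + 1),
    x = c(1 - w1, w1),
    dims = c(n_out, n_in))
}

# Sparse operator lifting an (Hin, Win, N) batch to (Hout, Wout, N) by
# separable bilinear interpolation, in the row layout used throughout.
bilinear_mat <- function(Hin, Win, Hout, Wout, N) {
  key <- paste0("bl_", Hin, "_", Win, "_", Hout, "_", Wout, "_", N)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  U <- Matrix::kronecker(bilinear_mat1d(Win, Wout), bilinear_mat1d(Hin, Hout))
  U <- Matrix::kronecker(Matrix::Diagonal(N), U)
  U <- methods::as(U, "CsparseMatrix")
  .nn_cache[[key]] <- U
  U
}

# ---- primitive ops (tape-aware) ---------------------------------------

# One stacked row-gather builds all nine kernel taps at once; with the
# channel-major column order (column (c-1)*9 + k) the (9*H*W*N) x C
# gather reinterprets as the (H*W*N) x 9C im2col matrix without a copy.
im2col3 <- function(x, mp, C) {
  cols <- rbind(x, 0)[mp$allmap, , drop = FALSE]
  dim(cols) <- c(mp$n_out, 9L * C)
  cols
}

# Rearrange a (9*Cin) x Cout kernel into the spatially flipped
# (9*Cout) x Cin kernel of the gradient convolution.
flip_kernel <- function(w, cin, cout) {
  a <- array(w, c(9L, cin, cout))[9:1, , , drop = FALSE]
  matrix(aperm(a, c(1L, 3L, 2L)), 9L * cout, cin)
}

# 3x3 same convolution.  Weights: (9*Cin) x Cout, rows ordered
# channel-major: row (c-1)*9 + k is input channel c, kernel tap k
# (matching im2col3's column order).  `b = NULL` omits the bias
# (redundant in front of batch norm).  The input gradient is itself a
# 3x3 convolution of the output gradient with the spatially flipped
# kernel, so the backward pass is two GEMMs plus one more im2col gather.
op_conv3 <- function(tape, x, w, b, H, W, N) {
  mp <- conv3_maps(H, W, N)
  cin <- ncol(x$val)
  cols <- im2col3(x$val, mp, cin)
  y <- cols %*% w$val
  if (!is.null(b)) y <- y + rep(b$val, each = nrow(y))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tp_node(tape, y, parents, function(g) {
    cout <- ncol(g)
    dw <- crossprod(cols, g)
    dx <- if (isTRUE(x$stop_grad)) NULL
    else im2col3(g, mp, cout) %*% flip_kernel(w$val, cin, cout)
    out <- list(dx, dw)
    if (!is.null(b)) out[[3]] <- colSums(g)
    out
  })
}

# 1x1 convolution == per-position dense layer.
op_conv1 <- function(tape, x, w, b = NULL) {
  y <- x$val %*% w$val
  if (!is.null(b)) y <- y + rep(b$val, each = nrow(y))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tp_node(tape, y, parents, function(g) {
    out <- list(tcrossprod(g, w$val), crossprod(x$val, g))
    if (!is.null(b)) out[[3]] <- colSums(g)
    out
  })
}

op_relu <- function(tape, x) {
  y <- x$val
  y[y < 0] <- 0
  tp_node(tape, y, list(x), function(g) {
    g[x$val <= 0] <- 0
    list(g)
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$val))
  tp_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(tape, a, b) {
  tp_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

op_concat <- function(tape, a, b) {
  ca <- ncol(a$val)
  tp_node(tape, cbind(a$val, b$val), list(a, b), function(g) {
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE])
  })
}

op_maxpool2 <- function(tape, x, H, W, N) {
  mp <- pool2_maps(H, W, N)
  C <- ncol(x$val)
  n_in <- nrow(x$val)
  cur <- x$val[mp$idx[[1]], , drop = FALSE]
  arg <- matrix(rep(mp$idx[[1]], C), ncol = C)
  for (k in 2:4) {
    xk <- x$val[mp$idx[[k]], , drop = FALSE]
    sel <- xk > cur
    cur[sel] <- xk[sel]
    arg[sel] <- rep(mp$idx[[k]], C)[sel]
  }
  tp_node(tape, cur, list(x), function(g) {
    dx <- matrix(0, n_in, C)
    lin <- as.vector(arg) + rep((seq_len(C) - 1L) * n_in, each = mp$n_out)
    dx[lin] <- as.vector(g)
    list(dx)
  })
}

op_upnearest2 <- function(tape, x, H, W, N) {
  map <- upnearest2_map(H, W, N)
  tp_node(tape, x$val[map, , drop = FALSE], list(x), function(g) {
    list(unname(rowsum(g, map)))
  })
}

op_upbilinear <- function(tape, x, Hin, Win, Hout, Wout, N) {
  U <- bilinear_mat(Hin, Win, Hout, Wout, N)
  y <- as.matrix(U %*% x$val)
  tp_node(tape, y, list(x), function(g) list(as.matrix(Matrix::crossprod(U, g))))
}

# Batch normalisation over all rows (batch x spatial), one statistic per
# channel.  `state` is an environment carrying running moments for
# inference; updated as a side effect in training mode.
op_bn <- function(tape, x, gamma, beta, state, training, momentum = 0.1,
                  eps = 1e-5) {
  m <- nrow(x$val)
  if (training) {
    mu <- colMeans(x$val)
    xc <- x$val - rep(mu, each = m)
    v <- colMeans(xc * xc)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
    xc <- x$val - rep(mu, each = m)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = m)
  y <- xhat * rep(gamma$val, each = m) + rep(beta$val, each = m)
  tp_node(tape, y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * rep(gamma$val, each = m)
    if (training) {
      dx <- (dxhat - rep(colMeans(dxhat), each = m) -
               xhat * rep(colMeans(dxhat * xhat), each = m)) *
        rep(inv_sd, each = m)
    } else {
      dx <- dxhat * rep(inv_sd, each = m)
    }
    list(dx, dgamma, dbeta)
  })
}

# Row-wise scaling by a single-column coefficient map (attention kappa).
op_scale_rows <- function(tape, x, k) {
  kv <- as.vector(k$val)
  tp_node(tape, x$val * kv, list(x, k), function(g) {
    list(g * kv, matrix(rowSums(g * x$val), ncol = 1))
  })
}

# Per-(sample, channel) scaling (squeeze-and-excitation re-weighting).
# `s` is N x C; `nidx` maps each row of x to its sample.
op_scale_channels <- function(tape, x, s, nidx) {
  sx <- s$val[nidx, , drop = FALSE]
  tp_node(tape, x$val * sx, list(x, s), function(g) {
    list(g * sx, unname(rowsum(g * x$val, nidx)))
  })
}

# Global average pool: (H*W*N) x C -> N x C.
op_squeeze <- function(tape, x, nidx, hw) {
  b <- unname(rowsum(x$val, nidx)) / hw
  tp_node(tape, b, list(x), function(g) {
    list(g[nidx, , drop = FALSE] / hw)
  })
}

# Dense layer on an N x C matrix (the excitation MLP).
op_dense <- function(tape, x, w, b) {
  y <- x$val %*% w$val + rep(b$val, each = nrow(x$val))
  tp_node(tape, y, list(x, w, b), function(g) {
    list(tcrossprod(g, w$val), crossprod(x$val, g), colSums(g))
  })
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

op_softmax <- function(tape, x) {
  p <- softmax_rows(x$val)
  tp_node(tape, p, list(x), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

# Fused softmax + cross-entropy from logits; `target` is an integer vector
# of 1-based class labels per row.  Mean over rows (voxels in the batch).
op_softmax_ce <- function(tape, logits, target) {
  p <- softmax_rows(logits$val)
  m <- nrow(p)
  idx <- cbind(seq_len(m), target)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  nd <- tp_node(tape, loss, list(logits), function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    list(g * d / m)
  })
  nd$probs <- p
  nd
}
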
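# Minimal reverse-mode autograd on a tape, sized for the phantom-scale
# reconstruction network. Tensors are plain R arrays: 2D features (H, W, C),
# 3D features (A, B, D, C) with the channel dimension last. Convolutions go
# through C++ im2col/col2im and BLAS GEMM; everything else is vectorized R.


# set dims without copying (inputs are freshly allocated)
set_dim <- function(x, d) { dim(x) <- d; x }

# in-place column-wise bias add on a freshly allocated matrix
add_bias <- function(m, b) {
  for (j in seq_along(b)) m[, j] <- m[, j] + b[j]
  m
}
tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

nd <- function(tape, value, parents = list(), backward = NULL, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$name <- name
  tape$n <- tape$n + 1L
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep: seed the output node and propagate in reverse creation
# order (creation order is a topological order of the DAG).
tape_backward <- function(tape, out_node, seed) {
  out_node$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node)
    for (j in seq_along(node$parents)) {
      if (!is.null(grads[[j]])) accumulate_grad(node$parents[[j]], grads[[j]])
    }
  }
  invisible(NULL)
}

# --- 2D convolution, kernel k x k, same padding, stride 1 ----------------

op_conv2d <- function(tape, x, w, b, k = 3L) {
  d <- dim(x$value)
  cin <- d[3]; cout <- dim(w$value)[4]
  cols <- .im2col2d(x$value, d[1], d[2], cin, k)
  wm <- matrix(w$value, k * k * cin, cout)
  ym <- add_bias(cols %*% wm, b$value)
  node <- nd(tape, set_dim(ym, c(d[1], d[2], cout)), list(x, w, b), function(node) {
    gm <- matrix(node$grad, d[1] * d[2], cout)
    gx <- .col2im2d(gm %*% t(wm), d[1], d[2], cin, k)
    gw <- crossprod(cols, gm)
    list(set_dim(gx, d), set_dim(gw, dim(w$value)), colSums(gm))
  })
  node
}

# --- 2D transposed convolution, kernel 2, stride 2 -----------------------

op_convT2d <- function(tape, x, w, b) {
  d <- dim(x$value)
  cin <- d[3]; cout <- dim(w$value)[4]
  H <- d[1]; W <- d[2]
  xm <- matrix(x$value, H * W, cin)
  out <- array(0, c(2 * H, 2 * W, cout))
  for (dh in 1:2) for (dw in 1:2) {
    sub <- xm %*% matrix(w$value[dh, dw, , ], cin, cout)
    out[seq(dh, 2 * H, 2), seq(dw, 2 * W, 2), ] <- array(sub, c(H, W, cout))
  }
  out <- set_dim(add_bias(set_dim(out, c(4 * H * W, cout)), b$value),
                 c(2 * H, 2 * W, cout))
  nd(tape, out, list(x, w, b), function(node) {
    gxm <- matrix(0, H * W, cin)
    gw <- array(0, dim(w$value))
    for (dh in 1:2) for (dw in 1:2) {
      gsub <- matrix(node$grad[seq(dh, 2 * H, 2), seq(dw, 2 * W, 2), ], H * W, cout)
      gw[dh, dw, , ] <- crossprod(xm, gsub)
      gxm <- gxm + gsub %*% t(matrix(w$value[dh, dw, , ], cin, cout))
    }
    gb <- colSums(matrix(node$grad, ncol = cout))
    list(array(gxm, d), gw, gb)
  })
}

# --- 3D convolution, cubic kernel k (1 or 3), same padding, stride 1 -----

op_conv3d <- function(tape, x, w, b, k = 3L) {
  d <- dim(x$value)
  cin <- d[4]; cout <- dim(w$value)[5]
  nsp <- prod(d[1:3])
  if (k == 1L) {
    xm <- matrix(x$value, nsp, cin)
    wm <- matrix(w$value, cin, cout)
    ym <- add_bias(xm %*% wm, b$value)
    return(nd(tape, set_dim(ym, c(d[1:3], cout)), list(x, w, b), function(node) {
      gm <- matrix(node$grad, nsp, cout)
      list(set_dim(gm %*% t(wm), d), set_dim(crossprod(xm, gm), dim(w$value)),
           colSums(gm))
    }))
  }
  cols <- .im2col3d(x$value, d[1], d[2], d[3], cin, k)
  wm <- matrix(w$value, k^3 * cin, cout)
  ym <- add_bias(cols %*% wm, b$value)
  nd(tape, set_dim(ym, c(d[1:3], cout)), list(x, w, b), function(node) {
    gm <- matrix(node$grad, nsp, cout)
    gx <- .col2im3d(gm %*% t(wm), d[1], d[2], d[3], cin, k)
    gw <- crossprod(cols, gm)
    list(set_dim(gx, d), set_dim(gw, dim(w$value)), colSums(gm))
  })
}

# --- 3D transposed convolution, kernel 2, stride 2 -----------------------

op_convT3d <- function(tape, x, w, b) {
  d <- dim(x$value)
  cin <- d[4]; cout <- dim(w$value)[5]
  A <- d[1]; B <- d[2]; D <- d[3]
  xm <- matrix(x$value, A * B * D, cin)
  out <- array(0, c(2 * A, 2 * B, 2 * D, cout))
  for (da in 1:2) for (db in 1:2) for (dd in 1:2) {
    sub <- xm %*% matrix(w$value[da, db, dd, , ], cin, cout)
    out[seq(da, 2 * A, 2), seq(db, 2 * B, 2), seq(dd, 2 * D, 2), ] <-
      array(sub, c(A, B, D, cout))
  }
  out <- set_dim(add_bias(set_dim(out, c(8 * A * B * D, cout)), b$value),
                 c(2 * A, 2 * B, 2 * D, cout))
  nd(tape, out, list(x, w, b), function(node) {
    gxm <- matrix(0, A * B * D, cin)
    gw <- array(0, dim(w$value))
    for (da in 1:2) for (db in 1:2) for (dd in 1:2) {
      gsub <- matrix(node$grad[seq(da, 2 * A, 2), seq(db, 2 * B, 2),
                               seq(dd, 2 * D, 2), ], A * B * D, cout)
      gw[da, db, dd, , ] <- crossprod(xm, gsub)
      gxm <- gxm + gsub %*% t(matrix(w$value[da, db, dd, , ], cin, cout))
    }
    list(array(gxm, d), gw, colSums(matrix(node$grad, ncol = cout)))
  })
}

# --- 2x2 max pooling, stride 2 (2D) --------------------------------------

op_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  parts <- list(x$value[seq(1, H, 2), seq(1, W, 2), , drop = FALSE],
                x$value[seq(2, H, 2), seq(1, W, 2), , drop = FALSE],
                x$value[seq(1, H, 2), seq(2, W, 2), , drop = FALSE],
                x$value[seq(2, H, 2), seq(2, W, 2), , drop = FALSE])
  y <- parts[[1]]
  which <- array(1L, dim(y))
  for (i in 2:4) {
    upd <- parts[[i]] > y
    y[upd] <- parts[[i]][upd]
    which[upd] <- i
  }
  nd(tape, y, list(x), function(node) {
    gx <- array(0, d)
    sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
    for (i in 1:4) {
      g <- node$grad
      g[which != i] <- 0
      gx[seq(sel[[i]][1], H, 2), seq(sel[[i]][2], W, 2), ] <- g
    }
    list(gx)
  })
}

# --- instance normalization (per channel over spatial dims) --------------

op_instnorm <- function(tape, x, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[length(d)]
  nsp <- prod(d[-length(d)])
  xm <- matrix(x$value, nsp, C)
  mu <- colMeans(xm)
  ym <- xm
  inv <- numeric(C)
  for (j in seq_len(C)) {
    xc <- xm[, j] - mu[j]
    inv[j] <- 1 / sqrt(mean(xc^2) + eps)
    ym[, j] <- xc * inv[j]
  }
  nd(tape, set_dim(ym, d), list(x), function(node) {
    gm <- matrix(node$grad, nsp, C)
    gx <- gm
    for (j in seq_len(C)) {
      g <- gm[, j]
      gx[, j] <- (g - mean(g) - ym[, j] * mean(g * ym[, j])) * inv[j]
    }
    list(set_dim(gx, d))
  })
}

# --- ReLU ----------------------------------------------------------------

op_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  nd(tape, y, list(x), function(node) {
    g <- node$grad
    g[x$value <= 0] <- 0
    list(g)
  })
}

# --- channel-wise concatenation (last dimension) -------------------------

op_concat <- function(tape, nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  base <- dims[[1]]
  chans <- vapply(dims, function(d) d[length(d)], numeric(1))
  # last-dimension concatenation of column-major arrays is vector c()
  out <- array(unlist(lapply(nodes, function(n) as.vector(n$value))),
               c(base[-length(base)], sum(chans)))
  sizes <- vapply(dims, prod, numeric(1))
  offsets <- cumsum(c(0, sizes))
  nd(tape, out, nodes, function(node) {
    g <- as.vector(node$grad)
    lapply(seq_along(nodes), function(i) {
      array(g[(offsets[i] + 1):offsets[i + 1]], dims[[i]])
    })
  })
}

# --- channel-to-depth reshape: (s, s, c3d * s) -> (s, s, s, c3d) ---------
# Channel index c = (q - 1) * c3d + m maps to depth q (axis 2 of the 3D
# block) and 3D channel m; the inverse reshape is its exact adjoint.

op_reshape_c2d <- function(tape, x, c3d) {
  d <- dim(x$value)
  s <- d[1]
  stopifnot(d[2] == s, d[3] == c3d * s)
  v <- x$value
  dim(v) <- c(s, s, c3d, s)      # (u, z, m, q)
  y <- aperm(v, c(1, 4, 2, 3))   # (u, q, z, m)
  nd(tape, y, list(x), function(node) {
    g <- aperm(node$grad, c(1, 3, 4, 2))  # back to (u, z, m, q)
    dim(g) <- d
    list(g)
  })
}

flatten_c2d <- function(D) {
  # inverse of the value mapping in op_reshape_c2d (used by tests)
  s <- dim(D)[1]; c3d <- dim(D)[4]
  g <- aperm(D, c(1, 3, 4, 2))
  dim(g) <- c(s, s, c3d * s)
  g
}

# --- 90-degree permutation about the vertical axis -----------------------
# y[p, q, z, c] = x[q, n + 1 - p, z, c]; applying it four times is the
# identity (rotation group of order 4).

rot90_z <- function(v) {
  n <- dim(v)[1]
  y <- aperm(v, c(2, 1, 3, 4))
  y[n:1, , , , drop = FALSE]
}

rot90_z_inv <- function(v) {
  n <- dim(v)[1]
  aperm(v[n:1, , , , drop = FALSE], c(2, 1, 3, 4))
}

op_permute_z <- function(tape, x) {
  d <- dim(x$value)
  if (d[1] != d[2]) stop("permutation requires cubical features", call. = FALSE)
  nd(tape, rot90_z(x$value), list(x), function(node) {
    list(rot90_z_inv(node$grad))
  })
}
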
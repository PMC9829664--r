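# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (flood fill, literal set
# arithmetic, all-pairs distances) without touching the package's
# implementation paths.

# Flood-fill component count over an explicit neighbour offset table.
oracle_component_count <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  seen <- array(FALSE, d)
  count <- 0
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    start <- idx[r, ]
    if (seen[start[1], start[2], start[3]]) next
    count <- count + 1
    stack <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  count
}

# Literal dilation: shift the voxel coordinate list by every offset with
# Euclidean norm <= r and clip at the boundary.
oracle_dilate <- function(mask, r) {
  d <- dim(mask)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  out <- array(FALSE, d)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(out)
  for (o in seq_len(nrow(g))) {
    q <- sweep(pts, 2, g[o, ], `+`)
    keep <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    out[q[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# Literal evaluation of the auxiliary-class definition: union over
# unordered fragment pairs of intersected dilations, minus the bone union.
oracle_auxiliary <- function(frag_arrays, r) {
  d <- dim(frag_arrays[[1]])
  n <- length(frag_arrays)
  dil <- lapply(frag_arrays, oracle_dilate, r = r)
  acc <- array(FALSE, d)
  if (n >= 2) {
    for (k in 1:(n - 1)) for (l in (k + 1):n) {
      acc <- acc | (dil[[k]] & dil[[l]])
    }
  }
  bone <- Reduce(`|`, frag_arrays)
  acc & !bone
}

# All-pairs brute-force ASSD on surface coordinate matrices.
oracle_assd <- function(sa, sb) {
  dmat <- function(a, b) {
    out <- matrix(0, nrow(a), nrow(b))
    for (i in seq_len(nrow(a))) {
      out[i, ] <- sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2 +
                         (a[i, 3] - b[, 3])^2)
    }
    out
  }
  d <- dmat(sa, sb)
  (sum(apply(d, 1, min)) + sum(apply(d, 2, min))) / (nrow(sa) + nrow(sb))
}

# Surface voxels by definition: in the mask with a face neighbour outside
# (grid boundary outside).
oracle_surface <- function(mask, spacing = 1) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  keep <- logical(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    for (ax in 1:3) for (s in c(-1, 1)) {
      q <- p; q[ax] <- q[ax] + s
      if (any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]) keep[r] <- TRUE
    }
  }
  pts[keep, , drop = FALSE] * spacing
}

# Random multi-fragment mask on a small grid: seed a few blobs, grow them a
# little, and relabel what survives into disjoint fragments.
random_fragment_arrays <- function(dim3, n_blobs = 3, grow = 1, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim3)
  for (b in seq_len(n_blobs)) {
    c0 <- sapply(dim3, function(n) sample.int(n, 1))
    rad <- sample(1:2, 1)
    lo <- pmax(c0 - rad, 1); hi <- pmin(c0 + rad, dim3)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  fs <- bonerecon::connected_components(bonerecon::binary_mask(m), 26)
  lapply(fs$fragments, function(f) f$data)
}

# Small solid cube mask helper.
cube_mask <- function(dim3, lo, hi) {
  m <- array(FALSE, dim3)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}
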
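# Thin-channel configuration: shape checks do not depend on channel widths.
thin_cfg <- function(levels, extent, classes = 3) {
  network_config(levels = levels, extent = extent, growth = 2, stem = 2,
                 c3d = 1, c_up = 2, c_fuse = 2, c_up3d = 2, n_fuse = 1,
                 classes = classes, seed = 1)
}

test_that("every intermediate matches the closed-form shape arithmetic", {
  for (L in c(3, 4, 5)) {
    for (E in c(16, 32)) {
      cfg <- thin_cfg(L, E)
      net <- net_init(cfg)
      x <- matrix(runif(E * E), E)
      fw <- bonerecon:::net_forward_tape(net, x, x, intermediates = TRUE)
      s <- E / 2^(0:(L - 1))
      for (v in 1:2) {
        sh <- fw$shapes[[sprintf("view%d", v)]]
        for (i in seq_len(L)) {
          # encoder: extent halves per level, channels grow by n_dense*growth
          expect_equal(sh$e[[i]][1:2], c(s[i], s[i]))
          expect_equal(sh$e[[i]][3], cfg$stem + i * cfg$n_dense * cfg$growth)
          # decoder 3D blocks are cubical with c3d channels
          expect_equal(sh$D[[i]], c(s[i], s[i], s[i], cfg$c3d))
        }
      }
      for (i in seq_len(L)) {
        expect_equal(fw$shapes$fusion[[i]], c(s[i], s[i], s[i], cfg$c_fuse))
      }
      expect_equal(dim(fw$logits$value), c(E, E, E, cfg$classes))
    }
  }
  # the largest extent once, at the shallowest depth
  cfg <- thin_cfg(3, 64)
  fw <- bonerecon:::net_forward_tape(net_init(cfg), matrix(0, 64, 64),
                                     matrix(0, 64, 64), intermediates = TRUE)
  expect_equal(dim(fw$logits$value), c(64, 64, 64, 3))
  expect_equal(fw$shapes$view1$D[[3]], c(16, 16, 16, 1))
})

test_that("network_config enforces the extent/level contract", {
  expect_error(network_config(levels = 5, extent = 24), "multiple")
  expect_error(network_config(levels = 4, extent = 4), "multiple")
  expect_error(network_config(classes = 4), "classes")
  # dense block output channels = input + n_dense * growth (concatenation)
  cfg <- thin_cfg(3, 16)
  plan <- bonerecon:::net_plan(cfg)
  expect_equal(plan$enc_out[1], cfg$stem + cfg$n_dense * cfg$growth)
})

test_that("channel-to-depth reshape is a bijection", {
  s <- 8; c3d <- 3
  tape <- bonerecon:::tape_new()
  x <- bonerecon:::nd(tape, array(rnorm(s * s * c3d * s), c(s, s, c3d * s)))
  y <- bonerecon:::op_reshape_c2d(tape, x, c3d)
  expect_equal(dim(y$value), c(s, s, s, c3d))
  expect_equal(bonerecon:::flatten_c2d(y$value), x$value)
})

test_that("the vertical-axis permutation is a 4-cycle with the stated mapping", {
  n <- 6
  x <- array(rnorm(n * n * 4 * 2), c(n, n, 4, 2))
  r1 <- bonerecon:::rot90_z(x)
  expect_identical(bonerecon:::rot90_z(bonerecon:::rot90_z(bonerecon:::rot90_z(r1))), x)
  # single-voxel tracer: (i, j, k, c) moves to (n+1-j, i, k, c)
  tr <- array(0, c(n, n, 4, 2)); tr[2, 5, 3, 1] <- 1
  out <- bonerecon:::rot90_z(tr)
  expect_equal(which(out != 0, arr.ind = TRUE)[1, ], c(n + 1 - 5, 2, 3, 1),
               ignore_attr = TRUE)
  # a block symmetric under 90-degree rotation about z is fixed by P
  cs <- seq_len(n) - (n + 1) / 2
  rad <- sqrt(outer(cs^2, cs^2, `+`))
  sym <- array(rep(rad, 4 * 2), c(n, n, 4, 2))
  expect_equal(bonerecon:::rot90_z(sym), sym)
  # inverse undoes the rotation
  expect_identical(bonerecon:::rot90_z_inv(r1), x)
})

test_that("forward output is a probability volume and is view-order aware", {
  cfg <- thin_cfg(3, 16)
  net <- net_init(cfg)
  set.seed(2)
  x1 <- matrix(runif(256), 16); x2 <- matrix(runif(256), 16)
  t0 <- Sys.time()
  probs <- net_forward(net, x1, x2)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  sums <- apply(probs, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(probs >= 0))
  inf <- net_infer(net, x1, x2)
  expect_true(all(inf$labels$data %in% 0:2))
  expect_equal(dim(inf$labels$data), c(16, 16, 16))
  # deterministic given fixed weights
  expect_identical(probs, net_forward(net, x1, x2))
  # swapping the two views changes the output (fusion is view-order aware)
  swapped <- net_forward(net, x2, x1)
  expect_gt(max(abs(swapped - probs)), 1e-8)
  expect_error(net_forward(net, matrix(0, 8, 8), x2), "extent")
})

test_that("all parameters receive nonzero gradients on a random batch", {
  cfg <- thin_cfg(3, 16)
  net <- net_init(cfg)
  set.seed(5)
  x1 <- matrix(runif(256), 16); x2 <- matrix(runif(256), 16)
  target <- array(sample(0:2, 16^3, TRUE), c(16, 16, 16))
  fw <- bonerecon:::net_forward_tape(net, x1, x2)
  probs <- softmax_classes(fw$logits$value)
  gl <- focal_loss_grad_logits(probs, target, focal_loss_params())
  bonerecon:::tape_backward(fw$tape, fw$logits, gl)
  for (nm in names(net$params)) {
    node <- get(nm, envir = fw$pnodes, inherits = FALSE)
    expect_false(is.null(node$grad), info = nm)
    expect_gt(max(abs(node$grad)), 0)
  }
})

test_that("layer backward passes agree with finite differences", {
  fd_check <- function(build, x0, tol = 1e-5) {
    # scalar objective: weighted sum of the op output
    tape <- bonerecon:::tape_new()
    x <- bonerecon:::nd(tape, x0)
    y <- build(tape, x)
    set.seed(1)
    wsum <- array(rnorm(length(y$value)), dim(y$value))
    bonerecon:::tape_backward(tape, y, wsum)
    g <- x$grad
    eps <- 1e-6
    for (i in sample(length(x0), 8)) {
      xp <- x0; xp[i] <- xp[i] + eps
      xm <- x0; xm[i] <- xm[i] - eps
      tp <- bonerecon:::tape_new()
      fp <- sum(build(tp, bonerecon:::nd(tp, xp))$value * wsum)
      tm <- bonerecon:::tape_new()
      fm <- sum(build(tm, bonerecon:::nd(tm, xm))$value * wsum)
      expect_lt(abs((fp - fm) / (2 * eps) - g[i]), tol)
    }
  }
  set.seed(4)
  w2 <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3))
  b2 <- rnorm(3)
  fd_check(function(tp, x) {
    bonerecon:::op_conv2d(tp, x, bonerecon:::nd(tp, w2), bonerecon:::nd(tp, b2))
  }, array(rnorm(6 * 6 * 2), c(6, 6, 2)))

  w3 <- array(rnorm(27 * 2 * 2, sd = 0.5), c(3, 3, 3, 2, 2))
  b3 <- rnorm(2)
  fd_check(function(tp, x) {
    bonerecon:::op_conv3d(tp, x, bonerecon:::nd(tp, w3), bonerecon:::nd(tp, b3))
  }, array(rnorm(4^3 * 2), c(4, 4, 4, 2)))

  wt <- array(rnorm(4 * 2 * 3, sd = 0.5), c(2, 2, 2, 3))
  bt <- rnorm(3)
  fd_check(function(tp, x) {
    bonerecon:::op_convT2d(tp, x, bonerecon:::nd(tp, wt), bonerecon:::nd(tp, bt))
  }, array(rnorm(4 * 4 * 2), c(4, 4, 2)))

  fd_check(function(tp, x) bonerecon:::op_instnorm(tp, x),
           array(rnorm(5 * 5 * 3), c(5, 5, 3)), tol = 1e-4)

  fd_check(function(tp, x) bonerecon:::op_maxpool2(tp, x),
           array(rnorm(6 * 6 * 2), c(6, 6, 2)))
})
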
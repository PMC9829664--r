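#' Reconstruction network configuration
#'
#' The network maps a Judet radiograph pair to a voxel-wise class-score
#' volume through three stages: a per-view 2D encoder of dense blocks with
#' max-pool downsampling across `levels` abstract levels, a per-view
#' decoder whose 2D features are reshaped channel-to-depth into cubical 3D
#' blocks, and a multi-scale 3D fusion that concatenates view 1 with the
#' permuted view 2 (and, below the deepest level, the upsampled previous
#' fusion), ending in a 1x1x1 classification convolution and softmax.
#'
#' @param levels number of abstract levels L (default 7; use 3-4 for
#'   desk-scale runs).
#' @param extent input image extent in pixels; must be a power-of-two
#'   multiple of `2^(levels - 1)`.
#' @param n_dense layers per dense block (default 4).
#' @param growth dense-block growth rate (channels added per layer).
#' @param stem channels of the initial 2D convolution.
#' @param c3d channels of each 3D decoded block (2D channels at level i are
#'   forced to `extent / 2^i * c3d` so the reshape is cubical).
#' @param c_up channels of 2D decoder upsampling.
#' @param c_fuse channels of each fusion convolution.
#' @param c_up3d channels of 3D fusion upsampling.
#' @param n_fuse fusion convolutions per level (default 2).
#' @param classes output classes: 2 (background/bone) or 3 (+ auxiliary).
#' @param seed weight-initialization seed.
#' @return a `network_config` list.
#' @export
network_config <- function(levels = 7, extent = 64, n_dense = 4, growth = 4,
                           stem = 8, c3d = 2, c_up = 8, c_fuse = 8,
                           c_up3d = 8, n_fuse = 2, classes = 3, seed = 42L) {
  if (levels < 2) stop("need at least 2 levels", call. = FALSE)
  if (!classes %in% c(2, 3)) stop("classes must be 2 or 3", call. = FALSE)
  if (extent < 2^(levels - 1) || extent %% 2^(levels - 1) != 0)
    stop("extent must be a multiple of 2^(levels-1)", call. = FALSE)
  structure(list(levels = as.integer(levels), extent = as.integer(extent),
                 n_dense = as.integer(n_dense), growth = as.integer(growth),
                 stem = as.integer(stem), c3d = as.integer(c3d),
                 c_up = as.integer(c_up), c_fuse = as.integer(c_fuse),
                 c_up3d = as.integer(c_up3d), n_fuse = as.integer(n_fuse),
                 classes = as.integer(classes), seed = as.integer(seed)),
            class = "network_config")
}

# Channel bookkeeping shared by initialization and the shape oracle tests.
net_plan <- function(cfg) {
  L <- cfg$levels
  s <- cfg$extent / 2^(0:(L - 1))            # spatial extent per level
  enc_out <- numeric(L)
  cin <- cfg$stem
  for (i in seq_len(L)) {
    enc_out[i] <- cin + cfg$n_dense * cfg$growth
    cin <- enc_out[i]
  }
  dec_out <- s * cfg$c3d
  dec_in <- numeric(L)
  dec_in[L] <- enc_out[L]
  if (L > 1) dec_in[seq_len(L - 1)] <- cfg$c_up + enc_out[seq_len(L - 1)]
  fus_in <- numeric(L)
  fus_in[L] <- 2 * cfg$c3d
  if (L > 1) fus_in[seq_len(L - 1)] <- 2 * cfg$c3d + cfg$c_up3d
  list(s = s, enc_out = enc_out, dec_in = dec_in, dec_out = dec_out,
       fus_in = fus_in)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Initialize a reconstruction network
#'
#' Allocates all weights (fan-in-scaled normal initialization, biases zero)
#' for the two per-view encoder/decoder streams and the shared fusion
#' stack, deterministically from the configuration seed.
#'
#' @param cfg a [network_config].
#' @return a `recon_net` environment holding `cfg` and named parameter
#'   arrays.
#' @export
net_init <- function(cfg) {
  plan <- net_plan(cfg)
  L <- cfg$levels
  params <- list()
  add_conv2d <- function(name, cin, cout, k = 3) {
    params[[paste0(name, ".w")]] <<- he_init(c(k, k, cin, cout), k * k * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_conv3d <- function(name, cin, cout, k = 3) {
    params[[paste0(name, ".w")]] <<- he_init(c(k, k, k, cin, cout), k^3 * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_convT2d <- function(name, cin, cout) {
    params[[paste0(name, ".w")]] <<- he_init(c(2, 2, cin, cout), 4 * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_convT3d <- function(name, cin, cout) {
    params[[paste0(name, ".w")]] <<- he_init(c(2, 2, 2, cin, cout), 8 * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  with_seed(cfg$seed, {
    for (v in 1:2) {
      pv <- sprintf("enc%d", v)
      add_conv2d(paste0(pv, ".stem"), 1, cfg$stem)
      cin <- cfg$stem
      for (i in seq_len(L)) {
        for (j in seq_len(cfg$n_dense)) {
          add_conv2d(sprintf("%s.l%d.d%d", pv, i, j),
                     cin + (j - 1) * cfg$growth, cfg$growth)
        }
        cin <- cin + cfg$n_dense * cfg$growth
      }
      dv <- sprintf("dec%d", v)
      for (i in seq_len(L)) {
        add_conv2d(sprintf("%s.l%d", dv, i), plan$dec_in[i], plan$dec_out[i])
        if (i < L) {
          add_convT2d(sprintf("%s.up%d", dv, i), plan$dec_out[i + 1], cfg$c_up)
        }
      }
    }
    for (i in seq_len(L)) {
      cin <- plan$fus_in[i]
      for (t in seq_len(cfg$n_fuse)) {
        add_conv3d(sprintf("fus.l%d.c%d", i, t), cin, cfg$c_fuse)
        cin <- cfg$c_fuse
      }
      if (i < L) add_convT3d(sprintf("fus.up%d", i), cfg$c_fuse, cfg$c_up3d)
    }
    add_conv3d("fus.out", cfg$c_fuse, cfg$classes, k = 1)
  })
  # Prior-probability initialization of the classification bias (standard
  # practice for focal-loss training of rare classes): the softmax starts
  # at plausible class priors instead of uniform, so early optimization is
  # not spent suppressing the rare classes everywhere.
  priors <- c(0.94, 0.05, 0.01)[seq_len(cfg$classes)]
  params[["fus.out.b"]] <- log(priors / sum(priors))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$params <- params
  class(net) <- "recon_net"
  net
}

#' @export
print.recon_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("recon_net: L=%d extent=%d classes=%d, %d parameter arrays (%d scalars)\n",
              x$cfg$levels, x$cfg$extent, x$cfg$classes, length(x$params), np))
  invisible(x)
}

# Forward pass on a tape. Returns the logits node plus the registry of
# parameter leaf nodes (for gradient collection) and, on request, the
# intermediate feature shapes for the architecture shape oracle.
net_forward_tape <- function(net, x1, x2, tape = tape_new(),
                             intermediates = FALSE) {
  cfg <- net$cfg
  L <- cfg$levels
  pnodes <- new.env(parent = emptyenv())
  getp <- function(name) {
    if (!exists(name, envir = pnodes, inherits = FALSE)) {
      if (is.null(net$params[[name]])) stop("unknown parameter: ", name)
      assign(name, nd(tape, net$params[[name]], name = name), envir = pnodes)
    }
    get(name, envir = pnodes, inherits = FALSE)
  }
  shapes <- list()
  dense_block <- function(x, prefix) {
    cur <- x
    for (j in seq_len(cfg$n_dense)) {
      t <- op_instnorm(tape, cur)
      t <- op_relu(tape, t)
      t <- op_conv2d(tape, t, getp(sprintf("%s.d%d.w", prefix, j)),
                     getp(sprintf("%s.d%d.b", prefix, j)))
      cur <- op_concat(tape, list(cur, t))
    }
    cur
  }
  run_view <- function(img, v) {
    xin <- nd(tape, array(img, c(dim(img), 1)))
    pv <- sprintf("enc%d", v)
    x <- op_conv2d(tape, xin, getp(paste0(pv, ".stem.w")), getp(paste0(pv, ".stem.b")))
    e <- vector("list", L)
    for (i in seq_len(L)) {
      e[[i]] <- dense_block(x, sprintf("%s.l%d", pv, i))
      if (i < L) x <- op_maxpool2(tape, e[[i]])
    }
    dv <- sprintf("dec%d", v)
    D <- vector("list", L)
    d_prev <- NULL
    for (i in rev(seq_len(L))) {
      inp <- if (i == L) e[[L]] else {
        up <- op_convT2d(tape, d_prev, getp(sprintf("%s.up%d.w", dv, i)),
                         getp(sprintf("%s.up%d.b", dv, i)))
        op_concat(tape, list(up, e[[i]]))
      }
      dd <- op_conv2d(tape, inp, getp(sprintf("%s.l%d.w", dv, i)),
                      getp(sprintf("%s.l%d.b", dv, i)))
      dd <- op_instnorm(tape, dd)
      dd <- op_relu(tape, dd)
      D[[i]] <- op_reshape_c2d(tape, dd, cfg$c3d)
      d_prev <- dd
    }
    if (intermediates) {
      shapes[[sprintf("view%d", v)]] <<- list(
        e = lapply(e, function(n) dim(n$value)),
        D = lapply(D, function(n) dim(n$value)))
    }
    D
  }
  D1 <- run_view(x1, 1)
  D2 <- run_view(x2, 2)
  f_prev <- NULL
  fdims <- vector("list", L)
  for (i in rev(seq_len(L))) {
    d2p <- op_permute_z(tape, D2[[i]])
    inputs <- list(D1[[i]], d2p)
    if (i < L) {
      up <- op_convT3d(tape, f_prev, getp(sprintf("fus.up%d.w", i)),
                       getp(sprintf("fus.up%d.b", i)))
      up <- op_instnorm(tape, up)
      up <- op_relu(tape, up)
      inputs <- c(inputs, list(up))
    }
    f <- op_concat(tape, inputs)
    for (t in seq_len(cfg$n_fuse)) {
      f <- op_conv3d(tape, f, getp(sprintf("fus.l%d.c%d.w", i, t)),
                     getp(sprintf("fus.l%d.c%d.b", i, t)))
      f <- op_instnorm(tape, f)
      f <- op_relu(tape, f)
    }
    fdims[[i]] <- dim(f$value)
    f_prev <- f
  }
  logits <- op_conv3d(tape, f_prev, getp("fus.out.w"), getp("fus.out.b"), k = 1)
  if (intermediates) shapes$fusion <- fdims
  list(logits = logits, tape = tape, pnodes = pnodes,
       shapes = if (intermediates) shapes else NULL)
}

as_image_matrix <- function(x) {
  if (inherits(x, "radiograph")) x$data else x
}

#' Forward pass: radiograph pair to class-probability volume
#'
#' @param net a `recon_net`.
#' @param x1,x2 the two Judet-view radiographs (`radiograph` objects or
#'   matrices at the configured extent).
#' @return array `(extent, extent, extent, classes)` of per-voxel softmax
#'   probabilities (summing to 1 over the last dimension).
#' @export
net_forward <- function(net, x1, x2) {
  x1 <- as_image_matrix(x1); x2 <- as_image_matrix(x2)
  if (!all(dim(x1) == net$cfg$extent) || !all(dim(x2) == net$cfg$extent))
    stop("radiograph extent does not match the network configuration", call. = FALSE)
  fw <- net_forward_tape(net, x1, x2)
  softmax_classes(fw$logits$value)
}

#' Reconstruct a label volume from a radiograph pair
#'
#' Runs the forward pass and takes the per-voxel argmax (ties broken
#' toward the lower class index).
#'
#' @inheritParams net_forward
#' @param spacing voxel spacing for the output volume (mm).
#' @return list with `labels` (a `label_volume`) and `probs`.
#' @export
net_infer <- function(net, x1, x2, spacing = 1) {
  probs <- net_forward(net, x1, x2)
  d <- dim(probs)
  nc <- d[4]
  m <- matrix(probs, ncol = nc)
  lab <- array(max.col(m, ties.method = "first") - 1L, d[1:3])
  list(labels = label_volume(lab, spacing), probs = probs)
}
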
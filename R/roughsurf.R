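#' Parameters of a self-affine rough fracture surface
#'
#' Fracture surfaces are modelled as random self-affine height fields with
#' an isotropic power-law roughness power spectrum, PSD(q) ~ q^(-2-2H),
#' synthesized spectrally between two spatial-frequency cutoffs and scaled
#' to a prescribed RMS roughness.
#'
#' @param extent lateral extent in voxels; must be a power of two (the
#'   synthesis is an FFT on a square grid).
#' @param hurst Hurst exponent H in (0, 1); default 0.8, typical of brittle
#'   fracture surfaces.
#' @param rms RMS roughness sigma in voxels (> 0), default 2.
#' @param q_low,q_high spatial-frequency cutoffs in cycles/voxel, within
#'   (0, 0.5]; the power law holds between them.
#' @param thickness slab thickness t in voxels (>= 1), default 2.
#' @param seed RNG seed.
#' @return a `rough_surface_params` list.
#' @export
rough_surface_params <- function(extent = 64, hurst = 0.8, rms = 2,
                                 q_low = 0.02, q_high = 0.3,
                                 thickness = 2, seed = 1L) {
  if (extent < 4 || bitwAnd(extent, extent - 1L) != 0)
    stop("extent must be a power of two >= 4", call. = FALSE)
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("Hurst exponent must lie in (0, 1)", call. = FALSE)
  if (!is.finite(rms) || rms <= 0) stop("RMS roughness must be > 0", call. = FALSE)
  if (thickness < 1) stop("thickness must be >= 1 voxel", call. = FALSE)
  if (q_low <= 0 || q_high > 0.5 || q_low >= q_high)
    stop("cutoffs must satisfy 0 < q_low < q_high <= 0.5", call. = FALSE)
  structure(list(extent = as.integer(extent), hurst = hurst, rms = rms,
                 q_low = q_low, q_high = q_high, thickness = thickness,
                 seed = as.integer(seed)),
            class = "rough_surface_params")
}

# FFT frequencies in cycles/sample for length n (DC, positive, negative).
fft_freqs <- function(n) {
  c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
}

#' Generate a random self-affine height field
#'
#' Spectral synthesis: complex Gaussian Fourier amplitudes shaped by
#' q^(-(1+H)) (so the power spectrum falls as q^(-2-2H)) inside the cutoff
#' band, inverse transformed and rescaled to zero mean and exact RMS sigma.
#' Deterministic given the seed.
#'
#' @param p a [rough_surface_params] object.
#' @return an `extent` x `extent` numeric matrix of heights in voxels.
#' @export
generate_height_field <- function(p) {
  n <- p$extent
  f <- fft_freqs(n)
  q <- sqrt(outer(f^2, f^2, `+`))
  amp <- ifelse(q >= p$q_low & q <= p$q_high, q^(-(1 + p$hurst)), 0)
  amp[1, 1] <- 0
  z <- with_seed(p$seed, {
    matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  })
  h <- Re(fft(amp * z, inverse = TRUE)) / (n * n)
  h <- h - mean(h)
  h * (p$rms / sqrt(mean(h^2)))
}

#' Radially averaged power spectral density of a height field
#'
#' Bins the 2D periodogram into rings of radial spatial frequency; used to
#' verify that synthesized surfaces recover the imposed power-law slope
#' -(2+2H) on a log-log scale.
#'
#' @param h numeric matrix (square height field).
#' @param nbins number of radial bins between just above DC and 0.5
#'   cycles/voxel.
#' @return data.frame with columns `q` (ring center frequency) and `psd`
#'   (mean periodogram power in the ring); empty rings are dropped.
#' @export
radial_psd <- function(h, nbins = 48) {
  n <- nrow(h)
  f <- fft_freqs(n)
  q <- sqrt(outer(f^2, f^2, `+`))
  pw <- Mod(fft(h))^2 / (n * n)^2
  edges <- exp(seq(log(1 / n), log(0.5), length.out = nbins + 1))
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= nbins & q > 0
  agg <- tapply(pw[keep], bin[keep], mean)
  qc <- tapply(q[keep], bin[keep], mean)
  data.frame(q = as.numeric(qc), psd = as.numeric(agg))
}

#' Fit the log-log slope of a radially averaged PSD
#'
#' @param h height field matrix.
#' @param q_low,q_high frequency band for the fit (cycles/voxel).
#' @return the fitted slope (expected close to -(2+2H)).
#' @export
psd_slope <- function(h, q_low = 0.02, q_high = 0.3) {
  ps <- radial_psd(h)
  ps <- ps[ps$q >= q_low & ps$q <= q_high & ps$psd > 0, ]
  unname(coef(lm(log(psd) ~ log(q), data = ps))[2])
}

# Min / max of each matrix entry over its 3x3 neighbourhood (edges
# replicated). Used to make the voxelized slab a topological separator:
# where the sheet jumps steeply between neighbouring columns, the slab is
# locally extended so fragments cannot stay diagonally connected across it.
neighborhood_range <- function(h) {
  n1 <- nrow(h); n2 <- ncol(h)
  lo <- h; hi <- h
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    i <- pmin(pmax(seq_len(n1) + di, 1), n1)
    j <- pmin(pmax(seq_len(n2) + dj, 1), n2)
    s <- h[i, j, drop = FALSE]
    lo <- pmin(lo, s)
    hi <- pmax(hi, s)
  }
  list(lo = lo, hi = hi)
}

#' Voxelize a height field into a slab mask
#'
#' Embeds the height sheet at the grid's mid-plane (z = mid + h(u, v)) in an
#' axis-aligned local frame and sets every voxel whose center lies within
#' t/2 (vertical distance) of the sheet; where the sheet jumps by more than
#' a voxel between neighbouring columns the slab is extended to the local
#' 3x3 height range, so the mask always separates the material above from
#' the material below (a flat sheet reduces exactly to a slab of thickness
#' t). The sheet spans the full lateral extent of its frame, so after
#' placement it can cut any bone cross-section it covers; the patch is
#' centered laterally when the grid is larger than the field.
#'
#' @param h height-field matrix (from [generate_height_field]).
#' @param thickness slab thickness t in voxels (>= 1).
#' @param extents grid extents, length 3.
#' @return a `binary_mask` of the slab (the surface mask G).
#' @export
voxelize_surface <- function(h, thickness, extents) {
  if (thickness < 1) stop("thickness must be >= 1 voxel", call. = FALSE)
  extents <- as.integer(extents)
  n <- nrow(h)
  rng <- neighborhood_range(h)
  mid <- ceiling(extents[3] / 2)
  off_u <- floor((extents[1] - n) / 2)
  off_v <- floor((extents[2] - n) / 2)
  mask <- array(FALSE, extents)
  us <- seq_len(n) + off_u
  vs <- seq_len(n) + off_v
  ok_u <- us >= 1 & us <= extents[1]
  ok_v <- vs >= 1 & vs <= extents[2]
  for (w in seq_len(extents[3])) {
    hit <- (w - mid) >= rng$lo - thickness / 2 & (w - mid) <= rng$hi + thickness / 2
    mask[us[ok_u], vs[ok_v], w] <- hit[ok_u, ok_v]
  }
  binary_mask(mask, 1)
}
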
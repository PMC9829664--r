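#' Parameters of a synthetic proximal-femur phantom
#'
#' The phantom is a union of simple solids exhibiting the anatomy the
#' AO/OTA fracture-location codes refer to: a vertical shaft capsule, an
#' angled neck capsule, a head sphere, and greater/lesser trochanter bumps,
#' embedded in a soft-tissue background. Geometry defaults scale with the
#' physical grid extent so the same shape can be produced at 16^3 test
#' resolution or 128^3 demo resolution.
#'
#' @param extent grid extent per axis in voxels (default 64).
#' @param spacing isotropic voxel size in mm (default 1).
#' @param shaft_radius,shaft_length shaft capsule radius / length (mm).
#' @param neck_radius,neck_length neck capsule radius / length (mm).
#' @param neck_shaft_angle_deg neck-shaft angle in degrees, in (90, 180);
#'   adult femora are typically 120-135.
#' @param head_radius femoral head sphere radius (mm).
#' @param gt_radius,lt_radius greater / lesser trochanter bump radii (mm).
#' @param bone_mean,bone_sd bone intensity distribution (HU). Default
#'   N(700, 100), well above the soft-tissue replacement range 63-193 HU
#'   used by the fracture augmentation.
#' @param tissue_mean,tissue_sd soft-tissue background intensity (HU),
#'   default N(40, 20).
#' @param seed RNG seed for the intensity noise.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(extent = 64, spacing = 1,
                           shaft_radius = 0.09 * E, shaft_length = 0.49 * E,
                           neck_radius = 0.07 * E, neck_length = 0.22 * E,
                           neck_shaft_angle_deg = 128,
                           head_radius = 0.13 * E,
                           gt_radius = 0.08 * E, lt_radius = 0.05 * E,
                           bone_mean = 700, bone_sd = 100,
                           tissue_mean = 40, tissue_sd = 20,
                           seed = 1L) {
  E <- extent * spacing  # physical extent in mm
  p <- list(extent = as.integer(extent), spacing = spacing,
            shaft_radius = shaft_radius, shaft_length = shaft_length,
            neck_radius = neck_radius, neck_length = neck_length,
            neck_shaft_angle_deg = neck_shaft_angle_deg,
            head_radius = head_radius, gt_radius = gt_radius,
            lt_radius = lt_radius, bone_mean = bone_mean, bone_sd = bone_sd,
            tissue_mean = tissue_mean, tissue_sd = tissue_sd,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  lens <- c(p$shaft_radius, p$shaft_length, p$neck_radius, p$neck_length,
            p$head_radius, p$gt_radius, p$lt_radius)
  if (any(lens <= 0)) stop("all radii and lengths must be positive", call. = FALSE)
  if (p$neck_shaft_angle_deg <= 90 || p$neck_shaft_angle_deg >= 180)
    stop("neck-shaft angle must lie in (90, 180) degrees", call. = FALSE)
  if (p$bone_mean <= p$tissue_mean)
    stop("bone mean intensity must exceed soft-tissue mean", call. = FALSE)
  g <- phantom_geometry(p)
  E <- p$extent * p$spacing
  hi <- g$head_center + p$head_radius
  if (any(hi > E) || any(g$head_center - p$head_radius < 0) ||
      g$shaft_top[3] + p$gt_radius > E)
    stop("phantom geometry exceeds the grid", call. = FALSE)
  invisible(p)
}

# Analytic solid positions (mm), derived from the parameter set.
phantom_geometry <- function(p) {
  E <- p$extent * p$spacing
  cx <- 0.42 * E; cy <- 0.5 * E
  z0 <- 0.06 * E
  shaft_base <- c(cx, cy, z0)
  shaft_top <- c(cx, cy, z0 + p$shaft_length)
  neck_base <- c(cx, cy, z0 + 0.94 * p$shaft_length)
  a <- (180 - p$neck_shaft_angle_deg) * pi / 180
  dirn <- c(sin(a), 0, cos(a))
  neck_tip <- neck_base + p$neck_length * dirn
  head_center <- neck_base + (p$neck_length + 0.3 * p$head_radius) * dirn
  gt_center <- c(cx - 0.6 * p$shaft_radius, cy, z0 + 1.02 * p$shaft_length)
  lt_center <- c(cx + 0.9 * p$shaft_radius, cy + 0.04 * E, z0 + 0.68 * p$shaft_length)
  list(shaft_base = shaft_base, shaft_top = shaft_top, neck_base = neck_base,
       neck_tip = neck_tip, head_center = head_center,
       gt_center = gt_center, lt_center = lt_center)
}

# Squared distance from points (px, py, pz) to segment a-b, vectorized.
dist2_segment <- function(px, py, pz, a, b) {
  u <- b - a
  len2 <- sum(u * u)
  t <- ((px - a[1]) * u[1] + (py - a[2]) * u[2] + (pz - a[3]) * u[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - a[1] - t * u[1])^2 + (py - a[2] - t * u[2])^2 + (pz - a[3] - t * u[3])^2
}

# Voxel-center coordinate arrays in mm for an extent^3 grid.
voxel_centers <- function(extent, spacing) {
  cs <- (seq_len(extent) - 0.5) * spacing
  list(x = rep(cs, times = extent^2),
       y = rep(rep(cs, each = extent), times = extent),
       z = rep(cs, each = extent^2))
}

# Logical vector: voxel centers inside the analytic union of solids.
phantom_inside <- function(p) {
  g <- phantom_geometry(p)
  v <- voxel_centers(p$extent, p$spacing)
  inside <- dist2_segment(v$x, v$y, v$z, g$shaft_base, g$shaft_top) <= p$shaft_radius^2
  inside <- inside | dist2_segment(v$x, v$y, v$z, g$neck_base, g$neck_tip) <= p$neck_radius^2
  d2 <- (v$x - g$head_center[1])^2 + (v$y - g$head_center[2])^2 + (v$z - g$head_center[3])^2
  inside <- inside | d2 <= p$head_radius^2
  d2 <- (v$x - g$gt_center[1])^2 + (v$y - g$gt_center[2])^2 + (v$z - g$gt_center[3])^2
  inside <- inside | d2 <= p$gt_radius^2
  d2 <- (v$x - g$lt_center[1])^2 + (v$y - g$lt_center[2])^2 + (v$z - g$lt_center[3])^2
  inside | d2 <= p$lt_radius^2
}

#' Generate an intact proximal-femur phantom
#'
#' Produces an intensity volume (bone intensities inside the bone mask,
#' soft-tissue intensities outside) and a single-fragment mask. The bone
#' mask is one 26-connected component by construction (all solids overlap
#' their neighbours); this is asserted at run time.
#'
#' @param params a [phantom_params] object.
#' @return list with elements `volume` (`intensity_volume`), `fragments`
#'   (`fragment_set` with n = 1) and `params`.
#' @export
make_phantom <- function(params) {
  validate_phantom_params(params)
  n <- params$extent
  mask <- array(phantom_inside(params), dim = c(n, n, n))
  frags <- connected_components(binary_mask(mask, params$spacing), 26)
  if (frags$n != 1L)
    stop("phantom bone mask is not a single connected component", call. = FALSE)
  vals <- with_seed(params$seed, {
    v <- rnorm(n^3, params$tissue_mean, params$tissue_sd)
    v[mask] <- rnorm(sum(mask), params$bone_mean, params$bone_sd)
    v
  })
  vol <- intensity_volume(array(vals, dim = c(n, n, n)), params$spacing)
  list(volume = vol, fragments = frags, params = params)
}

#' Generate a cohort of intact phantoms
#'
#' Draws per-sample geometry parameters uniformly from ranges and builds
#' one phantom per draw with a per-sample derived seed. All samples start
#' tagged `"intact"`; fracture tags are assigned by the augmentation engine.
#'
#' @param n_intact number of phantoms (>= 1).
#' @param params_ranges named list of `c(lo, hi)` ranges overriding numeric
#'   [phantom_params] fields; `NULL` uses mild anatomical variation
#'   (+-10% on shaft/neck/head sizes, neck-shaft angle 120-135).
#' @param seed cohort seed; per-sample seeds are derived from it.
#' @param extent,spacing grid geometry passed to [phantom_params].
#' @return list of samples, each `list(volume, fragments, type_tag, id, seed)`.
#' @export
make_cohort <- function(n_intact, params_ranges = NULL, seed = 1L,
                        extent = 64, spacing = 1) {
  if (n_intact < 1) stop("n_intact must be >= 1", call. = FALSE)
  E <- extent * spacing
  if (is.null(params_ranges)) {
    params_ranges <- list(
      shaft_radius = c(0.081, 0.099) * E,
      neck_radius = c(0.063, 0.077) * E,
      neck_length = c(0.198, 0.242) * E,
      head_radius = c(0.117, 0.143) * E,
      neck_shaft_angle_deg = c(120, 135))
  }
  for (nm in names(params_ranges)) {
    r <- params_ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("invalid range for ", nm, call. = FALSE)
  }
  lapply(seq_len(n_intact), function(i) {
    si <- derive_seed(seed, i)
    draws <- with_seed(si, lapply(params_ranges, function(r) runif(1, r[1], r[2])))
    p <- do.call(phantom_params,
                 c(list(extent = extent, spacing = spacing, seed = si), draws))
    ph <- make_phantom(p)
    list(volume = ph$volume, fragments = ph$fragments,
         type_tag = "intact", id = sprintf("phantom%03d", i), seed = si)
  })
}

#' Axis-aligned AO-region bounding boxes of a phantom
#'
#' Maps the AO/OTA fracture-location codes to voxel-index bounding boxes on
#' the phantom: 31A trochanteric, 31B femoral neck, 31C femoral head,
#' 32 diaphyseal (shaft). Boxes are clamped to the grid and each intersects
#' the bone mask by construction.
#'
#' @param params a [phantom_params] object.
#' @return named list of boxes, each `list(lo, hi)` in 1-based voxel indices.
#' @export
region_map <- function(params) {
  g <- phantom_geometry(params)
  sp <- params$spacing; n <- params$extent
  to_idx <- function(mm) pmin(pmax(round(mm / sp + 0.5), 1), n)
  box <- function(center, half) {
    list(lo = to_idx(center - half), hi = to_idx(center + half))
  }
  neck_mid <- (g$neck_base + g$neck_tip) / 2
  # Lower-shaft box kept below the lesser trochanter so it meets only shaft.
  shaft_lo <- g$shaft_base + c(0, 0, 0.05 * params$shaft_length)
  shaft_mid_z <- shaft_lo[3] + 0.2 * params$shaft_length
  list(
    `31A` = box(c(g$shaft_top[1], g$shaft_top[2], g$shaft_top[3]),
                c(params$shaft_radius + params$gt_radius,
                  params$shaft_radius + 2, params$gt_radius + 2)),
    `31B` = box(neck_mid, rep(params$neck_radius * 1.4, 3)),
    `31C` = box(g$head_center, rep(params$head_radius, 3)),
    `32` = box(c(g$shaft_base[1], g$shaft_base[2], shaft_mid_z),
               c(params$shaft_radius, params$shaft_radius,
                 shaft_mid_z - shaft_lo[3]))
  )
}
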
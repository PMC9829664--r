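#' Sample a fracture-surface placement for an AO-coded location
#'
#' Draws an affine placement (rotation + translation) for a fracture
#' surface: the translation is uniform inside the AO region's bounding box
#' and the rotation tilts the surface normal away from the vertical axis by
#' an angle drawn from a per-code range, with uniform azimuth. Default tilt
#' ranges: near-transverse for shaft fractures (32: 0-20 degrees), oblique
#' for femoral neck (31B: 30-70), moderate for trochanteric/head
#' (31A, 31C: 0-30).
#'
#' @param ao AO/OTA location code, one of `"31A"`, `"31B"`, `"31C"`, `"32"`.
#' @param regions region box map from [region_map].
#' @param seed RNG seed (placement is deterministic given it).
#' @param tilt_ranges named list of `c(lo, hi)` tilt ranges in degrees.
#' @return a `fracture_placement`: list with `ao`, `tilt_deg`, `azimuth_deg`,
#'   `translation` (voxel coordinates of the surface centroid) and `seed`.
#' @export
sample_placement <- function(ao, regions, seed = 1L,
                             tilt_ranges = list(`31A` = c(0, 30),
                                                `31B` = c(30, 70),
                                                `31C` = c(0, 30),
                                                `32` = c(0, 20))) {
  if (!ao %in% names(regions) || !ao %in% names(tilt_ranges))
    stop("unknown AO code: ", ao, call. = FALSE)
  box <- regions[[ao]]
  with_seed(seed, {
    tr <- tilt_ranges[[ao]]
    structure(list(ao = ao,
                   tilt_deg = runif(1, tr[1], tr[2]),
                   azimuth_deg = runif(1, 0, 360),
                   translation = runif(3, box$lo, box$hi),
                   seed = as.integer(seed)),
              class = "fracture_placement")
  })
}

# Rotation matrix: tilt about y then azimuth about z (degrees).
placement_rotation <- function(placement) {
  t <- placement$tilt_deg * pi / 180
  a <- placement$azimuth_deg * pi / 180
  ry <- matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rz %*% ry
}

#' Place a rough surface in the volume grid
#'
#' Applies the placement's rigid transform to the slab implied by a height
#' field and voxelizes it by inverse mapping with nearest-neighbour lookup
#' of the height field (hole-free and binary-preserving): a grid voxel
#' belongs to the placed surface mask when, expressed in the surface's
#' local frame, it lies within the lateral extent and within t/2 of the
#' height sheet.
#'
#' @param h height-field matrix.
#' @param thickness slab thickness in voxels.
#' @param placement a [sample_placement] result.
#' @param extents grid extents (length 3).
#' @param spacing grid spacing (carried onto the output mask).
#' @return a `binary_mask` (the placed surface, T(G)).
#' @export
place_surface <- function(h, thickness, placement, extents, spacing = 1) {
  extents <- as.integer(extents)
  n <- nrow(h)
  R <- placement_rotation(placement)
  ctr <- placement$translation
  half <- (n - 1) / 2
  # local = R^T (p - ctr); restrict work to the patch's bounding sphere
  rad <- sqrt(2) * half + max(abs(h)) + thickness
  lo <- pmax(floor(ctr - rad), 1)
  hi <- pmin(ceiling(ctr + rad), extents)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  px <- rep(xs, times = length(ys) * length(zs)) - ctr[1]
  py <- rep(rep(ys, each = length(xs)), times = length(zs)) - ctr[2]
  pz <- rep(zs, each = length(xs) * length(ys)) - ctr[3]
  lu <- R[1, 1] * px + R[2, 1] * py + R[3, 1] * pz
  lv <- R[1, 2] * px + R[2, 2] * py + R[3, 2] * pz
  lw <- R[1, 3] * px + R[2, 3] * py + R[3, 3] * pz
  iu <- round(lu + half) + 1
  iv <- round(lv + half) + 1
  inside <- iu >= 1 & iu <= n & iv >= 1 & iv <= n
  hit <- logical(length(px))
  if (any(inside)) {
    rng <- neighborhood_range(h)
    ij <- cbind(iu[inside], iv[inside])
    hit[inside] <- lw[inside] >= rng$lo[ij] - thickness / 2 &
      lw[inside] <= rng$hi[ij] + thickness / 2
  }
  mask <- array(FALSE, extents)
  mask[xs, ys, zs] <- array(hit, c(length(xs), length(ys), length(zs)))
  binary_mask(mask, spacing)
}

#' Split a bone mask with a placed fracture surface
#'
#' The augmented fracture mask is the intersection of the bone with the
#' placed surface, and the augmented bone is the bone minus the surface,
#' relabeled into connected components. Draws that fail to actually
#' fracture the bone (fewer than two remaining components, or a sliver
#' component below `min_frag_frac` of the bone volume) are reported as
#' rejections so the caller can resample the placement, never as errors.
#'
#' @param m_b intact bone `binary_mask` (nonempty).
#' @param g_placed placed surface `binary_mask` (same extents).
#' @param min_frag_frac minimum fragment size as a fraction of bone voxels
#'   (default 0.01).
#' @return a `bone_split`: list with `accepted` (logical); when accepted,
#'   `fragments` (a `fragment_set`) and `gap` (the fracture mask), otherwise
#'   `reason`.
#' @export
split_bone <- function(m_b, g_placed, min_frag_frac = 0.01) {
  if (!any(m_b$data)) stop("cannot split an empty bone mask", call. = FALSE)
  if (!identical(dim(m_b$data), dim(g_placed$data)))
    stop("mask extents differ", call. = FALSE)
  gap <- mask_algebra(m_b, g_placed, "intersection")
  rest <- mask_algebra(m_b, g_placed, "difference")
  if (!any(rest$data)) {
    return(structure(list(accepted = FALSE, reason = "surface swallowed the bone"),
                     class = "bone_split"))
  }
  frags <- connected_components(rest, 26)
  if (frags$n < 2L) {
    return(structure(list(accepted = FALSE, reason = "surface did not split the bone"),
                     class = "bone_split"))
  }
  sizes <- vapply(frags$fragments, function(f) sum(f$data), numeric(1))
  if (min(sizes) < min_frag_frac * sum(m_b$data)) {
    return(structure(list(accepted = FALSE, reason = "sliver fragment"),
                     class = "bone_split"))
  }
  structure(list(accepted = TRUE, fragments = frags, gap = gap),
            class = "bone_split")
}

#' Replace fracture-gap intensities with soft tissue
#'
#' Voxels inside the fracture mask are replaced by independent draws from a
#' uniform soft-tissue distribution on [63, 193] HU (mean 128 HU, matching
#' the reported intensity drop at fracture sites); all other voxels are
#' untouched, bit for bit.
#'
#' @param vol an `intensity_volume` (Q).
#' @param gap a `binary_mask` (the augmented fracture mask), same extents.
#' @param seed RNG seed.
#' @param range soft-tissue intensity range in HU, default `c(63, 193)`.
#' @return the augmented `intensity_volume` (Q*).
#' @export
replace_intensity <- function(vol, gap, seed = 1L, range = c(63, 193)) {
  if (!identical(dim(vol$data), dim(gap$data)))
    stop("extents differ", call. = FALSE)
  out <- vol$data
  nrep <- sum(gap$data)
  if (nrep > 0) {
    out[gap$data] <- with_seed(seed, runif(nrep, range[1], range[2]))
  }
  intensity_volume(out, vol$spacing)
}

#' Manufacture a nondisplaced fracture sample from an intact one
#'
#' Composes the augmentation pipeline: generate a random self-affine rough
#' surface, place it at a random pose inside the requested AO region, split
#' the bone mask with it, and replace the gap intensities with soft-tissue
#' values. Draws that fail to split the bone are rejected and resampled up
#' to `max_retries` times. Fragments keep their anatomical position, so
#' every augmented sample is tagged `"nondisplaced"` (the approach cannot
#' manufacture displaced fractures).
#'
#' @param vol intact `intensity_volume` (Q).
#' @param frags intact `fragment_set` (n = 1) or a `binary_mask`.
#' @param ao AO code or vector of codes (one is drawn per attempt).
#' @param regions region box map from [region_map].
#' @param surf a [rough_surface_params] template (its seed is re-derived per
#'   attempt); `NULL` chooses a lateral extent spanning half the grid.
#' @param seed master seed; all draws derive from it.
#' @param max_retries retry budget for rejected draws (default 25).
#' @param min_frag_frac passed to [split_bone].
#' @return list with `volume` (Q*), `fragments`, `gap`, `type_tag`
#'   (`"nondisplaced"`), `ao`, `placement`, `attempts`.
#' @export
augment_sample <- function(vol, frags, ao, regions, surf = NULL, seed = 1L,
                           max_retries = 25, min_frag_frac = 0.01) {
  m_b <- if (inherits(frags, "fragment_set")) fragment_union(frags) else frags
  if (inherits(frags, "fragment_set") && frags$n != 1L)
    stop("augmentation expects an intact (single-fragment) input", call. = FALSE)
  extents <- dim(m_b$data)
  if (is.null(surf)) {
    # Nondisplaced fracture gaps are hairline: roughness scales with the
    # grid (1 voxel RMS on a 32-voxel bone) and is long-wavelength
    # dominated, so the relabeled gap stays 2-4 voxels wide - the width
    # the r = 2 auxiliary dilation is designed to bridge.
    surf <- rough_surface_params(extent = 2^ceiling(log2(max(extents) / 2)),
                                 rms = max(0.8, max(extents) / 32),
                                 q_high = 0.15)
  }
  for (attempt in seq_len(max_retries)) {
    s <- derive_seed(seed, attempt)
    code <- if (length(ao) > 1L) with_seed(s, sample(ao, 1)) else ao
    sp <- rough_surface_params(extent = surf$extent, hurst = surf$hurst,
                               rms = surf$rms, q_low = surf$q_low,
                               q_high = surf$q_high, thickness = surf$thickness,
                               seed = derive_seed(s, 1L))
    h <- generate_height_field(sp)
    placement <- sample_placement(code, regions, seed = derive_seed(s, 2L))
    g <- place_surface(h, sp$thickness, placement, extents, m_b$spacing)
    split <- split_bone(m_b, g, min_frag_frac)
    if (split$accepted) {
      q_star <- replace_intensity(vol, split$gap, seed = derive_seed(s, 3L))
      return(list(volume = q_star, fragments = split$fragments,
                  gap = split$gap, type_tag = "nondisplaced", ao = code,
                  placement = placement, attempts = attempt))
    }
  }
  stop(sprintf("augmentation failed after %d draws (AO %s, seed %d)",
               max_retries, paste(ao, collapse = "/"), seed), call. = FALSE)
}
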
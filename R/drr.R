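#' Rotate a volume about the vertical axis
#'
#' Rotates the voxel grid by `angle_deg` about the z axis around the grid
#' center, resampling with trilinear interpolation; voxels sampled outside
#' the original grid are filled with `fill` (air, -1000 HU, by default so
#' rotations add no attenuating material).
#'
#' @param vol an `intensity_volume`.
#' @param angle_deg rotation angle in degrees (counter-clockwise looking
#'   down the z axis).
#' @param fill intensity for out-of-grid samples (HU).
#' @return an `intensity_volume` on the same grid.
#' @export
rotate_volume_z <- function(vol, angle_deg, fill = -1000) {
  d <- dim(vol$data)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xs <- rep(seq_len(d[1]), times = d[2]) - cx
  ys <- rep(seq_len(d[2]), each = d[1]) - cy
  # inverse mapping: sample source at R(-a) * p
  sx <- ca * xs + sa * ys + cx
  sy <- -sa * xs + ca * ys + cy
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  plane <- function(i, j) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    idx <- ifelse(ok, i + (j - 1) * d[1], 1L)
    list(idx = idx, ok = ok)
  }
  c00 <- plane(i0, j0); c10 <- plane(i0 + 1, j0)
  c01 <- plane(i0, j0 + 1); c11 <- plane(i0 + 1, j0 + 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  np <- d[1] * d[2]
  out <- array(fill, d)
  for (k in seq_len(d[3])) {
    sl <- vol$data[, , k]
    v00 <- ifelse(c00$ok, sl[c00$idx], fill)
    v10 <- ifelse(c10$ok, sl[c10$idx], fill)
    v01 <- ifelse(c01$ok, sl[c01$idx], fill)
    v11 <- ifelse(c11$ok, sl[c11$idx], fill)
    out[, , k] <- w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
  }
  intensity_volume(out, vol$spacing)
}

#' Simulate a digitally reconstructed radiograph (DRR)
#'
#' Parallel-beam projection: the volume is rotated by `angle_deg` about the
#' vertical axis, Hounsfield intensities are mapped to a nonnegative
#' attenuation proxy `max(HU + 1000, 0)` (water-referenced, so air
#' contributes nothing), and attenuation is integrated along rays
#' perpendicular to the detector (the y axis of the rotated grid), scaled
#' by the voxel spacing. The image is min-max normalized to [0, 1] unless
#' `normalize = FALSE`, in which case the raw line integrals are returned
#' (useful for linearity checks).
#'
#' @param vol an `intensity_volume`.
#' @param angle_deg view angle in degrees about z.
#' @param normalize min-max normalize the image (default TRUE).
#' @return a `radiograph`: list with `data` (matrix indexed by detector
#'   horizontal u and vertical z), `angle_deg` and `pixel_spacing` (mm).
#' @export
project <- function(vol, angle_deg, normalize = TRUE) {
  rot <- if (angle_deg != 0) rotate_volume_z(vol, angle_deg) else vol
  mu <- pmax(rot$data + 1000, 0)
  img <- apply(mu, c(1, 3), sum) * vol$spacing[2]
  if (normalize) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  }
  structure(list(data = img, angle_deg = angle_deg,
                 pixel_spacing = vol$spacing[c(1, 3)]),
            class = "radiograph")
}

#' Simulate a Judet-view biplanar radiograph pair
#'
#' The two views are taken at -45 and +45 degrees about the vertical axis
#' (avoiding contralateral-leg overlap); a nonzero `rotational_error_deg`
#' offsets only the second view, emulating imperfect patient positioning
#' for sensitivity studies. With zero error the views are exactly 90
#' degrees apart, as the fusion module's permutation assumes.
#'
#' @param vol an `intensity_volume`.
#' @param rotational_error_deg inter-view rotational error in degrees
#'   (|error| <= 45).
#' @return list with radiographs `x1`, `x2` and `rotational_error_deg`.
#' @export
judet_pair <- function(vol, rotational_error_deg = 0) {
  if (abs(rotational_error_deg) > 45)
    stop("|rotational error| must be <= 45 degrees", call. = FALSE)
  list(x1 = project(vol, -45),
       x2 = project(vol, 45 + rotational_error_deg),
       rotational_error_deg = rotational_error_deg)
}

#' Write a radiograph as a 16-bit grayscale PNG
#'
#' @param rg a `radiograph` (values in [0, 1]).
#' @param path output path.
#' @export
write_radiograph <- function(rg, path) {
  img <- t(rg$data[, rev(seq_len(ncol(rg$data))), drop = FALSE])
  png::writePNG(img, path)
  invisible(path)
}
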
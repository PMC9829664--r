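#' Discrete spherical structuring element
#'
#' All integer voxel offsets with Euclidean norm (center to center) at most
#' `r`. Contains the zero offset and is symmetric under negation.
#'
#' @param r radius in voxels (integer >= 1; default in callers is 2).
#' @return a `structuring_element`: list with `r` and an `offsets` matrix
#'   (one integer triple per row).
#' @export
spherical_element <- function(r) {
  if (length(r) != 1L || !is.finite(r) || r < 1 || r != round(r))
    stop("structuring-element radius must be an integer >= 1", call. = FALSE)
  r <- as.integer(r)
  g <- expand.grid(du = -r:r, dv = -r:r, dw = -r:r)
  keep <- g$du^2 + g$dv^2 + g$dw^2 <= r^2
  structure(list(r = r, offsets = as.matrix(g[keep, , drop = FALSE])),
            class = "structuring_element")
}

#' Morphological dilation of a binary mask
#'
#' Minkowski dilation by a structuring element, clipped at the grid boundary
#' (voxels never wrap; a fragment near the border dilates only inside the
#' grid). The output always contains the input (the element holds the zero
#' offset).
#'
#' @param mask a `binary_mask`.
#' @param el a [spherical_element].
#' @return a `binary_mask`.
#' @export
dilate <- function(mask, el) {
  out <- .dilate_offsets(as.vector(mask$data), dim(mask$data),
                         matrix(as.integer(el$offsets), ncol = 3))
  binary_mask(array(out, dim(mask$data)), mask$spacing)
}

#' Synthesize the auxiliary (fracture-gap) class from bone fragments
#'
#' The auxiliary class marks the fracture-representative voxels lying
#' between nearby bone fragments: every fragment is dilated by a spherical
#' element of radius `r`, the dilations of each unordered fragment pair are
#' intersected, the pairwise intersections are united, and the union of the
#' original fragments is subtracted. An intact bone (one fragment) has no
#' pairs, hence an empty auxiliary mask; fragments further apart than the
#' two dilations can bridge also produce nothing.
#'
#' @param frags a `fragment_set` (pairwise disjoint).
#' @param r dilation radius in voxels (default 2).
#' @return a `binary_mask`, disjoint from every fragment.
#' @export
synthesize_auxiliary <- function(frags, r = 2) {
  spacing <- frags$fragments[[1]]$spacing
  dims <- dim(frags$fragments[[1]]$data)
  if (frags$n < 2L) {
    return(binary_mask(array(FALSE, dims), spacing))
  }
  el <- spherical_element(r)
  dil <- lapply(frags$fragments, function(f) dilate(f, el)$data)
  acc <- array(FALSE, dims)
  for (k in seq_len(frags$n - 1L)) {
    for (l in seq.int(k + 1L, frags$n)) {
      acc <- acc | (dil[[k]] & dil[[l]])
    }
  }
  bone <- fragment_union(frags)$data
  binary_mask(acc & !bone, spacing)
}

#' Assemble a ground-truth label volume
#'
#' Background is 0 everywhere, bone (the union of all fragments) is 1, and
#' the auxiliary fracture-gap mask, when supplied, is 2. The auxiliary mask
#' must be disjoint from the bone (it never overwrites it); omit it for the
#' two-class network variant.
#'
#' @param frags a `fragment_set`.
#' @param aux a `binary_mask` of auxiliary voxels, or `NULL`.
#' @return a `label_volume` with classes `{0, 1}` or `{0, 1, 2}`.
#' @export
build_labels <- function(frags, aux = NULL) {
  bone <- fragment_union(frags)
  lab <- array(0L, dim(bone$data))
  lab[bone$data] <- 1L
  if (!is.null(aux)) {
    if (!identical(dim(aux$data), dim(bone$data)))
      stop("auxiliary mask extents differ from fragments", call. = FALSE)
    if (any(aux$data & bone$data))
      stop("auxiliary mask overlaps bone fragments", call. = FALSE)
    lab[aux$data] <- 2L
  }
  label_volume(lab, bone$spacing)
}
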
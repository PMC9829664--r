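#' Voxel volume containers
#'
#' The package works on rank-3 voxel grids with a fixed axis convention:
#' axis 1 = x (left-right), axis 2 = y (anterior-posterior), axis 3 = z
#' (the vertical, superior-inferior axis referenced by the Judet views and
#' the fusion permutation). Three containers share this layout:
#' `intensity_volume` (Hounsfield-unit scalars), `binary_mask` (logical),
#' and `label_volume` (integer classes 0 = background, 1 = bone,
#' 2 = auxiliary / fracture gap). A `fragment_set` is an ordered list of
#' pairwise-disjoint binary masks, one per bone fragment.
#'
#' @param data rank-3 array.
#' @param spacing per-axis voxel size in mm (length 1 or 3, default 1 mm
#'   isotropic).
#' @return An object of the corresponding class, a list with elements
#'   `data` and `spacing`.
#' @name volumes
NULL

check_grid <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected a rank-3 array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all grid extents must be >= 1", call. = FALSE)
  invisible(dim(data))
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  spacing
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, spacing = 1) {
  check_grid(data)
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "intensity_volume")
}

#' @rdname volumes
#' @export
binary_mask <- function(data, spacing = 1) {
  check_grid(data)
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "binary_mask")
}

#' @rdname volumes
#' @export
label_volume <- function(data, spacing = 1) {
  check_grid(data)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, 2)))
    stop("label volume may only contain classes 0, 1, 2", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "label_volume")
}

#' @rdname volumes
#' @param fragments list of `binary_mask` objects with identical extents.
#' @export
fragment_set <- function(fragments) {
  if (length(fragments) < 1L) stop("a fragment set needs n >= 1 fragments", call. = FALSE)
  dims <- dim(fragments[[1]]$data)
  for (f in fragments) {
    if (!inherits(f, "binary_mask")) stop("fragments must be binary masks", call. = FALSE)
    if (!identical(dim(f$data), dims)) stop("fragment extents differ", call. = FALSE)
  }
  if (length(fragments) > 1L) {
    acc <- fragments[[1]]$data
    for (f in fragments[-1]) {
      if (any(acc & f$data)) stop("fragments must be pairwise disjoint", call. = FALSE)
      acc <- acc | f$data
    }
  }
  structure(list(fragments = fragments, n = length(fragments)),
            class = "fragment_set")
}

#' Union of all fragments of a fragment set
#' @param frags a `fragment_set`.
#' @return a `binary_mask`.
#' @export
fragment_union <- function(frags) {
  acc <- frags$fragments[[1]]$data
  if (frags$n > 1L) for (f in frags$fragments[-1]) acc <- acc | f$data
  binary_mask(acc, frags$fragments[[1]]$spacing)
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [intensity_volume]. The voxel grid
#' is used in stored index order (axis 3 taken as the vertical axis) and
#' spacing is taken from the header `pixdim`.
#'
#' @param path path to a NIfTI file containing a 3D image.
#' @return an `intensity_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI image, got rank ", length(d), call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  intensity_volume(array(as.numeric(img), dim = d), spacing)
}

#' Write a volume to NIfTI
#'
#' Label volumes and binary masks are written with an integer datatype so
#' class values round-trip exactly.
#'
#' @param vol an `intensity_volume`, `label_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  data <- vol$data
  dtype <- "double"
  if (inherits(vol, c("label_volume", "binary_mask"))) {
    storage.mode(data) <- "integer"
    dtype <- "int16"
  }
  attr(data, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(data, datatype = dtype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label connected components of a mask as bone fragments
#'
#' Partitions a binary mask into connected components and returns them as a
#' [fragment_set], ordered by decreasing voxel count with ties broken by the
#' smallest linear index of any member voxel, so fragment labels are
#' deterministic across runs.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6, 18 or 26 (default 26: oblique fracture surfaces
#'   produce diagonal adjacencies that 6-connectivity would over-split).
#' @return a `fragment_set` partitioning the input mask.
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26", call. = FALSE)
  if (!any(mask$data)) stop("empty mask has no components", call. = FALSE)
  lab <- .label_components(as.vector(mask$data), dim(mask$data), as.integer(connectivity))
  counts <- tabulate(lab)
  first_idx <- vapply(seq_along(counts), function(k) match(k, lab), integer(1))
  ord <- order(-counts, first_idx)
  frags <- lapply(ord, function(k) {
    binary_mask(array(lab == k, dim(mask$data)), mask$spacing)
  })
  fragment_set(frags)
}

#' Voxel-wise set algebra on binary masks
#'
#' @param a,b `binary_mask` objects with identical extents.
#' @param op one of `"union"`, `"intersection"`, `"difference"`.
#' @return a `binary_mask`.
#' @export
mask_algebra <- function(a, b, op = c("union", "intersection", "difference")) {
  op <- match.arg(op)
  if (!identical(dim(a$data), dim(b$data)))
    stop("mask extents differ", call. = FALSE)
  out <- switch(op,
    union        = a$data | b$data,
    intersection = a$data & b$data,
    difference   = a$data & !b$data)
  binary_mask(out, a$spacing)
}

#' @export
print.fragment_set <- function(x, ...) {
  sizes <- vapply(x$fragments, function(f) sum(f$data), numeric(1))
  cat("fragment_set:", x$n, "fragment(s), voxels:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
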
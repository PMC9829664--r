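#' Bone mask of a label volume under the evaluation merging rule
#'
#' Evaluation compares bone only: auxiliary (fracture-gap) voxels are merged
#' into the background in both prediction and ground truth before any
#' metric is computed.
#'
#' @param lab a `label_volume` (or `binary_mask`, returned unchanged).
#' @return a `binary_mask` of class-1 voxels.
#' @export
bone_mask <- function(lab) {
  if (inherits(lab, "binary_mask")) return(lab)
  binary_mask(array(lab$data == 1L, dim(lab$data)), lab$spacing)
}

#' Intersection-over-Union of the bone class
#'
#' Volume-overlap metric `|A n B| / |A u B|` on the bone masks after
#' merging the auxiliary class into background in both volumes. Both masks
#' empty is defined as perfect agreement (IoU = 1).
#'
#' @param pred,gt `label_volume`s (or binary masks) with equal extents.
#' @return IoU in [0, 1].
#' @export
iou <- function(pred, gt) {
  a <- bone_mask(pred)$data
  b <- bone_mask(gt)$data
  if (!identical(dim(a), dim(b))) stop("extents differ", call. = FALSE)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Extract surface voxel coordinates of a mask
#'
#' A mask voxel is a surface voxel when at least one of its six face
#' neighbours is outside the mask; the grid boundary counts as outside.
#' Coordinates are voxel centers scaled by the spacing (mm).
#'
#' @param mask a nonempty `binary_mask`.
#' @return numeric matrix (n x 3) of surface coordinates in mm.
#' @export
extract_surface <- function(mask) {
  m <- mask$data
  if (!any(m)) stop("surface of an empty mask is undefined", call. = FALSE)
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- m
  for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & shift(ax, by)
  surf <- which(m & !interior, arr.ind = TRUE)
  sweep(surf, 2, mask$spacing, `*`)
}

#' Average symmetric surface distance (ASSD)
#'
#' Mean Euclidean distance between the two masks' boundary surfaces: for
#' every surface voxel of each mask the distance to the nearest surface
#' voxel of the other is taken, and the grand mean over both directions is
#' formed, weighted by surface sizes:
#' `(sum_A d(a, S_B) + sum_B d(b, S_A)) / (|S_A| + |S_B|)`.
#'
#' @param pred,gt nonempty masks (or `label_volume`s; bone class is used
#'   with auxiliary merged to background).
#' @param spacing optional spacing override (mm per voxel).
#' @return distance in mm (0 for identical masks).
#' @export
assd <- function(pred, gt, spacing = NULL) {
  a <- bone_mask(pred); b <- bone_mask(gt)
  if (!identical(dim(a$data), dim(b$data))) stop("extents differ", call. = FALSE)
  if (!is.null(spacing)) {
    a$spacing <- check_spacing(spacing); b$spacing <- check_spacing(spacing)
  }
  if (!any(a$data) || !any(b$data))
    stop("ASSD is undefined for an empty mask", call. = FALSE)
  sa <- extract_surface(a)
  sb <- extract_surface(b)
  da <- .nn_min_dists(sa, sb)
  db <- .nn_min_dists(sb, sa)
  (sum(da) + sum(db)) / (nrow(sa) + nrow(sb))
}

#' Evaluate a cohort of reconstructions
#'
#' Computes per-sample IoU and ASSD (bone class, auxiliary merged to
#' background) and aggregates mean and SD per sample type and overall.
#'
#' @param preds,gts aligned lists of `label_volume`s.
#' @param type_tags character vector of sample types (e.g. `"intact"`,
#'   `"nondisplaced"`, `"displaced"`), same length.
#' @return an `eval_result`: list with `per_sample` (data.frame: id, type,
#'   iou, assd) and `summary` (data.frame: type, n, mean/sd per metric;
#'   types in fixed order with `"overall"` last).
#' @export
evaluate_cohort <- function(preds, gts, type_tags) {
  if (length(preds) != length(gts) || length(preds) != length(type_tags))
    stop("preds, gts and type_tags lengths differ", call. = FALSE)
  per <- data.frame(
    id = seq_along(preds),
    type = as.character(type_tags),
    iou = vapply(seq_along(preds), function(i) iou(preds[[i]], gts[[i]]), numeric(1)),
    assd = vapply(seq_along(preds), function(i) assd(preds[[i]], gts[[i]]), numeric(1)))
  type_order <- c(intersect(c("intact", "nondisplaced", "displaced"), per$type),
                  setdiff(unique(per$type), c("intact", "nondisplaced", "displaced")))
  summarize <- function(df, label) {
    data.frame(type = label, n = nrow(df),
               iou_mean = mean(df$iou), iou_sd = if (nrow(df) > 1) sd(df$iou) else 0,
               assd_mean = mean(df$assd), assd_sd = if (nrow(df) > 1) sd(df$assd) else 0)
  }
  rows <- lapply(type_order, function(tt) summarize(per[per$type == tt, ], tt))
  summ <- do.call(rbind, c(rows, list(summarize(per, "overall"))))
  structure(list(per_sample = per, summary = summ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Cohort evaluation (bone class, auxiliary merged to background):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired two-sided t-test between per-fold metric values
#'
#' Standard paired t-test used to compare two methods across
#' cross-validation folds. Degenerate inputs are handled explicitly: all
#' differences zero gives t = 0, p = 1; a constant nonzero difference has
#' zero variance and is flagged with an infinite t statistic rather than an
#' error from the test machinery.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `p_value`, `mean_diff`, `df`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("score lengths differ", call. = FALSE)
  if (length(a) < 2) stop("need at least two pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p_value = 1, mean_diff = 0,
                  df = length(d) - 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_diff = mean(d),
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter),
       degenerate = FALSE)
}
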
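#' Focal-loss parameters
#'
#' @param gamma focusing parameter, in [0, 5]; gamma = 0 recovers plain
#'   cross-entropy, larger values down-weight easy voxels. Default 2.
#' @param weights per-class weights (background, bone, auxiliary),
#'   nonnegative. Default `c(0.15, 0.25, 0.6)`, reflecting the extreme
#'   background >> bone >> auxiliary voxel imbalance. Two-class runs use
#'   the first two weights renormalized to sum 1.
#' @param n_classes 2 or 3; trims and renormalizes `weights` accordingly.
#' @return a `focal_loss_params` list.
#' @export
focal_loss_params <- function(gamma = 2, weights = c(0.15, 0.25, 0.6),
                              n_classes = length(weights)) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 5)
    stop("gamma must lie in [0, 5]", call. = FALSE)
  if (any(weights < 0)) stop("class weights must be nonnegative", call. = FALSE)
  if (n_classes < length(weights)) {
    weights <- weights[seq_len(n_classes)]
    weights <- weights / sum(weights)
  }
  if (length(weights) != n_classes)
    stop("need one weight per output class", call. = FALSE)
  structure(list(gamma = gamma, weights = weights, eps = 1e-7),
            class = "focal_loss_params")
}

#' Per-voxel focal term
#'
#' The standard nonnegative focal modulation of cross-entropy:
#' `-(1-p)^gamma * log(p)` for positive voxels and `-p^gamma * log(1-p)`
#' for negative ones. Probabilities are clamped to `[eps, 1-eps]`.
#'
#' @param p predicted probability (vector/array in [0, 1]).
#' @param y binary target (same shape, 0/1).
#' @param gamma focusing parameter.
#' @param eps clamp for numerical safety.
#' @return nonnegative loss values, same shape as `p`.
#' @export
focal_term <- function(p, y, gamma, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- rep_len(as.numeric(y), length(p))
  ifelse(y > 0, -(1 - p)^gamma * log(p), -p^gamma * log(1 - p))
}

# One-hot membership of class i (0-based) in an integer target array.
class_indicator <- function(target, i) as.numeric(target == i)

#' Weighted voxel-wise focal loss
#'
#' Evaluated one-vs-rest per class channel: for each class i the focal term
#' is averaged over all voxels of its probability map against the one-hot
#' target, then the per-class means are combined with the class weights.
#' The per-class mean (rather than sum) makes the weights scale-free with
#' respect to volume size.
#'
#' @param probs array whose last dimension indexes classes; per-voxel
#'   probabilities (e.g. a class-probability volume of shape
#'   `(nx, ny, nz, C)`).
#' @param target integer array of class labels `0..C-1`, shape equal to
#'   `probs` without its last dimension.
#' @param params a [focal_loss_params] object.
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(probs, target, params) {
  dp <- dim(probs)
  nc <- dp[length(dp)]
  if (length(params$weights) != nc)
    stop("number of weights differs from probability channels", call. = FALSE)
  if (!identical(as.integer(dp[-length(dp)]), as.integer(dim(target))))
    stop("probability and target shapes differ", call. = FALSE)
  if (max(target) >= nc) stop("target class exceeds channel count", call. = FALSE)
  n <- length(target)
  pm <- matrix(probs, nrow = n, ncol = nc)
  total <- 0
  for (i in seq_len(nc)) {
    y <- class_indicator(as.vector(target), i - 1L)
    total <- total + params$weights[i] * mean(focal_term(pm[, i], y, params$gamma, params$eps))
  }
  total
}

#' Gradient of the focal loss with respect to the probabilities
#'
#' Analytic derivative of [focal_loss]; used by the finite-difference
#' gradient check and, chained through softmax, by training.
#'
#' @inheritParams focal_loss
#' @return array of the same shape as `probs`.
#' @export
focal_loss_grad <- function(probs, target, params) {
  dp <- dim(probs)
  nc <- dp[length(dp)]
  n <- length(target)
  pm <- matrix(probs, nrow = n, ncol = nc)
  g <- matrix(0, n, nc)
  eps <- params$eps
  for (i in seq_len(nc)) {
    p <- pmin(pmax(pm[, i], eps), 1 - eps)
    y <- class_indicator(as.vector(target), i - 1L)
    inner <- ifelse(y > 0,
                    params$gamma * (1 - p)^(params$gamma - 1) * log(p) - (1 - p)^params$gamma / p,
                    -params$gamma * p^(params$gamma - 1) * log(1 - p) + p^params$gamma / (1 - p))
    # zero where clamped (loss is flat there)
    inner[pm[, i] < eps | pm[, i] > 1 - eps] <- 0
    g[, i] <- params$weights[i] * inner / n
  }
  array(g, dp)
}

#' Gradient of the focal loss with respect to softmax logits
#'
#' @param probs softmax probabilities (last dimension = classes).
#' @inheritParams focal_loss
#' @return array shaped like `probs`: d loss / d logits.
#' @export
focal_loss_grad_logits <- function(probs, target, params) {
  dp <- dim(probs)
  nc <- dp[length(dp)]
  n <- length(target)
  pm <- matrix(probs, nrow = n, ncol = nc)
  gp <- matrix(focal_loss_grad(probs, target, params), n, nc)
  dot <- rowSums(gp * pm)
  array(pm * (gp - dot), dp)
}

#' Softmax over the class (last) dimension
#'
#' @param logits array whose last dimension indexes classes.
#' @return array of probabilities summing to 1 over the last dimension.
#' @export
softmax_classes <- function(logits) {
  dp <- dim(logits)
  nc <- dp[length(dp)]
  m <- matrix(logits, ncol = nc)
  mx <- m[, 1]
  for (j in seq_len(nc)[-1]) mx <- pmax(mx, m[, j])
  m <- exp(m - mx)
  array(m / rowSums(m), dp)
}
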
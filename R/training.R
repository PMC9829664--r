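#' Stratified k-fold assignment
#'
#' Distributes each sample type's members across folds as evenly as
#' possible (per-type fold counts differ by at most 1), deterministically
#' given the seed.
#'
#' @param type_tags character vector of per-sample types.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k) aligned with `type_tags`.
#' @export
stratified_kfold <- function(type_tags, k = 5, seed = 1L) {
  tab <- table(type_tags)
  if (any(tab < k))
    stop("every sample type needs at least k samples", call. = FALSE)
  folds <- integer(length(type_tags))
  with_seed(seed, {
    for (tt in names(tab)) {
      idx <- which(type_tags == tt)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Early-stopping monitor
#'
#' Tracks a validation-loss sequence and reports when it has failed to
#' improve for `patience` consecutive evaluations.
#'
#' @param patience number of non-improving evaluations tolerated.
#' @param min_delta minimum decrease counting as an improvement.
#' @return an environment with `update(val)` (returns TRUE when training
#'   should stop), `best` (best value seen) and `best_index`.
#' @export
early_stopper <- function(patience = 10, min_delta = 0) {
  es <- new.env(parent = emptyenv())
  es$best <- Inf
  es$best_index <- 0L
  es$count <- 0L
  es$n_seen <- 0L
  es$update <- function(val) {
    es$n_seen <- es$n_seen + 1L
    if (val < es$best - min_delta) {
      es$best <- val
      es$best_index <- es$n_seen
      es$count <- 0L
    } else {
      es$count <- es$count + 1L
    }
    es$count >= patience
  }
  es
}

#' Prepare a training sample from a volume and its fragments
#'
#' Builds the ground-truth label volume (with the auxiliary fracture-gap
#' class when training a 3-class network) and simulates the Judet DRR pair.
#'
#' @param volume an `intensity_volume`.
#' @param fragments a `fragment_set`.
#' @param classes 2 or 3.
#' @param aux_radius dilation radius for the auxiliary class (default 2).
#' @param rotational_error_deg inter-view error passed to [judet_pair].
#' @return list with `x1`, `x2` (image matrices), `target` (integer array)
#'   and `labels` (the `label_volume`).
#' @export
prepare_sample <- function(volume, fragments, classes = 3, aux_radius = 2,
                           rotational_error_deg = 0) {
  aux <- if (classes == 3) synthesize_auxiliary(fragments, aux_radius) else NULL
  labels <- build_labels(fragments, aux)
  pair <- judet_pair(volume, rotational_error_deg)
  list(x1 = pair$x1$data, x2 = pair$x2$data,
       target = labels$data, labels = labels)
}

net_loss <- function(net, sample, loss_params) {
  probs <- net_forward(net, sample$x1, sample$x2)
  focal_loss(probs, sample$target, loss_params)
}

#' Train a reconstruction network
#'
#' Full-batch Adam on the weighted voxel-wise focal loss, with optional
#' early stopping on a validation set. The best-validation parameter
#' snapshot is restored at the end when validation is used.
#'
#' @param net a `recon_net` (modified in place and returned).
#' @param samples list of training samples from [prepare_sample].
#' @param loss_params a [focal_loss_params]; defaults to gamma 2 and
#'   weights (0.15, 0.25, 0.6) trimmed to the configured classes.
#' @param steps maximum optimization steps.
#' @param lr Adam learning rate (default 1e-4).
#' @param betas Adam momentum parameters, default `c(0.9, 0.99)`.
#' @param val_samples optional validation samples for early stopping.
#' @param val_every evaluate validation loss every this many steps.
#' @param patience early-stopping patience in validation rounds.
#' @param verbose print progress.
#' @return the trained `recon_net`, with a `log` data.frame attached
#'   (`net$log`: step, loss, val_loss).
#' @export
net_train <- function(net, samples, loss_params = NULL, steps = 100,
                      lr = 1e-4, betas = c(0.9, 0.99), val_samples = NULL,
                      val_every = 10, patience = 10, verbose = FALSE) {
  cfg <- net$cfg
  if (is.null(loss_params)) {
    loss_params <- focal_loss_params(n_classes = cfg$classes)
  }
  if (length(loss_params$weights) != cfg$classes)
    stop("loss weights do not match the configured classes", call. = FALSE)
  pn <- names(net$params)
  if (!is.null(net$opt) && identical(names(net$opt$m), pn)) {
    m <- net$opt$m; v <- net$opt$v; t0 <- net$opt$t
  } else {
    m <- lapply(net$params, function(p) array(0, dim(p) %||% length(p)))
    v <- m
    t0 <- 0L
  }
  es <- early_stopper(patience)
  best_params <- NULL
  log <- data.frame(step = integer(), loss = numeric(), val_loss = numeric())
  eps <- 1e-8
  for (step in seq_len(steps)) {
    grads <- NULL
    total <- 0
    for (sample in samples) {
      fw <- net_forward_tape(net, sample$x1, sample$x2)
      probs <- softmax_classes(fw$logits$value)
      loss <- focal_loss(probs, sample$target, loss_params)
      if (!is.finite(loss))
        stop("non-finite training loss at step ", step, call. = FALSE)
      total <- total + loss
      gl <- focal_loss_grad_logits(probs, sample$target, loss_params)
      tape_backward(fw$tape, fw$logits, gl)
      if (is.null(grads)) grads <- setNames(vector("list", length(pn)), pn)
      for (nm in pn) {
        node <- if (exists(nm, envir = fw$pnodes, inherits = FALSE))
          get(nm, envir = fw$pnodes, inherits = FALSE) else NULL
        if (is.null(node) || is.null(node$grad)) next
        grads[[nm]] <- if (is.null(grads[[nm]])) node$grad else grads[[nm]] + node$grad
      }
    }
    nb <- length(samples)
    t_adam <- t0 + step
    for (nm in pn) {
      g <- grads[[nm]]
      if (is.null(g)) next
      g <- g / nb
      m[[nm]] <- betas[1] * m[[nm]] + (1 - betas[1]) * g
      v[[nm]] <- betas[2] * v[[nm]] + (1 - betas[2]) * g^2
      mhat <- m[[nm]] / (1 - betas[1]^t_adam)
      vhat <- v[[nm]] / (1 - betas[2]^t_adam)
      net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    vl <- NA_real_
    stop_now <- FALSE
    if (!is.null(val_samples) && step %% val_every == 0) {
      vl <- mean(vapply(val_samples, function(s) net_loss(net, s, loss_params),
                        numeric(1)))
      if (vl <= es$best) best_params <- net$params
      stop_now <- es$update(vl)
    }
    log <- rbind(log, data.frame(step = step, loss = total / nb, val_loss = vl))
    if (verbose && (step %% 10 == 0 || step == 1)) {
      message(sprintf("step %4d  loss %.5f  val %.5f", step, total / nb, vl))
    }
    if (stop_now) break
  }
  if (!is.null(best_params)) net$params <- best_params
  net$opt <- list(m = m, v = v, t = t0 + nrow(log))
  net$log <- log
  net$loss_params <- loss_params
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a network checkpoint
#'
#' The checkpoint stores the configuration and all weights.
#'
#' @param net a `recon_net`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, params = net$params, log = net$log,
               opt = net$opt), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- net_init(ck$cfg)
  net$params <- ck$params
  net$log <- ck$log
  net$opt <- ck$opt
  net
}

#' Experiment configuration for the variant comparison
#'
#' Three variants are supported: `"base"` (2 output classes, no
#' auxiliary), `"aux"` (3 classes, auxiliary fracture-gap class), and
#' `"fracaug"` (3 classes plus fractural augmentation of the training
#' folds).
#'
#' @param variant one of `"base"`, `"aux"`, `"fracaug"`.
#' @param net a [network_config]; its `classes` field is forced by the
#'   variant (2 for base, 3 otherwise).
#' @param n_phantoms cohort size (intact phantoms generated; half are then
#'   fractured to build the nondisplaced stratum).
#' @param frac_fraction fraction of the cohort turned into nondisplaced
#'   fracture samples (default 0.5).
#' @param folds cross-validation folds (2 for a simple split, 5 for the
#'   full protocol).
#' @param steps,lr,patience,val_every training settings per fold.
#' @param augment_per_intact extra augmented samples manufactured per
#'   intact training sample for the `"fracaug"` variant.
#' @param ao_codes AO locations sampled by the augmentation.
#' @param aux_radius auxiliary-class dilation radius.
#' @param seed global experiment seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(variant = c("fracaug", "aux", "base"),
                              net = network_config(levels = 3, extent = 16,
                                                   classes = 3),
                              n_phantoms = 12, frac_fraction = 0.5, folds = 2,
                              steps = 60, lr = 2e-3, patience = 10,
                              val_every = 10, augment_per_intact = 1,
                              ao_codes = c("31A", "31B", "31C", "32"),
                              aux_radius = 2, seed = 1L) {
  variant <- match.arg(variant)
  net$classes <- if (variant == "base") 2L else 3L
  structure(list(variant = variant, net = net, n_phantoms = n_phantoms,
                 frac_fraction = frac_fraction, folds = folds, steps = steps,
                 lr = lr, patience = patience, val_every = val_every,
                 augment_per_intact = augment_per_intact, ao_codes = ao_codes,
                 aux_radius = aux_radius, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Build a mixed intact / fractured phantom cohort
#'
#' Generates intact phantoms and converts a fraction of them into
#' nondisplaced fracture samples with the augmentation engine, so every
#' downstream stage has ground-truth fragments for both strata.
#'
#' @param n number of phantoms.
#' @param extent grid extent (voxels).
#' @param frac_fraction fraction fractured.
#' @param ao_codes AO codes sampled for the fractures.
#' @param seed cohort seed.
#' @return list of samples `list(volume, fragments, type_tag, id, seed)`.
#' @export
build_cohort <- function(n, extent = 16, frac_fraction = 0.5,
                         ao_codes = c("31A", "31B", "31C", "32"), seed = 1L) {
  cohort <- make_cohort(n, extent = extent, seed = seed)
  n_frac <- round(n * frac_fraction)
  if (n_frac > 0) {
    frac_idx <- with_seed(derive_seed(seed, 7L), sample.int(n, n_frac))
    for (i in frac_idx) {
      s <- cohort[[i]]
      regions <- region_map(phantom_params(extent = extent, seed = s$seed))
      aug <- augment_sample(s$volume, s$fragments, ao_codes, regions,
                            seed = derive_seed(seed, 100L + i))
      cohort[[i]]$volume <- aug$volume
      cohort[[i]]$fragments <- aug$fragments
      cohort[[i]]$type_tag <- aug$type_tag
      cohort[[i]]$ao <- aug$ao
    }
  }
  cohort
}

#' Run a cross-validated reconstruction experiment
#'
#' Builds (or receives) a phantom cohort, assigns stratified folds, trains
#' the configured variant on each training portion (with one training-fold
#' sample held out per round for early stopping) and evaluates IoU/ASSD on
#' the test fold. The `"fracaug"` variant additionally augments intact
#' training samples into nondisplaced fracture samples before training.
#'
#' @param cfg an [experiment_config].
#' @param cohort optional pre-built cohort from [build_cohort] (so several
#'   variants can share identical data).
#' @param rotational_errors numeric vector of inter-view errors (degrees)
#'   at which the test folds are additionally evaluated (0 = the standard
#'   protocol; further entries reproduce the misalignment sweep).
#' @return an `experiment_result`: list with `eval` (an `eval_result` over
#'   all test folds at error 0), `fold_means` (per-fold mean IoU/ASSD),
#'   `rotational` (data.frame of metrics per rotational error, if
#'   requested), `folds`, and `cfg`.
#' @export
run_experiment <- function(cfg, cohort = NULL, rotational_errors = 0) {
  if (is.null(cohort)) {
    cohort <- build_cohort(cfg$n_phantoms, cfg$net$extent, cfg$frac_fraction,
                           cfg$ao_codes, seed = cfg$seed)
  }
  tags <- vapply(cohort, `[[`, character(1), "type_tag")
  folds <- stratified_kfold(tags, k = cfg$folds, seed = derive_seed(cfg$seed, 11L))
  classes <- cfg$net$classes
  preds <- list(); gts <- list(); ptags <- character(0)
  fold_rows <- list()
  rot_rows <- list()
  for (fold in seq_len(cfg$folds)) {
    train_idx <- which(folds != fold)
    test_idx <- which(folds == fold)
    train_set <- cohort[train_idx]
    if (cfg$variant == "fracaug") {
      intacts <- Filter(function(s) s$type_tag == "intact", train_set)
      extra <- list()
      for (j in seq_along(intacts)) {
        for (rpt in seq_len(cfg$augment_per_intact)) {
          s <- intacts[[j]]
          regions <- region_map(phantom_params(extent = cfg$net$extent,
                                               seed = s$seed))
          aug <- augment_sample(s$volume, s$fragments, cfg$ao_codes, regions,
                                seed = derive_seed(cfg$seed, 1000L + fold * 100L +
                                                     j * 10L + rpt))
          extra[[length(extra) + 1L]] <- list(volume = aug$volume,
                                              fragments = aug$fragments,
                                              type_tag = aug$type_tag)
        }
      }
      train_set <- c(train_set, extra)
    }
    prepared <- lapply(train_set, function(s) {
      prepare_sample(s$volume, s$fragments, classes, cfg$aux_radius)
    })
    # hold one training sample out per round for early stopping
    val_i <- with_seed(derive_seed(cfg$seed, 20L + fold),
                       sample.int(length(prepared), 1))
    net <- net_init(cfg$net)
    net_train(net, prepared[-val_i], steps = cfg$steps, lr = cfg$lr,
              val_samples = prepared[val_i], val_every = cfg$val_every,
              patience = cfg$patience)
    fold_pred <- list(); fold_gt <- list(); fold_tags <- character(0)
    for (i in test_idx) {
      s <- cohort[[i]]
      gt <- prepare_sample(s$volume, s$fragments, classes, cfg$aux_radius)
      for (err in rotational_errors) {
        pair <- judet_pair(s$volume, err)
        inf <- net_infer(net, pair$x1, pair$x2, spacing = s$volume$spacing)
        if (err == rotational_errors[1]) {
          preds[[length(preds) + 1L]] <- inf$labels
          gts[[length(gts) + 1L]] <- gt$labels
          ptags <- c(ptags, s$type_tag)
          fold_pred[[length(fold_pred) + 1L]] <- inf$labels
          fold_gt[[length(fold_gt) + 1L]] <- gt$labels
          fold_tags <- c(fold_tags, s$type_tag)
        }
        rot_rows[[length(rot_rows) + 1L]] <- data.frame(
          fold = fold, id = s$id, type = s$type_tag, error_deg = err,
          iou = iou(inf$labels, gt$labels),
          assd = assd(inf$labels, gt$labels))
      }
    }
    fe <- evaluate_cohort(fold_pred, fold_gt, fold_tags)
    fold_rows[[fold]] <- data.frame(fold = fold,
                                    iou = mean(fe$per_sample$iou),
                                    assd = mean(fe$per_sample$assd))
  }
  structure(list(eval = evaluate_cohort(preds, gts, ptags),
                 fold_means = do.call(rbind, fold_rows),
                 rotational = do.call(rbind, rot_rows),
                 folds = folds, cfg = cfg),
            class = "experiment_result")
}

#' Compare two experiment variants with a paired t-test on fold means
#'
#' @param res_a,res_b `experiment_result`s run on the same cohort and fold
#'   assignment.
#' @param metric `"iou"` or `"assd"`.
#' @return the [paired_ttest] result.
#' @export
compare_variants <- function(res_a, res_b, metric = c("iou", "assd")) {
  metric <- match.arg(metric)
  paired_ttest(res_a$fold_means[[metric]], res_b$fold_means[[metric]])
}
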
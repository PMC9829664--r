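test_that("stratified folds are balanced, deterministic and validated", {
  tags <- rep(c("intact", "nondisplaced"), each = 10)
  f <- stratified_kfold(tags, k = 5, seed = 1)
  for (fold in 1:5) {
    expect_equal(sum(f == fold & tags == "intact"), 2)
    expect_equal(sum(f == fold & tags == "nondisplaced"), 2)
  }
  # pigeonhole: per-type fold counts differ by at most 1 for awkward n
  tags2 <- c(rep("a", 7), rep("b", 11))
  f2 <- stratified_kfold(tags2, k = 3, seed = 2)
  for (tt in c("a", "b")) {
    counts <- table(factor(f2[tags2 == tt], levels = 1:3))
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(stratified_kfold(tags, 5, seed = 9),
                   stratified_kfold(tags, 5, seed = 9))
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2), "at least k")
})

test_that("early stopping triggers exactly at patience exhaustion", {
  # scripted validation sequence: improves until step 3, then plateaus
  vals <- c(1.0, 0.8, 0.6, 0.61, 0.62, 0.6, 0.65, 0.7, 0.71, 0.72)
  es <- early_stopper(patience = 4)
  stopped_at <- NA
  for (i in seq_along(vals)) {
    if (es$update(vals[i])) { stopped_at <- i; break }
  }
  # non-improving evaluations are 4, 5, 6 (ties don't improve), 7 -> stop at 7
  expect_equal(stopped_at, 7)
  expect_equal(es$best, 0.6)
  expect_equal(es$best_index, 3)
})

test_that("prepare_sample builds class-consistent targets and views", {
  p <- phantom_params(extent = 16, seed = 2)
  ph <- make_phantom(p)
  s2 <- prepare_sample(ph$volume, ph$fragments, classes = 2)
  expect_true(all(s2$target %in% 0:1))
  expect_equal(dim(s2$x1), c(16, 16))
  aug <- augment_sample(ph$volume, ph$fragments, c("31A", "31B", "32"),
                        region_map(p), seed = 1)
  s3 <- prepare_sample(aug$volume, aug$fragments, classes = 3)
  expect_true(any(s3$target == 2L))
})

test_that("a tiny training run decreases the loss and logs every step", {
  p <- phantom_params(extent = 16, seed = 3)
  ph <- make_phantom(p)
  s <- prepare_sample(ph$volume, ph$fragments, classes = 2)
  cfg <- network_config(levels = 3, extent = 16, growth = 2, stem = 4,
                        c3d = 1, c_up = 2, c_fuse = 4, c_up3d = 2,
                        n_fuse = 1, classes = 2, seed = 3)
  net <- net_init(cfg)
  net <- net_train(net, list(s), steps = 30, lr = 3e-3)
  expect_equal(nrow(net$log), 30)
  expect_equal(net$log$step, 1:30)
  expect_true(all(is.finite(net$log$loss)))
  expect_lt(mean(tail(net$log$loss, 5)), mean(head(net$log$loss, 5)))
})

test_that("checkpoints round-trip and training resumes deterministically", {
  p <- phantom_params(extent = 16, seed = 4)
  ph <- make_phantom(p)
  s <- prepare_sample(ph$volume, ph$fragments, classes = 2)
  cfg <- network_config(levels = 3, extent = 16, growth = 2, stem = 2,
                        c3d = 1, c_up = 2, c_fuse = 2, c_up3d = 2,
                        n_fuse = 1, classes = 2, seed = 5)
  netA <- net_train(net_init(cfg), list(s), steps = 10, lr = 1e-3)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(netA, tmp)
  netB <- load_checkpoint(tmp)
  expect_identical(netA$params, netB$params)
  expect_identical(net_forward(netA, s$x1, s$x2), net_forward(netB, s$x1, s$x2))
  # resuming reproduces the continued-run losses (Adam state persisted)
  netC <- net_train(net_init(cfg), list(s), steps = 20, lr = 1e-3)
  netB <- net_train(netB, list(s), steps = 10, lr = 1e-3)
  expect_equal(netB$log$loss, tail(netC$log$loss, 10), tolerance = 1e-10)
})

test_that("early stopping restores the best-validation snapshot in training", {
  p <- phantom_params(extent = 16, seed = 6)
  ph <- make_phantom(p)
  s <- prepare_sample(ph$volume, ph$fragments, classes = 2)
  cfg <- network_config(levels = 3, extent = 16, growth = 2, stem = 2,
                        c3d = 1, c_up = 2, c_fuse = 2, c_up3d = 2,
                        n_fuse = 1, classes = 2, seed = 6)
  net <- net_train(net_init(cfg), list(s), steps = 40, lr = 5e-3,
                   val_samples = list(s), val_every = 5, patience = 2)
  expect_true(any(!is.na(net$log$val_loss)))
})

test_that("experiment configs enforce the variant contract", {
  e_base <- experiment_config("base")
  expect_equal(e_base$net$classes, 2L)
  e_aux <- experiment_config("aux")
  expect_equal(e_aux$net$classes, 3L)
  e_fa <- experiment_config("fracaug")
  expect_equal(e_fa$net$classes, 3L)
})

test_that("cohorts mix intact and nondisplaced strata reproducibly", {
  co <- build_cohort(6, extent = 16, frac_fraction = 0.5, seed = 2)
  tags <- vapply(co, `[[`, character(1), "type_tag")
  expect_equal(sum(tags == "nondisplaced"), 3)
  expect_equal(sum(tags == "intact"), 3)
  co2 <- build_cohort(6, extent = 16, frac_fraction = 0.5, seed = 2)
  expect_identical(vapply(co2, `[[`, character(1), "type_tag"), tags)
  expect_identical(co[[1]]$volume$data, co2[[1]]$volume$data)
  for (s in co[tags == "nondisplaced"]) expect_gte(s$fragments$n, 2)
})
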
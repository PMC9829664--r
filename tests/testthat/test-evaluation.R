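test_that("IoU matches direct counts and the merging convention", {
  d <- c(6, 6, 6)
  a <- binary_mask(cube_mask(d, c(2, 2, 2), c(3, 3, 3)))
  expect_equal(iou(a, a), 1)
  b <- binary_mask(cube_mask(d, c(5, 5, 5), c(6, 6, 6)))
  expect_equal(iou(a, b), 0)
  # 2x2x2 cube against itself shifted by one voxel: overlap 4, union 12
  shifted <- binary_mask(cube_mask(d, c(3, 2, 2), c(4, 3, 3)))
  expect_equal(iou(a, shifted), 1 / 3)
  # auxiliary class merges into background on both sides
  la <- array(0L, d); la[2:3, 2:3, 2:3] <- 1L; la[5, 5, 5] <- 2L
  lb <- array(0L, d); lb[2:3, 2:3, 2:3] <- 1L; lb[1, 1, 1] <- 2L
  expect_equal(iou(label_volume(la), label_volume(lb)), 1)
  # both empty is perfect agreement
  e <- binary_mask(array(FALSE, d))
  expect_equal(iou(e, e), 1)
  expect_error(iou(a, binary_mask(array(TRUE, c(5, 5, 5)))), "extents")
})

test_that("surface extraction finds face-boundary voxels", {
  d <- c(7, 7, 7)
  cube3 <- binary_mask(cube_mask(d, c(3, 3, 3), c(5, 5, 5)))
  s <- extract_surface(cube3)
  expect_equal(nrow(s), 26)  # 27 voxels minus 1 interior
  single <- binary_mask(cube_mask(d, c(4, 4, 4), c(4, 4, 4)))
  expect_equal(nrow(extract_surface(single)), 1)
  plane <- binary_mask(cube_mask(d, c(1, 1, 4), c(7, 7, 4)))
  expect_equal(nrow(extract_surface(plane)), 49)
  # grid boundary counts as outside
  full <- binary_mask(array(TRUE, c(3, 3, 3)))
  expect_equal(nrow(extract_surface(full)), 26)
  expect_error(extract_surface(binary_mask(array(FALSE, d))), "empty")
})

test_that("ASSD matches the exhaustive all-pairs oracle", {
  d <- c(8, 8, 8)
  a <- binary_mask(cube_mask(d, c(3, 3, 3), c(4, 4, 4)))
  expect_equal(assd(a, a), 0)
  shifted <- binary_mask(cube_mask(d, c(4, 3, 3), c(5, 4, 4)))
  expect_equal(assd(a, shifted),
               oracle_assd(extract_surface(a), extract_surface(shifted)))
  # linear in spacing
  expect_equal(assd(a, shifted, spacing = 2), 2 * assd(a, shifted, spacing = 1))
  # symmetry and random-mask oracle agreement
  set.seed(9)
  for (i in 1:6) {
    ma <- array(runif(12^3) < 0.08, c(12, 12, 12))
    mb <- array(runif(12^3) < 0.08, c(12, 12, 12))
    if (!any(ma) || !any(mb)) next
    bma <- binary_mask(ma); bmb <- binary_mask(mb)
    expect_equal(assd(bma, bmb), assd(bmb, bma))
    expect_equal(assd(bma, bmb),
                 oracle_assd(extract_surface(bma), extract_surface(bmb)),
                 tolerance = 1e-12)
  }
  expect_error(assd(a, binary_mask(array(FALSE, d))), "empty")
})

test_that("ASSD grows with translation distance for a convex shape", {
  d <- c(16, 8, 8)
  vals <- sapply(0:4, function(k) {
    a <- binary_mask(cube_mask(d, c(2, 3, 3), c(4, 5, 5)))
    b <- binary_mask(cube_mask(d, c(2 + k, 3, 3), c(4 + k, 5, 5)))
    assd(a, b)
  })
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("cohort evaluation aggregates per type with exact identities", {
  d <- c(6, 6, 6)
  mk <- function(lo, hi) label_volume(cube_mask(d, lo, hi) * 1L)
  gt <- mk(c(2, 2, 2), c(4, 4, 4))
  p_same <- gt
  p_shift <- mk(c(3, 2, 2), c(5, 4, 4))
  res <- evaluate_cohort(list(p_same), list(gt), "intact")
  expect_equal(res$summary$iou_mean[res$summary$type == "intact"], 1)
  expect_equal(res$summary$iou_sd, c(0, 0))

  res2 <- evaluate_cohort(list(p_same, p_shift, p_same, p_shift),
                          list(gt, gt, gt, gt),
                          c("intact", "intact", "nondisplaced", "nondisplaced"))
  s <- res2$summary
  expect_equal(s$type, c("intact", "nondisplaced", "overall"))
  # overall mean equals the count-weighted mean of per-type means
  w <- s$n[1:2] / sum(s$n[1:2])
  expect_equal(s$iou_mean[3], sum(w * s$iou_mean[1:2]))
  expect_error(evaluate_cohort(list(p_same), list(gt, gt), "intact"), "lengths")
})

test_that("the paired t-test matches the textbook formula and flags degeneracy", {
  same <- c(0.8, 0.7, 0.9)
  r <- paired_ttest(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)

  r2 <- paired_ttest(c(1, 2, 3), c(0.5, 1.5, 2.5))
  expect_true(is.infinite(r2$t) && r2$t > 0)
  expect_true(r2$degenerate)

  a <- c(0.82, 0.75, 0.91)
  b <- c(0.78, 0.70, 0.84)
  r3 <- paired_ttest(a, b)
  dd <- a - b
  t_hand <- mean(dd) / (sd(dd) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  expect_equal(r3$t, t_hand, tolerance = 1e-12)
  expect_equal(r3$p_value, p_hand, tolerance = 1e-12)
  expect_false(r3$degenerate)
  expect_error(paired_ttest(1:3, 1:4), "lengths")
  expect_error(paired_ttest(1, 2), "two pairs")
})
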
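test_that("spherical structuring elements enumerate integer offsets by norm", {
  e1 <- spherical_element(1)
  expect_equal(nrow(e1$offsets), 7)   # center + 6 face neighbours
  e2 <- spherical_element(2)
  # brute-force enumeration of integer triples with x^2+y^2+z^2 <= 4
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  expect_equal(nrow(e2$offsets), sum(rowSums(g^2) <= 4))
  expect_equal(nrow(e2$offsets), 33)
  # symmetric under negation, contains zero
  key <- function(m) unname(sort(apply(m, 1, paste, collapse = ",")))
  expect_equal(key(e2$offsets), key(-e2$offsets))
  expect_true(any(rowSums(abs(e2$offsets)) == 0))
  expect_error(spherical_element(0), "radius")
})

test_that("dilation is extensive, monotone and matches the offset oracle", {
  d <- c(9, 9, 9)
  empty <- binary_mask(array(FALSE, d))
  expect_false(any(dilate(empty, spherical_element(2))$data))

  center <- array(FALSE, d); center[5, 5, 5] <- TRUE
  out <- dilate(binary_mask(center), spherical_element(2))
  expect_equal(sum(out$data), 33)
  expect_equal(out$data, oracle_dilate(center, 2))

  set.seed(2)
  a <- array(runif(prod(d)) < 0.05, d)
  b <- a; b[sample(prod(d), 10)] <- TRUE  # a subset of b
  da <- dilate(binary_mask(a), spherical_element(2))$data
  db <- dilate(binary_mask(b), spherical_element(2))$data
  expect_true(all(a[da == FALSE] == FALSE))      # extensive: a subset dilate(a)
  expect_true(all(da[a]))                        # contains input
  expect_true(all(db[da]))                       # monotone
  expect_equal(da, oracle_dilate(a, 2))
})

test_that("auxiliary synthesis matches the literal set-arithmetic oracle", {
  # intact: no fragment pairs, empty auxiliary
  solid <- fragment_set(list(binary_mask(cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6)))))
  expect_false(any(synthesize_auxiliary(solid, 2)$data))

  # two 3x3x3 cubes with a 1-voxel planar gap
  d <- c(9, 9, 9)
  a <- cube_mask(d, c(1, 4, 4), c(3, 6, 6))
  b <- cube_mask(d, c(5, 4, 4), c(7, 6, 6))
  fs <- fragment_set(list(binary_mask(a), binary_mask(b)))
  got <- synthesize_auxiliary(fs, 2)$data
  expect_equal(got, oracle_auxiliary(list(a, b), 2))
  # the mid-plane voxels between the facing faces are all marked
  expect_true(all(got[4, 4:6, 4:6]))
  expect_false(any(got & (a | b)))

  # gap of 5 voxels: dilations by 2 cannot meet
  b_far <- cube_mask(c(13, 9, 9), c(9, 4, 4), c(11, 6, 6))
  a_far <- cube_mask(c(13, 9, 9), c(1, 4, 4), c(3, 6, 6))
  fs_far <- fragment_set(list(binary_mask(a_far), binary_mask(b_far)))
  expect_false(any(synthesize_auxiliary(fs_far, 2)$data))

  # three collinear fragments with 1-voxel gaps: both gap planes marked
  d3 <- c(11, 7, 7)
  f1 <- cube_mask(d3, c(1, 3, 3), c(3, 5, 5))
  f2 <- cube_mask(d3, c(5, 3, 3), c(7, 5, 5))
  f3 <- cube_mask(d3, c(9, 3, 3), c(11, 5, 5))
  fs3 <- fragment_set(lapply(list(f1, f2, f3), binary_mask))
  got3 <- synthesize_auxiliary(fs3, 2)$data
  expect_equal(got3, oracle_auxiliary(list(f1, f2, f3), 2))
  expect_true(all(got3[4, 3:5, 3:5]))
  expect_true(all(got3[8, 3:5, 3:5]))
})

test_that("auxiliary mask is symmetric in fragment order and monotone in r", {
  arrs <- random_fragment_arrays(c(12, 12, 12), n_blobs = 4, seed = 5)
  if (length(arrs) >= 2) {
    fs <- fragment_set(lapply(arrs, binary_mask))
    fs_perm <- fragment_set(lapply(rev(arrs), binary_mask))
    m1 <- synthesize_auxiliary(fs, 2)$data
    expect_identical(m1, synthesize_auxiliary(fs_perm, 2)$data)
    m_r1 <- synthesize_auxiliary(fs, 1)$data
    m_r3 <- synthesize_auxiliary(fs, 3)$data
    expect_true(all(m1[m_r1]))   # m_f(1) subset of m_f(2)
    expect_true(all(m_r3[m1]))   # m_f(2) subset of m_f(3)
  }
})

test_that("label volumes conserve class counts and reject aux/bone overlap", {
  d <- c(9, 9, 9)
  a <- cube_mask(d, c(1, 4, 4), c(3, 6, 6))
  b <- cube_mask(d, c(5, 4, 4), c(7, 6, 6))
  fs <- fragment_set(list(binary_mask(a), binary_mask(b)))
  aux <- synthesize_auxiliary(fs, 2)
  lab <- build_labels(fs, aux)
  expect_equal(sum(lab$data == 1), sum(a) + sum(b))
  expect_equal(sum(lab$data == 2), sum(aux$data))
  expect_setequal(unique(as.vector(lab$data)), c(0L, 1L, 2L))

  lab2 <- build_labels(fs, NULL)
  expect_setequal(unique(as.vector(lab2$data)), c(0L, 1L))

  bad <- binary_mask(a)  # overlaps fragment 1
  expect_error(build_labels(fs, bad), "overlap")
})

test_that("fractured phantom labels show background >> bone >> auxiliary", {
  p <- phantom_params(extent = 32, seed = 6)
  ph <- make_phantom(p)
  aug <- augment_sample(ph$volume, ph$fragments, "31B", region_map(p), seed = 2)
  aux <- synthesize_auxiliary(aug$fragments, 2)
  lab <- build_labels(aug$fragments, aux)
  counts <- tabulate(lab$data + 1L, 3)
  expect_gt(counts[1], 10 * counts[2])  # background dominates bone
  expect_gt(counts[2], counts[3])       # bone dominates auxiliary
  expect_gt(counts[3], 0)
})
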
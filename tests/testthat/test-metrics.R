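block_mask <- function(dim3 = c(8, 8, 8), from = 3, to = 4, shift = c(0, 0, 0),
                       spacing = 2) {
  v <- array(FALSE, dim3)
  v[(from:to) + shift[1], (from:to) + shift[2], (from:to) + shift[3]] <- TRUE
  binary_mask(v, spacing)
}

test_that("dice handles the identity, disjoint and half-overlap cases", {
  a <- block_mask()
  expect_equal(dice(a, a), 1)

  b <- block_mask(shift = c(4, 0, 0))
  expect_equal(dice(a, b), 0)

  # 2x2x2 blocks shifted by one voxel: |A| = |B| = 8, intersection 4
  s <- block_mask(shift = c(1, 0, 0))
  expect_equal(dice(a, s), 0.5)
  expect_equal(dice(s, a), dice(a, s))
})

test_that("dice is spacing-invariant and errors on invalid input", {
  v <- array(FALSE, c(6, 6, 6)); v[2:4, 2:3, 2:5] <- TRUE
  w <- array(FALSE, c(6, 6, 6)); w[3:5, 2:4, 3:5] <- TRUE
  expect_equal(dice(binary_mask(v, 1), binary_mask(w, 1)),
               dice(binary_mask(v, c(2, 3.5, 1)), binary_mask(w, c(2, 3.5, 1))))

  expect_error(dice(binary_mask(v, 1), binary_mask(w, 2)), "spacing")
  expect_error(dice(binary_mask(v, 1), binary_mask(w[1:5, , ], 1)), "shape")
  e <- binary_mask(array(FALSE, c(6, 6, 6)), 1)
  expect_error(dice(e, e), "empty")
})

test_that("hd95 reproduces hand-computable distances", {
  a <- block_mask()
  expect_equal(hd95(a, a), 0)

  # two single voxels 7 mm apart: every directed distance is 7
  v1 <- array(FALSE, c(6, 6, 6)); v1[2, 2, 2] <- TRUE
  v2 <- array(FALSE, c(6, 6, 6)); v2[2, 2, 4] <- TRUE
  m1 <- binary_mask(v1, c(1, 1, 3.5)); m2 <- binary_mask(v2, c(1, 1, 3.5))
  expect_equal(hd95(m1, m2), 7)
  expect_equal(hd95(m2, m1), 7)

  e <- binary_mask(array(FALSE, c(8, 8, 8)), 2)
  expect_error(hd95(a, e), "empty")
})

test_that("hd95 equals the all-pairs brute-force oracle on random blobs", {
  set.seed(202)
  for (i in 1:12) {
    p <- random_blob_pair()
    expect_equal(hd95(p$a, p$b), bf_hd(p$a, p$b), tolerance = 1e-9)
    expect_equal(hd95(p$a, p$b), hd95(p$b, p$a), tolerance = 1e-12)
  }
})

test_that("hd95 scales linearly with spacing and is bounded by the max Hausdorff", {
  set.seed(303)
  for (i in 1:5) {
    p <- random_blob_pair(max_dim = 20L)
    h1 <- hd95(p$a, p$b)
    a2 <- binary_mask(p$a$voxels, 3 * p$a$spacing_mm)
    b2 <- binary_mask(p$b$voxels, 3 * p$b$spacing_mm)
    expect_equal(hd95(a2, b2), 3 * h1, tolerance = 1e-9)
    expect_lte(h1, hd95(p$a, p$b, probs = 1) + 1e-12)
  }
})

test_that("restrict_to_region implements the distance-band definition", {
  set.seed(404)
  p <- random_blob_pair(max_dim = 16L)
  mask <- p$a; target <- p$b

  # margin beyond the grid diagonal keeps everything
  diag_mm <- sqrt(sum((dim(mask$voxels) * mask$spacing_mm)^2))
  r <- restrict_to_region(mask, target, margin_mm = diag_mm + 1)
  expect_identical(r$voxels, mask$voxels)

  # margin 0 is the intersection
  r0 <- restrict_to_region(mask, target, margin_mm = 0)
  expect_identical(r0$voxels, mask$voxels & target$voxels)

  # single-voxel target at 2 mm isotropic, margin 4 mm: exhaustive check
  v <- array(FALSE, c(9, 9, 9)); v[5, 5, 5] <- TRUE
  tgt <- binary_mask(v, 2)
  all_mask <- binary_mask(array(TRUE, c(9, 9, 9)), 2)
  r4 <- restrict_to_region(all_mask, tgt, margin_mm = 4)
  idx <- which(array(TRUE, c(9, 9, 9)), arr.ind = TRUE)
  d <- sqrt(colSums((t(idx - 5) * 2)^2))
  expect_identical(as.vector(r4$voxels), d <= 4)

  expect_error(restrict_to_region(mask, binary_mask(array(FALSE, dim(mask$voxels)),
                                                    mask$spacing_mm), 5), "empty")
  expect_error(restrict_to_region(mask, target, -1), ">= 0")
})

test_that("metrics_for_cohort emits one row per record and flags missing ones", {
  recs <- list(
    tiny_record("p01", "obs1", "hp", "prostate", shift = 0L),
    tiny_record("p01", "obs1", "hp", "bowel", missing = TRUE),
    tiny_record("p01", "obs2", "conv", "prostate", shift = 1L))
  expect_message(m <- metrics_for_cohort(recs), "missing")
  expect_equal(nrow(m), 3)
  expect_equal(m$dsc[1], 1)       # ai == corrected
  expect_equal(m$hd95[1], 0)
  expect_true(is.na(m$dsc[2]) && m$missing[2])
  expect_lt(m$dsc[3], 1)          # shifted ai vs corrected
  expect_gt(m$hd95[3], 0)
})
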
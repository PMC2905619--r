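test_that("membership thresholding retains exactly the strict exceedances", {
  expect_identical(select_background_outliers(c(0.9, 0.2, 0.0), 0.5),
                   c(TRUE, FALSE, FALSE))
  grades <- c(0.3, 0.5, 0.500001)
  expect_identical(select_background_outliers(grades, 0.5),
                   c(FALSE, FALSE, TRUE))
  # a vacuously low threshold keeps everything
  expect_true(all(select_background_outliers(runif(50), 1e-12)))
})

test_that("histogram break scan matches the hand-enumerated fixture", {
  full <- c(rep(2, 5), rep(9, 3), rep(10, 2))
  retained <- c(rep(9, 3), rep(10, 2))
  brk <- histogram_break_threshold(full, retained, bin_width = 1)
  expect_equal(brk, 2)
  # segmented voxels are the retained ones strictly above the break bin
  seg <- retained[round(retained) > brk]
  expect_length(seg, 5L)
})

test_that("identical or empty retained sets yield the NO_BREAK sentinel", {
  full <- c(1, 1, 2, 3, 3, 3)
  expect_true(is.na(histogram_break_threshold(full, full)))
  expect_true(is.na(histogram_break_threshold(full, numeric(0))))
})

test_that("the first differing bin from the right wins, not lower ones", {
  full <- c(rep(5, 4), rep(8, 3), rep(12, 2))
  retained <- c(rep(5, 1), rep(8, 3), rep(12, 1)) # differs at 12 already
  expect_equal(histogram_break_threshold(full, retained), 12)
})

test_that("a retained multiset not contained in the full one is an error", {
  expect_error(histogram_break_threshold(c(1, 2, 3), c(3, 3)),
               "sub-multiset")
  expect_error(histogram_break_threshold(c(1, 2, 3), c(9)),
               "sub-multiset")
  expect_error(histogram_break_threshold(c(1, 2), c(1, 1, 2, 2)),
               "sub-multiset")
})

test_that("bin widths other than one are honoured", {
  full <- c(rep(10, 4), rep(20, 3), rep(40, 2))
  retained <- c(rep(20, 3), rep(40, 2))
  expect_equal(histogram_break_threshold(full, retained, bin_width = 10), 10)
})

test_that("a zero-contrast brain yields empty masks in both planes", {
  vol <- uniform_brain(value = 100)
  cfg <- seg_config()
  for (plane in c("axial", "coronal")) {
    mask <- segment_plane(vol, plane, cfg)
    expect_identical(sum(mask), 0L)
    log <- attr(mask, "log")
    expect_identical(nrow(log), dim(vol$data)[plane_axis(plane)])
  }
})

test_that("an implanted bright blob is recovered, matching stage-wise oracles", {
  vol <- uniform_brain(dims = c(20L, 20L, 8L), value = 100)
  # add mild structure so each slice has two tissue values
  blob <- array(FALSE, dim(vol$data))
  blob[9:12, 9:12, 4:5] <- vol$brain_mask[9:12, 9:12, 4:5]
  vol$data[blob] <- 200
  cfg <- seg_config(min_slice_voxels = 20)

  axial <- segment_plane(vol, "axial", cfg)
  coronal <- segment_plane(vol, "coronal", cfg)
  cons <- consensus_segmentation(axial, coronal)
  expect_identical(cons, blob)

  # stage-wise enumeration on the central axial slice
  v <- as.vector(vol$data[, , 4])
  init <- unname(quantile(v, c(0.05, 0.95)))
  oracle <- fcm_oracle(v, m = 2, init = init)
  retained <- oracle$memberships[, 1] > cfg$membership_threshold
  brk <- histogram_break_threshold(v, v[retained])
  manual <- retained & round(v) > brk
  expect_identical(array(manual, c(20, 20)), blob[, , 4])
})

test_that("consensus is the voxelwise intersection", {
  dims <- c(6L, 5L, 4L)
  a <- random_mask(dims, 0.4, seed = 1)
  expect_identical(consensus_segmentation(a, a), a)
  b <- random_mask(dims, 0.4, seed = 2)
  cons <- consensus_segmentation(a, b)
  expect_true(all(cons[a & b]))
  expect_identical(sum(cons & !(a & b)), 0L)
  disjoint <- a & !a
  expect_identical(sum(consensus_segmentation(a, disjoint)), 0L)
  expect_error(consensus_segmentation(a, random_mask(c(6L, 5L, 3L), 0.4)),
               "grid mismatch")
})

test_that("candidate assembly is the union with the removed set", {
  dims <- c(8L, 8L, 2L)
  cons <- array(FALSE, dims); cons[1:10] <- TRUE
  rem <- array(FALSE, dims); rem[7:12] <- TRUE # overlap of 4
  out <- assemble_candidates(cons, rem)
  expect_identical(sum(out), 12L)
  empty <- array(FALSE, dims)
  expect_identical(assemble_candidates(cons, empty), cons)
  expect_identical(sum(assemble_candidates(empty, rem)), sum(rem))
})

test_that("consensus is contained in both plane masks on phantom data", {
  ph <- make_phantom(phantom_spec(dims = c(32L, 32L, 16L), rng_seed = 8L))
  cfg <- seg_config(membership_threshold = 0.05)
  seg <- segment_wmh(ph$volume, cfg)
  cons <- consensus_segmentation(seg$plane_masks$axial,
                                 seg$plane_masks$coronal)
  expect_true(all(seg$plane_masks$axial[cons]))
  expect_true(all(seg$plane_masks$coronal[cons]))
  expect_true(all(seg$wmh[cons]))
})

test_that("first-pass removal restores the two-class balance on loaded slices", {
  # a phantom whose bright voxels are concentrated on three slices with
  # intensities extending far beyond the tissue range
  ph <- make_phantom(phantom_spec(dims = c(40L, 40L, 20L),
                                  bright_fraction = 0, rng_seed = 13L))
  vol <- ph$volume
  set.seed(13)
  bright <- array(FALSE, dim(vol$data))
  for (s in c(8L, 10L, 12L)) {
    idx <- which(vol$brain_mask[, , s])
    take <- sample(idx, round(0.12 * length(idx)))
    sl <- bright[, , s]; sl[take] <- TRUE; bright[, , s] <- sl
  }
  # unambiguously hyperintense: 2.5-5 times the tissue mode
  vol$data[bright] <- sample(300:600, sum(bright), replace = TRUE)

  norm <- normalize_intensity(vol)
  res <- remove_unambiguous(vol, norm, 4.25)
  for (s in c(8L, 10L, 12L)) {
    surviving <- bright[, , s] & !res$removed[, , s]
    frac <- sum(surviving) / sum(vol$brain_mask[, , s])
    expect_lte(frac, 0.06)
  }
})

test_that("tiny slices skip clustering and the consensus discards their noise", {
  ph <- make_phantom(phantom_spec(dims = c(24L, 24L, 12L),
                                  bright_fraction = 0, rng_seed = 3L))
  cfg <- seg_config(membership_threshold = 0.05)
  axial <- segment_plane(ph$volume, "axial", cfg)
  log <- attr(axial, "log")
  small <- log$clustered == 0
  expect_true(any(small)) # polar slices fall under the voxel floor
  expect_identical(sum(log$segmented[small]), 0L)
})
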
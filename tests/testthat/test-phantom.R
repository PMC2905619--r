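test_that("phantom generation is deterministic given its seed", {
  a <- make_phantom(phantom_spec(rng_seed = 77L))
  b <- make_phantom(phantom_spec(rng_seed = 77L))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$nawm_mask, b$nawm_mask)
  c <- make_phantom(phantom_spec(rng_seed = 78L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("phantom structure obeys its spec", {
  ph <- make_phantom(phantom_spec(rng_seed = 5L))
  vol <- ph$volume
  expect_true(all(vol$data[!vol$brain_mask] == 0))
  expect_true(all(ph$nawm_mask[!vol$brain_mask] == FALSE)) # NAWM inside brain
  expect_true(all(ph$base_slices >= 1 &
                  ph$base_slices <= dim(vol$data)[3]))
  # base slices host no pre-existing bright voxels
  for (s in ph$base_slices) {
    expect_lte(max(vol$data[, , s]), 170)
  }
})

test_that("with a zero bright fraction no voxel exceeds the tissue tail", {
  spec <- phantom_spec(bright_fraction = 0, rng_seed = 6L)
  ph <- make_phantom(spec)
  # 6 SDs above the tissue mean bounds the Gaussian tail at this volume size
  expect_lte(max(ph$volume$data), spec$tissue_mean + 6 * spec$tissue_sd)
})

test_that("a default slice histogram is bimodal with a sparse right tail", {
  ph <- make_phantom(phantom_spec(rng_seed = 9L))
  s <- ph$base_slices[2]
  v <- as.vector(ph$volume$data[, , s])
  h <- hist(v, breaks = seq(-0.5, max(v) + 9.5, by = 10), plot = FALSE)
  counts <- h$counts
  # two local maxima (dark background/CSF and tissue) separated by a trough
  dark_peak <- which.max(counts[1:5])
  tissue_region <- 6:length(counts)
  tissue_peak <- tissue_region[which.max(counts[tissue_region])]
  trough <- min(counts[(dark_peak + 1):(tissue_peak - 1)])
  expect_lt(trough, 0.2 * counts[dark_peak])
  expect_lt(trough, 0.2 * counts[tissue_peak])
})

test_that("slice preparation enforces the 2% removal rule", {
  set.seed(15)
  slice <- matrix(0, 30, 30)
  brain <- matrix(FALSE, 30, 30); brain[5:26, 5:26] <- TRUE
  slice[brain] <- rnorm(sum(brain), 100, 5)
  # no voxel above: unchanged
  res <- prepare_base_slice(slice, manual_threshold = 200, brain)
  expect_identical(res$values, slice)
  expect_equal(res$removed_fraction, 0)
  # 0.7% above: accepted, voxels zeroed
  nb <- sum(brain)
  idx <- which(brain)[seq_len(ceiling(0.007 * nb))]
  hot <- slice; hot[idx] <- 500
  res <- prepare_base_slice(hot, manual_threshold = 200, brain)
  expect_lt(res$removed_fraction, 0.02)
  expect_true(all(res$values[idx] == 0))
  # 3% above: rejected
  idx3 <- which(brain)[seq_len(ceiling(0.03 * nb))]
  hot3 <- slice; hot3[idx3] <- 500
  expect_error(prepare_base_slice(hot3, manual_threshold = 200, brain),
               "rejected")
})

test_that("the upper limit is the rightmost bin holding four or more voxels", {
  build <- function(counts) {
    v <- unlist(mapply(rep, as.numeric(names(counts)), counts))
    dims <- c(length(v), 1L, 1L)
    flair_volume(array(v, dims), array(TRUE, dims))
  }
  expect_equal(compute_upper_limit(build(c(`100` = 5, `101` = 3, `102` = 4))), 102)
  expect_equal(compute_upper_limit(build(c(`50` = 1000, `200` = 4))), 200)
  expect_error(compute_upper_limit(build(c(`100` = 3, `101` = 2))),
               "four or more")
})

test_that("insertion replaces exactly the requested voxels within range", {
  ph <- make_phantom(phantom_spec(rng_seed = 12L))
  s <- ph$base_slices[1]
  nb <- sum(ph$volume$brain_mask[, , s])
  ins <- insert_synthetic_wmh(ph$volume, s, ph$nawm_mask,
                              load_percent = 5, site = "top",
                              lower_limit = 150, upper_limit = 260,
                              rng_seed = 4L)
  n <- as.integer(round(0.05 * nb))
  expect_identical(sum(ins$truth), n)
  vals <- ins$volume$data[ins$truth]
  expect_true(all(vals >= 150 & vals <= 260))
  # untouched voxels identical
  expect_identical(ins$volume$data[!ins$truth], ph$volume$data[!ins$truth])
  # truth confined to the slice
  expect_identical(sum(ins$truth[, , -s]), 0L)
  # determinism
  again <- insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 5, "top",
                                150, 260, rng_seed = 4L)
  expect_identical(again$volume$data, ins$volume$data)
  expect_identical(again$truth, ins$truth)
})

test_that("fill sites start from opposite edges and load scales the count", {
  ph <- make_phantom(phantom_spec(rng_seed = 12L))
  s <- ph$base_slices[1]
  top <- insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 2, "top",
                              150, 260, rng_seed = 1L)
  bottom <- insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 2, "bottom",
                                 150, 260, rng_seed = 1L)
  rows_top <- which(top$truth[, , s], arr.ind = TRUE)[, 2]
  rows_bottom <- which(bottom$truth[, , s], arr.ind = TRUE)[, 2]
  expect_gt(min(rows_top), max(rows_bottom) - 1)
  n1 <- sum(insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 1, "top",
                                 150, 260, 1L)$truth)
  n10 <- sum(insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 10, "top",
                                  150, 260, 1L)$truth)
  expect_equal(n10, 10 * n1, tolerance = 0.11) # rounding of 1% counts
})

test_that("impossible insertions are rejected", {
  ph <- make_phantom(phantom_spec(rng_seed = 12L))
  s <- ph$base_slices[1]
  tiny_nawm <- array(FALSE, dim(ph$volume$data))
  tiny_nawm[24, 24, s] <- TRUE
  expect_error(insert_synthetic_wmh(ph$volume, s, tiny_nawm, 10, "top",
                                    150, 260, 1L), "insufficient NAWM")
  expect_error(insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 11, "top",
                                    150, 260, 1L), "load_percent")
  expect_error(insert_synthetic_wmh(ph$volume, s, ph$nawm_mask, 5, "top",
                                    260, 150, 1L), "lower_limit")
})

test_that("fully separated inserted intensities are recovered exactly", {
  spec <- phantom_spec(bright_fraction = 0, rng_seed = 33L)
  # a membership threshold calibrated for these phantom conditions: above the
  # boundary grade of cleaned tissue, below the grade of the inserted floor
  cfg <- seg_config(membership_threshold = 0.05)
  prep <- wmhseg:::prepare_precision_volume(spec, cfg)
  ceiling_all <- max(prep$volume$data, na.rm = TRUE)
  vol <- prep$volume
  truths <- list()
  for (si in seq_along(prep$base_slices)) {
    ins <- insert_synthetic_wmh(vol, prep$base_slices[si], prep$nawm,
                                load_percent = 5, site = "top",
                                lower_limit = ceiling_all + 5,
                                upper_limit = ceiling_all + 60,
                                rng_seed = 40L + si)
    vol <- ins$volume
    truths[[si]] <- ins$truth
  }
  seg <- segment_wmh(vol, cfg)
  for (si in seq_along(prep$base_slices)) {
    s <- prep$base_slices[si]
    rep <- similarity_metrics(seg$wmh[, , s], truths[[si]][, , s])
    expect_equal(rep$si, 1)
  }
})
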
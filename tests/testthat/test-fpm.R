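test_that("FPM1 masks candidates with the thresholded template", {
  dims <- c(8L, 8L, 4L)
  cand <- random_mask(dims, 0.3, seed = 4)
  all_wm <- wm_template(array(1, dims))
  no_wm <- wm_template(array(0, dims))
  expect_identical(fpm1_mask(cand, all_wm), cand)
  expect_identical(sum(fpm1_mask(cand, no_wm)), 0L)

  set.seed(9)
  tmpl <- wm_template(array(runif(prod(dims)), dims))
  out <- fpm1_mask(cand, tmpl, 0.41)
  expect_identical(out, cand & (tmpl$prob >= 0.41))
})

test_that("FPM1 is contractive and monotone in the threshold", {
  dims <- c(10L, 10L, 6L)
  cand <- random_mask(dims, 0.25, seed = 5)
  set.seed(6)
  tmpl <- wm_template(array(runif(prod(dims)), dims))
  prev <- cand
  for (p in seq(0.1, 0.9, by = 0.1)) {
    out <- fpm1_mask(cand, tmpl, p)
    expect_true(all(cand[out]))      # output subset of candidates
    expect_true(all(prev[out]))      # shrinks as p grows
    prev <- out
  }
})

test_that("FPM2 keeps contained components and drops isolated ones", {
  dims <- c(12L, 12L, 6L)
  cand <- array(FALSE, dims)
  cand[2:4, 2:4, 2:3] <- TRUE    # inside the template
  cand[9:11, 9:11, 5:6] <- TRUE  # far from it
  prob <- array(0, dims)
  prob[1:6, 1:6, 1:4] <- 1
  tmpl <- wm_template(prob)
  out <- fpm2_connectivity(cand, tmpl, p2 = 0.63)
  expect_true(all(out[2:4, 2:4, 2:3]))
  expect_identical(sum(out[9:11, 9:11, 5:6]), 0L)
  expect_true(all(cand[out]))
})

test_that("diagonal adjacency counts under 26- but not 6-connectivity", {
  dims <- c(3L, 3L, 3L)
  cand <- array(FALSE, dims); cand[1, 1, 1] <- TRUE
  prob <- array(0, dims); prob[2, 2, 2] <- 1
  tmpl <- wm_template(prob)
  expect_true(adjacent26(c(1, 1, 1), c(2, 2, 2))) # oracle sanity
  expect_identical(sum(fpm2_connectivity(cand, tmpl, 0.63, connectivity = 26)), 1L)
  expect_identical(sum(fpm2_connectivity(cand, tmpl, 0.63, connectivity = 6)), 0L)
})

test_that("FPM2 never splits a connected component", {
  for (seed in 1:4) {
    dims <- c(10L, 10L, 8L)
    cand <- random_mask(dims, 0.12, seed = seed)
    set.seed(seed + 100)
    tmpl <- wm_template(array(runif(prod(dims)) < 0.1, dims) * 1.0)
    out <- fpm2_connectivity(cand, tmpl, p2 = 0.5)
    labels <- label_components(cand, 26)
    for (id in setdiff(unique(as.vector(labels)), 0L)) {
      comp <- labels == id
      kept <- sum(out[comp])
      expect_true(kept == 0L || kept == sum(comp))
    }
    expect_true(all(cand[out]))
  }
})

test_that("a template of ones leaves both strategies as the identity", {
  dims <- c(9L, 9L, 5L)
  cand <- random_mask(dims, 0.2, seed = 12)
  tmpl <- wm_template(array(1, dims))
  expect_identical(fpm1_mask(cand, tmpl, 0.41), cand)
  expect_identical(fpm2_connectivity(cand, tmpl, 0.63), cand)
})

test_that("component labelling matches manual enumeration", {
  dims <- c(5L, 5L, 1L)
  m <- array(FALSE, dims)
  m[1:2, 1, 1] <- TRUE           # component A
  m[4:5, 4:5, 1] <- TRUE         # component B
  m[3, 2, 1] <- TRUE             # touches A diagonally
  lab26 <- label_components(m, 26)
  expect_identical(length(setdiff(unique(as.vector(lab26)), 0L)), 2L)
  expect_identical(lab26[1, 1, 1], lab26[3, 2, 1])
  lab6 <- label_components(m, 6)
  expect_identical(length(setdiff(unique(as.vector(lab6)), 0L)), 3L)
})

test_that("the FPM sweep returns one scored row per threshold", {
  dims <- c(16L, 16L, 8L)
  cand <- random_mask(dims, 0.15, seed = 21)
  ref <- random_mask(dims, 0.15, seed = 22)
  set.seed(23)
  tmpl <- wm_template(array(runif(prod(dims)), dims))
  tab <- sweep_fpm(cand, tmpl, ref, strategy = "fpm1")
  expect_identical(nrow(tab), 7L)
  expect_equal(tab$threshold, 0.41 + 0.04 * (-3:3))
  expect_true(all(tab$pce + tab$pue == 100))
  # stricter thresholds can only reduce false positives
  expect_true(all(diff(tab$fp) <= 0))
})
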
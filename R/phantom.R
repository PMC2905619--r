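#' Phantom specification
#'
#' Describes a FLAIR-like digital phantom: an ellipsoidal "brain" of
#' mid-intensity tissue on a zero (skull-stripped) background, a central
#' dark ellipsoid of CSF-like intensities, an interior normal-appearing
#' white matter (NAWM) compartment available for lesion insertion, and an
#' optional sparse population of pre-existing bright voxels that gives the
#' volume histogram the heavy right tail seen in subjects with white matter
#' disease. A slice histogram therefore shows the two dominant modes (dark
#' background/CSF and brain tissue) that two-class fuzzy clustering relies
#' on, plus a sparse hyperintense tail.
#'
#' A designated set of lesion-free "base" axial slices is reserved for
#' synthetic insertion; pre-existing bright voxels are placed only on the
#' remaining slices, mirroring subjects whose hyperintensities lie on other
#' slices than the ones selected for the precision experiment.
#'
#' Default intensities emulate a bias-corrected 3T FLAIR in arbitrary
#' integer units: tissue around 120 with noise SD 11 (about 9%), CSF/dark
#' structures around 25, and a 2% burden of bright voxels spread uniformly
#' over 150-260 (roughly 1.25-2.2 times the tissue mode).
#'
#' @param dims integer length-3 grid shape.
#' @param tissue_mean,tissue_sd brain tissue intensity distribution.
#' @param csf_mean,csf_sd dark CSF intensity distribution (must stay below
#'   the tissue mean).
#' @param bright_fraction fraction of brain voxels replaced by pre-existing
#'   bright voxels, in `[0, 0.15]`.
#' @param bright_range intensity range (length 2) of pre-existing bright
#'   voxels.
#' @param n_base_slices number of lesion-free axial slices reserved for
#'   insertion, spread around the brain's equator.
#' @param rng_seed integer seed; generation is deterministic given the spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48L, 48L, 28L),
                         tissue_mean = 120, tissue_sd = 11,
                         csf_mean = 25, csf_sd = 6,
                         bright_fraction = 0.02,
                         bright_range = c(150, 260),
                         n_base_slices = 4L,
                         rng_seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 8L),
            tissue_mean > csf_mean, tissue_sd > 0, csf_sd > 0,
            length(bright_range) == 2L, bright_range[1] < bright_range[2],
            n_base_slices >= 1L)
  if (bright_fraction < 0 || bright_fraction > 0.15) {
    stop("'bright_fraction' must lie in [0, 0.15]", call. = FALSE)
  }
  structure(list(dims = as.integer(dims),
                 tissue_mean = tissue_mean, tissue_sd = tissue_sd,
                 csf_mean = csf_mean, csf_sd = csf_sd,
                 bright_fraction = bright_fraction,
                 bright_range = bright_range,
                 n_base_slices = as.integer(n_base_slices),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(dims, semi, centre = (dims + 1) / 2) {
  i <- (seq_len(dims[1]) - centre[1]) / semi[1]
  j <- (seq_len(dims[2]) - centre[2]) / semi[2]
  k <- (seq_len(dims[3]) - centre[3]) / semi[3]
  d2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  m <- d2 <= 1
  attributes(m) <- list(dim = dims)
  m
}

#' Generate a FLAIR-like phantom volume
#'
#' Builds the phantom described by a [phantom_spec()]: the brain is an
#' ellipsoid filling about 80% of the in-plane grid, CSF a smaller central
#' ellipsoid, and NAWM an interior ellipsoid clear of both the brain edge
#' (where cortex would be) and a safety margin around the CSF. Intensities
#' are drawn from the spec's distributions, rounded to integer signal units
#' and floored at zero. Generation is bit-reproducible given the spec's
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [flair_volume()]), `nawm_mask` (logical),
#'   `base_slices` (axial indices of the lesion-free slices) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  brain <- ellipsoid_mask(dims, semi = c(0.42, 0.42, 0.46) * dims)
  csf <- ellipsoid_mask(dims, semi = c(0.10, 0.15, 0.21) * dims)
  nawm <- ellipsoid_mask(dims, semi = c(0.30, 0.30, 0.39) * dims) &
    !ellipsoid_mask(dims, semi = c(0.135, 0.18, 0.27) * dims)
  nawm <- nawm & brain & !csf

  mid <- (dims[3] + 1) / 2
  span <- max(1, round(0.16 * dims[3]))
  base_slices <- unique(round(seq(mid - span, mid + span,
                                  length.out = spec$n_base_slices)))

  data <- with_seed(spec$rng_seed, {
    x <- array(0, dims)
    n_brain <- sum(brain)
    x[brain] <- stats::rnorm(n_brain, spec$tissue_mean, spec$tissue_sd)
    x[csf & brain] <- stats::rnorm(sum(csf & brain), spec$csf_mean, spec$csf_sd)
    n_bright <- round(spec$bright_fraction * n_brain)
    if (n_bright > 0) {
      host <- brain & !csf
      if (length(base_slices)) host[, , base_slices] <- FALSE
      host_idx <- which(host)
      if (n_bright > length(host_idx)) {
        stop("infeasible bright fraction: not enough host voxels", call. = FALSE)
      }
      sel <- sample(host_idx, n_bright)
      lo <- ceiling(spec$bright_range[1]); hi <- floor(spec$bright_range[2])
      x[sel] <- sample(seq.int(lo, hi), n_bright, replace = TRUE)
    }
    x <- round(x)
    x[x < 0] <- 0
    x
  })

  list(volume = flair_volume(data, brain), nawm_mask = nawm & brain,
       base_slices = base_slices, spec = spec)
}

#' Clean a base slice for synthetic insertion
#'
#' Removes (zeroes) every voxel above the slice's manually identified
#' hyperintensity threshold, so the slice is lesion-free before synthetic
#' voxels are added. A slice is usable only if the removal affects less than
#' 2% of its brain voxels; otherwise it is rejected with an error.
#'
#' @param values numeric slice matrix (zero outside the brain).
#' @param manual_threshold intensity above which voxels count as
#'   hyperintense on this slice.
#' @param brain optional logical matrix of slice brain voxels; defaults to
#'   `values > 0`.
#' @return list with `values` (cleaned slice), `removed_fraction` and
#'   `n_removed`.
#' @export
prepare_base_slice <- function(values, manual_threshold, brain = NULL) {
  if (is.null(brain)) brain <- !is.na(values) & values > 0
  if (!sum(brain)) stop("slice has no brain voxels", call. = FALSE)
  removed <- brain & !is.na(values) & values > manual_threshold
  frac <- sum(removed) / sum(brain)
  if (frac >= 0.02) {
    stop(sprintf("slice rejected: %.1f%% of brain voxels exceed the manual threshold (limit 2%%)",
                 100 * frac), call. = FALSE)
  }
  values[removed] <- 0
  list(values = values, removed_fraction = frac, n_removed = sum(removed))
}

#' Upper intensity limit for synthetic hyperintensities
#'
#' Computes the whole-volume intensity histogram at the given bin width and
#' returns the value of the rightmost bin containing four or more voxels.
#' Drawing synthetic values below this limit avoids creating artificial
#' peaks beyond the tail of the real histogram.
#'
#' @param volume a [flair_volume()].
#' @param bin_width histogram bin width in signal intensity units.
#' @return the upper limit (numeric, representative bin value).
#' @export
compute_upper_limit <- function(volume, bin_width = 1) {
  stopifnot(inherits(volume, "flair_volume"), bin_width > 0)
  v <- volume$data[volume$brain_mask & !is.na(volume$data)]
  if (!length(v)) stop("volume is empty", call. = FALSE)
  b <- intensity_bins(v, bin_width)
  counts <- table(b)
  qualifying <- as.integer(names(counts))[counts >= 4]
  if (!length(qualifying)) {
    stop("no histogram bin contains four or more voxels", call. = FALSE)
  }
  max(qualifying) * bin_width
}

#' Insert synthetic hyperintense voxels into a slice
#'
#' Replaces a fixed fraction of one axial slice's brain voxels with
#' synthetic hyperintense values, using NAWM voxels taken in contiguous row
#' order from the top or bottom edge of the slice. Values are drawn
#' uniformly (at integer resolution) from `[lower_limit, upper_limit]`,
#' where the lower limit is the slice's manual hyperintensity threshold and
#' the upper limit comes from [compute_upper_limit()]. The exact set of
#' replaced voxels is returned as the ground-truth mask.
#'
#' @param volume a [flair_volume()] whose base slices have been cleaned.
#' @param slice_index axial slice to modify.
#' @param nawm_mask logical NAWM mask on the volume grid.
#' @param load_percent lesion load as percent of the slice's brain voxels,
#'   in (0, 10].
#' @param site `"top"` or `"bottom"`: edge of the slice from which NAWM
#'   voxels are filled.
#' @param lower_limit,upper_limit intensity range of the synthetic values
#'   (`lower_limit < upper_limit`).
#' @param rng_seed integer seed; insertion is deterministic given the seed.
#' @return list with `volume` (modified [flair_volume()]) and `truth`
#'   (logical mask marking exactly the inserted voxels).
#' @export
insert_synthetic_wmh <- function(volume, slice_index, nawm_mask,
                                 load_percent, site = c("top", "bottom"),
                                 lower_limit, upper_limit, rng_seed = 1L) {
  stopifnot(inherits(volume, "flair_volume"))
  site <- match.arg(site)
  nawm_mask <- as_mask_array(nawm_mask, "nawm_mask")
  check_same_grid(volume$data, nawm_mask, "volume", "nawm_mask")
  if (!isTRUE(load_percent > 0 && load_percent <= 10)) {
    stop("'load_percent' must lie in (0, 10]", call. = FALSE)
  }
  if (!isTRUE(lower_limit < upper_limit)) {
    stop("'lower_limit' must be below 'upper_limit'", call. = FALSE)
  }
  axis <- plane_axis("axial", volume$orientation)
  brain_slice <- extract_slice(volume$brain_mask, axis, slice_index)
  n <- round(load_percent / 100 * sum(brain_slice))
  if (n < 1) stop("requested load amounts to zero voxels", call. = FALSE)

  host <- extract_slice(nawm_mask, axis, slice_index) & brain_slice &
    !is.na(extract_slice(volume$data, axis, slice_index))
  coords <- which(host, arr.ind = TRUE)
  if (nrow(coords) < n) {
    stop(sprintf("insufficient NAWM voxels on slice %d: need %d, have %d",
                 slice_index, n, nrow(coords)), call. = FALSE)
  }
  ord <- if (site == "top") order(-coords[, 2], coords[, 1])
         else order(coords[, 2], coords[, 1])
  chosen <- coords[ord[seq_len(n)], , drop = FALSE]

  lo <- ceiling(lower_limit); hi <- floor(upper_limit)
  new_values <- with_seed(rng_seed,
                          sample(seq.int(lo, hi), n, replace = TRUE))

  slice_vals <- extract_slice(volume$data, axis, slice_index)
  slice_truth <- array(FALSE, dim(slice_vals))
  slice_vals[chosen] <- new_values
  slice_truth[chosen] <- TRUE

  out <- volume
  out$data <- assign_slice(out$data, axis, slice_index, slice_vals)
  truth <- array(FALSE, dim(volume$data))
  truth <- assign_slice(truth, axis, slice_index, slice_truth)
  list(volume = out, truth = truth)
}
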
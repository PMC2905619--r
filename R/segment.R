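#' Segmentation configuration
#'
#' Collects every tunable constant of the pipeline in one place, with the
#' method's defaults. Two thresholds define the method for a given FLAIR
#' acquisition protocol: the z-score cutoff for first-pass removal
#' (`z_threshold`, fixed at 4.25) and the background-CSF membership grade
#' above which a voxel is treated as a class outlier
#' (`membership_threshold`). The membership threshold should be calibrated
#' once on two representative volumes with differing lesion loads (see
#' [calibrate_membership_threshold()]) and then held fixed.
#'
#' @param z_threshold z-score above which voxels are removed first-pass.
#' @param membership_threshold background-CSF membership grade cutoff, in
#'   (0, 1); voxels with a grade strictly above it are retained as class
#'   outliers.
#' @param m fuzzy C-means fuzziness exponent (> 1).
#' @param fcm_tol convergence tolerance on the maximum FCM center change.
#' @param fcm_max_iter FCM iteration cap.
#' @param bin_width histogram bin width in signal intensity units.
#' @param planes the two slice planes whose segmentations are intersected.
#' @param min_slice_voxels slices with fewer nonzero voxels skip clustering
#'   and contribute an empty mask (the two-plane consensus then protects
#'   against misclassification on small slices).
#' @param cluster_full_grid cluster all voxels of each slice (zeros of the
#'   skull-stripped image included, the default) or brain-mask voxels only.
#' @param filter_iterations,filter_time_step,filter_conductance anisotropic
#'   diffusion parameters (see [anisotropic_diffusion_filter()]); set
#'   `filter_iterations = 0` for inputs that are already filtered.
#' @param rng_seed integer seed recorded for provenance; the segmentation
#'   itself is deterministic.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(z_threshold = 4.25,
                       membership_threshold = 0.10,
                       m = 2,
                       fcm_tol = 1e-5,
                       fcm_max_iter = 300,
                       bin_width = 1,
                       planes = c("axial", "coronal"),
                       min_slice_voxels = 50,
                       cluster_full_grid = TRUE,
                       filter_iterations = 5,
                       filter_time_step = 0.0625,
                       filter_conductance = 1.95,
                       rng_seed = 1L) {
  stopifnot(z_threshold > 0, membership_threshold > 0,
            membership_threshold < 1, m > 1, bin_width > 0,
            fcm_tol > 0, fcm_max_iter >= 1, length(planes) == 2L)
  structure(list(
    z_threshold = z_threshold,
    membership_threshold = membership_threshold,
    m = m, fcm_tol = fcm_tol, fcm_max_iter = fcm_max_iter,
    bin_width = bin_width, planes = planes,
    min_slice_voxels = min_slice_voxels,
    cluster_full_grid = cluster_full_grid,
    filter_iterations = filter_iterations,
    filter_time_step = filter_time_step,
    filter_conductance = filter_conductance,
    rng_seed = as.integer(rng_seed)
  ), class = "seg_config")
}

#' Retain background-CSF class outliers
#'
#' Hyperintense voxels are outliers of both fuzzy classes and so carry a
#' nonzero membership grade in the background-CSF class. This step keeps
#' exactly the voxels whose background-CSF grade strictly exceeds the
#' threshold -- the dark background/CSF voxels themselves plus the
#' hyperintense outliers -- discarding the bulk of normal brain tissue.
#'
#' @param grades numeric vector of background-CSF membership grades.
#' @param grade_threshold scalar in (0, 1).
#' @return logical vector marking retained entries.
#' @export
select_background_outliers <- function(grades, grade_threshold) {
  stopifnot(is.numeric(grades),
            grade_threshold > 0, grade_threshold < 1)
  grades > grade_threshold
}

#' Dual-histogram break-point threshold
#'
#' Compares the intensity histogram of all clustered voxels on a slice with
#' the histogram of the retained (membership-thresholded) subset, using a
#' shared binning of width `bin_width` (intensities are rounded to the
#' nearest bin). Scanning bins from the right-hand tail downward, the first
#' bin whose two counts differ is the break: hyperintensities on the slice
#' are the retained voxels in bins strictly above it. If the histograms never
#' differ, or nothing was retained, the slice has no detectable
#' hyperintensities and the `NO_BREAK` sentinel (`NA`) is returned.
#'
#' @param full_values intensities of every clustered voxel on the slice.
#' @param retained_values intensities of the retained subset (must be a
#'   sub-multiset of `full_values`).
#' @param bin_width histogram bin width in signal intensity units.
#' @return the break bin value (numeric), or `NA` for `NO_BREAK`.
#' @export
histogram_break_threshold <- function(full_values, retained_values,
                                      bin_width = 1) {
  stopifnot(bin_width > 0)
  if (length(retained_values) > length(full_values)) {
    stop("retained values are not a sub-multiset of the full slice", call. = FALSE)
  }
  if (length(retained_values) == 0L || length(full_values) == 0L) {
    return(NA_real_)
  }
  fb <- intensity_bins(full_values, bin_width)
  rb <- intensity_bins(retained_values, bin_width)
  rng <- range(fb)
  if (length(rb) && (min(rb) < rng[1] || max(rb) > rng[2])) {
    stop("retained values are not a sub-multiset of the full slice", call. = FALSE)
  }
  bins <- seq.int(rng[1], rng[2])
  nf <- tabulate(fb - rng[1] + 1L, nbins = length(bins))
  nr <- tabulate(rb - rng[1] + 1L, nbins = length(bins))
  if (any(nr > nf)) {
    stop("retained values are not a sub-multiset of the full slice", call. = FALSE)
  }
  differ <- which(nf != nr)
  if (length(differ) == 0L) return(NA_real_)
  bins[max(differ)] * bin_width
}

## integer bin index: bins are width-`bin_width` intervals on a shared
## origin; values are rounded to the nearest bin
intensity_bins <- function(values, bin_width) {
  as.integer(round(values / bin_width))
}

#' Per-plane slice-wise hyperintensity segmentation
#'
#' Runs the per-slice segmentation along one plane: two-class fuzzy C-means
#' on the slice's clustered voxels, membership thresholding of the
#' background-CSF grades, and the dual-histogram break rule. Voxels removed
#' first-pass (marked `NA` in `reduced`) are excluded from clustering and
#' from both histograms. Slices with too few nonzero voxels, or without two
#' distinct values, skip clustering and contribute an empty mask.
#'
#' @param reduced the `reduced` volume from [remove_unambiguous()] (a
#'   [flair_volume()]; `NA` marks excluded voxels).
#' @param plane `"axial"` or `"coronal"`.
#' @param config a [seg_config()].
#' @return logical mask of per-plane hyperintense voxels, with a
#'   `"log"` attribute: one data.frame row per slice (plane, slice index,
#'   clustered/retained/segmented voxel counts, break value or `NA`).
#' @export
segment_plane <- function(reduced, plane, config = seg_config()) {
  stopifnot(inherits(reduced, "flair_volume"), inherits(config, "seg_config"))
  plane <- match.arg(plane, c("axial", "coronal"))
  axis <- plane_axis(plane, reduced$orientation)
  dims <- dim(reduced$data)
  out <- array(FALSE, dims)
  n_slices <- dims[axis]
  log_rows <- vector("list", n_slices)

  for (i in seq_len(n_slices)) {
    vals <- extract_slice(reduced$data, axis, i)
    msk <- extract_slice(reduced$brain_mask, axis, i)
    scope <- if (config$cluster_full_grid) !is.na(vals) else (msk & !is.na(vals))
    v <- vals[scope]
    n_nonzero <- sum(v > 0)
    slice_mask <- array(FALSE, dim(vals))
    brk <- NA_real_
    n_retained <- 0L
    n_seg <- 0L
    clustered <- 0L

    if (n_nonzero >= config$min_slice_voxels && length(unique(v)) >= 2L) {
      clustered <- length(v)
      fit <- fcm_two_class(v, m = config$m, tol = config$fcm_tol,
                           max_iter = config$fcm_max_iter)
      retained <- select_background_outliers(fit$memberships[, "background_csf"],
                                             config$membership_threshold)
      n_retained <- sum(retained)
      brk <- histogram_break_threshold(v, v[retained], config$bin_width)
      if (!is.na(brk)) {
        hyper <- retained &
          intensity_bins(v, config$bin_width) > round(brk / config$bin_width)
        n_seg <- sum(hyper)
        sel <- array(FALSE, dim(vals))
        sel[scope] <- hyper
        slice_mask <- sel
      }
    }
    out <- assign_slice(out, axis, i, slice_mask)
    log_rows[[i]] <- data.frame(plane = plane, slice = i,
                                clustered = clustered,
                                retained = n_retained,
                                break_value = brk,
                                segmented = n_seg)
  }
  attr(out, "log") <- do.call(rbind, log_rows)
  out
}

#' Two-plane consensus segmentation
#'
#' Only voxels classified as hyperintense in both the axial and coronal
#' segmentations are accepted. This removes spurious detections from slices
#' with few voxels (typically small superior axial slices), where two-class
#' clustering is unreliable.
#'
#' @param axial,coronal logical masks on the same grid.
#' @return logical mask, the voxelwise AND.
#' @export
consensus_segmentation <- function(axial, coronal) {
  axial <- as_mask_array(axial, "axial")
  coronal <- as_mask_array(coronal, "coronal")
  check_same_grid(axial, coronal, "axial", "coronal")
  axial & coronal
}

#' Reunite consensus candidates with first-pass removals
#'
#' Voxels removed before clustering were by definition unambiguously
#' hyperintense, so they belong in the final candidate set: the output is
#' the voxelwise OR of the two-plane consensus and the removed set.
#'
#' @param consensus logical consensus mask.
#' @param removed logical mask of first-pass removed voxels.
#' @return logical candidate mask.
#' @export
assemble_candidates <- function(consensus, removed) {
  consensus <- as_mask_array(consensus, "consensus")
  removed <- as_mask_array(removed, "removed")
  check_same_grid(consensus, removed, "consensus", "removed")
  consensus | removed
}

#' WMH candidate segmentation on a prepared volume
#'
#' Convenience wrapper running normalization, first-pass removal, the two
#' per-plane segmentations, the consensus, and the reassembly of removed
#' voxels. Filtering is NOT applied here; see [run_pipeline()] for the full
#' protocol starting from an unfiltered volume.
#'
#' @param filtered a filtered [flair_volume()].
#' @param config a [seg_config()].
#' @return list with `wmh` (logical candidate mask), `removed`,
#'   `plane_masks` (named list), `log` (per-slice data.frame).
#' @export
segment_wmh <- function(filtered, config = seg_config()) {
  norm <- normalize_intensity(filtered)
  rem <- remove_unambiguous(filtered, norm, config$z_threshold)
  plane_masks <- lapply(config$planes, function(p)
    segment_plane(rem$reduced, p, config))
  names(plane_masks) <- config$planes
  consensus <- consensus_segmentation(plane_masks[[1L]], plane_masks[[2L]])
  wmh <- assemble_candidates(consensus, rem$removed)
  logs <- do.call(rbind, lapply(plane_masks, attr, "log"))
  rownames(logs) <- NULL
  list(wmh = wmh, removed = rem$removed, plane_masks = plane_masks, log = logs)
}
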
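#' Intensity normalization to zero mean and unit variance
#'
#' Standardizes the FLAIR intensities to z-scores so that a single
#' hyperintensity cutoff can be applied across subjects and scanners. The
#' mean and variance are computed over the brain mask only (population
#' variance convention, denominator `n`); voxels outside the mask are set to
#' `NA` so they are excluded from all downstream statistics.
#'
#' @param volume a [flair_volume()].
#' @return Object of class `normalized_volume`: list with `data` (z-score
#'   array, `NA` outside the brain mask), `brain_mask`, `center`, `scale`.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "flair_volume"))
  inside <- volume$brain_mask & !is.na(volume$data)
  n <- sum(inside)
  if (n == 0) stop("brain mask is empty", call. = FALSE)
  v <- volume$data[inside]
  mu <- mean(v)
  sigma2 <- sum((v - mu)^2) / n
  if (sigma2 <= 0) {
    stop("zero variance: intensities are constant within the brain mask",
         call. = FALSE)
  }
  z <- array(NA_real_, dim(volume$data))
  z[inside] <- (volume$data[inside] - mu) / sqrt(sigma2)
  structure(
    list(data = z, brain_mask = volume$brain_mask,
         center = mu, scale = sqrt(sigma2)),
    class = "normalized_volume"
  )
}

#' First-pass removal of unambiguously hyperintense voxels
#'
#' Two-class fuzzy C-means assumes two dominant clusters (brain and
#' background-CSF). On slices with heavy lesion load that balance breaks
#' down and lesion volume is underestimated, so voxels that are obviously
#' hyperintense on the normalized image (z-score strictly greater than
#' `z_threshold`, default 4.25) are removed before clustering. The removed
#' set is returned as a mask and is re-united with the clustering candidates
#' by [assemble_candidates()] at the end of the pipeline.
#'
#' The comparison is strict: a voxel at exactly the threshold is kept.
#'
#' @param filtered the filtered [flair_volume()].
#' @param normalized the matching [normalize_intensity()] output.
#' @param z_threshold removal cutoff in z-score units (> 0).
#' @return list with `reduced` (a `flair_volume` whose removed voxels are
#'   set to `NA`, excluding them from clustering and histograms) and
#'   `removed` (logical mask of removed voxels).
#' @export
remove_unambiguous <- function(filtered, normalized, z_threshold = 4.25) {
  stopifnot(inherits(filtered, "flair_volume"),
            inherits(normalized, "normalized_volume"))
  check_same_grid(filtered$data, normalized$data, "filtered", "normalized")
  if (!isTRUE(z_threshold > 0)) stop("'z_threshold' must be > 0", call. = FALSE)
  removed <- !is.na(normalized$data) & normalized$data > z_threshold
  reduced <- filtered
  reduced$data[removed] <- NA_real_
  list(reduced = reduced, removed = removed)
}
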
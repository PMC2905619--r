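#' Voxel-wise similarity between an automatic and a reference mask
#'
#' Computes true-positive, false-positive and false-negative voxel counts
#' and the four derived agreement measures, all relative to the reference
#' (e.g. manual) segmentation:
#' \describe{
#'   \item{SI}{similarity index (Dice), `2*TP / (2*TP + FP + FN)`, in `[0, 1]`.}
#'   \item{PCE}{percent correct estimation, `100*TP / (TP + FN)`.}
#'   \item{PUE}{percent underestimation, `100*FN / (TP + FN)`; PCE + PUE = 100.}
#'   \item{POE}{percent overestimation, `100*FP / (TP + FN)`; may exceed 100
#'     when false positives outnumber the reference volume.}
#' }
#' An empty automatic mask is legal (SI = 0, PCE = 0, PUE = 100, POE = 0);
#' an empty reference leaves every denominator undefined and is an error.
#'
#' @param auto logical automatic mask.
#' @param reference logical reference mask on the same grid (non-empty).
#' @return Object of class `similarity_report`: list with `tp`, `fp`, `fn`,
#'   `si`, `pce`, `pue`, `poe`.
#' @export
similarity_metrics <- function(auto, reference) {
  auto <- as_mask_array(auto, "auto")
  reference <- as_mask_array(reference, "reference")
  check_same_grid(auto, reference, "auto", "reference")
  n_ref <- sum(reference)
  if (n_ref == 0L) {
    stop("reference mask is empty: similarity denominators are undefined",
         call. = FALSE)
  }
  tp <- sum(auto & reference)
  fp <- sum(auto & !reference)
  fn <- n_ref - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    si = 2 * tp / (2 * tp + fp + fn),
    pce = 100 * tp / (tp + fn),
    pue = 100 * fn / (tp + fn),
    poe = 100 * fp / (tp + fn)
  ), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> TP %d FP %d FN %d | SI %.4f PCE %.1f PUE %.1f POE %.1f\n",
              x$tp, x$fp, x$fn, x$si, x$pce, x$pue, x$poe))
  invisible(x)
}

#' Per-slice similarity report
#'
#' Scores the automatic mask against the reference slice by slice along one
#' plane, additionally reporting each slice's reference load as a percent of
#' its brain voxels. Slices with an empty reference get `NA` metrics but a
#' raw false-positive count, so overestimation on lesion-free slices remains
#' visible.
#'
#' @param auto,reference logical masks on the same grid.
#' @param brain_mask optional logical brain mask for the load denominator.
#' @param plane slice plane, `"axial"` (default) or `"coronal"`.
#' @param orientation orientation code of the grid.
#' @return data.frame with columns scope, slice, tp, fp, fn, si, pce, pue,
#'   poe, ref_load_percent.
#' @export
similarity_by_slice <- function(auto, reference, brain_mask = NULL,
                                plane = "axial", orientation = "RAS") {
  auto <- as_mask_array(auto, "auto")
  reference <- as_mask_array(reference, "reference")
  check_same_grid(auto, reference, "auto", "reference")
  axis <- plane_axis(plane, orientation)
  n <- dim(auto)[axis]
  rows <- lapply(seq_len(n), function(i) {
    a <- extract_slice(auto, axis, i)
    r <- extract_slice(reference, axis, i)
    nb <- if (is.null(brain_mask)) NA_integer_ else
      sum(extract_slice(brain_mask, axis, i))
    tp <- sum(a & r); fp <- sum(a & !r); fn <- sum(r) - tp
    if (sum(r) == 0L) {
      data.frame(scope = paste0(plane, "_slice"), slice = i, tp = 0L,
                 fp = fp, fn = 0L, si = NA_real_, pce = NA_real_,
                 pue = NA_real_, poe = NA_real_,
                 ref_load_percent = if (is.na(nb)) NA_real_ else 0)
    } else {
      data.frame(scope = paste0(plane, "_slice"), slice = i, tp = tp,
                 fp = fp, fn = fn,
                 si = 2 * tp / (2 * tp + fp + fn),
                 pce = 100 * tp / (tp + fn),
                 pue = 100 * fn / (tp + fn),
                 poe = 100 * fp / (tp + fn),
                 ref_load_percent = if (is.na(nb) || nb == 0) NA_real_ else
                   100 * sum(r) / nb)
    }
  })
  do.call(rbind, rows)
}
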
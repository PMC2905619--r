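#' Read a FLAIR volume and its brain mask from NIfTI files
#'
#' Accepts plain (`.nii`) and gzipped (`.nii.gz`) NIfTI. The image
#' orientation and voxel spacing are taken from the header; the original
#' header is kept as an attribute so output masks can be written on the same
#' grid and orientation.
#'
#' @param flair_path path to the bias-corrected, skull-stripped FLAIR image.
#' @param mask_path path to the binary brain mask.
#' @return a [flair_volume()] with a `nifti_reference` attribute.
#' @export
read_flair <- function(flair_path, mask_path) {
  img <- RNifti::readNifti(flair_path)
  msk <- RNifti::readNifti(mask_path)
  check_same_grid(unclass(img), unclass(msk), "flair", "brain mask")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) sp <- c(1, 1, 1)
  vol <- flair_volume(array(as.numeric(img), dim(img)),
                      as_mask_array(array(as.numeric(msk), dim(msk)), "brain mask"),
                      voxel_spacing = sp[1:3],
                      orientation = RNifti::orientation(img))
  attr(vol, "nifti_reference") <- img
  vol
}

#' Read a binary mask from a NIfTI file
#'
#' Values must be within `1e-6` of 0 or 1; anything else is an error naming
#' the offending values.
#'
#' @param path NIfTI file path.
#' @param reference optional volume (or array) whose grid the mask must match.
#' @return logical array with a `nifti_reference` attribute.
#' @export
read_mask <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  m <- as_mask_array(array(as.numeric(img), dim(img)), basename(path))
  if (!is.null(reference)) {
    ref_arr <- if (inherits(reference, "flair_volume")) reference$data else reference
    check_same_grid(m, ref_arr, basename(path), "reference")
  }
  attr(m, "nifti_reference") <- img
  m
}

#' Read a white matter probability template from a NIfTI file
#'
#' The template must already be registered and resampled onto the FLAIR grid.
#'
#' @param path NIfTI file path.
#' @param reference optional volume whose grid the template must match.
#' @return a [wm_template()].
#' @export
read_template <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  prob <- array(as.numeric(img), dim(img))
  if (!is.null(reference)) {
    ref_arr <- if (inherits(reference, "flair_volume")) reference$data else reference
    check_same_grid(prob, ref_arr, basename(path), "reference")
  }
  tmpl <- wm_template(prob, orientation = RNifti::orientation(img))
  attr(tmpl, "nifti_reference") <- img
  tmpl
}

#' Write a volume or mask as NIfTI
#'
#' @param x numeric array, logical mask, or [flair_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference optional NIfTI image (or object carrying a
#'   `nifti_reference` attribute) providing header geometry.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, reference = NULL) {
  if (is.null(reference)) reference <- attr(x, "nifti_reference")
  if (inherits(reference, "flair_volume") || !is.null(attr(reference, "nifti_reference"))) {
    reference <- attr(reference, "nifti_reference")
  }
  arr <- if (inherits(x, "flair_volume")) x$data else x
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim(arr))
  } else {
    arr <- array(as.numeric(arr), dim(arr))
  }
  img <- if (is.null(reference)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}
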
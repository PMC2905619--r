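#' FLAIR volume container
#'
#' Bundles a 3D FLAIR intensity array with its binary brain mask and voxel
#' spacing. The pipeline expects the volume to be bias-corrected and
#' skull-stripped upstream, so intensities outside the brain mask are forced
#' to zero on construction. An anatomical orientation code (three letters,
#' e.g. `"RAS"`) records which array axis runs along which body axis; it is
#' used to locate axial and coronal slice planes.
#'
#' @param data numeric 3D array of FLAIR intensities (arbitrary units, >= 0
#'   inside the brain). `NA` entries are only permitted to mark voxels
#'   excluded from clustering (see [remove_unambiguous()]).
#' @param brain_mask logical (or 0/1) 3D array of the same shape marking
#'   brain voxels.
#' @param voxel_spacing positive numeric length-3, voxel edge lengths in mm.
#' @param orientation three-letter orientation code; the default `"RAS"`
#'   means axes run left-to-Right, posterior-to-Anterior, inferior-to-Superior.
#'
#' @return An object of class `flair_volume`: a list with elements `data`,
#'   `brain_mask`, `voxel_spacing`, `orientation`.
#' @export
flair_volume <- function(data, brain_mask,
                         voxel_spacing = c(1, 1, 1),
                         orientation = "RAS") {
  data <- as_volume_array(data, "data")
  brain_mask <- as_mask_array(brain_mask, "brain_mask")
  check_same_grid(data, brain_mask, "data", "brain_mask")
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("'voxel_spacing' must be three strictly positive lengths", call. = FALSE)
  }
  check_orientation(orientation)
  data[!brain_mask & !is.na(data)] <- 0
  structure(
    list(data = data, brain_mask = brain_mask,
         voxel_spacing = as.numeric(voxel_spacing),
         orientation = toupper(orientation)),
    class = "flair_volume"
  )
}

#' @export
print.flair_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flair_volume> %d x %d x %d, %d brain voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], sum(x$brain_mask),
              paste(signif(x$voxel_spacing, 3), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' White matter probability template
#'
#' A probability volume in `[0, 1]` on the same grid as the FLAIR image,
#' typically a population template (e.g. the MNI 152 white matter prior)
#' already affine-registered and resampled into the subject's FLAIR space.
#'
#' @param prob numeric 3D array with values in `[0, 1]`.
#' @param orientation three-letter orientation code (see [flair_volume()]).
#' @return Object of class `wm_template`.
#' @export
wm_template <- function(prob, orientation = "RAS") {
  prob <- as_volume_array(prob, "prob")
  if (anyNA(prob) || any(prob < 0) || any(prob > 1)) {
    stop("template probabilities must lie in [0, 1]", call. = FALSE)
  }
  check_orientation(orientation)
  structure(list(prob = prob, orientation = toupper(orientation)),
            class = "wm_template")
}

## ---- internal helpers -----------------------------------------------------

as_volume_array <- function(x, what) {
  if (is.list(x)) stop(sprintf("'%s' must be an array, not a list", what), call. = FALSE)
  x <- unclass(x)
  if (is.null(dim(x))) stop(sprintf("'%s' must have a dim attribute", what), call. = FALSE)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) {
    stop(sprintf("'%s' must be a 2D or 3D array", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

#' Coerce an array to a binary mask
#'
#' Accepts logical arrays or numeric arrays whose values are within `1e-6`
#' of 0 or 1 (the tolerance absorbs NIfTI scaling round-off). Anything else
#' is rejected with a message naming the offending values.
#'
#' @param x array-like mask.
#' @param what label used in error messages.
#' @return logical array.
#' @export
as_mask_array <- function(x, what = "mask") {
  if (is.logical(x)) {
    m <- unclass(x)
    if (is.null(dim(m))) stop(sprintf("'%s' must have a dim attribute", what), call. = FALSE)
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    if (anyNA(m)) stop(sprintf("'%s' contains NA", what), call. = FALSE)
    attributes(m) <- list(dim = dim(m))
    return(m)
  }
  v <- as_volume_array(x, what)
  if (anyNA(v)) stop(sprintf("'%s' contains NA", what), call. = FALSE)
  bad <- abs(v) > 1e-6 & abs(v - 1) > 1e-6
  if (any(bad)) {
    offenders <- unique(signif(v[bad], 6))
    stop(sprintf("'%s' is not binary; offending values: %s", what,
                 paste(utils::head(offenders, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- v > 0.5
  attributes(m) <- list(dim = dim(v))
  m
}

check_same_grid <- function(a, b, name_a = "x", name_b = "y") {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || any(da != db)) {
    stop(sprintf("grid mismatch: %s is %s but %s is %s",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

check_orientation <- function(orientation) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      nchar(orientation) != 3L) {
    stop("'orientation' must be a three-letter code such as \"RAS\"", call. = FALSE)
  }
  invisible(TRUE)
}

#' Array axis of a slice plane
#'
#' Maps an anatomical slice plane to the array dimension whose index varies
#' across slices of that plane: axial slices are orthogonal to the
#' superior-inferior axis, coronal slices to the anterior-posterior axis.
#'
#' @param plane `"axial"` or `"coronal"`.
#' @param orientation three-letter orientation code of the volume.
#' @return integer axis index in 1..3.
#' @export
plane_axis <- function(plane, orientation = "RAS") {
  plane <- match.arg(plane, c("axial", "coronal"))
  check_orientation(orientation)
  letters3 <- strsplit(toupper(orientation), "")[[1]]
  target <- switch(plane, axial = c("S", "I"), coronal = c("A", "P"))
  ax <- which(letters3 %in% target)
  if (length(ax) != 1L) {
    stop(sprintf("cannot locate the %s plane in orientation '%s'",
                 plane, orientation), call. = FALSE)
  }
  ax
}

## Extract slice i along axis as a matrix (drops the slice axis)
extract_slice <- function(arr, axis, i) {
  switch(axis,
         `1` = arr[i, , , drop = TRUE],
         `2` = arr[, i, , drop = TRUE],
         `3` = arr[, , i, drop = TRUE])
}

## Assign logical slice values back into a 3D array along axis
assign_slice <- function(arr, axis, i, value) {
  if (axis == 1L) arr[i, , ] <- value
  else if (axis == 2L) arr[, i, ] <- value
  else arr[, , i] <- value
  arr
}

## run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
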
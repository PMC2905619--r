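#' Edge-preserving anisotropic diffusion filter
#'
#' Explicit 6-neighbour (face-connected) Perona-Malik diffusion with an
#' exponential conductance function, applied to the masked FLAIR volume
#' before clustering. Diffusion is weighted by the local gradient so strong
#' edges (tissue boundaries, lesion margins) are preserved while noise within
#' homogeneous tissue is attenuated. Boundary handling is Neumann
#' (reflective), which conserves the volume's total intensity.
#'
#' The per-iteration update at voxel \eqn{x} is
#' \deqn{I_{t+1}(x) = I_t(x) + \tau \sum_{d} c(\nabla_d I)\, \nabla_d I,}
#' where the sum runs over the face neighbours, \eqn{\nabla_d I} is the
#' one-sided difference towards neighbour \eqn{d}, and
#' \eqn{c(g) = \exp\{-(g/K)^2\}} with conductance \eqn{K}. The defaults
#' (5 iterations, time step 0.0625, conductance 1.95) give the minimal
#' smoothing recommended for 3D volumes; the explicit scheme is stable for
#' time steps up to 1/6 in 3D.
#'
#' Voxel spacing is ignored by default (unit spacing assumed); set
#' `use_spacing = TRUE` to scale the one-sided differences by the physical
#' spacing.
#'
#' @param volume a [flair_volume()].
#' @param iterations non-negative iteration count; 0 returns the input.
#' @param time_step positive diffusion time step.
#' @param conductance conductance parameter \eqn{K}, in intensity units.
#' @param per_slice if `TRUE`, diffuse within axial slices only (2D);
#'   default is fully 3D.
#' @param use_spacing if `TRUE`, scale gradients by `voxel_spacing`.
#' @return a [flair_volume()] with filtered intensities.
#' @export
anisotropic_diffusion_filter <- function(volume, iterations = 5,
                                         time_step = 0.0625,
                                         conductance = 1.95,
                                         per_slice = FALSE,
                                         use_spacing = FALSE) {
  stopifnot(inherits(volume, "flair_volume"))
  if (iterations < 0) stop("'iterations' must be >= 0", call. = FALSE)
  if (time_step <= 0) stop("'time_step' must be > 0", call. = FALSE)
  img <- volume$data
  if (any(!is.finite(img))) {
    stop("volume contains non-finite intensities", call. = FALSE)
  }
  if (iterations == 0) return(volume)

  axes <- if (per_slice) setdiff(1:3, plane_axis("axial", volume$orientation)) else 1:3
  axes <- axes[dim(img)[axes] > 1L]
  h <- if (use_spacing) volume$voxel_spacing else c(1, 1, 1)
  k2 <- conductance^2

  for (it in seq_len(iterations)) {
    delta <- array(0, dim(img))
    for (ax in axes) {
      fwd <- (shift_array(img, ax, -1L) - img) / h[ax]
      bwd <- (shift_array(img, ax, +1L) - img) / h[ax]
      delta <- delta +
        (exp(-(fwd * fwd) / k2) * fwd + exp(-(bwd * bwd) / k2) * bwd) / h[ax]
    }
    img <- img + time_step * delta
  }
  out <- volume
  out$data <- img
  out$data[!out$brain_mask] <- 0
  out
}

## Shift an array along an axis by one voxel with edge replication, so the
## one-sided difference at the boundary vanishes (Neumann condition).
## by = -1 brings the next-index neighbour to each voxel; by = +1 the previous.
shift_array <- function(arr, axis, by) {
  n <- dim(arr)[axis]
  idx <- if (by < 0) c(seq_len(n - 1L) + 1L, n) else c(1L, seq_len(n - 1L))
  switch(axis,
         `1` = arr[idx, , , drop = FALSE],
         `2` = arr[, idx, , drop = FALSE],
         `3` = arr[, , idx, drop = FALSE])
}
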
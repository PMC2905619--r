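#' False-positive minimization configuration
#'
#' @param strategy `"none"`, `"fpm1"` (mask candidates with the thresholded
#'   white matter template) or `"fpm2"` (keep only candidate components
#'   connected in 3D to the thresholded template).
#' @param p1 template probability threshold for FPM1 (default 0.41).
#' @param p2 template probability threshold for FPM2 (default 0.63); the 3D
#'   connectivity rule is more liberal, hence the higher threshold.
#' @param connectivity 6, 18 or 26 neighbours, used both for component
#'   labelling and for template adjacency in FPM2.
#' @return list of class `fpm_config`.
#' @export
fpm_config <- function(strategy = c("none", "fpm1", "fpm2"),
                       p1 = 0.41, p2 = 0.63, connectivity = 26) {
  strategy <- match.arg(strategy)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  }
  structure(list(strategy = strategy, p1 = p1, p2 = p2,
                 connectivity = connectivity), class = "fpm_config")
}

#' FPM1: mask candidates with the thresholded white matter template
#'
#' Keeps exactly the candidate voxels whose template white matter
#' probability is at least `p1`. Simple and strict: hyperintensities
#' extending beyond the thresholded white matter compartment are truncated.
#'
#' @param candidates logical candidate mask.
#' @param template a [wm_template()] on the same grid.
#' @param p1 probability threshold (inclusive).
#' @return logical mask, a subset of `candidates`.
#' @export
fpm1_mask <- function(candidates, template, p1 = 0.41) {
  candidates <- as_mask_array(candidates, "candidates")
  stopifnot(inherits(template, "wm_template"), p1 >= 0, p1 <= 1)
  check_same_grid(candidates, template$prob, "candidates", "template")
  candidates & (template$prob >= p1)
}

#' FPM2: keep candidate components connected in 3D to the template
#'
#' Labels the 3D connected components of the candidate mask and keeps a
#' component if and only if at least one of its voxels lies in, or is a 3D
#' neighbour of, a voxel with template probability at least `p2`. Components
#' are kept or removed whole, so lesions are never truncated; the price is a
#' more liberal rule, hence the higher default threshold.
#'
#' @param candidates logical candidate mask.
#' @param template a [wm_template()] on the same grid.
#' @param p2 probability threshold (inclusive).
#' @param connectivity 6, 18 or 26 neighbours for both labelling and
#'   adjacency.
#' @return logical mask, a union of whole candidate components.
#' @export
fpm2_connectivity <- function(candidates, template, p2 = 0.63,
                              connectivity = 26) {
  candidates <- as_mask_array(candidates, "candidates")
  stopifnot(inherits(template, "wm_template"), p2 >= 0, p2 <= 1)
  check_same_grid(candidates, template$prob, "candidates", "template")
  if (!sum(candidates)) return(candidates)

  labels <- label_components(candidates, connectivity)
  wm <- template$prob >= p2
  touch <- wm | dilate_mask(wm, connectivity)
  kept_ids <- unique(labels[candidates & touch])
  out <- array(FALSE, dim(candidates))
  if (length(kept_ids)) out[labels %in% kept_ids & candidates] <- TRUE
  out
}

#' Label 3D connected components of a binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return integer array: 0 outside the mask, component id (1, 2, ...) inside.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask_array(mask, "mask")
  dims <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, dims)
  if (!length(idx)) return(labels)

  coords <- arrayInd(idx, dims)
  key <- (coords[, 3] - 1) * (dims[1] * dims[2]) +
         (coords[, 2] - 1) * dims[1] + coords[, 1]
  pos <- seq_along(idx)
  offsets <- neighbour_offsets(connectivity)
  ## half the offsets suffice for an undirected adjacency graph
  half <- offsets[offsets[, 1] > 0 |
                  (offsets[, 1] == 0 & offsets[, 2] > 0) |
                  (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] > 0), ,
                  drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(half))) {
    d <- half[r, ]
    ni <- coords[, 1] + d[1]; nj <- coords[, 2] + d[2]; nk <- coords[, 3] + d[3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
          nk >= 1 & nk <= dims[3]
    nkey <- (nk[ok] - 1) * (dims[1] * dims[2]) + (nj[ok] - 1) * dims[1] + ni[ok]
    hit <- match(nkey, key)
    src <- pos[ok][!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) edges <- c(edges, rbind(src, dst))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

neighbour_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  unname(g[keep, , drop = FALSE])
}

## binary dilation by the chosen neighbourhood, via array shifts
dilate_mask <- function(mask, connectivity = 26) {
  offsets <- neighbour_offsets(connectivity)
  out <- mask
  for (r in seq_len(nrow(offsets))) {
    out <- out | shift_mask(mask, offsets[r, ])
  }
  out
}

shift_mask <- function(mask, offset) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    d <- offset[a]
    n <- dims[a]
    if (d >= 0) { src[[a]] <- seq_len(n - d); dst[[a]] <- seq_len(n - d) + d }
    else { src[[a]] <- seq_len(n + d) - d; dst[[a]] <- seq_len(n + d) }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Apply the configured false-positive minimization strategy
#'
#' @param candidates logical candidate mask.
#' @param template a [wm_template()] (required unless strategy is "none").
#' @param config an [fpm_config()].
#' @return logical mask, a subset of `candidates`.
#' @export
apply_fpm <- function(candidates, template = NULL, config = fpm_config()) {
  stopifnot(inherits(config, "fpm_config"))
  if (config$strategy == "none") return(as_mask_array(candidates, "candidates"))
  if (is.null(template)) {
    stop("a white matter template is required for FPM", call. = FALSE)
  }
  switch(config$strategy,
         fpm1 = fpm1_mask(candidates, template, config$p1),
         fpm2 = fpm2_connectivity(candidates, template, config$p2,
                                  config$connectivity))
}

#' Sweep FPM template thresholds against a reference mask
#'
#' Applies one FPM strategy over a grid of template probability thresholds
#' and scores each result against a reference segmentation, reproducing the
#' usual threshold-sensitivity table (threshold, SI, PCE, POE, PUE).
#'
#' @param candidates logical candidate mask (segmentation before FPM).
#' @param template a [wm_template()].
#' @param reference logical reference mask (e.g. manual tracing).
#' @param strategy `"fpm1"` or `"fpm2"`.
#' @param thresholds numeric vector of template probability thresholds; the
#'   default spans three steps of 0.04 on either side of the strategy's
#'   selected value.
#' @param connectivity neighbourhood for FPM2.
#' @return data.frame with columns strategy, threshold, tp, fp, fn, si, pce,
#'   poe, pue.
#' @export
sweep_fpm <- function(candidates, template, reference,
                      strategy = c("fpm1", "fpm2"),
                      thresholds = NULL, connectivity = 26) {
  strategy <- match.arg(strategy)
  if (is.null(thresholds)) {
    centre <- if (strategy == "fpm1") 0.41 else 0.63
    thresholds <- centre + 0.04 * (-3:3)
  }
  rows <- lapply(thresholds, function(p) {
    filtered <- if (strategy == "fpm1") {
      fpm1_mask(candidates, template, p)
    } else {
      fpm2_connectivity(candidates, template, p, connectivity)
    }
    rep <- similarity_metrics(filtered, reference)
    data.frame(strategy = strategy, threshold = p, tp = rep$tp, fp = rep$fp,
               fn = rep$fn, si = rep$si, pce = rep$pce, poe = rep$poe,
               pue = rep$pue)
  })
  do.call(rbind, rows)
}
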
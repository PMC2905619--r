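#' Two-class fuzzy C-means on a vector of intensities
#'
#' Alternating optimization of the fuzzy C-means objective
#' \deqn{J = \sum_{i}\sum_{k} u_{ik}^m (v_i - c_k)^2}
#' for two clusters (background-CSF and brain). Each value receives a
#' membership grade in each class; the two grades sum to one. Iteration
#' alternates the closed-form membership update
#' \eqn{u_{ik} = 1 / \sum_j (|v_i-c_k| / |v_i-c_j|)^{2/(m-1)}}
#' and the weighted-mean center update, stopping when the largest center
#' change falls below `tol` or after `max_iter` sweeps.
#'
#' Initialization is deterministic: the starting centers default to the 5th
#' and 95th percentiles of the values, so repeated runs are reproducible
#' without a random seed. Values coinciding exactly with a center get a crisp
#' membership of 1 in that cluster.
#'
#' @param values numeric vector (at least 2 distinct values).
#' @param m fuzziness exponent (> 1); 2 is the conventional choice.
#' @param tol convergence tolerance on the maximum center change.
#' @param max_iter maximum number of iterations.
#' @param init optional numeric length-2 starting centers.
#' @return Object of class `fcm_fit`: list with `memberships` (n x 2 matrix,
#'   columns `background_csf` and `brain`, ordered so that
#'   `centers["background_csf"] <= centers["brain"]`), `centers`,
#'   `objective` (per-iteration objective values), `iterations`, `converged`.
#' @export
fcm_two_class <- function(values, m = 2, tol = 1e-5, max_iter = 300,
                          init = NULL) {
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be numeric without NA", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("insufficient data: need at least as many values as clusters",
         call. = FALSE)
  }
  if (length(unique(values)) < 2L) {
    stop("degenerate cluster: all values are identical", call. = FALSE)
  }
  if (!isTRUE(m > 1)) stop("fuzziness 'm' must be > 1", call. = FALSE)

  if (is.null(init)) {
    init <- unname(stats::quantile(values, c(0.05, 0.95), names = FALSE))
    if (init[1] == init[2]) init <- range(values)
  }
  if (length(init) != 2L || init[1] == init[2]) {
    stop("'init' must be two distinct starting centers", call. = FALSE)
  }
  centers <- sort(as.numeric(init))
  expo <- 2 / (m - 1)
  objective <- numeric(0)
  converged <- FALSE
  u <- NULL
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    u <- fcm_memberships(values, centers, expo)
    um <- u^m
    new_centers <- c(
      sum(um[, 1] * values) / sum(um[, 1]),
      sum(um[, 2] * values) / sum(um[, 2])
    )
    objective <- c(objective,
                   sum(um[, 1] * (values - new_centers[1])^2) +
                   sum(um[, 2] * (values - new_centers[2])^2))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  u <- fcm_memberships(values, centers, expo)

  ord <- order(centers)
  centers <- centers[ord]
  u <- u[, ord, drop = FALSE]
  colnames(u) <- c("background_csf", "brain")
  names(centers) <- c("background_csf", "brain")

  structure(list(memberships = u, centers = centers, objective = objective,
                 iterations = iter, converged = converged),
            class = "fcm_fit")
}

## closed-form membership update; handles values coinciding with a center
fcm_memberships <- function(values, centers, expo) {
  d1 <- abs(values - centers[1])
  d2 <- abs(values - centers[2])
  u1 <- 1 / (1 + (d1 / d2)^expo)
  at1 <- d1 == 0
  at2 <- d2 == 0
  u1[at1] <- 1
  u1[at2 & !at1] <- 0
  cbind(u1, 1 - u1)
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> centers: %.4g / %.4g, %d iterations%s\n",
              x$centers[1], x$centers[2], x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
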
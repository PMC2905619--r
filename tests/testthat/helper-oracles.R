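# Independent oracles, coded directly from the defining formulas with plain
# loops. They share no code with the package internals.

# Brute-force alternating-optimization FCM for two clusters.
fcm_oracle <- function(values, m = 2, init, iters = 5000, tol = 1e-13) {
  centers <- sort(as.numeric(init))
  n <- length(values)
  u <- matrix(0, n, 2)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      d <- abs(values[i] - centers)
      if (any(d == 0)) {
        u[i, ] <- 0
        u[i, which.min(d)] <- 1
      } else {
        for (k in 1:2) {
          u[i, k] <- 1 / sum((d[k] / d)^(2 / (m - 1)))
        }
      }
    }
    new_centers <- numeric(2)
    for (k in 1:2) {
      new_centers[k] <- sum(u[, k]^m * values) / sum(u[, k]^m)
    }
    done <- max(abs(new_centers - centers)) < tol
    centers <- new_centers
    if (done) break
  }
  ord <- order(centers)
  list(centers = centers[ord], memberships = u[, ord, drop = FALSE])
}

# One explicit Perona-Malik step on a 2D matrix: 4-neighbour differences,
# exponential conductance, Neumann boundaries (missing neighbours contribute
# nothing).
pm_step_oracle <- function(mat, dt, K) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- mat
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      flux <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + d[1]; nj <- j + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc) {
          g <- mat[ni, nj] - mat[i, j]
          flux <- flux + exp(-(g / K)^2) * g
        }
      }
      out[i, j] <- mat[i, j] + dt * flux
    }
  }
  out
}

# Linear (unweighted) diffusion step for the edge-preservation contrast.
linear_step_oracle <- function(mat, dt) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- mat
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      flux <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + d[1]; nj <- j + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc) {
          flux <- flux + (mat[ni, nj] - mat[i, j])
        }
      }
      out[i, j] <- mat[i, j] + dt * flux
    }
  }
  out
}

# Set-based Dice coefficient.
dice_oracle <- function(a, b) {
  ia <- which(a); ib <- which(b)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# 26-connectivity adjacency test between two voxel coordinates.
adjacent26 <- function(p, q) {
  all(abs(p - q) <= 1) && any(p != q)
}
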
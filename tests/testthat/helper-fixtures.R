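# Small reusable fixtures, built in code.

# A uniform ellipsoidal "brain" volume: zeros outside, `value` inside.
uniform_brain <- function(dims = c(20L, 20L, 8L), value = 100) {
  ph <- make_phantom(phantom_spec(dims = pmax(dims, 8L), bright_fraction = 0,
                                  rng_seed = 99L))
  vol <- ph$volume
  vol$data[vol$brain_mask] <- value
  vol
}

# Random logical mask with approximately `p` density.
random_mask <- function(dims, p = 0.1, seed = 1) {
  set.seed(seed)
  m <- array(stats::runif(prod(dims)) < p, dims)
  m
}

# Lazily computed, cached full-scale precision experiment shared by the
# acceptance tests.
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_precision_experiment(n_volumes = 6L, seed = 101L)
    }
    cache
  }
})
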
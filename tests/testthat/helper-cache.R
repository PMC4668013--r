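# Shared cache for expensive simulation batches so several tests can reuse
# one batch instead of re-simulating it.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache, inherits = FALSE)
}

# deterministic draws for fixtures
rgamma_fixture <- function(n, shape, scale) {
  set.seed(1234)
  rgamma(n, shape = shape, scale = scale)
}

rnorm_fixture <- function(n, mean = 0, sd = 1) {
  set.seed(4321 + n)
  rnorm(n, mean, sd)
}

runif_fixture <- function(n, min = 0, max = 1) {
  set.seed(2468 + n)
  runif(n, min, max)
}

# small PN population reused by fast model tests
tiny_population <- function(n = 200, duration_ms = 3000, seed = 11) {
  cached(sprintf("pop_%d_%d_%d", n, duration_ms, seed),
         generate_pn_population(n_trains = n, duration_ms = duration_ms,
                                seed = seed))
}
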
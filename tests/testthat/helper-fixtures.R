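# Shared fixtures: a small fast phantom for pipeline tests and a lazily
# computed cache for the expensive mini-study runs used by the acceptance
# tests.

tiny_phantom <- function(channels = 4, grid = c(12, 12, 12),
                         counts = c(3, 6, 6, 9), phase_amp = pi / 2,
                         snr_range = c(2, 15), seed = 5) {
  phantom_config(
    grid = grid, channels = channels,
    bundles = list(list(from = c(0.1, 0.35, 0.3), to = c(0.9, 0.35, 0.3),
                        radius = 1.8)),
    iso_regions = list(list(center = c(0.5, 0.5, 0.5), radius = 2,
                            d_iso = 3e-3)),
    counts = counts, phase_amp = phase_amp, snr_range = snr_range,
    seed = seed)
}

# noise-free low-rank stack: two spatial patterns mixed across volumes
lowrank_stack <- function(nx = 10, q = 24, seed = 3) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  with_seed(seed, {
    p1 <- array(rnorm(nx^3), c(nx, nx, nx))
    p2 <- array(rnorm(nx^3), c(nx, nx, nx))
    a <- runif(q, 0.5, 2)
    b <- runif(q, -1, 1)
    arr <- array(0, c(nx, nx, nx, q))
    for (v in seq_len(q)) arr[, , , v] <- a[v] * p1 + b[v] * p2
    arr
  })
}

# expensive mini-study results, computed once per test run
study_cache <- new.env(parent = emptyenv())

cached_floor_study <- function() {
  if (is.null(study_cache$floor))
    study_cache$floor <- noise_floor_study(seed = 1)
  study_cache$floor
}

cached_channel_sweep <- function() {
  if (is.null(study_cache$sweep))
    study_cache$sweep <- channel_sweep_study(seed = 1)
  study_cache$sweep
}
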
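# shared fixtures: a coarse-but-honest tuning configuration for tests that
# exercise the full pipeline, and cached geometries
fast_cfg <- function(n_freq = 10) {
  tuning_config(freq_grid = 10^seq(log10(2), 3, length.out = n_freq),
                prescan_points = 5L, bisect_rel_tol = 0.02,
                refine_resolution = 2)
}

cat_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_geometry(species_record("cat"))
    cache
  }
})

# dense-solver oracle for the layered-shell ladder: assemble the full
# (N+1)x(N+1) complex matrix and solve with base R
dense_ladder_solve <- function(k, c_film, k_core, f, A = 1) {
  N <- length(k)
  w <- 2 * pi * f
  d <- 1i * w * c_film
  M <- matrix(0 + 0i, N + 1, N + 1)
  M[1, 1] <- k_core + d[1]
  M[1, 2] <- -d[1]
  for (i in seq_len(N)) {
    row <- i + 1
    M[row, row] <- k[i] + d[i] + d[i + 1]
    M[row, row - 1] <- -d[i]
    if (i < N) M[row, row + 1] <- -d[i + 1]
  }
  rhs <- c(rep(0 + 0i, N), d[N + 1] * A)
  solve(M, rhs)
}
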
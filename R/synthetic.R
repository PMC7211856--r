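#' Specification of a synthetic corpuscle population
#'
#' Generates corpuscle morphometries with the statistical structure observed
#' across real species: outer radius log-uniform over the observed 4-320 um
#' range; lamella count increasing with radius but noisy (defaults chosen to
#' land the population N ~ radius r-squared near the observed 0.43); lamellar
#' thickness proportional to radius with strong lognormal scatter (targeting
#' the weak observed correlation, r-squared about 0.23); and body mass
#' independent of all structural parameters (no mass-structure correlation is
#' observed in real data), log-uniform over 0.01 kg to 40 t.
#'
#' @param n Number of corpuscles.
#' @param seed Integer seed; generation is a pure function of its fields.
#' @param radius_range Outer-radius range, um (log-uniform).
#' @param lamellae_a,lamellae_b,lamellae_sd Lamella-count model
#'   `N = round(a + b R + Normal(0, sd))`, clipped to >= 5.
#' @param thickness_c,thickness_sdlog Thickness model
#'   `h = c R exp(Normal(0, sdlog))`.
#' @param mass_log10_range Range of log10 body mass, kg.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n, seed = 0L, radius_range = c(4, 320),
                            lamellae_a = 15, lamellae_b = 0.05,
                            lamellae_sd = 6, thickness_c = 0.02,
                            thickness_sdlog = 0.8,
                            mass_log10_range = c(-2, 4.6)) {
  stopifnot(n >= 0, radius_range[1] > 0, radius_range[2] > radius_range[1],
            lamellae_sd >= 0, thickness_c > 0, thickness_sdlog >= 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 radius_range = radius_range, lamellae_a = lamellae_a,
                 lamellae_b = lamellae_b, lamellae_sd = lamellae_sd,
                 thickness_c = thickness_c,
                 thickness_sdlog = thickness_sdlog,
                 mass_log10_range = mass_log10_range),
            class = "population_spec")
}

#' Generate a synthetic corpuscle population
#'
#' Deterministic for a fixed spec (seed included); the output passes
#' species-table validation and uses the same CSV dialect as the packaged
#' table.
#'
#' @param spec A [population_spec()].
#' @return A `species_table` data frame with `n` rows.
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  empty <- data.frame(common_name = character(0), species_name = character(0),
                      mass_kg = numeric(0), outer_radius = numeric(0),
                      radius_unit = character(0), n_lamellae = integer(0),
                      lamellar_thickness = numeric(0),
                      thickness_unit = character(0), class = character(0),
                      habitat = character(0), paper_peak_hz = numeric(0),
                      paper_bandwidth_hz = numeric(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    class(empty) <- c("species_table", "data.frame")
    return(empty)
  }
  withr_seed(spec$seed, {
    R <- exp(stats::runif(n, log(spec$radius_range[1]),
                          log(spec$radius_range[2])))
    N <- round(spec$lamellae_a + spec$lamellae_b * R +
                 stats::rnorm(n, 0, spec$lamellae_sd))
    N <- pmax(N, 5)
    h <- spec$thickness_c * R * exp(stats::rnorm(n, 0, spec$thickness_sdlog))
    # thickness cannot exceed the per-layer share of the outer-core span
    h <- pmin(h, 0.79 * 0.8 * R / N)
    mass <- 10^stats::runif(n, spec$mass_log10_range[1],
                            spec$mass_log10_range[2])
    out <- data.frame(
      common_name = sprintf("synthetic_%03d", seq_len(n)),
      species_name = sprintf("Syntheticus corpusculi %03d", seq_len(n)),
      mass_kg = mass, outer_radius = R, radius_unit = "um",
      n_lamellae = as.integer(N), lamellar_thickness = h,
      thickness_unit = "um", class = "mammal", habitat = "terrestrial",
      paper_peak_hz = NA_real_, paper_bandwidth_hz = NA_real_,
      source = "synthetic", stringsAsFactors = FALSE)
    validate_species_table(out)
    class(out) <- c("species_table", "data.frame")
    out
  })
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a seeded linear-regression dataset
#'
#' `y = slope * x + intercept + Normal(0, sigma)` with `x` equally spaced on
#' `[0, 10]`; deterministic per seed.
#'
#' @param slope,intercept,sigma Model parameters (`sigma >= 0`).
#' @param n Number of points (>= 3).
#' @param seed Integer seed.
#' @return A list with numeric vectors `x` and `y`.
#' @export
gen_regression_dataset <- function(slope, intercept, sigma, n, seed = 0L) {
  stopifnot(n >= 3L, sigma >= 0)
  withr_seed(seed, {
    x <- seq(0, 10, length.out = n)
    y <- slope * x + intercept + stats::rnorm(n, 0, sigma)
    list(x = x, y = y)
  })
}

#' Analytic single-layer fixture for the mechanics solver
#'
#' A one-lamella stack whose core co-moves with the lamella has the closed
#' form `T(w) = i w c / (k + i w c)`, i.e.
#' `|T| = w c / sqrt(k^2 + w^2 c^2)` - a first-order high-pass with corner
#' frequency `k / (2 pi c)`. Returns the coefficient set for
#' [transfer_solve()] plus the closed-form magnitude evaluator.
#'
#' @param k Lamellar areal stiffness, Pa/m.
#' @param c_film Film areal damping, Pa s/m.
#' @return List with `k`, `c_film`, `closed_form` (function of frequency Hz
#'   returning `|T|`), and `solve` (function of frequency Hz running the
#'   package solver in merged-core mode).
#' @export
single_layer_fixture <- function(k, c_film) {
  stopifnot(k > 0, c_film > 0)
  list(
    k = k, c_film = c_film,
    closed_form = function(f) {
      w <- 2 * pi * f
      w * c_film / sqrt(k^2 + (w * c_film)^2)
    },
    solve = function(f) {
      Mod(transfer_solve(k, c_film, k_core = Inf, f = f,
                         merged_core = TRUE)$T)
    })
}
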
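test_that("shell stiffness follows the thin-shell membrane law", {
  expect_equal(shell_stiffness(1400, 0, 100e-6), 0)
  k1 <- shell_stiffness(1400, 0.24e-6, 100e-6, nu = 0.49)
  # independent hand evaluation of 2 E h / ((1 - nu^2) r^2)
  expect_equal(k1, 88432.68851, tolerance = 1e-9)
  expect_equal(shell_stiffness(2800, 0.24e-6, 100e-6, nu = 0.49), 2 * k1)
  expect_equal(shell_stiffness(1400, 0.48e-6, 100e-6, nu = 0.49), 2 * k1)
  expect_equal(shell_stiffness(1400, 0.24e-6, 200e-6, nu = 0.49), k1 / 4)
  expect_error(shell_stiffness(1400, 1e-6, 0), "positive")
})

test_that("film damping follows the squeeze-film law", {
  expect_equal(film_damping(0, 100e-6, 2e-6), 0)
  c1 <- film_damping(3.5e-3, 100e-6, 2e-6, kappa = 1)
  expect_equal(c1, 4375000, tolerance = 1e-9)      # hand evaluation
  expect_equal(film_damping(7e-3, 100e-6, 2e-6), 2 * c1)
  expect_equal(film_damping(3.5e-3, 100e-6, 1e-6), 8 * c1)
  expect_error(film_damping(3.5e-3, 100e-6, 0), "positive")
  expect_error(film_damping(3.5e-3, 0, 2e-6), "positive")
})

test_that("single-layer solver matches the analytic high-pass closed form", {
  set.seed(42)
  for (i in 1:50) {
    k <- 10^runif(1, 2, 7)
    cf <- 10^runif(1, 2, 7)
    f <- 10^runif(1, log10(2), 3)
    fx <- single_layer_fixture(k, cf)
    expect_equal(fx$solve(f), fx$closed_form(f), tolerance = 1e-10)
  }
  # corner frequency: |T| = 1/sqrt(2)
  fx <- single_layer_fixture(1e5, 2)
  expect_equal(fx$solve(1e5 / (2 * pi * 2)), 1 / sqrt(2), tolerance = 1e-10)
  # high-pass zero at DC
  expect_lt(fx$solve(1e-4), 1e-6)
})

test_that("tridiagonal solution matches a dense solve on random stacks", {
  set.seed(7)
  for (i in 1:20) {
    N <- 5L
    k <- 10^runif(N, 3, 6)
    cf <- 10^runif(N + 1L, 3, 6)
    k_core <- 10 * max(k)
    f <- 10^runif(1, log10(2), 3)
    got <- transfer_solve(k, cf, k_core, f)
    want <- dense_ladder_solve(k, cf, k_core, f)
    expect_lt(max(Mod(got$U - want)), 1e-10 * max(Mod(want)))
    expect_lt(got$residual, 1e-10)
  }
})

test_that("transfer is linear in drive and bounded by unity", {
  g <- cat_geometry()
  m <- material_params()
  t1 <- transfer_ratio(g, m, 50, A = 1)
  t2 <- transfer_ratio(g, m, 50, A = 3.25)
  expect_equal(t2$U, 3.25 * t1$U, tolerance = 1e-12)
  expect_equal(t2$T, t1$T, tolerance = 1e-12)
  for (f in c(2, 20, 200, 1000)) {
    expect_lt(Mod(transfer_ratio(g, m, f)$T), 1 + 1e-9)
    expect_gt(Mod(transfer_ratio(g, m, f)$T), 0)
  }
})

test_that("every tabulated geometry is a mechanical high-pass", {
  tab <- species_table()
  m <- material_params()
  for (i in seq_len(nrow(tab))) {
    g <- build_geometry(tab[i, ])
    expect_lt(Mod(transfer_ratio(g, m, 2)$T),
              Mod(transfer_ratio(g, m, 1000)$T))
  }
  # |T| non-decreasing across the band for the default cat
  g <- cat_geometry()
  sweep <- transfer_sweep(g, m, 10^seq(log10(2), 3, length.out = 25))
  expect_true(all(diff(sweep$T_abs) > -1e-12))
})

test_that("transfer ratio is invariant under consistent unit rescaling", {
  # scaling all lengths by s multiplies k and c by 1/s each: T unchanged
  g <- cat_geometry()
  m <- material_params()
  co <- lamellar:::assemble_coefficients(g, m)
  s <- 1e6
  for (f in c(5, 48, 500)) {
    t_m <- transfer_solve(co$k, co$c, co$k_core, f)
    t_um <- transfer_solve(co$k / s, co$c / s, co$k_core / s, f)
    expect_equal(t_um$T, t_m$T, tolerance = 1e-9)
  }
})

test_that("degenerate systems error", {
  expect_error(transfer_solve(0, c(0, 0), 1e3, 50), "singular")
})
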
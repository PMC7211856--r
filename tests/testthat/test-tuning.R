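mk_curve <- function(f, th, species = "synthetic") {
  out <- data.frame(frequency_hz = f, threshold_um = th,
                    detectable = is.finite(th),
                    rate_hz = ifelse(is.finite(th), f, 0))
  attr(out, "species") <- species
  class(out) <- c("tuning_curve", "data.frame")
  out
}

test_that("features of a V-shaped curve match hand-computed crossings", {
  curve <- mk_curve(c(10, 30, 100, 300, 1000), c(10, 2, 1, 2, 10))
  ft <- extract_features(curve, tuning_config())
  expect_equal(ft$a_min_um, 1)
  expect_equal(ft$peak_hz, 100)
  # log-log interpolated 3.5*A_min crossings, evaluated independently
  expect_equal(ft$band_lo_hz, 20.474909, tolerance = 1e-6)
  expect_equal(ft$band_hi_hz, 455.964274, tolerance = 1e-6)
  expect_equal(ft$band_width_hz, ft$band_hi_hz - ft$band_lo_hz)
})

test_that("flat curves invoke the 0 Hz lower-limit convention", {
  curve <- mk_curve(c(2, 20, 200, 1000), c(1.1, 1.0, 1.05, 1.2))
  ft <- extract_features(curve, tuning_config())
  expect_equal(ft$band_lo_hz, 0)
  expect_equal(ft$band_hi_hz, 1000)
})

test_that("sentinels are handled: partial curves work, empty curves error", {
  curve <- mk_curve(c(2, 20, 200, 1000), c(NA, 1, 2, NA))
  ft <- extract_features(curve, tuning_config())
  expect_equal(ft$peak_hz, 20)
  # NA neighbours count as above-cutoff when interpolating band limits
  expect_true(ft$band_lo_hz > 2 && ft$band_lo_hz < 20)
  expect_true(ft$band_hi_hz > 200 && ft$band_hi_hz < 1000)

  empty <- mk_curve(c(2, 20), c(NA, NA))
  expect_error(extract_features(empty, tuning_config()),
               "no detectable")
})

test_that("tuning curves round-trip through CSV", {
  curve <- mk_curve(c(2, 20, 200), c(5.25, NA, 0.125))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_tuning_curve(curve, tmp)
  back <- read_tuning_curve(tmp)
  expect_equal(back$frequency_hz, curve$frequency_hz)
  expect_equal(back$threshold_um, curve$threshold_um)
  expect_equal(back$detectable, curve$detectable)
})

test_that("bisection agrees with a coarse amplitude-grid oracle", {
  g <- cat_geometry()
  m <- material_params()
  cfg <- fast_cfg()
  f <- 50
  th <- threshold_at_frequency(g, m, f, cfg = cfg)
  expect_true(th$detectable)
  # 20-point log-spaced scan: the first entraining grid amplitude must
  # bracket the bisection result within one grid cell
  T_abs <- Mod(transfer_ratio(g, m, f)$T)
  grid <- 10^seq(log10(cfg$amp_bracket_um[1]), log10(cfg$amp_bracket_um[2]),
                 length.out = 20)
  rates <- vapply(grid, function(A)
    entrain_rate(f, T_abs * A * 1e-6, g$r_core, dt = cfg$dt), numeric(1))
  first <- which(rates >= 0.9 * f)[1]
  expect_false(is.na(first))
  expect_gte(th$threshold_um, grid[first - 1])
  expect_lte(th$threshold_um, grid[first] * (1 + cfg$bisect_rel_tol))
})

test_that("thresholds are sentinel above the entrainment ceiling", {
  g <- cat_geometry()
  m <- material_params()
  expect_warning(
    th <- threshold_at_frequency(g, m, 900, cfg = fast_cfg()),
    "no 1:1 entrainment")
  expect_false(th$detectable)
  expect_true(is.na(th$threshold_um))
})

test_that("threshold is stable under bisection-tolerance refinement", {
  g <- cat_geometry()
  m <- material_params()
  cfg_coarse <- fast_cfg()
  cfg_fine <- cfg_coarse
  cfg_fine$bisect_rel_tol <- cfg_coarse$bisect_rel_tol / 2
  t1 <- threshold_at_frequency(g, m, 50, cfg = cfg_coarse)$threshold_um
  t2 <- threshold_at_frequency(g, m, 50, cfg = cfg_fine)$threshold_um
  expect_lt(abs(t1 - t2) / t2, 2 * cfg_coarse$bisect_rel_tol)
})

test_that("the calibrated cat curve is U-shaped with an interior minimum", {
  res <- species_tuning("cat", cfg = fast_cfg(), refine = FALSE)
  det <- which(res$curve$detectable)
  i_min <- det[which.min(res$curve$threshold_um[det])]
  expect_gt(i_min, 1)
  expect_lt(i_min, nrow(res$curve))
  expect_gt(res$curve$threshold_um[det[1]],
            res$features$a_min_um)           # falling low-frequency branch
})
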
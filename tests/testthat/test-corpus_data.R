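test_that("packaged species table loads and validates", {
  tab <- species_table()
  expect_s3_class(tab, "species_table")
  expect_equal(nrow(tab), 19L)

  cat_row <- species_record("cat", tab)
  expect_equal(cat_row$outer_radius, 255.6)
  expect_equal(cat_row$n_lamellae, 30)
  expect_equal(cat_row$lamellar_thickness, 0.24)

  # pixel-unit records are flagged on both length fields
  px <- tab[tab$radius_unit == "px", ]
  expect_setequal(px$common_name, c("dog", "monkey", "rooster", "snake"))
  expect_true(all(px$thickness_unit == "px"))
})

test_that("malformed tables are rejected with informative errors", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))

  writeLines("common_name,species_name", tmp)
  expect_error(load_species_table(tmp), "missing column")

  tab <- as.data.frame(species_table())
  bad <- tab
  bad$outer_radius[3] <- -1
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_species_table(tmp), "outer_radius.*row 3")

  bad <- tab
  bad$mass_kg[5] <- "heavy"
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_species_table(tmp), "non-numeric.*mass_kg")

  writeLines(character(0), tmp)
  expect_error(load_species_table(tmp))

  expect_error(load_species_table(tempfile()), "does not exist")
})

test_that("species table round-trips through CSV exactly", {
  tab <- species_table()
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_species_table(tab, tmp)
  back <- load_species_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("geometry layout places lamellae uniformly with positive gaps", {
  # single lamella: mid-radius at the midpoint of [r_core, R]
  rec <- list(outer_radius = 100, n_lamellae = 1, lamellar_thickness = 1)
  g <- build_geometry(rec)
  expect_equal(g$r_core, 20e-6)
  expect_equal(g$r_mid, 60e-6)
  expect_length(g$gaps, 2L)
  expect_true(all(g$gaps > 0))

  # cat: 30 lamellae between 51.12 and 255.6 um, all gaps positive
  g <- cat_geometry()
  expect_equal(g$n_lamellae, 30L)
  expect_equal(g$r_core, 51.12e-6)
  expect_true(all(g$r_mid > g$r_core & g$r_mid < g$R))
  expect_true(all(g$gaps > 0))
  expect_equal(sum(g$h) + sum(g$gaps), g$R - g$r_core,
               tolerance = 1e-12)
})

test_that("infeasible layouts error unless the fallback is enabled", {
  rec <- list(outer_radius = 10, n_lamellae = 10, lamellar_thickness = 2)
  expect_error(build_geometry(rec), "do not fit")
  g <- build_geometry(rec, layout_policy(min_gap_fallback = TRUE))
  expect_true(all(g$gaps > 0))
  expect_true(all(g$h > 0))
})

test_that("geometry construction is deterministic and scale-covariant", {
  rec <- list(outer_radius = 120, n_lamellae = 7, lamellar_thickness = 2.5)
  g1 <- build_geometry(rec)
  g2 <- build_geometry(rec)
  expect_identical(g1, g2)

  s <- 3.7
  rec_s <- list(outer_radius = s * 120, n_lamellae = 7,
                lamellar_thickness = s * 2.5)
  gs <- build_geometry(rec_s)
  expect_equal(gs$r_mid, s * g1$r_mid, tolerance = 1e-12)
  expect_equal(gs$gaps, s * g1$gaps, tolerance = 1e-12)
  expect_equal(gs$r_core, s * g1$r_core, tolerance = 1e-12)
})

test_that("pixel-unit records simulate through the h/R ratio", {
  dog <- species_record("dog")
  g <- build_geometry(dog, layout_policy(nominal_radius_um = 100))
  expect_true(g$ratio_mode)
  expect_equal(g$R, 100e-6)
  # thickness/radius ratio preserved
  expect_equal(g$h[1] / g$R, dog$lamellar_thickness / dog$outer_radius,
               tolerance = 1e-12)
})
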
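test_that("ols recovers exact linear relations", {
  x <- 1:5
  res <- ols(x, 2 * x + 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$n, 5L)
})

test_that("ols matches a closed-form normal-equations oracle", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- 0.7 * x + rnorm(6)
    res <- ols(x, y)
    # independent normal-equations + t-distribution evaluation
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    resid <- y - intercept - slope * x
    s2 <- sum(resid^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    tval <- slope / se
    p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
    r2 <- cor(x, y)^2
    expect_equal(res$slope, slope, tolerance = 1e-10)
    expect_equal(res$intercept, intercept, tolerance = 1e-10)
    expect_equal(res$r_squared, r2, tolerance = 1e-10)
    expect_equal(res$p_two_tailed, p, tolerance = 1e-10)
  }
})

test_that("degenerate regressions error", {
  expect_error(ols(rep(1, 5), 1:5), "zero variance")
  expect_error(ols(1:2, 1:2), "at least 3")
  expect_error(ols(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("structural battery applies the exclusion policy and bookkeeping", {
  tab <- species_table()
  res <- structural_regressions(tab)
  # pixel records excluded from absolute-length regressions
  len_rows <- res[res$y %in% c("outer_radius_um", "lamellar_thickness_um"), ]
  expect_true(all(len_rows$n == 15L))
  expect_true(all(grepl("dog", len_rows$excluded)))
  # dimensionless ratio and lamella count use all 19 species
  expect_equal(res$n[res$y == "thickness_radius_ratio"], 19L)
  expect_equal(res$n[res$y == "n_lamellae" & res$x == "mass_kg"], 19L)
  # n plus exclusions accounts for every record
  full_rows <- res[!grepl("mammal", res$y), ]
  n_excl <- vapply(strsplit(full_rows$excluded, ";"),
                   function(e) sum(nzchar(e)), 0L)
  expect_true(all(full_rows$n + n_excl == 19L))
  # the mammal sub-analyses cover the 11 mammals
  mam <- res[grepl("mammal", res$y), ]
  n_excl_m <- vapply(strsplit(mam$excluded, ";"),
                     function(e) sum(nzchar(e)), 0L)
  expect_true(all(mam$n + n_excl_m == 11L))
})

test_that("battery output round-trips to CSV", {
  res <- structural_regressions(species_table())
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_regressions(res, tmp)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$r2, res$r2, tolerance = 1e-6)
  expect_equal(back$y, res$y)
})

test_that("slope recovery stays inside the analytic confidence interval", {
  # scaled-down version of the coverage property (full run in acceptance)
  hits <- 0L
  for (s in 1:100) {
    d <- gen_regression_dataset(1.5, -2, 1, 30, seed = s)
    res <- ols(d$x, d$y)
    sxx <- sum((d$x - mean(d$x))^2)
    resid <- d$y - res$intercept - res$slope * d$x
    se <- sqrt(sum(resid^2) / (length(d$x) - 2) / sxx)
    ci <- res$slope + c(-1, 1) * qt(0.975, length(d$x) - 2) * se
    if (ci[1] <= 1.5 && 1.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
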
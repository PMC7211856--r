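#' Ordinary least-squares regression with slope test
#'
#' Simple linear regression `y ~ x` reporting slope, intercept, r-squared
#' (squared Pearson correlation) and the two-tailed p-value of the slope's t
#' statistic on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @param x_name,y_name Labels carried into the result.
#' @return A `regression_result` list: `x_name`, `y_name`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_two_tailed`, `excluded` (character vector).
#' @export
ols <- function(x, y, x_name = deparse(substitute(x)),
                y_name = deparse(substitute(y))) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points for a regression")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("regression inputs must be finite")
  }
  if (stats::var(x) == 0) stop("zero variance in x: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(x_name = x_name, y_name = y_name, n = length(x),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_two_tailed = unname(sm$coefficients[2L, 4L]),
                 excluded = character(0)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: n = %d, slope = %.4g, intercept = %.4g, r2 = %.3f, p = %.4g%s\n",
              x$y_name, x$x_name, x$n, x$slope, x$intercept, x$r_squared,
              x$p_two_tailed,
              if (length(x$excluded) > 0L)
                paste0(" (excluded: ", paste(x$excluded, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Cross-species structural regression battery
#'
#' Runs the comparative-morphometry regressions on a species table: corpuscle
#' outer radius, lamellar thickness, thickness/radius ratio and lamella count
#' against body mass; thickness and lamella count against outer radius; and
#' the mammal-only and terrestrial-mammal-only radius-versus-mass
#' sub-analyses.
#'
#' Exclusion policy: pixel-unit records enter only the regressions of
#' dimensionless quantities (the thickness/radius ratio, the lamella count);
#' any regression involving an absolute length drops them. Body mass is used
#' untransformed by default - this choice, not log mass, reproduces the
#' source study's printed p-values - with `mass_transform = "log10"`
#' available.
#'
#' @param records A `species_table`.
#' @param mass_transform `"linear"` (default) or `"log10"`.
#' @return A `data.frame` with one row per regression: `x`, `y`, `n`, `slope`,
#'   `intercept`, `r2`, `p`, `excluded` (semicolon-separated names).
#' @export
structural_regressions <- function(records, mass_transform = c("linear",
                                                               "log10")) {
  mass_transform <- match.arg(mass_transform)
  tab <- as.data.frame(records)
  px <- tab$radius_unit == "px"
  um <- tab[!px, ]
  px_names <- tab$common_name[px]
  mass_of <- function(d) {
    if (mass_transform == "log10") log10(d$mass_kg) else d$mass_kg
  }
  mass_label <- if (mass_transform == "log10") "log10(mass_kg)" else "mass_kg"

  run <- function(x, y, x_name, y_name, excluded, n_total = nrow(tab)) {
    if (length(x) < 3L) {
      stop(sprintf("fewer than 3 usable records for %s ~ %s after exclusions",
                   y_name, x_name))
    }
    res <- ols(x, y, x_name, y_name)
    res$excluded <- excluded
    stopifnot(res$n + length(excluded) == n_total)
    res
  }
  mammal <- tab$class == "mammal"
  um_mammal <- um[um$class == "mammal", ]
  um_terr <- um_mammal[um_mammal$habitat == "terrestrial", ]
  excl_mam <- setdiff(tab$common_name[mammal], um_mammal$common_name)
  excl_terr <- setdiff(tab$common_name[mammal], um_terr$common_name)

  results <- list(
    run(mass_of(um), um$outer_radius, mass_label, "outer_radius_um", px_names),
    run(mass_of(um), um$lamellar_thickness, mass_label,
        "lamellar_thickness_um", px_names),
    run(mass_of(tab), tab$lamellar_thickness / tab$outer_radius, mass_label,
        "thickness_radius_ratio", character(0)),
    run(mass_of(tab), tab$n_lamellae, mass_label, "n_lamellae", character(0)),
    run(um$outer_radius, um$lamellar_thickness, "outer_radius_um",
        "lamellar_thickness_um", px_names),
    run(um$outer_radius, um$n_lamellae, "outer_radius_um", "n_lamellae",
        px_names),
    run(mass_of(um_mammal), um_mammal$outer_radius, mass_label,
        "outer_radius_um_mammals", excl_mam, n_total = sum(mammal)),
    run(mass_of(um_terr), um_terr$outer_radius, mass_label,
        "outer_radius_um_terrestrial_mammals", excl_terr,
        n_total = sum(mammal))
  )
  data.frame(
    x = vapply(results, `[[`, "", "x_name"),
    y = vapply(results, `[[`, "", "y_name"),
    n = vapply(results, `[[`, 0L, "n"),
    slope = vapply(results, `[[`, 0, "slope"),
    intercept = vapply(results, `[[`, 0, "intercept"),
    r2 = vapply(results, `[[`, 0, "r_squared"),
    p = vapply(results, `[[`, 0, "p_two_tailed"),
    excluded = vapply(results, function(r) paste(r$excluded, collapse = ";"),
                      ""),
    stringsAsFactors = FALSE)
}

#' Write a regression battery to CSV
#'
#' @param results Output of [structural_regressions()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_regressions <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
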
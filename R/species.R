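#' Load and validate a species morphometry table
#'
#' Reads a CSV of lamellar-corpuscle (Pacinian / Herbst corpuscle) structural
#' measurements: one row per species with body mass, corpuscle outer radius,
#' number of outer-core lamellae and average lamellar thickness. Length fields
#' are either in micrometres (`um`) or, where the source micrograph carried no
#' scale bar, in pixels (`px`); a pixel-unit record is only meaningful through
#' its dimensionless thickness/radius ratio.
#'
#' @param path Path to a CSV file with header
#'   `common_name,species_name,mass_kg,outer_radius,radius_unit,n_lamellae,`
#'   `lamellar_thickness,thickness_unit,class,habitat,paper_peak_hz,`
#'   `paper_bandwidth_hz,source`.
#' @return A `data.frame` of class `species_table`, one validated row per
#'   species. The `paper_peak_hz` / `paper_bandwidth_hz` columns are carried as
#'   reference data only and are never used as model inputs.
#' @export
#' @examples
#' tab <- load_species_table(system.file("extdata", "species_table.csv",
#'                                       package = "lamellar"))
#' nrow(tab)  # 19
load_species_table <- function(path) {
  if (!file.exists(path)) {
    stop("species table file does not exist: ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  required <- c("common_name", "species_name", "mass_kg", "outer_radius",
                "radius_unit", "n_lamellae", "lamellar_thickness",
                "thickness_unit", "class", "habitat", "paper_peak_hz",
                "paper_bandwidth_hz", "source")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("species table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    stop("species table is empty: ", path)
  }
  tab <- tab[required]
  validate_species_table(tab)
  class(tab) <- c("species_table", "data.frame")
  tab
}

validate_species_table <- function(tab) {
  num_cols <- c("mass_kg", "outer_radius", "n_lamellae", "lamellar_thickness")
  for (col in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s', row %d (%s)",
                   col, bad[1L], tab$common_name[bad[1L]]))
    }
    tab[[col]] <- as.numeric(tab[[col]])
    neg <- which(tab[[col]] <= 0)
    if (length(neg) > 0L) {
      stop(sprintf("non-positive value in column '%s', row %d (%s)",
                   col, neg[1L], tab$common_name[neg[1L]]))
    }
  }
  if (any(tab$n_lamellae != round(tab$n_lamellae))) {
    bad <- which(tab$n_lamellae != round(tab$n_lamellae))[1L]
    stop(sprintf("non-integer lamella count in row %d (%s)",
                 bad, tab$common_name[bad]))
  }
  for (col in c("radius_unit", "thickness_unit")) {
    bad <- which(!tab[[col]] %in% c("um", "px"))
    if (length(bad) > 0L) {
      stop(sprintf("invalid unit in column '%s', row %d (must be um or px)",
                   col, bad[1L]))
    }
  }
  # a record measured in pixels is flagged on both length fields
  inconsistent <- which(tab$radius_unit != tab$thickness_unit)
  if (length(inconsistent) > 0L) {
    stop(sprintf("inconsistent unit flags in row %d (%s): radius '%s', thickness '%s'",
                 inconsistent[1L], tab$common_name[inconsistent[1L]],
                 tab$radius_unit[inconsistent[1L]],
                 tab$thickness_unit[inconsistent[1L]]))
  }
  bad_class <- which(!tab$class %in% c("mammal", "bird", "reptile", "amphibian"))
  if (length(bad_class) > 0L) {
    stop(sprintf("invalid taxonomic class in row %d: '%s'",
                 bad_class[1L], tab$class[bad_class[1L]]))
  }
  bad_hab <- which(!is.na(tab$habitat) & !tab$habitat %in% c("terrestrial", "aquatic"))
  if (length(bad_hab) > 0L) {
    stop(sprintf("invalid habitat in row %d: '%s'",
                 bad_hab[1L], tab$habitat[bad_hab[1L]]))
  }
  invisible(tab)
}

#' Write a species table to CSV
#'
#' Inverse of [load_species_table()]; a written table reloads with all fields
#' identical.
#'
#' @param tab A `species_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' The packaged 19-species corpuscle table
#'
#' Convenience accessor for the morphometry table shipped with the package
#' (19 species spanning mammals, birds, reptiles and one amphibian; body mass
#' from 19 g to 36 t, corpuscle outer radius from 4.6 to 317 um). Four records
#' (dog, monkey, rooster, snake) are pixel-unit and enter absolute-length
#' analyses only through the thickness/radius ratio.
#'
#' @return A `species_table` data frame with 19 rows.
#' @export
species_table <- function() {
  load_species_table(system.file("extdata", "species_table.csv",
                                 package = "lamellar", mustWork = TRUE))
}

#' Retrieve one species record
#'
#' @param name Common name as it appears in the table (e.g. `"cat"`).
#' @param tab Species table; defaults to the packaged one.
#' @return A one-row `species_table` data frame.
#' @export
species_record <- function(name, tab = species_table()) {
  i <- match(name, tab$common_name)
  if (is.na(i)) {
    stop("unknown species '", name, "'; available: ",
         paste(tab$common_name, collapse = ", "))
  }
  tab[i, , drop = FALSE]
}

#' Layout policy for constructing a layered geometry
#'
#' The source table gives only three structural numbers per corpuscle (outer
#' radius, lamella count, mean lamellar thickness); per-lamella radial
#' locations are not published. The layout policy fills that gap: the inner
#' core occupies a fixed fraction of the outer radius and lamella mid-radii
#' are spaced uniformly between core and outer surface, with the interlamellar
#' fluid gaps as the residual spacing.
#'
#' @param core_fraction Inner-core radius as a fraction of outer radius
#'   (default 0.2).
#' @param nominal_radius_um Outer radius, in micrometres, assigned to
#'   pixel-unit records when simulated through their dimensionless
#'   thickness/radius ratio (default 100).
#' @param min_gap_fallback If `TRUE`, a record whose lamellae are too thick to
#'   fit the available span has its thickness shrunk to leave a minimal gap
#'   instead of erroring.
#' @param min_gap_fraction Minimal gap width as a fraction of lamellar
#'   thickness used by the fallback (default 0.1).
#' @return A `layout_policy` list.
#' @export
layout_policy <- function(core_fraction = 0.2, nominal_radius_um = 100,
                          min_gap_fallback = FALSE, min_gap_fraction = 0.1) {
  stopifnot(core_fraction > 0, core_fraction < 1, nominal_radius_um > 0,
            min_gap_fraction > 0)
  structure(list(core_fraction = core_fraction,
                 nominal_radius_um = nominal_radius_um,
                 min_gap_fallback = min_gap_fallback,
                 min_gap_fraction = min_gap_fraction),
            class = "layout_policy")
}

#' Build a concentric-layer corpuscle geometry
#'
#' Converts a species record (outer radius R, lamella count N, lamellar
#' thickness h) into a simulation-ready layered geometry: N lamellae of
#' thickness h with uniformly spaced mid-radii between the inner-core surface
#' and the outer surface, separated by N+1 fluid gaps (gap 0 sits above the
#' core, gap N under the driven outer surface). All lengths are stored in
#' metres.
#'
#' Pixel-unit records carry no absolute scale; they are simulated through the
#' dimensionless h/R ratio at the layout's nominal radius and flagged
#' `ratio_mode`.
#'
#' @param record One-row `species_table` data frame, or a list with fields
#'   `outer_radius` (um), `n_lamellae`, `lamellar_thickness` (um) and
#'   optionally `radius_unit`/`thickness_unit`.
#' @param layout A [layout_policy()].
#' @return A `corpuscle_geometry` list with elements `R`, `r_core` (m),
#'   `r_mid`, `h`, `gaps` (m; length N, N and N+1), `n_lamellae`,
#'   `ratio_mode`, `species`.
#' @export
#' @examples
#' geom <- build_geometry(species_record("cat"))
#' geom$n_lamellae              # 30
#' range(geom$r_mid) * 1e6      # within (51.12, 255.6) um
build_geometry <- function(record, layout = layout_policy()) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  N <- as.integer(record$n_lamellae)
  R_um <- record$outer_radius
  h_um <- record$lamellar_thickness
  unit <- if (!is.null(record$radius_unit)) record$radius_unit else "um"
  ratio_mode <- identical(unit, "px")
  if (ratio_mode) {
    # only h/R is meaningful; rescale to the nominal radius
    ratio <- h_um / R_um
    R_um <- layout$nominal_radius_um
    h_um <- ratio * R_um
  }
  if (!is.finite(R_um) || R_um <= 0) stop("outer radius must be positive")
  if (!is.finite(h_um) || h_um <= 0) stop("lamellar thickness must be positive")
  if (N < 1L) stop("need at least one lamella")

  R <- R_um * 1e-6
  h <- h_um * 1e-6
  r_core <- layout$core_fraction * R
  span <- R - r_core
  gap <- (span - N * h) / (N + 1)
  if (gap <= 0) {
    if (layout$min_gap_fallback) {
      gap_target <- layout$min_gap_fraction * h
      h <- (span - (N + 1) * gap_target) / N
      if (h <= 0) stop("geometry infeasible even with minimum-gap fallback")
      gap <- (span - N * h) / (N + 1)
    } else {
      stop(sprintf(paste0("lamellae do not fit: N*h = %.3g um exceeds the ",
                          "available span %.3g um (enable min_gap_fallback ",
                          "or adjust the layout)"),
                   N * h * 1e6, span * 1e6))
    }
  }
  # lamella i occupies [r_core + i*gap + (i-1)*h, r_core + i*gap + i*h]
  i <- seq_len(N)
  r_mid <- r_core + i * gap + (i - 0.5) * h
  geom <- structure(list(R = R, r_core = r_core, r_mid = r_mid,
                         h = rep(h, N), gaps = rep(gap, N + 1L),
                         n_lamellae = N, ratio_mode = ratio_mode,
                         species = if (!is.null(record$common_name))
                           record$common_name else NA_character_),
                    class = "corpuscle_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  with(geom, {
    stopifnot(r_core > 0, R > r_core, all(h > 0), all(gaps > 0),
              all(diff(r_mid) > 0), r_mid[1] > r_core,
              r_mid[length(r_mid)] <= R)
    total <- sum(h) + sum(gaps)
    if (abs(total - (R - r_core)) > 1e-12 * (R - r_core)) {
      stop("geometry inconsistent: thicknesses and gaps do not tile the span")
    }
  })
  invisible(geom)
}

#' @export
print.corpuscle_geometry <- function(x, ...) {
  cat(sprintf("corpuscle geometry%s: R = %.4g um, core %.4g um, %d lamellae (h = %.4g um, gap = %.4g um)%s\n",
              if (!is.na(x$species)) paste0(" [", x$species, "]") else "",
              x$R * 1e6, x$r_core * 1e6, x$n_lamellae, x$h[1] * 1e6,
              x$gaps[1] * 1e6,
              if (x$ratio_mode) " (pixel-ratio mode)" else ""))
  invisible(x)
}

#' Material parameters of the corpuscle outer core
#'
#' Lamellae are elastic shells with Young's modulus `E` (1.4 kPa, from
#' quasi-static experiments on human corpuscles); the interlamellar fluid has
#' viscosity `mu` (3.5 mPa s, roughly five times water at body temperature).
#' `kappa` is the package's single fitted constant: a dimensionless factor on
#' the squeeze-film damping that absorbs the spherical-harmonic mode-shape
#' factors this surrogate does not resolve. It is calibrated once against the
#' cat corpuscle ([calibrate_kappa()]) and then frozen for all species.
#'
#' @param E Lamellar Young's modulus, Pa.
#' @param mu Interlamellar fluid viscosity, Pa s.
#' @param nu Lamellar Poisson ratio (near-incompressible soft tissue).
#' @param kappa Global squeeze-film calibration constant.
#' @param k_core_factor Core areal stiffness as a multiple of the stiffest
#'   lamella's (a nearly rigid backing).
#' @return A `material_params` list.
#' @export
material_params <- function(E = 1400, mu = 3.5e-3, nu = 0.49,
                            kappa = kappa_default(), k_core_factor = 10) {
  stopifnot(E > 0, mu > 0, nu >= 0, nu < 0.5, kappa > 0, k_core_factor > 0)
  structure(list(E = E, mu = mu, nu = nu, kappa = kappa,
                 k_core_factor = k_core_factor),
            class = "material_params")
}

#' The frozen squeeze-film calibration constant
#'
#' Value of `kappa` obtained by calibrating the full pipeline's cat peak
#' frequency to 48 Hz (see [calibrate_kappa()]); frozen here and reused for
#' every species.
#'
#' @return A scalar.
#' @export
kappa_default <- function() 0.0205353
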
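#' Mechanosensitive channel-current parameters
#'
#' The inner-core stage is an analytic surrogate: the core-surface
#' displacement is reduced to a scalar neurite membrane strain by a geometric
#' gain, and strain is converted to channel current by a saturating
#' (Michaelis-type) function. Defaults were fixed, together with the
#' calibrated mechanics constant, so that the cat pipeline entrains at its
#' 48 Hz tuning minimum with thresholds in the 0.01-100 um decade.
#'
#' @param I_max Saturating current, nA.
#' @param eps_sat Strain at half-saturation (dimensionless).
#' @param gain Strain per unit relative core compression (dimensionless).
#' @param rectification `"half"` (compression-only gating; default) or
#'   `"full"`.
#' @return A `channel_params` list.
#' @export
channel_params <- function(I_max = 10, eps_sat = 0.01, gain = 30,
                           rectification = c("half", "full")) {
  rectification <- match.arg(rectification)
  stopifnot(I_max > 0, eps_sat > 0, gain > 0)
  structure(list(I_max = I_max, eps_sat = eps_sat, gain = gain,
                 rectification = rectification),
            class = "channel_params")
}

#' Neurite membrane strain from inner-core displacement
#'
#' Geometric reduction of the Stage-1 output: the compressive phase of the
#' core-surface displacement, normalised by the core radius and scaled by a
#' gain, is taken as the neurite membrane strain:
#' `eps(t) = G * max(u(t), 0) / r_core` (half-wave rectified; full-wave uses
#' `|u|`). Strain is non-negative by construction and linear in `u` before
#' rectification.
#'
#' @param u_inner Inner-core surface displacement time series, m.
#' @param r_core Core radius, m.
#' @param gain Dimensionless gain `G`.
#' @param rectification `"half"` or `"full"`.
#' @return Strain time series (dimensionless, >= 0).
#' @export
neurite_strain <- function(u_inner, r_core, gain = 1,
                           rectification = c("half", "full")) {
  rectification <- match.arg(rectification)
  if (!is.finite(r_core) || r_core <= 0) stop("r_core must be positive")
  u_pos <- if (rectification == "half") pmax(u_inner, 0) else abs(u_inner)
  gain * u_pos / r_core
}

#' Channel current from membrane strain
#'
#' Monotone saturating conversion `I = I_max * eps / (eps + eps_sat)`:
#' zero at rest, half-saturated at `eps = eps_sat`, asymptoting to `I_max`.
#'
#' @param eps Strain (dimensionless, >= 0; rectification happens upstream in
#'   [neurite_strain()]).
#' @param params A [channel_params()].
#' @return Current, nA, in `[0, I_max)`.
#' @export
channel_current <- function(eps, params = channel_params()) {
  if (any(eps < 0)) stop("strain must be non-negative (rectify upstream)")
  params$I_max * eps / (eps + params$eps_sat)
}
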
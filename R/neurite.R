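#' Conductance-based point-neuron parameters
#'
#' Classic sodium-potassium-leak excitable membrane (squid-axon parameter
#' set), with every gating rate multiplied by a temperature factor
#' `phi = 3^((T_C - 6.3) / 10)`. The afferent's preferred stimulus period and
#' its one-spike-per-cycle ceiling both scale with `phi`; the package default
#' temperature places the membrane's tuning dip in the observed 40-50 Hz
#' cluster while still following stimuli well above 100 Hz. (At 30 C and
#' beyond the classic parameter set heat-blocks: gating becomes quasi-
#' instantaneous and the membrane cannot spike at all, so a body-temperature
#' setting is not usable.) The same neuron is used for every species.
#'
#' @param C_m Membrane capacitance, uF/cm^2.
#' @param g_Na,g_K,g_L Maximal conductances, mS/cm^2.
#' @param E_Na,E_K,E_L Reversal potentials, mV.
#' @param T_C Temperature, Celsius.
#' @param membrane_area Neurite membrane area, cm^2; converts the channel
#'   current (nA) into a current density.
#' @return A `neuron_params` list (includes the derived `phi`).
#' @export
neuron_params <- function(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                          E_Na = 50, E_K = -77, E_L = -54.387,
                          T_C = 4, membrane_area = 1e-4) {
  stopifnot(C_m > 0, g_Na >= 0, g_K >= 0, g_L >= 0, membrane_area > 0)
  phi <- 3^((T_C - 6.3) / 10)
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L, T_C = T_C, phi = phi,
                 membrane_area = membrane_area),
            class = "neuron_params")
}

#' Integrate the membrane equation under an arbitrary current drive
#'
#' Fixed-step fourth-order Runge-Kutta integration of the four-state
#' conductance model from rest. The drive is a current time series sampled at
#' the integration step.
#'
#' @param I_drive Current drive, nA, sampled every `dt` seconds (length
#'   determines the duration).
#' @param params A [neuron_params()].
#' @param dt Time step, s. Must be at most 0.025 ms; the 1e-5 s default keeps
#'   fourth-order Runge-Kutta comfortably inside its stability region for all
#'   temperatures up to ~27 C.
#' @return Membrane voltage time series, mV, same length as `I_drive`.
#' @export
integrate_neuron <- function(I_drive, params = neuron_params(), dt = 1e-5) {
  stopifnot(dt > 0, dt <= 2.5e-5)
  J <- I_drive * 1e-3 / params$membrane_area   # nA -> uA/cm^2
  hh_integrate_cpp(J, dt, params$C_m, params$g_Na, params$g_K, params$g_L,
                   params$E_Na, params$E_K, params$E_L, params$phi)
}

#' Detect spikes as upward threshold crossings
#'
#' @param V Voltage time series, mV, uniformly sampled.
#' @param dt Sampling step, s.
#' @param threshold Crossing threshold, mV.
#' @param min_isi Refractory floor, s: a crossing closer than this to the
#'   previous accepted spike is discarded.
#' @return A `spike_train` list: `spike_times` (s, strictly increasing) and
#'   `duration` (s).
#' @export
detect_spikes <- function(V, dt, threshold = 0, min_isi = 1e-3) {
  stopifnot(dt > 0, min_isi >= 0)
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  times <- up * dt
  kept <- numeric(0)
  t_last <- -Inf
  for (t in times) {
    if (t - t_last >= min_isi) {
      kept <- c(kept, t)
      t_last <- t
    }
  }
  structure(list(spike_times = kept, duration = (length(V) - 1L) * dt),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes over %.4g s\n",
              length(x$spike_times), x$duration))
  invisible(x)
}

#' Mean firing rate over an analysis window
#'
#' @param train A `spike_train`.
#' @param window Numeric `c(t0, t1)`, s; spikes in `[t0, t1)` are counted.
#'   The window should exclude the onset transient (the tuning pipeline drops
#'   the first five stimulus cycles).
#' @return Rate, Hz.
#' @export
firing_rate <- function(train, window = c(0, train$duration)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  n <- sum(train$spike_times >= window[1] & train$spike_times < window[2])
  n / (window[2] - window[1])
}

#' Steady-state firing rate under the corpuscle's sinusoidal drive
#'
#' Fast path through all three stages for a pure-tone stimulus: the inner-core
#' displacement amplitude (Stage 1 output) is converted to strain and
#' saturating channel current analytically inside the integrator, and spikes
#' are counted over the last `n_cycles - skip_cycles` stimulus cycles.
#'
#' @param f Stimulus frequency, Hz.
#' @param u_inner_amp Inner-core displacement amplitude, m.
#' @param r_core Core radius, m.
#' @param channel A [channel_params()].
#' @param neuron A [neuron_params()].
#' @param n_cycles,skip_cycles Total and discarded stimulus cycles.
#' @param dt Integration step, s.
#' @return Steady-state firing rate, Hz.
#' @export
entrain_rate <- function(f, u_inner_amp, r_core, channel = channel_params(),
                         neuron = neuron_params(), n_cycles = 25L,
                         skip_cycles = 5L, dt = 1e-5) {
  stopifnot(f > 0, u_inner_amp >= 0, n_cycles > skip_cycles)
  res <- hh_entrain_cpp(f, u_inner_amp, r_core, channel$gain, channel$I_max,
                        channel$eps_sat,
                        identical(channel$rectification, "full"),
                        neuron$membrane_area, dt, as.integer(n_cycles),
                        as.integer(skip_cycles), 0, 1e-3,
                        neuron$C_m, neuron$g_Na, neuron$g_K, neuron$g_L,
                        neuron$E_Na, neuron$E_K, neuron$E_L, neuron$phi)
  res$rate_hz
}
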
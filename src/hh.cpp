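#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classic sodium-potassium-leak excitable membrane, all gating rates scaled
// by a temperature factor phi = Q10^((T - 6.3)/10), Q10 = 3. V in mV, time in
// ms, currents in uA/cm^2. Fixed-step fourth-order Runge-Kutta.

struct HHParams {
  double Cm, gNa, gK, gL, ENa, EK, EL, phi;
};

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

struct HHState { double V, m, h, n; };

static inline void hh_deriv(const HHState &s, double I, const HHParams &p,
                            HHState &d) {
  double am = 0.1 * vtrap(s.V + 40.0, 10.0);
  double bm = 4.0 * std::exp(-(s.V + 65.0) / 18.0);
  double ah = 0.07 * std::exp(-(s.V + 65.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(s.V + 35.0) / 10.0));
  double an = 0.01 * vtrap(s.V + 55.0, 10.0);
  double bn = 0.125 * std::exp(-(s.V + 65.0) / 80.0);
  double INa = p.gNa * s.m * s.m * s.m * s.h * (s.V - p.ENa);
  double IK = p.gK * s.n * s.n * s.n * s.n * (s.V - p.EK);
  double IL = p.gL * (s.V - p.EL);
  d.V = (I - INa - IK - IL) / p.Cm;
  d.m = p.phi * (am * (1.0 - s.m) - bm * s.m);
  d.h = p.phi * (ah * (1.0 - s.h) - bh * s.h);
  d.n = p.phi * (an * (1.0 - s.n) - bn * s.n);
}

static inline void rk4_step(HHState &s, double I0, double Imid, double I1,
                            double dt, const HHParams &p) {
  HHState k1, k2, k3, k4, tmp;
  hh_deriv(s, I0, p, k1);
  tmp.V = s.V + 0.5 * dt * k1.V; tmp.m = s.m + 0.5 * dt * k1.m;
  tmp.h = s.h + 0.5 * dt * k1.h; tmp.n = s.n + 0.5 * dt * k1.n;
  hh_deriv(tmp, Imid, p, k2);
  tmp.V = s.V + 0.5 * dt * k2.V; tmp.m = s.m + 0.5 * dt * k2.m;
  tmp.h = s.h + 0.5 * dt * k2.h; tmp.n = s.n + 0.5 * dt * k2.n;
  hh_deriv(tmp, Imid, p, k3);
  tmp.V = s.V + dt * k3.V; tmp.m = s.m + dt * k3.m;
  tmp.h = s.h + dt * k3.h; tmp.n = s.n + dt * k3.n;
  hh_deriv(tmp, I1, p, k4);
  s.V += dt / 6.0 * (k1.V + 2.0 * k2.V + 2.0 * k3.V + k4.V);
  s.m += dt / 6.0 * (k1.m + 2.0 * k2.m + 2.0 * k3.m + k4.m);
  s.h += dt / 6.0 * (k1.h + 2.0 * k2.h + 2.0 * k3.h + k4.h);
  s.n += dt / 6.0 * (k1.n + 2.0 * k2.n + 2.0 * k3.n + k4.n);
}

static HHState rest_state() {
  HHState s;
  s.V = -65.0;
  double am = 0.1 * vtrap(s.V + 40.0, 10.0);
  double bm = 4.0 * std::exp(-(s.V + 65.0) / 18.0);
  double ah = 0.07 * std::exp(-(s.V + 65.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(s.V + 35.0) / 10.0));
  double an = 0.01 * vtrap(s.V + 55.0, 10.0);
  double bn = 0.125 * std::exp(-(s.V + 65.0) / 80.0);
  s.m = am / (am + bm); s.h = ah / (ah + bh); s.n = an / (an + bn);
  return s;
}

// [[Rcpp::export]]
NumericVector hh_integrate_cpp(NumericVector I_drive, double dt_s,
                               double Cm, double gNa, double gK, double gL,
                               double ENa, double EK, double EL, double phi) {
  int n = I_drive.size();
  if (n < 2) stop("drive must have at least two samples");
  double dt = dt_s * 1e3; // ms
  HHParams p = {Cm, gNa, gK, gL, ENa, EK, EL, phi};
  HHState s = rest_state();
  NumericVector V(n);
  V[0] = s.V;
  for (int i = 0; i + 1 < n; ++i) {
    double I0 = I_drive[i], I1 = I_drive[i + 1];
    rk4_step(s, I0, 0.5 * (I0 + I1), I1, dt, p);
    if (!std::isfinite(s.V) || std::fabs(s.V) > 500.0)
      stop("integration unstable (non-finite voltage); reduce dt");
    V[i + 1] = s.V;
  }
  return V;
}

// Drive the neuron with the corpuscle pipeline's sinusoidal inner-core
// displacement, computing the mechanosensitive current analytically at each
// substep; count entrained spikes in the analysis window.
// [[Rcpp::export]]
List hh_entrain_cpp(double f_hz, double u_amp_m, double r_core_m, double gain,
                    double I_max_nA, double eps_sat, bool full_wave,
                    double area_cm2, double dt_s, int n_cycles,
                    int skip_cycles, double v_threshold, double min_isi_s,
                    double Cm, double gNa, double gK, double gL,
                    double ENa, double EK, double EL, double phi) {
  if (f_hz <= 0) stop("frequency must be positive");
  double dt = dt_s * 1e3;                  // ms
  double period_ms = 1e3 / f_hz;
  double t_total = n_cycles * period_ms;
  double t_skip = skip_cycles * period_ms;
  long n_steps = (long)std::ceil(t_total / dt);
  double w = 2.0 * M_PI * f_hz * 1e-3;     // rad per ms
  double amp_strain = gain * u_amp_m / r_core_m;
  double nA_to_uAcm2 = 1e-3 / area_cm2;
  HHParams p = {Cm, gNa, gK, gL, ENa, EK, EL, phi};
  HHState s = rest_state();

  double min_isi_ms = min_isi_s * 1e3;
  double t_last_spike = -1e9;
  int n_spikes = 0;
  double v_prev = s.V, v_max = s.V;

  for (long i = 0; i < n_steps; ++i) {
    double t0 = i * dt, t1 = t0 + dt, tm = t0 + 0.5 * dt;
    double e0 = amp_strain * std::sin(w * t0);
    double em = amp_strain * std::sin(w * tm);
    double e1 = amp_strain * std::sin(w * t1);
    e0 = full_wave ? std::fabs(e0) : std::max(e0, 0.0);
    em = full_wave ? std::fabs(em) : std::max(em, 0.0);
    e1 = full_wave ? std::fabs(e1) : std::max(e1, 0.0);
    double I0 = I_max_nA * e0 / (e0 + eps_sat) * nA_to_uAcm2;
    double Im = I_max_nA * em / (em + eps_sat) * nA_to_uAcm2;
    double I1 = I_max_nA * e1 / (e1 + eps_sat) * nA_to_uAcm2;
    rk4_step(s, I0, Im, I1, dt, p);
    if (!std::isfinite(s.V) || std::fabs(s.V) > 500.0)
      stop("integration unstable (non-finite voltage); reduce dt");
    if (s.V > v_max) v_max = s.V;
    if (v_prev < v_threshold && s.V >= v_threshold &&
        (t1 - t_last_spike) >= min_isi_ms) {
      t_last_spike = t1;
      if (t1 >= t_skip) ++n_spikes;
    }
    v_prev = s.V;
  }
  double window_s = (n_cycles - skip_cycles) * period_ms * 1e-3;
  return List::create(_["rate_hz"] = n_spikes / window_s,
                      _["n_spikes"] = n_spikes,
                      _["v_max"] = v_max);
}
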
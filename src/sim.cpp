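#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// KLVA activation rate functions (1/ms); voltage in mV.
static inline double alpha_d(double V) { return 0.20 * std::exp((V + 60.0) / 21.8); }
static inline double beta_d(double V)  { return 0.17 * std::exp(-(V + 60.0) / 14.0); }

// Forward-Euler integration of one model variant.
//
// Unit system: mV, ms, nS, pF, pA (so I/C is mV/ms and g*V is pA with no
// conversion factors). g_syn is sampled piecewise-constant per step; I_ext is
// either a scalar or a per-step vector. The spike-current state (s1, s2) is
// decayed exactly by exp(-dt/tau_i) each step. Threshold crossings are
// checked at the end of each step on the monitored potential (node if
// present, soma otherwise); the crossing time T_theta is located within the
// step by linear interpolation so that spike timing is (nearly) independent
// of dt. The spike-current components are initialised with their exactly
// decayed values A_i * exp(-(t_end - T_theta)/tau_i), and the charge the
// transient would have delivered between T_theta and the end of the crossing
// step, sum_i A_i tau_i (1 - exp(-(t_end - T_theta)/tau_i)), is deposited on
// the spike-generating compartment as a voltage impulse, so the injected
// waveform is both charge-conserving and timed from the crossing itself.
// Detection is disabled for T_ref after a spike (refractory release is
// continuous: if the potential is still above threshold when the refractory
// period ends, the next spike is stamped at T_last + T_ref); membrane
// dynamics and decaying spike currents run on unaltered throughout.
//
// If forced_spike_times is non-empty, threshold detection is bypassed and
// the stereotyped spike currents are injected at exactly those times
// (replaying a recorded spike sequence, e.g. for time-step reliability
// comparisons with a common event sequence).
//
// [[Rcpp::export]]
List cpp_simulate(List spec, NumericVector g_syn, NumericVector I_ext,
                  double dt, int n_steps, List init,
                  int record_stride, bool record_d, bool record_spike_current,
                  bool allow_divergence, NumericVector forced_spike_times) {
  const bool has_node = as<bool>(spec["has_node"]);
  const bool has_gen  = as<bool>(spec["has_gen"]);
  const bool has_klva = as<bool>(spec["has_klva"]);

  const double C_soma = as<double>(spec["C_soma"]);
  const double g_leak = as<double>(spec["g_leak_soma"]);
  const double g_klva = has_klva ? as<double>(spec["g_klva_bar"]) : 0.0;
  const double E_L    = as<double>(spec["E_L"]);
  const double E_K    = has_klva ? as<double>(spec["E_K"]) : 0.0;
  const double E_syn  = as<double>(spec["E_syn"]);
  const double tau_scale = has_klva ? as<double>(spec["tau_scale"]) : 1.0;

  double C_node = 0, g_ln = 0, g_ax = 0;
  if (has_node) {
    C_node = as<double>(spec["C_node"]);
    g_ln   = as<double>(spec["g_leak_node"]);
    g_ax   = as<double>(spec["g_axon"]);
  }
  double I_const = 0, A1 = 0, A2 = 0, tau1 = 1, tau2 = 1,
         V_theta = 0, T_ref = 0;
  if (has_gen) {
    I_const = as<double>(spec["I_const"]);
    A1      = as<double>(spec["A1"]);
    A2      = as<double>(spec["A2"]);
    tau1    = as<double>(spec["tau1"]);
    tau2    = as<double>(spec["tau2"]);
    V_theta = as<double>(spec["V_theta"]);
    T_ref   = as<double>(spec["T_ref"]);
  }

  if ((int)g_syn.size() < n_steps)
    stop("g_syn trace shorter than the number of steps");
  const bool iext_vec = I_ext.size() > 1;
  if (iext_vec && (int)I_ext.size() < n_steps)
    stop("I_ext trace shorter than the number of steps");

  double V  = as<double>(init["V_soma"]);
  double Vn = has_node ? as<double>(init["V_node"]) : 0.0;
  double d  = has_klva ? as<double>(init["d"]) : 0.0;
  double s1 = has_gen ? as<double>(init["s1"]) : 0.0;
  double s2 = has_gen ? as<double>(init["s2"]) : 0.0;

  const double e1 = has_gen ? std::exp(-dt / tau1) : 1.0;
  const double e2 = has_gen ? std::exp(-dt / tau2) : 1.0;

  const int n_rec = n_steps / record_stride + 1;
  NumericVector Vrec(n_rec);
  NumericVector Vnrec(has_node ? n_rec : 0);
  NumericVector drec((record_d && has_klva) ? n_rec : 0);
  NumericVector s1rec((record_spike_current && has_gen) ? n_rec : 0);
  NumericVector s2rec((record_spike_current && has_gen) ? n_rec : 0);

  Vrec[0] = V;
  if (has_node) Vnrec[0] = Vn;
  if (drec.size()) drec[0] = d;
  if (s1rec.size()) { s1rec[0] = s1; s2rec[0] = s2; }

  std::vector<double> spk_t;  // continuous crossing times (ms)
  std::vector<int> spk_step;  // step index at which each crossing was found
  double T_last = R_NegInf;   // time of last crossing (ms)
  bool has_last = false;
  if (!Rf_isNull(init["t_last_spike"])) {
    T_last = as<double>(init["t_last_spike"]);
    has_last = true;
  }
  bool clamped = false;
  int diverged_at = -1;
  int ri = 0;
  const bool forced = forced_spike_times.size() > 0;
  int next_forced = 0;

  for (int i = 0; i < n_steps; ++i) {
    const double gs = g_syn[i];
    const double Ie = iext_vec ? I_ext[i] : I_ext[0];
    const double Ispk = s1 + s2;

    double I_soma = g_leak * (E_L - V) + gs * (E_syn - V) + Ie;
    double dinf = 0, taud = 1;
    if (has_klva) {
      const double a = alpha_d(V), b = beta_d(V);
      dinf = a / (a + b);
      taud = tau_scale / (a + b);
      I_soma += g_klva * d * (E_K - V);
    }
    const double Vmon_old = has_node ? Vn : V;
    double Vn_new = Vn;
    if (has_node) {
      I_soma += g_ax * (Vn - V);
      const double I_node = g_ln * (E_L - Vn) + g_ax * (V - Vn) + I_const + Ispk;
      Vn_new = Vn + dt * I_node / C_node;
    } else if (has_gen) {
      I_soma += I_const + Ispk;
    }
    const double V_new = V + dt * I_soma / C_soma;

    if (has_klva) {
      d += dt * (dinf - d) / taud;
      if (d < 0.0) { d = 0.0; clamped = true; }
      else if (d > 1.0) { d = 1.0; clamped = true; }
    }
    s1 *= e1;
    s2 *= e2;
    V = V_new;
    Vn = Vn_new;

    if (!std::isfinite(V) || (has_node && !std::isfinite(Vn)) ||
        (has_klva && !std::isfinite(d))) {
      diverged_at = i + 1;
      if (!allow_divergence)
        stop("non-finite membrane state at t = %g ms (step %d); "
             "the time step is too large for this model", (i + 1) * dt, i + 1);
      for (int k = ri + 1; k < n_rec; ++k) {
        Vrec[k] = NA_REAL;
        if (has_node) Vnrec[k] = NA_REAL;
        if (drec.size()) drec[k] = NA_REAL;
        if (s1rec.size()) { s1rec[k] = NA_REAL; s2rec[k] = NA_REAL; }
      }
      ri = n_rec - 1;
      break;
    }

    if (has_gen) {
      const double t_end = (i + 1) * dt;
      // charge-conserving injection of the spike transient started at T
      const auto inject = [&](double T) {
        const double x1 = (t_end - T) / tau1;
        const double x2 = (t_end - T) / tau2;
        const double dQ = A1 * tau1 * (1.0 - std::exp(-x1)) +
                          A2 * tau2 * (1.0 - std::exp(-x2));
        if (has_node) Vn += dQ / C_node; else V += dQ / C_soma;
        s1 += A1 * std::exp(-x1);
        s2 += A2 * std::exp(-x2);
        spk_t.push_back(T);
        spk_step.push_back(i + 1);
      };
      if (forced) {
        while (next_forced < forced_spike_times.size() &&
               forced_spike_times[next_forced] <= t_end + 1e-9) {
          inject(forced_spike_times[next_forced]);
          ++next_forced;
        }
      } else {
        const double Vmon = has_node ? Vn : V;
        const bool free = !has_last || (t_end - T_last >= T_ref - 1e-12);
        if (Vmon >= V_theta && free) {
          double T_theta;
          if (Vmon_old < V_theta) {
            const double f = (V_theta - Vmon_old) / (Vmon - Vmon_old);
            T_theta = (i + f) * dt;
          } else {
            T_theta = i * dt;  // already above threshold at the step start
          }
          if (has_last && T_theta < T_last + T_ref) T_theta = T_last + T_ref;
          T_last = T_theta;
          has_last = true;
          inject(T_theta);
        }
      }
    }

    if ((i + 1) % record_stride == 0) {
      ++ri;
      Vrec[ri] = V;
      if (has_node) Vnrec[ri] = Vn;
      if (drec.size()) drec[ri] = d;
      if (s1rec.size()) { s1rec[ri] = s1; s2rec[ri] = s2; }
    }
  }

  return List::create(
    _["V_soma"] = Vrec,
    _["V_node"] = has_node ? (SEXP)Vnrec : R_NilValue,
    _["d"] = drec.size() ? (SEXP)drec : R_NilValue,
    _["s1"] = s1rec.size() ? (SEXP)s1rec : R_NilValue,
    _["s2"] = s2rec.size() ? (SEXP)s2rec : R_NilValue,
    _["spike_times"] = wrap(spk_t),
    _["spike_steps"] = wrap(spk_step),
    _["d_clamped"] = clamped,
    _["diverged_at_step"] = diverged_at,
    _["final"] = List::create(
      _["V_soma"] = V, _["V_node"] = has_node ? Vn : NA_REAL,
      _["d"] = has_klva ? d : NA_REAL, _["s1"] = s1, _["s2"] = s2,
      _["t_last_spike"] = has_last ? T_last : NA_REAL));
}

// Superposition of alpha kernels H * (t/tau) * exp(1 - t/tau) at the given
// event times, sampled on a grid of n_grid points spaced dt apart. Each
// kernel is truncated at trunc_mult * tau past its onset.
//
// [[Rcpp::export]]
NumericVector cpp_alpha_conductance(NumericVector spike_times, int n_grid,
                                    double dt, double H, double tau,
                                    double trunc_mult) {
  NumericVector g(n_grid);
  const double width = trunc_mult * tau;
  const int n = spike_times.size();
  for (int k = 0; k < n; ++k) {
    const double ts = spike_times[k];
    int j0 = (int)std::ceil(ts / dt);
    if (j0 < 0) j0 = 0;
    int j1 = (int)std::floor((ts + width) / dt);
    if (j1 >= n_grid) j1 = n_grid - 1;
    for (int j = j0; j <= j1; ++j) {
      const double x = (j * dt - ts) / tau;
      if (x >= 0.0) g[j] += H * x * std::exp(1.0 - x);
    }
  }
  return g;
}
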
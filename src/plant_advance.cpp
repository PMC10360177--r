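#include <Rcpp.h>
using namespace Rcpp;

// Advance the respiratory plant by n_sub explicit-Euler substeps of length dt
// with the stimulation command held constant (zero-order hold over one control
// interval).  Substep order matches the R reference composition in
// plant_advance(..., use_compiled = FALSE):
//   1. intrinsic drive and effective activations from the current state
//   2. oscillator phase advance, wrap, Hering-Breuer reset against current V
//   3. lung volume Euler update
//   4. fatigue state Euler update (clipped to [0, 1])
//
// state: V, F_dia, F_eic, theta
// pars:  tau_lung, g_dia, g_eic, g_syn, D0, T0, V_HB, V_release, kf_dia,
//        rho_dia, kf_eic, rho_eic, hb_on
// returns: V, F_dia, F_eic, theta, onset_sub (1-based substep at which the
//          oscillator wrapped into intrinsic inspiration, 0 if none),
//          n_resets, V_max
// [[Rcpp::export]]
NumericVector plant_advance_cpp(NumericVector state, NumericVector pars,
                                double a_dia, double a_eic,
                                double q_dia_rate, double q_eic_rate,
                                int n_sub, double dt) {
  double V = state[0], F_dia = state[1], F_eic = state[2], theta = state[3];
  const double tau = pars[0], g_dia = pars[1], g_eic = pars[2],
               g_syn = pars[3], D0 = pars[4], T0 = pars[5], V_HB = pars[6],
               V_release = pars[7], kf_dia = pars[8], rho_dia = pars[9],
               kf_eic = pars[10], rho_eic = pars[11];
  const bool hb_on = pars[12] != 0.0;
  int onset_sub = 0, n_resets = 0;
  double V_max = V;

  for (int i = 0; i < n_sub; ++i) {
    // intrinsic drive: half-sine over the inspiratory half of the cycle
    double intr = (theta < 0.5) ? std::sin(2.0 * M_PI * theta) : 0.0;
    double ad = a_dia * (1.0 - F_dia);
    double ae = a_eic * (1.0 - F_eic);

    // oscillator advance; the inflation reflex (V >= V_HB) both defers the
    // next inspiratory onset (expiratory prolongation) and terminates an
    // ongoing inspiration (phase jump to the expiratory half)
    theta += dt / T0;
    if (theta >= 1.0) {
      if (hb_on && V >= V_release) {
        theta = 1.0 - 1e-9;          // onset inhibited until the lung deflates
      } else {
        theta -= 1.0;
        onset_sub = i + 1;
      }
    }
    if (hb_on && V >= V_HB && theta < 0.5) {
      theta = 0.5;
      ++n_resets;
    }

    // first-order lung mechanics with diaphragm-intercostal synergy
    double P = D0 * intr + g_dia * ad + g_eic * ae + g_syn * ad * ae;
    V += dt * (P - V) / tau;
    if (V < 0.0) V = 0.0;
    if (V > V_max) V_max = V;

    // charge-driven fatigue with first-order recovery
    F_dia += dt * (kf_dia * q_dia_rate * (1.0 - F_dia) - rho_dia * F_dia);
    if (F_dia < 0.0) F_dia = 0.0; else if (F_dia > 1.0) F_dia = 1.0;
    F_eic += dt * (kf_eic * q_eic_rate * (1.0 - F_eic) - rho_eic * F_eic);
    if (F_eic < 0.0) F_eic = 0.0; else if (F_eic > 1.0) F_eic = 1.0;
  }

  NumericVector out(7);
  out[0] = V; out[1] = F_dia; out[2] = F_eic; out[3] = theta;
  out[4] = onset_sub; out[5] = n_resets; out[6] = V_max;
  return out;
}
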
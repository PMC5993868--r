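#include <Rcpp.h>
using namespace Rcpp;

// Channel parameter matrix layout (one row per channel):
//  0 gbar (mS/cm2), 1 e_rev (mV),
//  2 act power, 3 act v_half, 4 act slope, 5 act tau_type (0 const, 1 bell),
//  6 act tau1 (const or tau_min), 7 act tau2 (tau_max), 8 act v_peak, 9 act width,
// 10 has_inact (0/1), 11 inact power, 12 inact v_half, 13 inact slope,
// 14 inact tau_type, 15 inact tau1, 16 inact tau2, 17 inact v_peak, 18 inact width

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double tau_of(double v, double type, double t1, double t2,
                            double vp, double w) {
  if (type < 0.5) return t1;
  double z = (v - vp) / w;
  return t1 + (t2 - t1) * std::exp(-z * z);
}

// [[Rcpp::export(name = ".cc_integrate")]]
List cc_integrate(double v0, double dt, double cm, double g_leak, double e_leak,
                  NumericVector inj_density, NumericMatrix ch,
                  bool record_currents) {
  const int n = inj_density.size();
  const int nch = ch.nrow();
  NumericVector v(n);
  NumericMatrix cur(record_currents ? n : 1, record_currents ? nch : 1);

  std::vector<double> m(nch), h(nch);
  for (int c = 0; c < nch; ++c) {
    m[c] = boltz(v0, ch(c, 3), ch(c, 4));
    h[c] = (ch(c, 10) > 0.5) ? boltz(v0, ch(c, 12), ch(c, 13)) : 1.0;
  }

  v[0] = v0;
  for (int i = 0; i < n; ++i) {
    double vi = v[i];
    double i_ion = g_leak * (vi - e_leak);
    for (int c = 0; c < nch; ++c) {
      double g = ch(c, 0) * std::pow(m[c], ch(c, 2));
      if (ch(c, 10) > 0.5) g *= std::pow(h[c], ch(c, 11));
      double ic = g * (vi - ch(c, 1));
      if (record_currents) cur(i, c) = ic;
      i_ion += ic;
    }
    if (i == n - 1) break;
    v[i + 1] = vi + dt * (-i_ion + inj_density[i]) / cm;
    if (!std::isfinite(v[i + 1]) || std::fabs(v[i + 1]) > 500.0) {
      stop("membrane potential diverged (|V| > 500 mV) at t = %.3f ms",
           (i + 1) * dt);
    }
    // exponential-Euler gate update at the pre-step voltage
    for (int c = 0; c < nch; ++c) {
      double minf = boltz(vi, ch(c, 3), ch(c, 4));
      double taum = tau_of(vi, ch(c, 5), ch(c, 6), ch(c, 7), ch(c, 8), ch(c, 9));
      m[c] = minf + (m[c] - minf) * std::exp(-dt / taum);
      if (ch(c, 10) > 0.5) {
        double hinf = boltz(vi, ch(c, 12), ch(c, 13));
        double tauh =
            tau_of(vi, ch(c, 14), ch(c, 15), ch(c, 16), ch(c, 17), ch(c, 18));
        h[c] = hinf + (h[c] - hinf) * std::exp(-dt / tauh);
      }
    }
  }

  return List::create(_["v"] = v, _["currents"] = cur);
}
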
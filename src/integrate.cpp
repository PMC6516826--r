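#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step exponential-Euler integration of a single-compartment
// threshold-reset neuron with a linear first-order sag current and a
// spike-triggered adaptation current:
//
//   C dV/dt   = -gL (V - EL) - Iw - Ia + Iinj(t)
//   tau_w dIw = gsag min(V - EL, 0) - Iw   (hyperpolarization-activated)
//   tau_a dIa = -Ia ;  Ia += aInc at each spike
//
// Units: ms, mV, pA, nS, pF (so pA/pF = mV/ms and pF/nS = ms).
// A spike is registered when V crosses vth from below; a stylized action
// potential (linear upstroke to vpeak over upSamples, downstroke to vreset
// over downSamples) is painted into the trace so that downstream slope-based
// spike detection sees a realistic waveform; integration resumes from vreset.
//
// [[Rcpp::export]]
List integrate_membrane_cpp(int n, double dt, double C, double gL, double EL,
                            double gsag, double tausag,
                            double vth, double vreset, double vpeak,
                            double aInc, double tauA,
                            NumericVector iinj,
                            int upSamples, int downSamples,
                            double v0) {
  NumericVector V(n);
  std::vector<double> spikes;
  double v = v0, Iw = 0.0, Ia = 0.0;
  const double eV = std::exp(-dt * gL / C);
  const double eW = tausag > 0 ? std::exp(-dt / tausag) : 0.0;
  const double eA = tauA > 0 ? std::exp(-dt / tauA) : 1.0;
  int hold = 0;        // samples left in the painted AP waveform
  double holdFrom = 0; // waveform start voltage
  int holdTotal = upSamples + downSamples;

  for (int i = 0; i < n; ++i) {
    if (hold > 0) {
      int k = holdTotal - hold; // 0-based position within waveform
      double vv;
      if (k < upSamples) {
        vv = holdFrom + (vpeak - holdFrom) * (double)(k + 1) / upSamples;
      } else {
        vv = vpeak + (vreset - vpeak) * (double)(k - upSamples + 1) / downSamples;
      }
      V[i] = vv;
      // sag and adaptation currents keep evolving during the waveform
      double wInf = gsag * std::min(vv - EL, 0.0);
      Iw = wInf + (Iw - wInf) * eW;
      Ia *= eA;
      v = vreset;
      hold--;
      continue;
    }
    double vInf = EL + (iinj[i] - Iw - Ia) / gL;
    v = vInf + (v - vInf) * eV;
    if (v >= vth) {
      spikes.push_back(i * dt);
      Ia += aInc;
      holdFrom = vth;
      hold = holdTotal;
      V[i] = vth;
      // re-enter waveform painting from the next sample
      double wInf = gsag * std::min(vth - EL, 0.0);
      Iw = wInf + (Iw - wInf) * eW;
      v = vreset;
      continue;
    }
    V[i] = v;
    double wInf = gsag * std::min(v - EL, 0.0);
    Iw = wInf + (Iw - wInf) * eW;
    Ia *= eA;
  }
  return List::create(_["voltage"] = V,
                      _["spike_times"] = wrap(spikes));
}
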
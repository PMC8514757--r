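#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;

static tt06::Mult mult_from(const NumericVector &m) {
  if (m.size() != 12) stop("conductance multiplier vector must have length 12");
  tt06::Mult mm;
  mm.gNa = m[0]; mm.gCaL = m[1]; mm.gKr = m[2]; mm.gKs = m[3];
  mm.gto = m[4]; mm.gK1 = m[5]; mm.gpCa = m[6]; mm.gpK = m[7];
  mm.gbNa = m[8]; mm.gbCa = m[9]; mm.pNaK = m[10]; mm.kNaCa = m[11];
  return mm;
}

static void check_finite(const double *s) {
  for (int i = 0; i < tt06::N_STATE; ++i)
    if (!R_finite(s[i]))
      stop("integration failure: non-finite state variable '%s'",
           tt06::state_name(i));
}

// [[Rcpp::export]]
NumericVector cpp_cell_default_state() {
  NumericVector out(tt06::N_STATE);
  tt06::default_state(REAL(out));
  return out;
}

// advance a single cell n_steps with constant stimulus current
// [[Rcpp::export]]
List cpp_cell_steps(NumericVector state, NumericVector mult, double i_stim,
                    double dt, int n_steps, int record_stride) {
  if (state.size() != tt06::N_STATE) stop("state must have length 19");
  tt06::Mult mm = mult_from(mult);
  tt06::Tables &tab = tt06::tables_for(dt);
  std::vector<double> s(state.begin(), state.end());
  int nrec = record_stride > 0 ? n_steps / record_stride : 0;
  NumericVector vm_trace(nrec), t_trace(nrec);
  int k = 0;
  for (int n = 0; n < n_steps; ++n) {
    if (!tt06::step(s.data(), mm, i_stim, dt, tab)) {
      check_finite(s.data());
      stop("integration failure: vm left [-120, 95] mV");
    }
    if (record_stride > 0 && (n + 1) % record_stride == 0 && k < nrec) {
      vm_trace[k] = s[0];
      t_trace[k] = (n + 1) * dt;
      ++k;
    }
  }
  check_finite(s.data());
  NumericVector out(s.begin(), s.end());
  out.attr("names") = state.attr("names");
  return List::create(_["state"] = out, _["t"] = t_trace, _["vm"] = vm_trace);
}

// pace a single cell: square stimulus pulses at a fixed cycle length.
// Per beat: diastolic vm (just before the stimulus), peak vm, upstroke time
// (-40 mV upward crossing, linear interpolation), APD90 (upstroke to
// repolarization to 90% of that beat's amplitude).
// [[Rcpp::export]]
List cpp_pace_cell(NumericVector state, NumericVector mult, double dt,
                   double bcl, int n_beats, double stim_amp,
                   double stim_dur, int trace_last_beats) {
  if (state.size() != tt06::N_STATE) stop("state must have length 19");
  tt06::Mult mm = mult_from(mult);
  tt06::Tables &tab = tt06::tables_for(dt);
  std::vector<double> s(state.begin(), state.end());

  NumericVector apd90(n_beats, NA_REAL), peak(n_beats), rest(n_beats),
      t_up(n_beats, NA_REAL);
  long steps_per_beat = (long)std::floor(bcl / dt + 0.5);
  long stim_steps = (long)std::floor(stim_dur / dt + 0.5);
  long total = steps_per_beat * n_beats;
  long trace_from = trace_last_beats > 0
                        ? total - steps_per_beat * trace_last_beats
                        : total;
  std::vector<double> tr_t, tr_v;
  if (trace_last_beats > 0)
    tr_v.reserve(steps_per_beat * trace_last_beats);

  int beat = -1;
  double vprev = s[0];
  bool seen_up = false;
  double v90 = 0.0;
  for (long n = 0; n < total; ++n) {
    long in_beat = n % steps_per_beat;
    if (in_beat == 0) {
      ++beat;
      rest[beat] = s[0];
      peak[beat] = s[0];
      seen_up = false;
    }
    double istim = (in_beat < stim_steps) ? stim_amp : 0.0;
    vprev = s[0];
    if (!tt06::step(s.data(), mm, istim, dt, tab)) {
      check_finite(s.data());
      stop("integration failure: vm left [-120, 95] mV");
    }
    double t = (n + 1) * dt;
    double v = s[0];
    if (v > peak[beat]) peak[beat] = v;
    if (!seen_up && vprev < -40.0 && v >= -40.0) {
      t_up[beat] = t - dt * (v + 40.0) / (v - vprev);
      seen_up = true;
      v90 = NA_REAL;  // resolved once peak is known (lazy: set below)
    }
    // APD90: first downward crossing of rest + 0.1*(peak - rest) after peak
    if (seen_up && !R_finite(apd90[beat])) {
      double thr = rest[beat] + 0.1 * (peak[beat] - rest[beat]);
      if (vprev > thr && v <= thr && t > t_up[beat] + 5.0) {
        double tc = t - dt * (thr - v) / (vprev - v);
        apd90[beat] = tc - t_up[beat];
      }
    }
    if (n >= trace_from) {
      tr_t.push_back(t);
      tr_v.push_back(v);
    }
  }
  check_finite(s.data());
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = state.attr("names");
  return List::create(_["state"] = fin, _["apd90"] = apd90, _["peak"] = peak,
                      _["rest"] = rest, _["t_upstroke"] = t_up,
                      _["trace_t"] = NumericVector(tr_t.begin(), tr_t.end()),
                      _["trace_vm"] = NumericVector(tr_v.begin(), tr_v.end()));
}
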
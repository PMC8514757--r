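#include <Rcpp.h>
#include <cstring>
#include "tt06.h"

using namespace Rcpp;

// Operator-split anisotropic monodomain integration over the conducting
// nodes of a tissue grid.
//
//   state    19 x n matrix of per-node ionic states (compact node order)
//   mult     12 x n per-node conductance multipliers (tissue class + I_Ks)
//   p, j, x  CSR arrays of the diffusion operator L (row-sum zero, units
//            1/ms); the diffusion update is V <- V + dt_diff * (L V)
//   stimuli  onset/duration/amplitude plus flattened node-index lists
//
// Reaction is stepped at dt_r for `sub` substeps per diffusion step
// (dt_diff = sub * dt_r). Probe voltages are recorded every reaction step;
// full-voltage frames every record_stride ms (0 = no frames).
// [[Rcpp::export]]
List cpp_run_monodomain(NumericMatrix state, NumericMatrix mult,
                        IntegerVector p, IntegerVector j, NumericVector x,
                        double dt_r, int sub, double duration, double t0,
                        NumericVector stim_on, NumericVector stim_dur,
                        NumericVector stim_amp, IntegerVector stim_idx,
                        IntegerVector stim_ptr, double record_stride,
                        IntegerVector probes) {
  const int n = state.ncol();
  if (state.nrow() != tt06::N_STATE) stop("state must be 19 x n");
  if (mult.ncol() != n || mult.nrow() != 12) stop("mult must be 12 x n");
  if ((int)p.size() != n + 1) stop("CSR row pointer has wrong length");
  const int nstim = stim_on.size();

  tt06::Tables &tab = tt06::tables_for(dt_r);
  std::vector<tt06::Mult> mm(n);
  for (int i = 0; i < n; ++i) {
    tt06::Mult &m = mm[i];
    m.gNa = mult(0, i); m.gCaL = mult(1, i); m.gKr = mult(2, i);
    m.gKs = mult(3, i); m.gto = mult(4, i); m.gK1 = mult(5, i);
    m.gpCa = mult(6, i); m.gpK = mult(7, i); m.gbNa = mult(8, i);
    m.gbCa = mult(9, i); m.pNaK = mult(10, i); m.kNaCa = mult(11, i);
  }

  // working copy of states, node-major for cache locality
  std::vector<double> S((size_t)n * tt06::N_STATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < tt06::N_STATE; ++k)
      S[(size_t)i * tt06::N_STATE + k] = state(k, i);

  const long n_macro = (long)std::floor(duration / (dt_r * sub) + 0.5);
  const long n_react = n_macro * sub;
  const double dt_diff = dt_r * sub;

  const int nprobe = probes.size();
  NumericMatrix probe_vm(n_react, nprobe);
  NumericVector probe_t(n_react);

  long n_frames = 0, frame_every = 0;
  if (record_stride > 0) {
    frame_every = (long)std::floor(record_stride / dt_diff + 0.5);
    if (frame_every < 1) frame_every = 1;
    n_frames = n_macro / frame_every;
  }
  NumericMatrix frames(n_frames > 0 ? n : 0, n_frames);
  NumericVector frame_t(n_frames);

  std::vector<double> istim(n, 0.0), vbuf(n), dv(n);
  long react_step = 0, frame_k = 0;

  for (long mstep = 0; mstep < n_macro; ++mstep) {
    for (int s = 0; s < sub; ++s, ++react_step) {
      double t = t0 + react_step * dt_r;
      std::memset(istim.data(), 0, n * sizeof(double));
      // 1e-6 ms slack so chunked runs with fp-differing time origins
      // resolve stimulus windows to the same reaction steps
      for (int q = 0; q < nstim; ++q) {
        if (t >= stim_on[q] - 1e-6 && t < stim_on[q] + stim_dur[q] - 1e-6) {
          for (int a = stim_ptr[q]; a < stim_ptr[q + 1]; ++a)
            istim[stim_idx[a]] += stim_amp[q];
        }
      }
      for (int i = 0; i < n; ++i) {
        if (!tt06::step(&S[(size_t)i * tt06::N_STATE], mm[i], istim[i], dt_r,
                        tab)) {
          for (int k = 0; k < tt06::N_STATE; ++k)
            if (!R_finite(S[(size_t)i * tt06::N_STATE + k]))
              stop("integration failure at t=%.2f ms, node %d: non-finite "
                   "'%s'", t, i + 1, tt06::state_name(k));
          stop("instability at t=%.2f ms, node %d: vm left [-120, 95] mV", t,
               i + 1);
        }
      }
      double tnow = t0 + (react_step + 1) * dt_r;
      for (int q = 0; q < nprobe; ++q)
        probe_vm(react_step, q) = S[(size_t)probes[q] * tt06::N_STATE];
      probe_t[react_step] = tnow;
    }
    // diffusion: V += dt_diff * L V
    for (int i = 0; i < n; ++i) vbuf[i] = S[(size_t)i * tt06::N_STATE];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int a = p[i]; a < p[i + 1]; ++a) acc += x[a] * vbuf[j[a]];
      dv[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      double v = vbuf[i] + dt_diff * dv[i];
      if (!(v > tt06::VERR_LO && v < tt06::VERR_HI))
        stop("instability at t=%.2f ms, node %d: vm=%.1f mV after diffusion",
             t0 + (mstep + 1) * dt_diff, i + 1, v);
      S[(size_t)i * tt06::N_STATE] = v;
    }
    if (frame_every > 0 && (mstep + 1) % frame_every == 0 &&
        frame_k < n_frames) {
      for (int i = 0; i < n; ++i)
        frames(i, frame_k) = S[(size_t)i * tt06::N_STATE];
      frame_t[frame_k] = t0 + (mstep + 1) * dt_diff;
      ++frame_k;
    }
    if (mstep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(tt06::N_STATE, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < tt06::N_STATE; ++k)
      fin(k, i) = S[(size_t)i * tt06::N_STATE + k];

  return List::create(_["state"] = fin, _["probe_t"] = probe_t,
                      _["probe_vm"] = probe_vm, _["frame_t"] = frame_t,
                      _["frames"] = frames);
}
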
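// Compiled forward-Euler core for the CSD reaction-diffusion model.
//
// One call advances the coupled (K, R) fields n_steps steps with the 5-point
// zero-flux Laplacian, applying stimulus clamps, block freezes and the
// F-modulated recovery rate, and records probe traces and field snapshots.
// The scheme is identical to the R reference stepper csd_step(); tests
// assert agreement between the two.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Event {
  std::vector<int> idx;  // 0-based cell indices (column-major)
  int s_on, s_off;       // active at state step m when s_on <= m < s_off
  double amplitude;      // stimulus only
  int insulate;          // block only: 1 = no-flux walls around the region
};

int step_of(double t, double dt) {
  // first integer step index m with m*dt >= t (tolerant to rounding)
  return (int)std::ceil(t / dt - 1e-9);
}

std::vector<Event> read_events(List evs, double dt, bool with_amp) {
  std::vector<Event> out;
  for (int i = 0; i < evs.size(); ++i) {
    List e = evs[i];
    Event ev;
    IntegerVector idx = e["idx"];
    ev.idx.assign(idx.begin(), idx.end());
    ev.s_on = step_of(as<double>(e["t_on"]), dt);
    ev.s_off = step_of(as<double>(e["t_off"]), dt);
    ev.amplitude = with_amp ? as<double>(e["amplitude"]) : 0.0;
    ev.insulate = (!with_amp && e.containsElementNamed("insulate"))
                      ? as<int>(e["insulate"]) : 0;
    out.push_back(ev);
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix K0, NumericMatrix R0, List par, int form,
              LogicalMatrix modulated, List stimuli, List blocks,
              IntegerMatrix probes, int n_steps, int probe_stride,
              int snap_stride, bool snap_R) {
  const int nr = K0.nrow(), nc = K0.ncol(), n = nr * nc;
  const double A = par["A"], B = par["B"], C = par["C"], Dd = par["D"],
               E = par["E"], Ff = par["F"], Krest = par["K_rest"],
               Ktheta = par["K_theta"], Kmax = par["K_max"],
               Rrest = par["R_rest"], dt = par["dt"], dx = par["dx"];
  const double inv_dx2 = 1.0 / (dx * dx);

  std::vector<double> K(K0.begin(), K0.end()), R(R0.begin(), R0.end());
  std::vector<double> Kn(n), Rn(n);
  std::vector<int> mod(n);
  for (int i = 0; i < n; ++i) mod[i] = modulated[i] ? 1 : 0;

  std::vector<Event> stim = read_events(stimuli, dt, true);
  std::vector<Event> blk = read_events(blocks, dt, false);

  const int np = probes.nrow();
  std::vector<int> pidx(np);
  for (int p = 0; p < np; ++p) pidx[p] = probes(p, 0) + probes(p, 1) * nr;

  const int n_rec = 1 + (probe_stride > 0 ? n_steps / probe_stride : 0);
  NumericVector rec_t(n_rec);
  NumericMatrix rec_K(n_rec, np), rec_R(n_rec, np);
  const int n_snap = snap_stride > 0 ? 1 + n_steps / snap_stride : 0;
  NumericVector snap_t(std::max(n_snap, 0));
  NumericVector snapK(n_snap > 0 ? (R_xlen_t)n * n_snap : 0);
  NumericVector snapRv((n_snap > 0 && snap_R) ? (R_xlen_t)n * n_snap : 0);

  int irec = 0, isnap = 0;
  rec_t[0] = 0.0;
  for (int p = 0; p < np; ++p) { rec_K(0, p) = K[pidx[p]]; rec_R(0, p) = R[pidx[p]]; }
  irec = 1;
  if (n_snap > 0) {
    snap_t[0] = 0.0;
    std::copy(K.begin(), K.end(), snapK.begin());
    if (snap_R) std::copy(R.begin(), R.end(), snapRv.begin());
    isnap = 1;
  }

  // cells inside an active insulated block: frozen and walled off (their
  // faces behave like the outer zero-flux boundary)
  std::vector<unsigned char> ins(n, 0);
  int ins_stamp = -1;  // last step the mask was rebuilt for
  bool any_ins = false;
  for (const Event& e : blk) any_ins = any_ins || e.insulate;
  auto rebuild_ins = [&](int m) {
    std::fill(ins.begin(), ins.end(), 0);
    for (const Event& e : blk) {
      if (e.insulate && m >= e.s_on && m < e.s_off) {
        for (int k : e.idx) ins[k] = 1;
      }
    }
    ins_stamp = m;
  };

  for (int s = 0; s < n_steps; ++s) {
    const int m = s + 1;  // step index of the new state
    if (any_ins) {
      bool edge = ins_stamp < 0;
      for (const Event& e : blk) {
        edge = edge || m == e.s_on || m == e.s_off;
      }
      if (edge) rebuild_ins(m);
    }
    // Euler update with mirror-ghost Laplacian
    for (int j = 0; j < nc; ++j) {
      const int jl = (j == 0 ? 0 : j - 1), jr = (j == nc - 1 ? nc - 1 : j + 1);
      const int c = j * nr, cl = jl * nr, cr = jr * nr;
      for (int i = 0; i < nr; ++i) {
        const int iu = (i == 0 ? 0 : i - 1), id = (i == nr - 1 ? nr - 1 : i + 1);
        const int k = c + i;
        const double Kc = K[k], Rc = R[k];
        if (any_ins && ins[k]) { Kn[k] = Kc; Rn[k] = Rc; continue; }
        double lap;
        if (any_ins) {
          const double Ku = ins[c + iu] ? Kc : K[c + iu];
          const double Kd = ins[c + id] ? Kc : K[c + id];
          const double Kl = ins[cl + i] ? Kc : K[cl + i];
          const double Kr2 = ins[cr + i] ? Kc : K[cr + i];
          lap = (Ku + Kd + Kl + Kr2 - 4.0 * Kc) * inv_dx2;
        } else {
          lap = (K[c + iu] + K[c + id] + K[cl + i] + K[cr + i] - 4.0 * Kc) *
                inv_dx2;
        }
        double f;
        const double dKr = Kc - Krest;
        if (form == 0) {
          f = dKr * (A * (Kc - Ktheta) * (Kc - Kmax) - B * (Rc - Rrest));
        } else {
          f = A * dKr * (Kc - Ktheta) * (Kc - Kmax) - B * (Rc - Rrest);
        }
        double dR = E * dKr - C * (Rc - Rrest);
        if (mod[k] && dR < 0.0) dR *= Ff;
        Kn[k] = Kc + dt * (Dd * lap + f);
        Rn[k] = Rc + dt * dR;
      }
    }
    // block freeze (absolute-refractory clamp; insulated blocks were
    // already skipped in the update)
    for (const Event& e : blk) {
      if (!e.insulate && m >= e.s_on && m < e.s_off) {
        for (int k : e.idx) { Kn[k] = K[k]; Rn[k] = R[k]; }
      }
    }
    K.swap(Kn);
    R.swap(Rn);
    // stimulus clamp
    for (const Event& e : stim) {
      if (m >= e.s_on && m < e.s_off) {
        for (int k : e.idx) K[k] = e.amplitude;
      }
    }
    // blow-up detection
    for (int k = 0; k < n; ++k) {
      if (!std::isfinite(K[k]) || !std::isfinite(R[k])) {
        stop("numerical blow-up at step %d (t = %g); check dt against the "
             "stability bound dx^2/(4*D) and the reaction stiffness",
             m, m * dt);
      }
    }
    if (probe_stride > 0 && m % probe_stride == 0) {
      rec_t[irec] = m * dt;
      for (int p = 0; p < np; ++p) {
        rec_K(irec, p) = K[pidx[p]];
        rec_R(irec, p) = R[pidx[p]];
      }
      ++irec;
    }
    if (snap_stride > 0 && m % snap_stride == 0) {
      snap_t[isnap] = m * dt;
      std::copy(K.begin(), K.end(), snapK.begin() + (R_xlen_t)isnap * n);
      if (snap_R)
        std::copy(R.begin(), R.end(), snapRv.begin() + (R_xlen_t)isnap * n);
      ++isnap;
    }
  }

  NumericMatrix Kf(nr, nc), Rf(nr, nc);
  std::copy(K.begin(), K.end(), Kf.begin());
  std::copy(R.begin(), R.end(), Rf.begin());
  if (n_snap > 0) snapK.attr("dim") = IntegerVector::create(nr, nc, n_snap);
  if (n_snap > 0 && snap_R) snapRv.attr("dim") = IntegerVector::create(nr, nc, n_snap);

  return List::create(
      _["times"] = rec_t, _["probe_K"] = rec_K, _["probe_R"] = rec_R,
      _["snap_times"] = snap_t, _["snap_K"] = snapK, _["snap_R"] = snapRv,
      _["K"] = Kf, _["R"] = Rf, _["step_index"] = n_steps);
}
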
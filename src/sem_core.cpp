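#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Morse force magnitude with symmetric cap.  delta = r - r_eq, so the sign of
// the returned value matches the sign of delta (attraction when stretched).
static inline double morse_mag(double J, double rho, double delta, double cap_mult) {
  double m = 2.0 * J * rho * (std::exp(2.0 * rho * delta) - std::exp(rho * delta));
  double cap = cap_mult * J * rho;
  if (m >  cap) m =  cap;
  if (m < -cap) m = -cap;
  return m;
}

// Overdamped explicit-Euler integration of the spring/particle system.
//
// pos        n x 3 particle positions (membrane + intracellular, all cells)
// si, sj     1-based spring endpoints (internal membrane edges + cytoskeleton)
// req, Jsp   per-spring equilibrium length and interaction strength
// lambda     per-particle friction coefficient
// la, lb     1-based endpoints of active external (adhesion) links
// f_applied  n x 3 constant external load (0 x 0 when absent)
// lumen_*    radial Morse source acting on lumen_targets (empty when inactive)
//
// Returns final positions and the elastic energy at the start of every step.
// [[Rcpp::export]]
List cpp_sem_steps(NumericMatrix pos_in,
                   IntegerVector si, IntegerVector sj,
                   NumericVector req, NumericVector Jsp,
                   double rho,
                   NumericVector lambda,
                   IntegerVector la, IntegerVector lb,
                   NumericMatrix f_applied,
                   IntegerVector lumen_targets,
                   NumericVector lumen_center,
                   double lumen_R, double lumen_J,
                   int n_steps, double dt, double cap_mult) {
  const int n = pos_in.nrow();
  const int ns = si.size();
  const int nl = la.size();
  const int nt = lumen_targets.size();
  const bool has_load = f_applied.nrow() == n;

  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos_in(i, 0); py[i] = pos_in(i, 1); pz[i] = pos_in(i, 2);
  }
  std::vector<double> gx(n), gy(n), gz(n), fx(n), fy(n), fz(n);
  NumericVector energy(n_steps);

  for (int step = 0; step < n_steps; ++step) {
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    double E = 0.0;

    for (int s = 0; s < ns; ++s) {
      const int i = si[s] - 1, j = sj[s] - 1;
      const double dx = px[j] - px[i], dy = py[j] - py[i], dz = pz[j] - pz[i];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12)
        stop("coincident particles on spring %d (particles %d and %d) at step %d",
             s + 1, i + 1, j + 1, step + 1);
      const double delta = r - req[s];
      E += delta * delta;
      const double f = morse_mag(Jsp[s], rho, delta, cap_mult) / r;
      gx[i] += f * dx; gy[i] += f * dy; gz[i] += f * dz;
      gx[j] -= f * dx; gy[j] -= f * dy; gz[j] -= f * dz;
    }
    energy[step] = E;

    // External force transmission: each linked particle additionally receives
    // its partner's internal + cytoskeleton force sum.
    std::copy(gx.begin(), gx.end(), fx.begin());
    std::copy(gy.begin(), gy.end(), fy.begin());
    std::copy(gz.begin(), gz.end(), fz.begin());
    for (int l = 0; l < nl; ++l) {
      const int a = la[l] - 1, b = lb[l] - 1;
      fx[a] += gx[b]; fy[a] += gy[b]; fz[a] += gz[b];
      fx[b] += gx[a]; fy[b] += gy[a]; fz[b] += gz[a];
    }

    // Specific forces: radial Morse repulsion from the lumen source.
    for (int t = 0; t < nt; ++t) {
      const int i = lumen_targets[t] - 1;
      const double dx = lumen_center[0] - px[i];
      const double dy = lumen_center[1] - py[i];
      const double dz = lumen_center[2] - pz[i];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;  // at the source: direction undefined, skip
      const double f = morse_mag(lumen_J, rho, r - lumen_R, cap_mult) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    }

    if (has_load) {
      for (int i = 0; i < n; ++i) {
        fx[i] += f_applied(i, 0); fy[i] += f_applied(i, 1); fz[i] += f_applied(i, 2);
      }
    }

    for (int i = 0; i < n; ++i) {
      const double mob = dt / lambda[i];
      px[i] += mob * fx[i]; py[i] += mob * fy[i]; pz[i] += mob * fz[i];
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("non-finite position for particle %d at step %d", i + 1, step + 1);
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  return List::create(_["pos"] = out, _["energy"] = energy);
}

// Greedy nearest-first adhesion pairing.  Candidate particle pairs (1-based)
// are pre-filtered by the caller (Moore-neighbour cells, no excluded pairs);
// this selects pairs closer than `cutoff`, nearest first, honouring a
// per-particle link quota.
// [[Rcpp::export]]
List cpp_pair_links(NumericMatrix pos,
                    IntegerVector ca, IntegerVector cb,
                    double cutoff, int max_links) {
  const int nc = ca.size();
  const double c2 = cutoff * cutoff;
  std::vector<int> keep;
  std::vector<double> d2;
  keep.reserve(nc / 8 + 1);
  for (int k = 0; k < nc; ++k) {
    const int a = ca[k] - 1, b = cb[k] - 1;
    const double dx = pos(a, 0) - pos(b, 0);
    const double dy = pos(a, 1) - pos(b, 1);
    const double dz = pos(a, 2) - pos(b, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < c2) { keep.push_back(k); d2.push_back(r2); }
  }
  std::vector<int> ord(keep.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (d2[x] != d2[y]) return d2[x] < d2[y];
    return keep[x] < keep[y];  // deterministic tie-break
  });
  std::vector<int> cnt(pos.nrow(), 0);
  std::vector<int> outa, outb;
  for (int o : ord) {
    const int k = keep[o];
    const int a = ca[k], b = cb[k];
    if (cnt[a - 1] < max_links && cnt[b - 1] < max_links) {
      outa.push_back(a); outb.push_back(b);
      ++cnt[a - 1]; ++cnt[b - 1];
    }
  }
  return List::create(_["a"] = wrap(outa), _["b"] = wrap(outb));
}
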
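// Core of the loop-extrusion engine: independent-move generation under
// barrier/boundary constraints, LEF-LEF collision resolution, and the
// per-cell epoch loop. Positions are double-precision but always integral
// base pairs (doubles hold exact integers far beyond chromosome sizes).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int STALL_NONE = 0, STALL_BARRIER = 1, STALL_LEFLEF = 2;

struct Unit {
  double pos;  // current position (bp)
  double tgt;  // constrained target position after this epoch's move
  int lef;     // owning LEF index
  bool fwd;    // true: moves 5'->3' (increasing coordinates)
  int stall;
};

// Boundary and barrier constraints applied to each unit independently.
// Barriers must be sorted by position; block: 0 = blocks reverse units,
// 1 = blocks forward units. A unit whose move would land on or cross a
// Bound blocking barrier stops 1 bp before it.
static void independent_targets(std::vector<Unit>& units,
                                const std::vector<double>& stride,
                                const std::vector<double>& bpos,
                                const std::vector<int>& bblock,
                                const std::vector<int>& bbound,
                                double L) {
  const int nb = (int)bpos.size();
  for (size_t u = 0; u < units.size(); ++u) {
    Unit& un = units[u];
    un.stall = STALL_NONE;
    if (un.fwd) {
      double t = std::min(un.pos + stride[u], L - 1);
      int k = (int)(std::lower_bound(bpos.begin(), bpos.end(), un.pos + 1) -
                    bpos.begin());
      for (; k < nb && bpos[k] <= t; ++k) {
        if (bbound[k] && bblock[k] == 1) {
          t = bpos[k] - 1;
          un.stall = STALL_BARRIER;
          break;
        }
      }
      un.tgt = t;
    } else {
      double t = std::max(un.pos - stride[u], 0.0);
      int k = (int)(std::lower_bound(bpos.begin(), bpos.end(), un.pos) -
                    bpos.begin());
      for (--k; k >= 0 && bpos[k] >= t; --k) {
        if (bbound[k] && bblock[k] == 0) {
          t = bpos[k] + 1;
          un.stall = STALL_BARRIER;
          break;
        }
      }
      un.tgt = t;
    }
  }
}

// LEF-LEF constraint resolution. Units of different LEFs may not pass one
// another: in genomic sort order, neighboring units keep their order, two
// approaching units split the remaining gap (odd spare bp to the unit ranked
// first in genomic order) and stop adjacent, and a unit blocked by an
// already-stalled unit stalls behind it. The relaxation sweeps alternate
// directions; every update is monotone (forward units' targets only
// decrease, reverse units' only increase), so it converges.
static void resolve_core(std::vector<Unit>& units) {
  const int m = (int)units.size();
  if (m <= 1) return;
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (units[a].pos != units[b].pos) return units[a].pos < units[b].pos;
    // rev before fwd at the same position: co-located opposite-direction
    // units (fresh loops, binding collisions) diverge rather than collide
    if (units[a].fwd != units[b].fwd) return !units[a].fwd;
    return units[a].lef < units[b].lef;
  });
  std::vector<double> sep(m - 1);
  for (int i = 0; i + 1 < m; ++i) {
    const Unit& a = units[ord[i]];
    const Unit& b = units[ord[i + 1]];
    // same-LEF units diverge and never conflict; co-located foreign units
    // (possible right after binding) need no separating bp
    sep[i] = (a.lef == b.lef) ? -1.0 : std::min(1.0, b.pos - a.pos);
  }
  auto relax_pair = [&](int i) -> bool {
    if (sep[i] < 0) return false;
    Unit& a = units[ord[i]];
    Unit& b = units[ord[i + 1]];
    if (a.tgt <= b.tgt - sep[i]) return false;
    bool changed = false;
    if (a.fwd && !b.fwd) {  // approaching pair: split the free gap
      double gap = b.pos - a.pos - sep[i];
      double wi = a.tgt - a.pos, wj = b.pos - b.tgt;
      double afair = std::ceil(gap / 2.0);
      double mva = std::min(wi, std::max(afair, gap - wj));
      double mvb = std::min(wj, gap - mva);
      double fa = a.pos + mva, fb = b.pos - mvb;
      if (fa != a.tgt) { a.tgt = fa; a.stall = STALL_LEFLEF; changed = true; }
      if (fb != b.tgt) { b.tgt = fb; b.stall = STALL_LEFLEF; changed = true; }
    } else if (a.fwd && b.fwd) {  // a catches up with b
      double fa = std::max(a.pos, b.tgt - sep[i]);
      if (fa < a.tgt) { a.tgt = fa; a.stall = STALL_LEFLEF; changed = true; }
    } else if (!a.fwd && !b.fwd) {  // b catches up with a
      double fb = std::min(b.pos, a.tgt + sep[i]);
      if (fb > b.tgt) { b.tgt = fb; b.stall = STALL_LEFLEF; changed = true; }
    }
    // rev-then-fwd pairs move apart: no conflict possible
    return changed;
  };
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 2 * m + 4) {
    changed = false;
    for (int i = 0; i + 1 < m; ++i)
      if (relax_pair(i)) changed = true;
    for (int i = m - 2; i >= 0; --i)
      if (relax_pair(i)) changed = true;
  }
  for (int i = 0; i + 1 < m; ++i) {
    if (units[ord[i]].tgt > units[ord[i + 1]].tgt)
      stop("internal error: extrusion units crossed during collision resolution");
  }
}

// [[Rcpp::export]]
List resolve_collisions_cpp(NumericVector rev_pos, NumericVector fwd_pos,
                            NumericVector rev_stride, NumericVector fwd_stride,
                            NumericVector bar_pos, IntegerVector bar_block,
                            LogicalVector bar_bound, double L) {
  const int n = rev_pos.size();
  if (fwd_pos.size() != n || rev_stride.size() != n || fwd_stride.size() != n)
    stop("rev/fwd position and stride vectors must have equal length");
  std::vector<Unit> units(2 * n);
  std::vector<double> stride(2 * n);
  for (int i = 0; i < n; ++i) {
    units[i] = {rev_pos[i], rev_pos[i], i, false, STALL_NONE};
    stride[i] = rev_stride[i];
    units[n + i] = {fwd_pos[i], fwd_pos[i], i, true, STALL_NONE};
    stride[n + i] = fwd_stride[i];
  }
  std::vector<double> bp(bar_pos.begin(), bar_pos.end());
  std::vector<int> bb(bar_block.begin(), bar_block.end());
  std::vector<int> bd(bar_bound.begin(), bar_bound.end());
  independent_targets(units, stride, bp, bb, bd, L);
  resolve_core(units);
  NumericVector rp(n), fp(n);
  IntegerVector rs(n), fs(n);
  for (int i = 0; i < n; ++i) {
    rp[i] = units[i].tgt;
    rs[i] = units[i].stall;
    fp[i] = units[n + i].tgt;
    fs[i] = units[n + i].stall;
  }
  return List::create(_["rev_pos"] = rp, _["fwd_pos"] = fp,
                      _["rev_stall"] = rs, _["fwd_stall"] = fs);
}

// One simulation instance (cell x chromosome): burn-in followed by the
// contact-sampling epoch loop. The RNG is R's; callers seed it per task.
// [[Rcpp::export]]
List simulate_cell_cpp(double L, int nlefs, NumericVector bar_pos,
                       IntegerVector bar_block, NumericVector bar_occ,
                       NumericVector bar_puu, NumericVector bar_pbb,
                       List par) {
  const double bin_size = as<double>(par["bin_size"]);
  const int band_rows = as<int>(par["band_rows"]);
  const double mean_stride = as<double>(par["mean_stride"]);
  const double stride_sd = as<double>(par["stride_sd"]);
  const double p_release = as<double>(par["p_release"]);
  const double hard_mult = as<double>(par["hard_mult"]);
  const double fsample = as<double>(par["sampling_fraction"]);
  const double tad_ratio = as<double>(par["tad_ratio"]);
  const int mode = as<int>(par["contact_mode"]);  // 0 all, 1 loop-only, 2 tad-only
  const double target_contacts = as<double>(par["target_contacts"]);  // < 0: off
  const int max_epochs = as<int>(par["max_epochs"]);
  const int burn_in_window = as<int>(par["burn_in_window"]);
  const double burn_in_tol = as<double>(par["burn_in_tol"]);
  const int burn_in_max = as<int>(par["burn_in_max"]);
  const double track_bin = as<double>(par["track_bin"]);  // 0: off
  const bool collect_lifetimes = as<bool>(par["collect_lifetimes"]);

  const int nb = bar_pos.size();
  std::vector<double> bpos(bar_pos.begin(), bar_pos.end());
  std::vector<int> bblock(bar_block.begin(), bar_block.end());
  std::vector<int> bbound(nb);
  for (int b = 0; b < nb; ++b)
    bbound[b] = (bar_occ[b] > 0) && (unif_rand() < bar_occ[b]);

  std::vector<double> rev(nlefs), fwd(nlefs);
  std::vector<int> stallR(nlefs, STALL_NONE), stallF(nlefs, STALL_NONE);
  std::vector<int> bind_epoch(nlefs, 0);
  std::vector<bool> active(nlefs, false);
  int n_active = 0;

  std::vector<int> cb1, cb2, lifetimes;
  double contacts = 0, discards = 0;
  const int ntrack = track_bin > 0 ? (int)std::ceil(L / track_bin) : 0;
  std::vector<double> visits(ntrack, 0.0);

  const int lifetime = std::max(1, (int)std::ceil(1.0 / std::max(p_release, 1e-12)));
  bool burnin = nlefs > 0 && burn_in_max > 0;
  int epoch = 0, burnin_epochs = 0, post_epochs = 0;
  std::vector<double> ls_hist;
  double mls = 0;

  auto record = [&](double x, double y) {
    double bi = std::floor(x / bin_size), bj = std::floor(y / bin_size);
    if (std::fabs(bi - bj) < band_rows) {
      cb1.push_back((int)std::min(bi, bj));
      cb2.push_back((int)std::max(bi, bj));
      contacts += 1;
    } else {
      discards += 1;
    }
  };

  std::vector<Unit> units;
  std::vector<double> stride;

  while (nlefs > 0) {
    // 1. bind inactive LEFs (progressively during burn-in)
    int target_active = nlefs;
    if (burnin) {
      double frac = (double)(burnin_epochs + 1) / lifetime;
      target_active = (int)std::min((double)nlefs, std::ceil(nlefs * frac));
    }
    for (int i = 0; i < nlefs && n_active < target_active; ++i) {
      if (active[i]) continue;
      double p = std::floor(unif_rand() * L);
      if (p >= L) p = L - 1;
      rev[i] = fwd[i] = p;
      stallR[i] = stallF[i] = STALL_NONE;
      bind_epoch[i] = epoch;
      active[i] = true;
      ++n_active;
    }

    // 3. sample contacts (disabled during burn-in); step 2 (indexing) is
    // folded into collision resolution, which sorts the active units
    if (!burnin) {
      for (int i = 0; i < nlefs; ++i) {
        if (!active[i] || unif_rand() >= fsample) continue;
        if (mode != 2) record(rev[i], fwd[i]);
        if (mode != 1 && tad_ratio > 0) {
          int k = (int)std::floor(tad_ratio);
          double fracr = tad_ratio - k;
          if (fracr > 0 && unif_rand() < fracr) ++k;
          double span = fwd[i] - rev[i];
          for (int t = 0; t < k; ++t) {
            double u = rev[i] + std::floor(unif_rand() * (span + 1));
            double v = rev[i] + std::floor(unif_rand() * (span + 1));
            record(std::min(u, fwd[i]), std::min(v, fwd[i]));
          }
        }
      }
    }

    // 4. candidate moves: normal strides truncated at 0, integer bp
    units.clear();
    stride.clear();
    for (int i = 0; i < nlefs; ++i) {
      if (!active[i]) continue;
      double sr = std::round(R::rnorm(mean_stride, stride_sd));
      double sf = std::round(R::rnorm(mean_stride, stride_sd));
      units.push_back({rev[i], rev[i], i, false, STALL_NONE});
      stride.push_back(std::max(sr, 0.0));
      units.push_back({fwd[i], fwd[i], i, true, STALL_NONE});
      stride.push_back(std::max(sf, 0.0));
    }

    // 5. barrier Markov states (occupancy 0 pins a barrier Unbound; the
    // draw is still consumed so masked/unmasked runs stay seed-aligned)
    for (int b = 0; b < nb; ++b) {
      double u = unif_rand();
      bool next = bbound[b] ? (u < bar_pbb[b]) : (u >= bar_puu[b]);
      bbound[b] = (bar_occ[b] > 0) && next;
    }

    // 6.-7. collisions; 8. advance
    independent_targets(units, stride, bpos, bblock, bbound, L);
    resolve_core(units);
    for (size_t u = 0; u < units.size(); ++u) {
      const Unit& un = units[u];
      if (un.fwd) {
        fwd[un.lef] = un.tgt;
        stallF[un.lef] = un.stall;
      } else {
        rev[un.lef] = un.tgt;
        stallR[un.lef] = un.stall;
      }
    }
    if (!burnin && ntrack > 0) {
      for (size_t u = 0; u < units.size(); ++u)
        visits[(int)(units[u].tgt / track_bin)] += 1;
    }

    // 9. release: Bernoulli with lifetime extension for hard-stalled LEFs
    for (int i = 0; i < nlefs; ++i) {
      if (!active[i]) continue;
      double pe = (stallR[i] == STALL_BARRIER && stallF[i] == STALL_BARRIER)
                      ? p_release / hard_mult
                      : p_release;
      if (unif_rand() < pe) {
        active[i] = false;
        --n_active;
        if (collect_lifetimes) lifetimes.push_back(epoch - bind_epoch[i] + 1);
      }
    }

    double tot = 0;
    int na = 0;
    for (int i = 0; i < nlefs; ++i)
      if (active[i]) { tot += fwd[i] - rev[i]; ++na; }
    mls = na > 0 ? tot / na : 0.0;

    ++epoch;
    if (burnin) {
      ++burnin_epochs;
      ls_hist.push_back(mls);
      bool done = burnin_epochs >= burn_in_max;
      const int W = burn_in_window;
      if (!done && target_active == nlefs && (int)ls_hist.size() >= 2 * W) {
        double s1 = 0, s0 = 0;
        const int T = (int)ls_hist.size();
        for (int t = T - W; t < T; ++t) s1 += ls_hist[t];
        for (int t = T - 2 * W; t < T - W; ++t) s0 += ls_hist[t];
        s1 /= W;
        s0 /= W;
        if (std::fabs(s1 - s0) <= burn_in_tol * std::max(s0, 1e-12)) done = true;
      }
      if (done) burnin = false;
    } else {
      ++post_epochs;
      if (target_contacts >= 0 && contacts >= target_contacts) break;
      if (post_epochs >= max_epochs) break;
    }
    if (epoch % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["bin1"] = IntegerVector(cb1.begin(), cb1.end()),
      _["bin2"] = IntegerVector(cb2.begin(), cb2.end()),
      _["contacts"] = contacts, _["discards"] = discards,
      _["epochs"] = epoch, _["burnin_epochs"] = burnin_epochs,
      _["lifetimes"] = IntegerVector(lifetimes.begin(), lifetimes.end()),
      _["track"] = NumericVector(visits.begin(), visits.end()),
      _["mean_loop_size"] = mls, _["n_active"] = n_active);
}
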
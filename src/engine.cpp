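// Structured-coalescent ancestry simulator (Hudson-style), with
// piecewise-constant demography, migration, crossover recombination under a
// rate map, and non-crossover (gene-conversion) recombination with geometric
// tract lengths. Coordinates are 0-based half-open; breakpoints are integer
// positions. Uses R's RNG so that set.seed() in the caller fixes the run.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;   // half-open [l, r), integer-valued
  int node;      // genealogy node currently carrying this material
  int ns;        // number of samples subtended at this interval
};

struct Lin {
  int pop;
  std::vector<Seg> segs;
  double xmass;    // crossover rate mass over the breakable span
  double gclinks;  // number of breakable links (for uniform gc rate)
};

struct RMap {
  std::vector<double> b, r, cb;  // breakpoints, rates, cumulative mass at b
  void init(const NumericVector &bb, const NumericVector &rr) {
    b.assign(bb.begin(), bb.end());
    r.assign(rr.begin(), rr.end());
    cb.resize(b.size());
    cb[0] = 0.0;
    for (size_t i = 1; i < b.size(); ++i)
      cb[i] = cb[i - 1] + (b[i] - b[i - 1]) * r[i - 1];
  }
  double cum(double x) const {
    if (x <= b.front()) return 0.0;
    if (x >= b.back()) return cb.back();
    size_t i = std::upper_bound(b.begin(), b.end(), x) - b.begin() - 1;
    return cb[i] + (x - b[i]) * r[i];
  }
  // smallest y with cum(y) = target (target strictly inside total mass)
  double inv(double target) const {
    size_t i = std::upper_bound(cb.begin(), cb.end(), target) - cb.begin();
    if (i == 0) i = 1;
    --i;
    if (i >= r.size()) return b.back();
    while (i < r.size() && r[i] <= 0.0) ++i;  // skip zero-rate intervals
    if (i >= r.size()) return b.back();
    double y = b[i] + (target - cb[i]) / r[i];
    if (y > b[i + 1]) y = b[i + 1];
    return y;
  }
};

const int EV_COAL = 0, EV_MIG = 1, EV_XO = 2, EV_GC = 3;

struct Engine {
  double L;
  int n_total, ploidy, npop;
  RMap map;
  double gc_rate, gc_mean;
  bool gc_whole_contig;
  std::vector<double> sizes;
  std::vector<std::vector<double> > mig;
  std::vector<double> migRow;   // row sums of mig
  std::vector<Lin> lins;
  std::vector<int> k;           // lineages per pop
  double tot_x, tot_gc, tot_mig;

  std::vector<double> node_time;
  std::vector<int> node_pop;
  std::vector<int> e_par, e_chi;
  std::vector<double> e_l, e_r;
  double counts[6];  // coal, mig, xo_drawn, xo_eff, gc_drawn, gc_eff
  std::vector<double> rec_time;
  std::vector<int> rec_type;
  std::vector<double> tracts;

  void lineageMass(Lin &A) const {
    double a = A.segs.front().l, b = A.segs.back().r;
    A.gclinks = (b - 1.0 > a) ? (b - 1.0 - a) : 0.0;
    A.xmass = (b - 1.0 > a) ? (map.cum(b - 1.0) - map.cum(a)) : 0.0;
  }

  void addTotals(const Lin &A) {
    tot_x += A.xmass;
    tot_gc += A.gclinks;
    tot_mig += migRow[A.pop];
    ++k[A.pop];
  }
  void subTotals(const Lin &A) {
    tot_x -= A.xmass;
    tot_gc -= A.gclinks;
    tot_mig -= migRow[A.pop];
    --k[A.pop];
  }
  void refreshMig() {
    tot_mig = 0.0;
    for (int p = 0; p < npop; ++p) {
      migRow[p] = 0.0;
      for (int q = 0; q < npop; ++q) migRow[p] += mig[p][q];
    }
    for (size_t i = 0; i < lins.size(); ++i) tot_mig += migRow[lins[i].pop];
  }

  int pickLineageInPop(int p, int skip) const {
    // uniform among lineages of pop p, excluding index `skip` (-1 = none)
    int m = k[p] - (skip >= 0 ? 1 : 0);
    int j = (int)std::floor(unif_rand() * m);
    if (j >= m) j = m - 1;
    for (size_t i = 0; i < lins.size(); ++i) {
      if ((int)i == skip || lins[i].pop != p) continue;
      if (j == 0) return (int)i;
      --j;
    }
    Rcpp::stop("internal error: lineage selection failed");
  }

  void record(double t, int type) {
    rec_time.push_back(t);
    rec_type.push_back(type);
  }

  // --- event executors ------------------------------------------------

  void doCoalescence(double t, int p) {
    counts[EV_COAL] += 1;
    record(t, EV_COAL);
    int i1 = pickLineageInPop(p, -1);
    int i2 = pickLineageInPop(p, i1);
    Lin &A = lins[i1];
    Lin &B = lins[i2];
    subTotals(A);
    subTotals(B);

    std::vector<Seg> out;
    out.reserve(A.segs.size() + B.segs.size());
    size_t ia = 0, ib = 0;
    Seg s1, s2;
    bool h1 = false, h2 = false;
    int unode = -1;
    while ((h1 || ia < A.segs.size()) && (h2 || ib < B.segs.size())) {
      if (!h1) { s1 = A.segs[ia++]; h1 = true; }
      if (!h2) { s2 = B.segs[ib++]; h2 = true; }
      if (s1.r <= s2.l) { out.push_back(s1); h1 = false; continue; }
      if (s2.r <= s1.l) { out.push_back(s2); h2 = false; continue; }
      if (s1.l < s2.l) {
        Seg pre = {s1.l, s2.l, s1.node, s1.ns};
        out.push_back(pre);
        s1.l = s2.l;
      } else if (s2.l < s1.l) {
        Seg pre = {s2.l, s1.l, s2.node, s2.ns};
        out.push_back(pre);
        s2.l = s1.l;
      }
      double ol = s1.l, orr = std::min(s1.r, s2.r);
      if (unode < 0) {
        unode = (int)node_time.size();
        node_time.push_back(t);
        node_pop.push_back(p);
      }
      e_par.push_back(unode); e_chi.push_back(s1.node);
      e_l.push_back(ol); e_r.push_back(orr);
      e_par.push_back(unode); e_chi.push_back(s2.node);
      e_l.push_back(ol); e_r.push_back(orr);
      int ns = s1.ns + s2.ns;
      if (ns < n_total) {
        Seg mg = {ol, orr, unode, ns};
        out.push_back(mg);
      }
      s1.l = orr; s2.l = orr;
      if (s1.l >= s1.r) h1 = false;
      if (s2.l >= s2.r) h2 = false;
    }
    while (h1 || ia < A.segs.size()) {
      if (!h1) { s1 = A.segs[ia++]; }
      out.push_back(s1); h1 = false;
    }
    while (h2 || ib < B.segs.size()) {
      if (!h2) { s2 = B.segs[ib++]; }
      out.push_back(s2); h2 = false;
    }
    // squash adjacent same-node segments
    std::vector<Seg> sq;
    sq.reserve(out.size());
    for (size_t i = 0; i < out.size(); ++i) {
      if (!sq.empty() && sq.back().node == out[i].node &&
          sq.back().r == out[i].l && sq.back().ns == out[i].ns)
        sq.back().r = out[i].r;
      else sq.push_back(out[i]);
    }
    // remove: erase higher index first
    int hi = std::max(i1, i2), lo = std::min(i1, i2);
    lins.erase(lins.begin() + hi);
    if (sq.empty()) {
      lins.erase(lins.begin() + lo);
    } else {
      lins[lo].pop = p;
      lins[lo].segs.swap(sq);
      lineageMass(lins[lo]);
      addTotals(lins[lo]);
    }
  }

  void doMigration(double t) {
    counts[EV_MIG] += 1;
    record(t, EV_MIG);
    double u = unif_rand() * tot_mig;
    size_t i = 0;
    for (; i < lins.size(); ++i) {
      u -= migRow[lins[i].pop];
      if (u <= 0) break;
    }
    if (i >= lins.size()) i = lins.size() - 1;
    int p = lins[i].pop;
    double v = unif_rand() * migRow[p];
    int dest = p;
    for (int q = 0; q < npop; ++q) {
      v -= mig[p][q];
      if (v <= 0) { dest = q; break; }
    }
    subTotals(lins[i]);
    lins[i].pop = dest;
    addTotals(lins[i]);
  }

  void doCrossover(double t) {
    counts[2] += 1;  // crossover_drawn
    record(t, EV_XO);
    double u = unif_rand() * tot_x;
    size_t i = 0;
    for (; i < lins.size(); ++i) {
      u -= lins[i].xmass;
      if (u <= 0) break;
    }
    if (i >= lins.size()) i = lins.size() - 1;
    Lin &A = lins[i];
    double a = A.segs.front().l, b = A.segs.back().r;
    double m = unif_rand() * A.xmass;
    double y = map.inv(map.cum(a) + m);
    double kpos = std::floor(y) + 1.0;  // break between floor(y) and floor(y)+1
    if (kpos <= a) kpos = a + 1.0;
    if (kpos >= b) kpos = b - 1.0;
    splitAt(i, kpos);
    counts[3] += 1;  // always effective: both sides of the span are non-empty
  }

  void splitAt(size_t i, double kpos) {
    Lin &A = lins[i];
    std::vector<Seg> left, right;
    for (size_t s = 0; s < A.segs.size(); ++s) {
      const Seg &sg = A.segs[s];
      if (sg.r <= kpos) left.push_back(sg);
      else if (sg.l >= kpos) right.push_back(sg);
      else {
        Seg sl = {sg.l, kpos, sg.node, sg.ns};
        Seg sr = {kpos, sg.r, sg.node, sg.ns};
        left.push_back(sl);
        right.push_back(sr);
      }
    }
    subTotals(A);
    A.segs.swap(left);
    lineageMass(A);
    addTotals(A);
    Lin B;
    B.pop = A.pop;
    B.segs.swap(right);
    lineageMass(B);
    lins.push_back(B);
    addTotals(lins.back());
  }

  void doGeneConversion(double t) {
    counts[4] += 1;  // gc_drawn
    record(t, EV_GC);
    size_t i;
    if (gc_whole_contig) {
      i = (size_t)std::floor(unif_rand() * lins.size());
      if (i >= lins.size()) i = lins.size() - 1;
    } else {
      double u = unif_rand() * tot_gc;
      for (i = 0; i < lins.size(); ++i) {
        u -= lins[i].gclinks;
        if (u <= 0) break;
      }
      if (i >= lins.size()) i = lins.size() - 1;
    }
    Lin &A = lins[i];
    double a = A.segs.front().l, b = A.segs.back().r;
    double kpos;
    if (gc_whole_contig) {
      kpos = 1.0 + std::floor(unif_rand() * (L - 1.0));
      if (kpos > L - 1.0) kpos = L - 1.0;
    } else {
      if (A.gclinks <= 0) return;  // degenerate single-site lineage
      kpos = a + 1.0 + std::floor(unif_rand() * A.gclinks);
      if (kpos > b - 1.0) kpos = b - 1.0;
    }
    double len = 1.0 + R::rgeom(1.0 / gc_mean);
    tracts.push_back(len);
    double tr = std::min(kpos + len, gc_whole_contig ? L : b);
    // split material into tract [kpos, tr) and the rest
    std::vector<Seg> inside, outside;
    for (size_t s = 0; s < A.segs.size(); ++s) {
      Seg sg = A.segs[s];
      if (sg.r <= kpos || sg.l >= tr) { outside.push_back(sg); continue; }
      if (sg.l < kpos) {
        Seg pre = {sg.l, kpos, sg.node, sg.ns};
        outside.push_back(pre);
        sg.l = kpos;
      }
      if (sg.r > tr) {
        Seg post = {tr, sg.r, sg.node, sg.ns};
        Seg in = {sg.l, tr, sg.node, sg.ns};
        inside.push_back(in);
        outside.push_back(post);
      } else inside.push_back(sg);
    }
    if (inside.empty() || outside.empty()) return;  // drawn but ineffective
    std::sort(outside.begin(), outside.end(),
              [](const Seg &x, const Seg &y) { return x.l < y.l; });
    counts[5] += 1;  // gc_effective
    subTotals(A);
    A.segs.swap(outside);
    lineageMass(A);
    addTotals(A);
    Lin B;
    B.pop = A.pop;
    B.segs.swap(inside);
    lineageMass(B);
    lins.push_back(B);
    addTotals(lins.back());
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_ancestry_cpp")]]
List sim_ancestry_cpp(IntegerVector sample_pops, double L,
                      NumericVector map_breaks, NumericVector map_rates,
                      double gc_rate, double gc_mean, bool gc_whole_contig,
                      int ploidy, int npop, NumericVector init_sizes,
                      NumericMatrix init_mig, NumericVector ev_time,
                      IntegerVector ev_type, IntegerVector ev_pop,
                      IntegerVector ev_pop2, NumericVector ev_value,
                      double max_events) {
  Engine E;
  E.L = L;
  E.n_total = sample_pops.size();
  E.ploidy = ploidy;
  E.npop = npop;
  E.map.init(map_breaks, map_rates);
  E.gc_rate = gc_rate;
  E.gc_mean = gc_mean;
  E.gc_whole_contig = gc_whole_contig;
  E.sizes.assign(init_sizes.begin(), init_sizes.end());
  E.mig.assign(npop, std::vector<double>(npop, 0.0));
  for (int p = 0; p < npop; ++p)
    for (int q = 0; q < npop; ++q) E.mig[p][q] = init_mig(p, q);
  E.migRow.assign(npop, 0.0);
  E.k.assign(npop, 0);
  E.tot_x = E.tot_gc = E.tot_mig = 0.0;
  std::fill(E.counts, E.counts + 6, 0.0);

  for (int s = 0; s < E.n_total; ++s) {
    E.node_time.push_back(0.0);
    E.node_pop.push_back(sample_pops[s]);
    Lin A;
    A.pop = sample_pops[s];
    Seg sg = {0.0, L, s, 1};
    A.segs.push_back(sg);
    E.lineageMass(A);
    E.lins.push_back(A);
  }
  E.refreshMig();
  for (size_t i = 0; i < E.lins.size(); ++i) {
    E.tot_x += E.lins[i].xmass;
    E.tot_gc += E.lins[i].gclinks;
    ++E.k[E.lins[i].pop];
  }

  double t = 0.0;
  int evi = 0;
  const int nev = ev_time.size();
  double steps = 0.0;
  std::vector<double> coalRate(npop, 0.0);

  while (!E.lins.empty()) {
    if (++steps > max_events)
      stop("event budget exceeded (%.0f); simulation aborted", max_events);
    double coal_tot = 0.0;
    for (int p = 0; p < npop; ++p) {
      double kk = E.k[p];
      coalRate[p] = (kk > 1) ?
        kk * (kk - 1.0) / 2.0 / ((double)E.ploidy * E.sizes[p]) : 0.0;
      coal_tot += coalRate[p];
    }
    double xo_tot = E.tot_x;
    double gc_tot = (E.gc_rate > 0.0) ?
      E.gc_rate * (E.gc_whole_contig ?
                   (double)E.lins.size() * (L - 1.0) : E.tot_gc) : 0.0;
    double R = coal_tot + E.tot_mig + xo_tot + gc_tot;
    double tnext = (evi < nev) ? ev_time[evi] : R_PosInf;
    if (R <= 0.0) {
      if (!R_FINITE(tnext))
        stop("simulation stalled: remaining lineages can never coalesce "
             "(isolated populations with no migration?)");
      t = tnext;
    } else {
      double dt = exp_rand() / R;
      if (t + dt >= tnext) {
        t = tnext;
      } else {
        t += dt;
        double u = unif_rand() * R;
        if (u < coal_tot) {
          int p = 0;
          for (; p < npop; ++p) {
            u -= coalRate[p];
            if (u <= 0) break;
          }
          if (p >= npop) p = npop - 1;
          E.doCoalescence(t, p);
        } else if (u < coal_tot + E.tot_mig) {
          E.doMigration(t);
        } else if (u < coal_tot + E.tot_mig + xo_tot) {
          E.doCrossover(t);
        } else {
          E.doGeneConversion(t);
        }
        continue;
      }
    }
    // apply demographic events scheduled at t == tnext
    while (evi < nev && ev_time[evi] <= t) {
      int ty = ev_type[evi];
      if (ty == 0) {                       // size change
        if (ev_value[evi] <= 0.0)
          stop("population size change to a non-positive size");
        E.sizes[ev_pop[evi]] = ev_value[evi];
      } else if (ty == 2) {                // migration change
        E.mig[ev_pop[evi]][ev_pop2[evi]] = ev_value[evi];
        E.refreshMig();
      } else {                             // ty == 1, split: derived -> ancestral
        int d = ev_pop[evi], anc = ev_pop2[evi];
        for (size_t i = 0; i < E.lins.size(); ++i) {
          if (E.lins[i].pop == d) {
            E.subTotals(E.lins[i]);
            E.lins[i].pop = anc;
            E.addTotals(E.lins[i]);
          }
        }
        for (int q = 0; q < npop; ++q) { E.mig[d][q] = 0.0; E.mig[q][d] = 0.0; }
        E.refreshMig();
      }
      ++evi;
    }
  }

  // squash edges: contiguous intervals with identical parent/child
  size_t ne = E.e_par.size();
  std::vector<size_t> idx(ne);
  for (size_t i = 0; i < ne; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (E.e_chi[a] != E.e_chi[b]) return E.e_chi[a] < E.e_chi[b];
    if (E.e_par[a] != E.e_par[b]) return E.e_par[a] < E.e_par[b];
    return E.e_l[a] < E.e_l[b];
  });
  std::vector<int> sp, sc;
  std::vector<double> sl, sr;
  for (size_t ii = 0; ii < ne; ++ii) {
    size_t i = idx[ii];
    if (!sp.empty() && sp.back() == E.e_par[i] && sc.back() == E.e_chi[i] &&
        sr.back() == E.e_l[i])
      sr.back() = E.e_r[i];
    else {
      sp.push_back(E.e_par[i]); sc.push_back(E.e_chi[i]);
      sl.push_back(E.e_l[i]); sr.push_back(E.e_r[i]);
    }
  }

  return List::create(
    _["node_time"] = wrap(E.node_time),
    _["node_pop"] = wrap(E.node_pop),
    _["edge_parent"] = wrap(sp),
    _["edge_child"] = wrap(sc),
    _["edge_left"] = wrap(sl),
    _["edge_right"] = wrap(sr),
    _["counts"] = NumericVector::create(
      _["coalescence"] = E.counts[0], _["migration"] = E.counts[1],
      _["crossover_drawn"] = E.counts[2],
      _["crossover_effective"] = E.counts[3],
      _["gc_drawn"] = E.counts[4], _["gc_effective"] = E.counts[5]),
    _["rec_time"] = wrap(E.rec_time),
    _["rec_type"] = wrap(E.rec_type),
    _["tracts"] = wrap(E.tracts));
}
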
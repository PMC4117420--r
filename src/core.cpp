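// Compiled core for the hydrophobin-film spin model: energy evaluation,
// Metropolis dynamics with protein-mimicking trial moves, and union-find
// cluster labelling with periodic winding (percolation) detection.
//
// Conventions (shared with the R layer):
//  * axial triangular-lattice coordinates (i, j), 0-based, periodic;
//    site index = i + W * j; the six neighbour directions, counterclockwise
//    from +e1, are d0..d5 with offsets below; opposite(d) = d + 3 (mod 6).
//  * spins: -1 = vacant, 0..5 = orientation (k means rotation by k * 60 deg).
//  * interaction table: integer vector of length 216, entry
//    tab[d + 6*si + 36*sj] in {0 = forbidden, 1 = trimer, 2 = P6 dock,
//    3 = P3 dock}.
//  * couplings enter the energy as E = -J0*nT - J1*nP6 - J2*nP3 - Jsurf*N,
//    +Inf if any occupied adjacent pair is forbidden.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DX[6] = {1, 0, -1, -1, 0, 1};
static const int DY[6] = {0, 1, 1, 0, -1, -1};

enum { CLS_FORB = 0, CLS_TRI = 1, CLS_P6 = 2, CLS_P3 = 3 };

// uniform integer in [0, n)
static inline int runi(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct Change { int site; int newspin; };

struct Proposal {
  bool valid;   // false: proposal rejected outright (target occupied, ...)
  bool finite;  // false: move creates a forbidden contact (dE = +Inf)
  double dE;
  int n;
  Change ch[6];
};

class Lattice {
public:
  int W, H, WH;
  std::vector<int> sp;
  const int* tab;
  double J[4];   // J[CLS_TRI], J[CLS_P6], J[CLS_P3]; J[0] unused
  double Jsurf;

  Lattice(IntegerMatrix spins, IntegerVector table, NumericVector J3,
          double jsurf) {
    W = spins.nrow();
    H = spins.ncol();
    WH = W * H;
    sp.assign(spins.begin(), spins.end());
    tab = INTEGER(table);
    J[0] = 0.0; J[1] = J3[0]; J[2] = J3[1]; J[3] = J3[2];
    Jsurf = jsurf;
  }

  inline int nb(int idx, int d) const {
    int i = idx % W, j = idx / W;
    int ni = i + DX[d]; if (ni < 0) ni += W; else if (ni >= W) ni -= W;
    int nj = j + DY[d]; if (nj < 0) nj += H; else if (nj >= H) nj -= H;
    return ni + W * nj;
  }

  inline int cls(int d, int si, int sj) const {
    return tab[d + 6 * si + 36 * sj];
  }

  // Full energy; finite flag cleared when a forbidden pair exists.
  double fullEnergy(bool& finite) const {
    double e = 0.0;
    finite = true;
    for (int a = 0; a < WH; ++a) {
      int sa = sp[a];
      if (sa < 0) continue;
      e -= Jsurf;
      for (int d = 0; d < 3; ++d) {   // half of the directions: each bond once
        int b = nb(a, d);
        int sb = sp[b];
        if (sb < 0) continue;
        int c = cls(d, sa, sb);
        if (c == CLS_FORB) { finite = false; return R_PosInf; }
        e -= J[c];
      }
    }
    return e;
  }

  void census(int& nT, int& nP6, int& nP3, int& nF, int& nOcc) const {
    nT = nP6 = nP3 = nF = nOcc = 0;
    for (int a = 0; a < WH; ++a) {
      int sa = sp[a];
      if (sa < 0) continue;
      ++nOcc;
      for (int d = 0; d < 3; ++d) {
        int b = nb(a, d);
        int sb = sp[b];
        if (sb < 0) continue;
        switch (cls(d, sa, sb)) {
          case CLS_TRI: ++nT; break;
          case CLS_P6:  ++nP6; break;
          case CLS_P3:  ++nP3; break;
          default:      ++nF;  break;
        }
      }
    }
  }

  // Energy of all terms incident to a small site set (bonds within the set
  // counted once). Returns false if a forbidden contact is present.
  bool localEnergy(const int* sites, int n, double& e) const {
    e = 0.0;
    for (int k = 0; k < n; ++k) {
      int a = sites[k];
      int sa = sp[a];
      if (sa < 0) continue;
      e -= Jsurf;
      for (int d = 0; d < 6; ++d) {
        int b = nb(a, d);
        int sb = sp[b];
        if (sb < 0) continue;
        bool inset = false;
        for (int m = 0; m < n; ++m) if (sites[m] == b) { inset = true; break; }
        if (inset && d >= 3) continue;  // within-set bond: count from d < 3 side
        int c = cls(d, sa, sb);
        if (c == CLS_FORB) return false;
        e -= J[c];
      }
    }
    return true;
  }

  // dE for a change list, evaluated by local recomputation (exact).
  void evalChanges(Proposal& p) {
    int sites[6];
    for (int k = 0; k < p.n; ++k) sites[k] = p.ch[k].site;
    double e0, e1;
    localEnergy(sites, p.n, e0);  // current config assumed finite
    int old[6];
    for (int k = 0; k < p.n; ++k) { old[k] = sp[p.ch[k].site]; sp[p.ch[k].site] = p.ch[k].newspin; }
    bool ok = localEnergy(sites, p.n, e1);
    for (int k = 0; k < p.n; ++k) sp[p.ch[k].site] = old[k];
    if (!ok) { p.finite = false; p.dE = R_PosInf; }
    else { p.finite = true; p.dE = e1 - e0; }
  }

  // ---- proposal builders ------------------------------------------------

  Proposal proposeAdsorb(int site, int orient) {
    Proposal p; p.valid = (sp[site] < 0); p.n = 1;
    p.ch[0].site = site; p.ch[0].newspin = orient;
    if (p.valid) evalChanges(p);
    return p;
  }

  Proposal proposeDesorb(int site) {
    Proposal p; p.valid = (sp[site] >= 0); p.n = 1;
    p.ch[0].site = site; p.ch[0].newspin = -1;
    if (p.valid) evalChanges(p);
    return p;
  }

  // tdir: -1 = stay, 0..5 = hop direction; rot in {-1, 0, +1}
  Proposal proposeHop(int site, int tdir, int rot) {
    Proposal p;
    int s = sp[site];
    if (s < 0 || (tdir < 0 && rot == 0)) { p.valid = false; return p; }
    int dest = (tdir < 0) ? site : nb(site, tdir);
    if (dest != site && sp[dest] >= 0) { p.valid = false; return p; }
    int s2 = ((s + rot) % 6 + 6) % 6;
    p.valid = true;
    if (dest == site) {
      p.n = 1; p.ch[0].site = site; p.ch[0].newspin = s2;
    } else {
      p.n = 2;
      p.ch[0].site = site; p.ch[0].newspin = -1;
      p.ch[1].site = dest; p.ch[1].newspin = s2;
    }
    evalChanges(p);
    return p;
  }

  // Locate the complete trimer containing `site` (sites out[0..2] in role
  // order: spin s, s+2, s+4). Returns false if incomplete.
  bool trimerAt(int site, int* out) const {
    int s = sp[site];
    if (s < 0) return false;
    // role-0 site of the trimer: the one whose own-direction partners are
    // the other two. Every member sees its partners through its own dirs.
    int p2 = nb(site, s), p3 = nb(site, (s + 1) % 6);
    if (sp[p2] != (s + 2) % 6 || sp[p3] != (s + 4) % 6) return false;
    out[0] = site; out[1] = p2; out[2] = p3;
    return true;
  }

  // Rigid trimer move: tdir -1/0..5, rot in {-1,0,1}, pivot index 0..2
  // (member about whose site the +/-60 deg rotation is taken).
  Proposal proposeTrimer(int site, int tdir, int rot, int pivot) {
    Proposal p;
    int tri[3];
    if (!trimerAt(site, tri) || (tdir < 0 && rot == 0)) { p.valid = false; return p; }
    int s = sp[tri[0]];
    // relative axial positions of members (role order) w.r.t. role-0 site
    int rx[3] = {0, DX[s], DX[(s + 1) % 6]};
    int ry[3] = {0, DY[s], DY[(s + 1) % 6]};
    int px = rx[pivot], py = ry[pivot];
    int qi = tri[0] % W, qj = tri[0] / W;
    int newsite[3], newspin[3];
    for (int k = 0; k < 3; ++k) {
      int vx = rx[k] - px, vy = ry[k] - py;
      int wx, wy;
      if (rot == 1)       { wx = -vy;      wy = vx + vy; }  // +60 deg
      else if (rot == -1) { wx = vx + vy;  wy = -vx;     }  // -60 deg
      else                { wx = vx;       wy = vy;      }
      int ai = qi + px + wx, aj = qj + py + wy;
      if (tdir >= 0) { ai += DX[tdir]; aj += DY[tdir]; }
      ai %= W; if (ai < 0) ai += W;
      aj %= H; if (aj < 0) aj += H;
      newsite[k] = ai + W * aj;
      int sk = sp[tri[k]];
      newspin[k] = ((sk + rot) % 6 + 6) % 6;
    }
    // targets must be vacant or belong to the moving trimer
    for (int k = 0; k < 3; ++k) {
      int t = newsite[k];
      if (sp[t] >= 0 && t != tri[0] && t != tri[1] && t != tri[2]) {
        p.valid = false; return p;
      }
    }
    p.valid = true;
    p.n = 0;
    for (int k = 0; k < 3; ++k) { p.ch[p.n].site = tri[k]; p.ch[p.n].newspin = -1; ++p.n; }
    for (int k = 0; k < 3; ++k) {
      bool merged = false;
      for (int m = 0; m < p.n; ++m)
        if (p.ch[m].site == newsite[k]) { p.ch[m].newspin = newspin[k]; merged = true; break; }
      if (!merged) { p.ch[p.n].site = newsite[k]; p.ch[p.n].newspin = newspin[k]; ++p.n; }
    }
    evalChanges(p);
    return p;
  }
};

// ---------------------------------------------------------------------------
// Monte Carlo engine

class Engine : public Lattice {
public:
  std::vector<int> occ, pos;   // occupied-site list and index map
  double E;
  double beta, pAbsent;
  double c0, c01;              // cumulative move-mix probabilities
  // union-find buffers (reused between records)
  std::vector<int> ufp, ufx, ufy, ufs;
  std::vector<char> ufw;

  Engine(IntegerMatrix spins, IntegerVector table, NumericVector J3,
         double jsurf, double beta_, double pAbsent_, NumericVector mix)
    : Lattice(spins, table, J3, jsurf) {
    beta = beta_; pAbsent = pAbsent_;
    double tot = mix[0] + mix[1] + mix[2];
    c0 = mix[0] / tot; c01 = (mix[0] + mix[1]) / tot;
    pos.assign(WH, -1);
    for (int a = 0; a < WH; ++a)
      if (sp[a] >= 0) { pos[a] = (int)occ.size(); occ.push_back(a); }
    bool fin;
    E = fullEnergy(fin);
    if (!fin) stop("initial configuration has infinite energy");
    ufp.resize(WH); ufx.resize(WH); ufy.resize(WH); ufs.resize(WH);
    ufw.resize(WH);
  }

  void applyChanges(const Proposal& p) {
    for (int k = 0; k < p.n; ++k) {
      int a = p.ch[k].site, ns = p.ch[k].newspin, os = sp[a];
      if (os < 0 && ns >= 0) { pos[a] = (int)occ.size(); occ.push_back(a); }
      else if (os >= 0 && ns < 0) {
        int idx = pos[a], last = occ.back();
        occ[idx] = last; pos[last] = idx; occ.pop_back(); pos[a] = -1;
      }
      sp[a] = ns;
    }
    E += p.dE;
  }

  // One trial move. greedy = zero-temperature quench (accept iff dE < 0).
  // Returns true if a move was accepted.
  bool attempt(bool greedy) {
    double u = unif_rand();
    if (u < c0) {
      // adsorption / desorption
      int site = runi(WH);
      if (sp[site] < 0) {
        if (pAbsent > 0 && unif_rand() < pAbsent) return false;
        Proposal p = proposeAdsorb(site, runi(6));
        if (!p.valid || !p.finite) return false;
        double acc = greedy ? (p.dE < 0 ? 1.0 : 0.0)
                            : std::min(1.0, 6.0 * std::exp(-beta * p.dE));
        if (acc == 1.0 || unif_rand() < acc) { applyChanges(p); return true; }
      } else {
        Proposal p = proposeDesorb(site);
        if (!p.finite) return false;
        double acc = greedy ? (p.dE < 0 ? 1.0 : 0.0)
                            : std::min(1.0, std::exp(-beta * p.dE) / 6.0);
        if (acc == 1.0 || unif_rand() < acc) { applyChanges(p); return true; }
      }
      return false;
    }
    bool isHop = (u < c01);
    if (occ.empty()) return false;
    int site = occ[runi((int)occ.size())];
    int opt = runi(20) + 1;          // (target, rotation) menu minus the null
    int t = opt / 3;                 // 0 = stay, 1..6 = direction t-1
    int r = opt % 3;                 // 0 keep, 1 = +60, 2 = -60
    int rot = (r == 2) ? -1 : r;
    int tdir = t - 1;
    Proposal p;
    if (isHop) {
      p = proposeHop(site, tdir, rot);
    } else {
      int pivot = (rot != 0) ? runi(3) : 0;
      p = proposeTrimer(site, tdir, rot, pivot);
    }
    if (!p.valid || !p.finite) return false;
    double acc = greedy ? (p.dE < 0 ? 1.0 : 0.0)
                        : std::min(1.0, std::exp(-beta * p.dE));
    if (acc == 1.0 || unif_rand() < acc) { applyChanges(p); return true; }
    return false;
  }

  // clusters over attractive bonds; returns largest size and wrap flag
  void clusters(int& largest, bool& percolated, IntegerVector* labels = 0,
                std::vector<int>* sizesOut = 0, std::vector<char>* wrapsOut = 0) {
    for (size_t k = 0; k < occ.size(); ++k) {
      int a = occ[k];
      ufp[a] = a; ufx[a] = 0; ufy[a] = 0; ufs[a] = 1; ufw[a] = 0;
    }
    for (size_t k = 0; k < occ.size(); ++k) {
      int a = occ[k];
      for (int d = 0; d < 3; ++d) {
        int b = nb(a, d);
        if (sp[b] < 0) continue;
        int c = cls(d, sp[a], sp[b]);
        if (c == CLS_FORB) continue;
        unite(a, b, DX[d], DY[d]);
      }
    }
    largest = 0; percolated = false;
    for (size_t k = 0; k < occ.size(); ++k) {
      int a = occ[k];
      if (ufp[a] == a) {
        if (ufs[a] > largest) largest = ufs[a];
        if (ufw[a]) percolated = true;
      }
    }
    if (labels) {
      std::vector<int> lab(WH, 0);
      int nl = 0;
      for (size_t k = 0; k < occ.size(); ++k) {
        int dx, dy;
        int r = find(occ[k], dx, dy);
        if (lab[r] == 0) {
          lab[r] = ++nl;
          if (sizesOut) sizesOut->push_back(ufs[r]);
          if (wrapsOut) wrapsOut->push_back(ufw[r]);
        }
      }
      for (size_t k = 0; k < occ.size(); ++k) {
        int dx, dy;
        (*labels)[occ[k]] = lab[find(occ[k], dx, dy)];
      }
    }
  }

  int find(int x, int& ox, int& oy) {
    int r = x, dx = 0, dy = 0;
    while (ufp[r] != r) { dx += ufx[r]; dy += ufy[r]; r = ufp[r]; }
    // path compression, re-rooting displacements at r
    int cur = x, cdx = dx, cdy = dy;
    while (ufp[cur] != r) {
      int nxt = ufp[cur];
      int ndx = cdx - ufx[cur], ndy = cdy - ufy[cur];
      ufp[cur] = r; ufx[cur] = cdx; ufy[cur] = cdy;
      cur = nxt; cdx = ndx; cdy = ndy;
    }
    if (cur != r) { ufx[cur] = cdx; ufy[cur] = cdy; }
    ox = dx; oy = dy;
    return r;
  }

  void unite(int a, int b, int dabx, int daby) {
    int dax, day, dbx, dby;
    int ra = find(a, dax, day);
    int rb = find(b, dbx, dby);
    if (ra == rb) {
      // cycle: nonzero winding means the cluster wraps the torus
      if (dax + dabx != dbx || day + daby != dby) ufw[ra] = 1;
      return;
    }
    ufp[rb] = ra;
    ufx[rb] = dax + dabx - dbx;
    ufy[rb] = day + daby - dby;
    ufs[ra] += ufs[rb];
    ufw[ra] = ufw[ra] || ufw[rb];
  }
};

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
double cpp_config_energy(IntegerMatrix spins, IntegerVector tab,
                         NumericVector J3, double Jsurf) {
  Lattice L(spins, tab, J3, Jsurf);
  bool fin;
  return L.fullEnergy(fin);
}

// [[Rcpp::export]]
IntegerVector cpp_bond_census(IntegerMatrix spins, IntegerVector tab) {
  Lattice L(spins, tab, NumericVector::create(0, 0, 0), 0.0);
  int nT, nP6, nP3, nF, nOcc;
  L.census(nT, nP6, nP3, nF, nOcc);
  IntegerVector out = IntegerVector::create(
    _["n_trimer"] = nT, _["n_p6"] = nP6, _["n_p3"] = nP3,
    _["n_forbidden"] = nF, _["n_occupied"] = nOcc);
  return out;
}

// move: c(type, site, a, b, c) with 0-based site index;
// type 0 adsorb (a = orientation), 1 desorb,
// type 2 hop (a = target dir -1..5, b = rot),
// type 3 trimer (a = dir, b = rot, c = pivot 0..2).
// [[Rcpp::export]]
double cpp_delta_energy(IntegerMatrix spins, IntegerVector tab,
                        NumericVector J3, double Jsurf, IntegerVector move) {
  Lattice L(spins, tab, J3, Jsurf);
  int type = move[0], site = move[1];
  Proposal p;
  switch (type) {
    case 0: p = L.proposeAdsorb(site, move[2]); break;
    case 1: p = L.proposeDesorb(site); break;
    case 2: p = L.proposeHop(site, move[2], move[3]); break;
    case 3: p = L.proposeTrimer(site, move[2], move[3], move[4]); break;
    default: stop("unknown move type");
  }
  if (!p.valid) {
    if (type == 0 && L.sp[site] >= 0) stop("adsorption onto an occupied site");
    if (type == 1) stop("desorption from a vacant site");
    if (type == 3 && !p.valid) {
      int tri[3];
      if (!L.trimerAt(site, tri)) stop("site is not part of a complete trimer");
    }
    return R_PosInf;  // rejected proposal (occupied target / null move)
  }
  return p.dE;
}

// [[Rcpp::export]]
LogicalVector cpp_is_complete_trimer(IntegerMatrix spins, IntegerVector tab,
                                     IntegerVector sites) {
  Lattice L(spins, tab, NumericVector::create(0, 0, 0), 0.0);
  LogicalVector out(sites.size());
  int tri[3];
  for (int k = 0; k < sites.size(); ++k) out[k] = L.trimerAt(sites[k], tri);
  return out;
}

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix spins, IntegerVector tab,
                        NumericVector J3, double Jsurf, double pAbsent,
                        double beta, int sweeps, NumericVector moveMix,
                        int recordEvery) {
  Engine eng(spins, tab, J3, Jsurf, beta, pAbsent, moveMix);
  std::vector<double> rows;
  rows.reserve((sweeps / recordEvery + 2) * 8);
  int nT, nP6, nP3, nF, nOcc, largest;
  bool perc;
  // record closure
  int recorded = 0;
  #define RECORD(sw) do {                                            \
    eng.census(nT, nP6, nP3, nF, nOcc);                              \
    eng.clusters(largest, perc);                                     \
    rows.push_back(sw); rows.push_back(nOcc); rows.push_back(largest); \
    rows.push_back(eng.E); rows.push_back(nT); rows.push_back(nP6);  \
    rows.push_back(nP3); rows.push_back(perc ? 1 : 0); ++recorded;   \
  } while (0)
  RECORD(0);
  for (int s = 1; s <= sweeps; ++s) {
    for (int k = 0; k < eng.WH; ++k) eng.attempt(false);
    if (s % recordEvery == 0 || s == sweeps) RECORD(s);
  }
  #undef RECORD
  NumericMatrix rec(8, recorded);
  std::copy(rows.begin(), rows.end(), rec.begin());
  IntegerMatrix fin(eng.W, eng.H);
  std::copy(eng.sp.begin(), eng.sp.end(), fin.begin());
  return List::create(_["records"] = rec, _["final"] = fin,
                      _["energy"] = eng.E);
}

// [[Rcpp::export]]
List cpp_quench(IntegerMatrix spins, IntegerVector tab, NumericVector J3,
                double Jsurf, NumericVector moveMix, int maxSweeps) {
  Engine eng(spins, tab, J3, Jsurf, 1.0, 0.0, moveMix);
  int sweepsDone = 0;
  for (int s = 1; s <= maxSweeps; ++s) {
    int acc = 0;
    for (int k = 0; k < eng.WH; ++k) if (eng.attempt(true)) ++acc;
    sweepsDone = s;
    if (acc == 0) break;
  }
  IntegerMatrix fin(eng.W, eng.H);
  std::copy(eng.sp.begin(), eng.sp.end(), fin.begin());
  return List::create(_["final"] = fin, _["sweeps"] = sweepsDone,
                      _["energy"] = eng.E);
}

// [[Rcpp::export]]
List cpp_label_clusters(IntegerMatrix spins, IntegerVector tab) {
  Engine eng(spins, tab, NumericVector::create(0, 0, 0), 0.0, 1.0, 0.0,
             NumericVector::create(1, 1, 1));
  IntegerVector labels(eng.WH);
  std::vector<int> sizes;
  std::vector<char> wraps;
  int largest; bool perc;
  eng.clusters(largest, perc, &labels, &sizes, &wraps);
  labels.attr("dim") = Dimension(eng.W, eng.H);
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["wraps"] = LogicalVector(wraps.begin(), wraps.end()),
                      _["largest"] = largest,
                      _["percolated"] = perc);
}

// Sequential random insertion with rejection of forbidden contacts.
// [[Rcpp::export]]
IntegerMatrix cpp_random_config(int W, int H, double density,
                                IntegerVector tab) {
  IntegerMatrix spins(W, H);
  std::fill(spins.begin(), spins.end(), -1);
  Lattice L(spins, tab, NumericVector::create(0, 0, 0), 0.0);
  int target = (int)std::lround(density * W * H);
  int placed = 0;
  long attempts = 0, maxAttempts = 200L * W * H + 1000L;
  while (placed < target && attempts < maxAttempts) {
    ++attempts;
    int site = runi(W * H);
    if (L.sp[site] >= 0) continue;
    int orient = runi(6);
    bool ok = true;
    for (int d = 0; d < 6 && ok; ++d) {
      int b = L.nb(site, d);
      if (L.sp[b] >= 0 && L.cls(d, orient, L.sp[b]) == CLS_FORB) ok = false;
    }
    if (ok) { L.sp[site] = orient; ++placed; }
  }
  IntegerMatrix out(W, H);
  std::copy(L.sp.begin(), L.sp.end(), out.begin());
  return out;
}
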
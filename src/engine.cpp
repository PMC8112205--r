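// Metropolis Monte Carlo engine for the membrane-adhesion lattice model.
//
// State: an L x L periodic lattice carrying
//   l  - membrane-substrate separation per patch (nm, >= 0)
//   mp - receptor occupancy on the upper (cell) membrane, 0/1
//   mm - ligand occupancy on the lower surface, 0/1
//   np - raft occupancy on the upper membrane, 0/1
//
// Energy (kBT units, kT = 1):
//   bending        kappa/(2 a^2) sum_i (Lap l_i)^2   (5-point Laplacian)
//   binding        -ub sum_i mp_i mm_i [lc - lb/2 < l_i < lc + lb/2]
//   raft-receptor  -ua sum_i np_i mp_i
//   raft-raft      -u  sum_<ij> np_i np_j            (each bond once)
//
// Moves: membrane height shifts (rejected outright if l < 0), protein hops
// to one of four neighbours (single occupancy per surface), raft hops into
// raft-free sites (receptors stay put). All moves accepted by the Metropolis
// rule; running energy components and complex counts are maintained
// incrementally and cross-checked against a full recompute on exit.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: tiny, fast, well-mixed; deterministic for a given seed.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { next(); next(); }
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Pars {
  double kappa, a, ub, lb, lc, ua, u, cb;
  void from_list(const List& p) {
    kappa = as<double>(p["kappa"]);
    a  = as<double>(p["a"]);
    ub = as<double>(p["u_b"]);
    lb = as<double>(p["l_b"]);
    lc = as<double>(p["l_c"]);
    ua = as<double>(p["u_a"]);
    u  = as<double>(p["u"]);
    cb = kappa / (2.0 * a * a);
  }
};

struct Sys {
  int L, N;
  std::vector<double> l;
  std::vector<int> mp, mm, np;
  std::vector<int> nbh;  // N x 4 neighbour table (right, left, down, up)
  Pars p;

  void init(const NumericVector& l_, const IntegerVector& mp_,
            const IntegerVector& mm_, const IntegerVector& np_,
            int L_, const List& pars) {
    L = L_; N = L * L;
    if ((int)l_.size() != N) stop("separation field length != L^2");
    l.assign(l_.begin(), l_.end());
    mp.assign(mp_.begin(), mp_.end());
    mm.assign(mm_.begin(), mm_.end());
    np.assign(np_.begin(), np_.end());
    p.from_list(pars);
    nbh.resize(4 * N);
    for (int i = 0; i < N; i++) {
      int r = i % L, c = i / L;
      nbh[4 * i + 0] = ((c + 1) % L) * L + r;
      nbh[4 * i + 1] = ((c + L - 1) % L) * L + r;
      nbh[4 * i + 2] = c * L + (r + 1) % L;
      nbh[4 * i + 3] = c * L + (r + L - 1) % L;
    }
  }

  inline bool in_well(double li) const {
    return li > p.lc - 0.5 * p.lb && li < p.lc + 0.5 * p.lb;
  }
  inline double lap(int i) const {
    return l[nbh[4 * i]] + l[nbh[4 * i + 1]] + l[nbh[4 * i + 2]] +
           l[nbh[4 * i + 3]] - 4.0 * l[i];
  }

  double e_bend_full() const {
    double s = 0;
    for (int i = 0; i < N; i++) { double d = lap(i); s += d * d; }
    return p.cb * s;
  }
  double e_bind_full() const {
    long k = 0;
    for (int i = 0; i < N; i++)
      if (mp[i] && mm[i] && in_well(l[i])) k++;
    return -p.ub * k;
  }
  double e_rp_full() const {
    long k = 0;
    for (int i = 0; i < N; i++) if (np[i] && mp[i]) k++;
    return -p.ua * k;
  }
  double e_rr_full() const {
    long b = 0;
    for (int i = 0; i < N; i++)
      if (np[i]) b += np[nbh[4 * i]] + np[nbh[4 * i + 1]] +
                      np[nbh[4 * i + 2]] + np[nbh[4 * i + 3]];
    return -p.u * 0.5 * (double)b;
  }
  long n_bound_full() const {
    long k = 0;
    for (int i = 0; i < N; i++)
      if (mp[i] && mm[i] && in_well(l[i])) k++;
    return k;
  }
  long n_r_on_raft_full() const {
    long k = 0;
    for (int i = 0; i < N; i++) if (np[i] && mp[i]) k++;
    return k;
  }

  // Energy change of a height move l[i] -> lnew (assumes lnew >= 0).
  // Returns the bending and binding parts separately.
  void d_height(int i, double lnew, double& de_b, double& de_bd,
                int& dbound) const {
    double dl = lnew - l[i];
    int sites[5]; double dlap[5]; int ns = 1;
    sites[0] = i; dlap[0] = -4.0 * dl;
    for (int d = 0; d < 4; d++) {
      int j = nbh[4 * i + d];
      int k;
      for (k = 0; k < ns; k++) if (sites[k] == j) break;
      if (k == ns) { sites[ns] = j; dlap[ns] = dl; ns++; }
      else dlap[k] += dl;
    }
    double s = 0;
    for (int k = 0; k < ns; k++) {
      double lo = lap(sites[k]), ln = lo + dlap[k];
      s += ln * ln - lo * lo;
    }
    de_b = p.cb * s;
    dbound = 0; de_bd = 0;
    if (mp[i] && mm[i]) {
      dbound = (in_well(lnew) ? 1 : 0) - (in_well(l[i]) ? 1 : 0);
      de_bd = -p.ub * dbound;
    }
  }

  // Receptor hop from -> to (destination assumed receptor-free).
  void d_receptor(int from, int to, double& de_bd, double& de_rp,
                  int& dbound, int& draft) const {
    dbound = 0;
    if (mm[from] && in_well(l[from])) dbound--;
    if (mm[to] && in_well(l[to])) dbound++;
    de_bd = -p.ub * dbound;
    draft = np[to] - np[from];
    de_rp = -p.ua * draft;
  }

  // Ligand hop from -> to (destination assumed ligand-free).
  void d_ligand(int from, int to, double& de_bd, int& dbound) const {
    dbound = 0;
    if (mp[from] && in_well(l[from])) dbound--;
    if (mp[to] && in_well(l[to])) dbound++;
    de_bd = -p.ub * dbound;
  }

  // Raft hop from -> to (destination assumed raft-free, receptors stay).
  void d_raft(int from, int to, double& de_rr, double& de_rp,
              int& dronraft) {
    int before = np[nbh[4 * from]] + np[nbh[4 * from + 1]] +
                 np[nbh[4 * from + 2]] + np[nbh[4 * from + 3]];
    np[from] = 0;
    int after = np[nbh[4 * to]] + np[nbh[4 * to + 1]] +
                np[nbh[4 * to + 2]] + np[nbh[4 * to + 3]];
    np[from] = 1;
    de_rr = -p.u * (after - before);
    dronraft = mp[to] - mp[from];
    de_rp = -p.ua * dronraft;
  }
};

inline bool metro(double de, Rng& rng) {
  return de <= 0.0 || rng.unif() < std::exp(-de);
}

}  // namespace

// [[Rcpp::export]]
NumericVector energy_components_cpp(NumericVector l, IntegerVector mp,
                                    IntegerVector mm, IntegerVector np,
                                    int L, List pars) {
  Sys s; s.init(l, mp, mm, np, L, pars);
  double eb = s.e_bend_full(), ebd = s.e_bind_full();
  double erp = s.e_rp_full(), err = s.e_rr_full();
  return NumericVector::create(
      _["e_bend"] = eb, _["e_bind"] = ebd, _["e_raft_receptor"] = erp,
      _["e_raft_raft"] = err, _["e_total"] = eb + ebd + erp + err);
}

// [[Rcpp::export]]
NumericVector laplacian_all_cpp(NumericVector l, int L) {
  IntegerVector dummy(L * L, 0);
  List pars = List::create(_["kappa"] = 1.0, _["a"] = 1.0, _["u_b"] = 0.0,
                           _["l_b"] = 1.0, _["l_c"] = 2.0, _["u_a"] = 0.0,
                           _["u"] = 0.0);
  Sys s; s.init(l, dummy, dummy, dummy, L, pars);
  NumericVector out(s.N);
  for (int i = 0; i < s.N; i++) out[i] = s.lap(i);
  return out;
}

// move_type: 1 height (site, lnew), 2 receptor hop (from, to),
//            3 ligand hop (from, to), 4 raft hop (from, to).
// Sites are 0-based. Validity (occupancy) is checked R-side.
// [[Rcpp::export]]
double local_delta_cpp(NumericVector l, IntegerVector mp, IntegerVector mm,
                       IntegerVector np, int L, List pars, int move_type,
                       int s1, int s2, double lnew) {
  Sys s; s.init(l, mp, mm, np, L, pars);
  double d1 = 0, d2 = 0; int a = 0, b = 0;
  switch (move_type) {
    case 1: s.d_height(s1, lnew, d1, d2, a); return d1 + d2;
    case 2: s.d_receptor(s1, s2, d1, d2, a, b); return d1 + d2;
    case 3: s.d_ligand(s1, s2, d1, a); return d1;
    case 4: s.d_raft(s1, s2, d1, d2, a); return d1 + d2;
    default: stop("unknown move type");
  }
}

// Full Metropolis run. Counts are doubles R-side but integral.
// Returns recorded samples, final state, running vs recomputed energies,
// and per-move-type attempt/acceptance counts.
// [[Rcpp::export]]
List run_engine_cpp(NumericVector l, IntegerVector mp, IntegerVector mm,
                    IntegerVector np, int L, List pars, bool ligands_mobile,
                    double n_height, double n_protein, double n_raft,
                    double n_relax, double n_sample, double sample_interval,
                    double step_height, double seed) {
  Sys s; s.init(l, mp, mm, np, L, pars);
  Rng rng((uint64_t)seed);

  // position lists and site -> list-index maps
  std::vector<int> rpos, lpos, npos;
  std::vector<int> rat(s.N, -1), lat(s.N, -1), nat(s.N, -1);
  for (int i = 0; i < s.N; i++) {
    if (s.mp[i]) { rat[i] = rpos.size(); rpos.push_back(i); }
    if (s.mm[i]) { lat[i] = lpos.size(); lpos.push_back(i); }
    if (s.np[i]) { nat[i] = npos.size(); npos.push_back(i); }
  }
  int nR = rpos.size(), nLg = lpos.size();
  int n_mobile = nR + (ligands_mobile ? nLg : 0);

  double e_bend = s.e_bend_full(), e_bind = s.e_bind_full();
  double e_rp = s.e_rp_full(), e_rr = s.e_rr_full();
  long nbound = s.n_bound_full(), nronraft = s.n_r_on_raft_full();
  double linit_mean = 0;
  for (int i = 0; i < s.N; i++) linit_mean += s.l[i];
  linit_mean /= s.N;

  long long nh = (long long)n_height, npr = (long long)n_protein,
            nr = (long long)n_raft;
  long long relax = (long long)n_relax, samp = (long long)n_sample,
            interval = (long long)sample_interval;
  if (interval < 1) interval = 1;
  long long nrec = samp / interval;
  NumericMatrix rec(nrec, 9);
  colnames(rec) = CharacterVector::create(
      "cycle", "e_bend", "e_bind", "e_raft_receptor", "e_raft_raft",
      "e_total", "n_complexes", "n_receptors_on_rafts", "n_in_well");
  long long irec = 0;
  long long att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};

  for (long long cyc = 1; cyc <= relax + samp; cyc++) {
    long long h = nh, pr = npr, rf = nr, rem = h + pr + rf;
    while (rem > 0) {
      uint64_t r = rng.next() % (uint64_t)rem;
      if (r < (uint64_t)h) {
        h--; att[0]++;
        int i = rng.below(s.N);
        double dl = (2.0 * rng.unif() - 1.0) * step_height;
        double ln = s.l[i] + dl;
        if (ln >= 0.0) {
          double de_b, de_bd; int dbound;
          s.d_height(i, ln, de_b, de_bd, dbound);
          if (metro(de_b + de_bd, rng)) {
            s.l[i] = ln; e_bend += de_b; e_bind += de_bd; nbound += dbound;
            acc[0]++;
          }
        }
      } else if (r < (uint64_t)(h + pr)) {
        pr--; att[1]++;
        if (n_mobile > 0) {
          int k = rng.below(n_mobile);
          if (k < nR) {
            int from = rpos[k];
            int to = s.nbh[4 * from + rng.below(4)];
            if (!s.mp[to]) {
              double de_bd, de_rp_; int dbound, draft;
              s.d_receptor(from, to, de_bd, de_rp_, dbound, draft);
              if (metro(de_bd + de_rp_, rng)) {
                s.mp[from] = 0; s.mp[to] = 1;
                rpos[k] = to; rat[to] = k; rat[from] = -1;
                e_bind += de_bd; e_rp += de_rp_;
                nbound += dbound; nronraft += draft;
                acc[1]++;
              }
            }
          } else {
            int kl = k - nR;
            int from = lpos[kl];
            int to = s.nbh[4 * from + rng.below(4)];
            if (!s.mm[to]) {
              double de_bd; int dbound;
              s.d_ligand(from, to, de_bd, dbound);
              if (metro(de_bd, rng)) {
                s.mm[from] = 0; s.mm[to] = 1;
                lpos[kl] = to; lat[to] = kl; lat[from] = -1;
                e_bind += de_bd; nbound += dbound;
                acc[1]++;
              }
            }
          }
        }
      } else {
        rf--; att[2]++;
        if (!npos.empty()) {
          int k = rng.below((int)npos.size());
          int from = npos[k];
          int to = s.nbh[4 * from + rng.below(4)];
          if (!s.np[to]) {
            double de_rr_, de_rp_; int dron;
            s.d_raft(from, to, de_rr_, de_rp_, dron);
            if (metro(de_rr_ + de_rp_, rng)) {
              s.np[from] = 0; s.np[to] = 1;
              npos[k] = to; nat[to] = k; nat[from] = -1;
              e_rr += de_rr_; e_rp += de_rp_; nronraft += dron;
              acc[2]++;
            }
          }
        }
      }
      rem--;
    }
    if (cyc > relax && (cyc - relax) % interval == 0 && irec < nrec) {
      double lm = 0;
      for (int i = 0; i < s.N; i++) lm += s.l[i];
      lm /= s.N;
      double shift = lm - linit_mean;
      long inwell = 0;
      for (int i = 0; i < s.N; i++)
        if (s.in_well(s.l[i] - shift)) inwell++;
      rec(irec, 0) = (double)(cyc - relax);
      rec(irec, 1) = e_bend; rec(irec, 2) = e_bind;
      rec(irec, 3) = e_rp; rec(irec, 4) = e_rr;
      rec(irec, 5) = e_bend + e_bind + e_rp + e_rr;
      rec(irec, 6) = (double)nbound;
      rec(irec, 7) = (double)nronraft;
      rec(irec, 8) = (double)inwell;
      irec++;
    }
  }

  NumericVector lout(s.l.begin(), s.l.end());
  IntegerVector mpo(s.mp.begin(), s.mp.end());
  IntegerVector mmo(s.mm.begin(), s.mm.end());
  IntegerVector npo(s.np.begin(), s.np.end());
  NumericVector running = NumericVector::create(
      _["e_bend"] = e_bend, _["e_bind"] = e_bind,
      _["e_raft_receptor"] = e_rp, _["e_raft_raft"] = e_rr,
      _["e_total"] = e_bend + e_bind + e_rp + e_rr);
  double rb = s.e_bend_full(), rbd = s.e_bind_full();
  double rrp = s.e_rp_full(), rrr = s.e_rr_full();
  NumericVector recomputed = NumericVector::create(
      _["e_bend"] = rb, _["e_bind"] = rbd, _["e_raft_receptor"] = rrp,
      _["e_raft_raft"] = rrr, _["e_total"] = rb + rbd + rrp + rrr);
  NumericVector attv = NumericVector::create(
      _["height"] = (double)att[0], _["protein"] = (double)att[1],
      _["raft"] = (double)att[2]);
  NumericVector accv = NumericVector::create(
      _["height"] = (double)acc[0], _["protein"] = (double)acc[1],
      _["raft"] = (double)acc[2]);
  return List::create(
      _["samples"] = rec, _["l"] = lout, _["m_plus"] = mpo,
      _["m_minus"] = mmo, _["n_plus"] = npo, _["running"] = running,
      _["recomputed"] = recomputed, _["attempted"] = attv,
      _["accepted"] = accv,
      _["n_bound"] = (double)nbound,
      _["n_receptors_on_rafts"] = (double)nronraft);
}
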
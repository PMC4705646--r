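// Monte Carlo / replica-exchange core for the coarse-grained chain model.
//
// The system description arrives from R as a flat list of term tables
// (bonds, angles, periodic dihedrals, flat-bottom NOEs, dihedral restraints,
// soft-sphere excluded volume, paired-base attractions, optional Rg
// restraint) plus precomputed move tables. All bead indices are 0-based
// here; the R wrappers convert. Rigid groups are never split by a proposal,
// so rigid-body transforms leave intra-group geometry exact; groups are
// additionally re-snapped onto their templates at every full-energy resync
// to keep floating-point drift at machine precision.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double RGAS = 1.9872e-3; // kcal/(mol K)

struct System {
  int nb;
  std::vector<int> resid, btype, group;
  // bonds
  std::vector<int> bi, bj; std::vector<double> b0, bk;
  // angles (theta0 in rad)
  std::vector<int> ai, aj, ak; std::vector<double> a0, akc;
  // periodic dihedrals (phi0 in rad)
  std::vector<int> di, dj, dk, dl; std::vector<double> dphi0, dkc;
  // attractions
  std::vector<int> ti, tj; std::vector<double> teps, tr0, tw;
  // flat-bottom NOEs
  std::vector<int> ni, nj;
  std::vector<double> nrmin, nrmax, nkmin, nkmax, nfmax;
  // dihedral restraints (phi0 in rad)
  std::vector<int> ri, rj, rk, rl; std::vector<double> rphi0, rK;
  // excluded volume
  std::vector<double> evr; double evk; bool evOn; double evCut;
  // Rg restraint
  bool rgOn; double rgTarget, rgK;
  // move tables
  std::vector<int> pivotAxis; std::vector<std::vector<int>> pivotSets;
  std::vector<double> pivotCum;
  std::vector<int> segU, segV, segA, segB;
  std::vector<std::vector<int>> helixSets;
  std::vector<int> localBeads;
  std::vector<int> backbone;            // bead ids in chain order (2n)
  std::vector<int> bOfRes, b2OfRes;     // per residue, -1 if absent
  // rigid templates for re-snapping
  std::vector<std::vector<int>> groupBeads;
  std::vector<arma::mat> groupTpl;
  double wPivot, wSeg, wHelix, wLocal;
  double ampPivot, ampSeg, ampHelix, ampHelixT, ampLocal; // rad / Angstrom
};

static std::vector<int> asIdx(SEXP x) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int k = 0; k < v.size(); ++k) out[k] = v[k] - 1;
  return out;
}
static std::vector<int> asInt(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> asNum(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

static System parseSystem(const List& s) {
  System S;
  S.nb = as<int>(s["nb"]);
  S.resid = asInt(s["resid"]); S.btype = asInt(s["btype"]);
  S.group = asInt(s["group"]);
  S.bi = asIdx(s["bondI"]); S.bj = asIdx(s["bondJ"]);
  S.b0 = asNum(s["bondB0"]); S.bk = asNum(s["bondK"]);
  S.ai = asIdx(s["angI"]); S.aj = asIdx(s["angJ"]); S.ak = asIdx(s["angK"]);
  S.a0 = asNum(s["angT0"]); S.akc = asNum(s["angKc"]);
  S.di = asIdx(s["dihI"]); S.dj = asIdx(s["dihJ"]);
  S.dk = asIdx(s["dihK"]); S.dl = asIdx(s["dihL"]);
  S.dphi0 = asNum(s["dihPhi0"]); S.dkc = asNum(s["dihKc"]);
  S.ti = asIdx(s["attrI"]); S.tj = asIdx(s["attrJ"]);
  S.teps = asNum(s["attrEps"]); S.tr0 = asNum(s["attrR0"]);
  S.tw = asNum(s["attrW"]);
  S.ni = asIdx(s["noeI"]); S.nj = asIdx(s["noeJ"]);
  S.nrmin = asNum(s["noeRmin"]); S.nrmax = asNum(s["noeRmax"]);
  S.nkmin = asNum(s["noeKmin"]); S.nkmax = asNum(s["noeKmax"]);
  S.nfmax = asNum(s["noeFmax"]);
  S.ri = asIdx(s["drI"]); S.rj = asIdx(s["drJ"]);
  S.rk = asIdx(s["drK"]); S.rl = asIdx(s["drL"]);
  S.rphi0 = asNum(s["drPhi0"]); S.rK = asNum(s["drKc"]);
  S.evr = asNum(s["evRad"]); S.evk = as<double>(s["evK"]);
  S.evOn = as<bool>(s["evOn"]);
  double mx = 0; for (double r : S.evr) mx = std::max(mx, r);
  S.evCut = 2.0 * mx;
  S.rgOn = as<bool>(s["rgOn"]);
  S.rgTarget = as<double>(s["rgTarget"]); S.rgK = as<double>(s["rgK"]);
  S.pivotAxis = asIdx(s["pivotAxis"]);
  List ps(s["pivotSets"]);
  for (int k = 0; k < ps.size(); ++k) S.pivotSets.push_back(asIdx(ps[k]));
  // selection weights ~ sqrt(moved-set size): arm reorientations decorrelate
  // interhelical angles and deserve more proposals than tail wiggles
  S.pivotCum.resize(S.pivotSets.size());
  double acc = 0;
  for (size_t k = 0; k < S.pivotSets.size(); ++k) {
    acc += std::pow((double)S.pivotSets[k].size(), 0.8);
    S.pivotCum[k] = acc;
  }
  for (double& v : S.pivotCum) v /= (acc > 0 ? acc : 1);
  S.segU = asIdx(s["segU"]); S.segV = asIdx(s["segV"]);
  S.segA = asIdx(s["segA"]); S.segB = asIdx(s["segB"]);
  List hs(s["helixSets"]);
  for (int k = 0; k < hs.size(); ++k) S.helixSets.push_back(asIdx(hs[k]));
  S.localBeads = asIdx(s["localBeads"]);
  S.backbone = asIdx(s["backbone"]);
  S.bOfRes = asIdx(s["bOfRes"]); S.b2OfRes = asIdx(s["b2OfRes"]);
  List gb(s["groupBeads"]);
  for (int k = 0; k < gb.size(); ++k) S.groupBeads.push_back(asIdx(gb[k]));
  List gt(s["groupTpl"]);
  for (int k = 0; k < gt.size(); ++k)
    S.groupTpl.push_back(as<arma::mat>(gt[k]));
  NumericVector w(s["moveWeights"]);
  S.wPivot = w[0]; S.wSeg = w[1]; S.wHelix = w[2]; S.wLocal = w[3];
  NumericVector a(s["amplitudes"]);
  S.ampPivot = a[0] * M_PI / 180.0; S.ampSeg = a[1] * M_PI / 180.0;
  S.ampHelix = a[2] * M_PI / 180.0; S.ampHelixT = a[3]; S.ampLocal = a[4];
  if (S.pivotSets.empty()) S.wPivot = 0;
  if (S.segU.empty()) S.wSeg = 0;
  if (S.helixSets.empty()) S.wHelix = 0;
  if (S.localBeads.empty()) S.wLocal = 0;
  return S;
}

// ------------------------------------------------------------------ grid

struct Grid {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  bool ok;
  void build(const System& S, const std::vector<double>& X) {
    cell = std::max(S.evCut, 4.0);
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < S.nb; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], X[3 * i + d]);
        hi[d] = std::max(hi[d], X[3 * i + d]);
      }
    double m = 3 * cell;
    ox = lo[0] - m; oy = lo[1] - m; oz = lo[2] - m;
    nx = (int)((hi[0] - lo[0] + 2 * m) / cell) + 1;
    ny = (int)((hi[1] - lo[1] + 2 * m) / cell) + 1;
    nz = (int)((hi[2] - lo[2] + 2 * m) / cell) + 1;
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < S.nb; ++i) cells[index(&X[3 * i])].push_back(i);
    ok = true;
  }
  inline bool inside(const double* p) const {
    return p[0] > ox && p[0] < ox + nx * cell &&
           p[1] > oy && p[1] < oy + ny * cell &&
           p[2] > oz && p[2] < oz + nz * cell;
  }
  inline size_t index(const double* p) const {
    int cx = (int)((p[0] - ox) / cell), cy = (int)((p[1] - oy) / cell),
        cz = (int)((p[2] - oz) / cell);
    cx = std::min(std::max(cx, 0), nx - 1);
    cy = std::min(std::max(cy, 0), ny - 1);
    cz = std::min(std::max(cz, 0), nz - 1);
    return ((size_t)cx * ny + cy) * nz + cz;
  }
  void remove(int bead, const double* p) {
    auto& v = cells[index(p)];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == bead) { v[k] = v.back(); v.pop_back(); return; }
  }
  void add(int bead, const double* p) { cells[index(p)].push_back(bead); }
};

// ------------------------------------------------------------ energy terms

static inline double dist(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double angleRad(const double* a, const double* b,
                              const double* c) {
  double u[3] = {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
  double v[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
  double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
  double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
  double ct = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu * nv);
  ct = std::min(1.0, std::max(-1.0, ct));
  return std::acos(ct);
}

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1]*b[2]-a[2]*b[1]; o[1] = a[2]*b[0]-a[0]*b[2];
  o[2] = a[0]*b[1]-a[1]*b[0];
}

static inline double dihedralRad(const double* p1, const double* p2,
                                 const double* p3, const double* p4) {
  double b1[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
  double b2[3] = {p3[0]-p2[0], p3[1]-p2[1], p3[2]-p2[2]};
  double b3[3] = {p4[0]-p3[0], p4[1]-p3[1], p4[2]-p3[2]};
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  if (nb2 < 1e-12) return 0.0;
  m1[0] = (n1[1]*b2[2]-n1[2]*b2[1]) / nb2;
  m1[1] = (n1[2]*b2[0]-n1[0]*b2[2]) / nb2;
  m1[2] = (n1[0]*b2[1]-n1[1]*b2[0]) / nb2;
  double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double y = m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2];
  return std::atan2(y, x);
}

static inline double noeEnergy(double r, double rmin, double rmax,
                               double kmin, double kmax, double fmax) {
  if (r >= rmin && r <= rmax) return 0.0;
  double d, k;
  if (r < rmin) { d = rmin - r; k = kmin; } else { d = r - rmax; k = kmax; }
  double dcap = (k > 0) ? fmax / k : 1e30;
  if (d <= dcap) return 0.5 * k * d * d;
  return 0.5 * fmax * dcap + fmax * (d - dcap);
}

static inline bool evExcluded(const System& S, int i, int j) {
  if (std::abs(S.resid[i] - S.resid[j]) <= 1) return true;
  if (S.group[i] > 0 && S.group[i] == S.group[j]) return true;
  return false;
}

static inline double evPair(const System& S, int i, int j, double r) {
  double sig = S.evr[i] + S.evr[j];
  if (r >= sig) return 0.0;
  double d = sig - r;
  return 0.5 * S.evk * d * d;
}

// Rg of all beads from running sums
static inline double rgFromSums(int nb, const double* Ssum, double Sq) {
  double mx = Ssum[0] / nb, my = Ssum[1] / nb, mz = Ssum[2] / nb;
  double v = Sq / nb - (mx * mx + my * my + mz * mz);
  return v > 0 ? std::sqrt(v) : 0.0;
}

// full energy with breakdown
static std::map<std::string, double> fullEnergy(const System& S,
                                                const std::vector<double>& X) {
  std::map<std::string, double> E;
  double e = 0;
  for (size_t k = 0; k < S.bi.size(); ++k) {
    double r = dist(&X[3 * S.bi[k]], &X[3 * S.bj[k]]);
    e += 0.5 * S.bk[k] * (r - S.b0[k]) * (r - S.b0[k]);
  }
  E["bond"] = e; e = 0;
  for (size_t k = 0; k < S.ai.size(); ++k) {
    double t = angleRad(&X[3*S.ai[k]], &X[3*S.aj[k]], &X[3*S.ak[k]]);
    e += 0.5 * S.akc[k] * (t - S.a0[k]) * (t - S.a0[k]);
  }
  E["angle"] = e; e = 0;
  for (size_t k = 0; k < S.di.size(); ++k) {
    double p = dihedralRad(&X[3*S.di[k]], &X[3*S.dj[k]], &X[3*S.dk[k]],
                           &X[3*S.dl[k]]);
    e += S.dkc[k] * (1.0 - std::cos(p - S.dphi0[k]));
  }
  E["dihedral"] = e; e = 0;
  if (S.evOn) {
    for (int i = 0; i < S.nb - 1; ++i)
      for (int j = i + 1; j < S.nb; ++j) {
        if (evExcluded(S, i, j)) continue;
        double r = dist(&X[3 * i], &X[3 * j]);
        if (r < S.evCut) e += evPair(S, i, j, r);
      }
  }
  E["ev"] = e; e = 0;
  for (size_t k = 0; k < S.ti.size(); ++k) {
    double r = dist(&X[3 * S.ti[k]], &X[3 * S.tj[k]]);
    double z = (r - S.tr0[k]) / S.tw[k];
    e += -S.teps[k] * std::exp(-0.5 * z * z);
  }
  E["attraction"] = e; e = 0;
  for (size_t k = 0; k < S.ni.size(); ++k) {
    double r = dist(&X[3 * S.ni[k]], &X[3 * S.nj[k]]);
    e += noeEnergy(r, S.nrmin[k], S.nrmax[k], S.nkmin[k], S.nkmax[k],
                   S.nfmax[k]);
  }
  E["noe"] = e; e = 0;
  for (size_t k = 0; k < S.ri.size(); ++k) {
    double p = dihedralRad(&X[3*S.ri[k]], &X[3*S.rj[k]], &X[3*S.rk[k]],
                           &X[3*S.rl[k]]);
    e += S.rK[k] * (1.0 - std::cos(p - S.rphi0[k]));
  }
  E["dihres"] = e; e = 0;
  if (S.rgOn) {
    double Ssum[3] = {0, 0, 0}, Sq = 0;
    for (int i = 0; i < S.nb; ++i) {
      for (int d = 0; d < 3; ++d) Ssum[d] += X[3 * i + d];
      Sq += X[3*i]*X[3*i] + X[3*i+1]*X[3*i+1] + X[3*i+2]*X[3*i+2];
    }
    double rg = rgFromSums(S.nb, Ssum, Sq);
    e = 0.5 * S.rgK * (rg - S.rgTarget) * (rg - S.rgTarget);
  }
  E["rg"] = e;
  double tot = 0;
  for (auto& kv : E) tot += kv.second;
  E["total"] = tot;
  return E;
}

// [[Rcpp::export(name = ".cppEnergy")]]
NumericVector cppEnergy(List sys, NumericMatrix coords) {
  System S = parseSystem(sys);
  std::vector<double> X(3 * S.nb);
  for (int i = 0; i < S.nb; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);
  for (double v : X) if (!std::isfinite(v)) stop("NaN coordinates");
  auto E = fullEnergy(S, X);
  NumericVector out(E.size());
  CharacterVector nm(E.size());
  int k = 0;
  for (auto& kv : E) { out[k] = kv.second; nm[k] = kv.first; ++k; }
  out.names() = nm;
  return out;
}

// ------------------------------------------------------------ MC machinery

struct MCState {
  std::vector<double> X;
  double E;
  double Ssum[3], Sq; // coordinate sums for Rg
  Grid grid;
  void initSums(int nb) {
    Ssum[0] = Ssum[1] = Ssum[2] = 0; Sq = 0;
    for (int i = 0; i < nb; ++i) {
      for (int d = 0; d < 3; ++d) Ssum[d] += X[3 * i + d];
      Sq += X[3*i]*X[3*i] + X[3*i+1]*X[3*i+1] + X[3*i+2]*X[3*i+2];
    }
  }
};

struct Proposal {
  std::vector<int> moved;
  std::vector<double> newPos; // 3 per moved bead
};

static void rotMat(const double* axis, double ang, double R[9]) {
  double c = std::cos(ang), s = std::sin(ang), t = 1 - c;
  double x = axis[0], y = axis[1], z = axis[2];
  R[0] = t*x*x + c;   R[1] = t*x*y - s*z; R[2] = t*x*z + s*y;
  R[3] = t*x*y + s*z; R[4] = t*y*y + c;   R[5] = t*y*z - s*x;
  R[6] = t*x*z - s*y; R[7] = t*y*z + s*x; R[8] = t*z*z + c;
}

struct RNG {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> U{0.0, 1.0};
  std::normal_distribution<double> N{0.0, 1.0};
  RNG(uint64_t seed) : eng(seed) {}
  double unif() { return U(eng); }
  double unif(double a, double b) { return a + (b - a) * U(eng); }
  int pick(int n) { return (int)(U(eng) * n) % n; }
  void axis(double* a) {
    double n2;
    do {
      a[0] = N(eng); a[1] = N(eng); a[2] = N(eng);
      n2 = a[0]*a[0] + a[1]*a[1] + a[2]*a[2];
    } while (n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    a[0] *= inv; a[1] *= inv; a[2] *= inv;
  }
};

// expand a backbone window [a, b] (positions into S.backbone) to bead set
static void segmentBeads(const System& S, int a, int b,
                         std::vector<int>& out) {
  out.clear();
  for (int t = a; t <= b; ++t) {
    int bead = S.backbone[t];
    out.push_back(bead);
    if (S.btype[bead] == 1) { // S bead: bring B and B2 along
      int res = S.resid[bead];
      if (S.bOfRes[res] >= 0) out.push_back(S.bOfRes[res]);
      if (S.b2OfRes[res] >= 0) out.push_back(S.b2OfRes[res]);
    }
  }
}

static void applyRigid(const std::vector<double>& X,
                       const std::vector<int>& moved, const double* origin,
                       const double R[9], const double* trans,
                       std::vector<double>& out) {
  out.resize(3 * moved.size());
  for (size_t k = 0; k < moved.size(); ++k) {
    const double* p = &X[3 * moved[k]];
    double v[3] = {p[0] - origin[0], p[1] - origin[1], p[2] - origin[2]};
    out[3*k]   = R[0]*v[0] + R[1]*v[1] + R[2]*v[2] + origin[0] + trans[0];
    out[3*k+1] = R[3]*v[0] + R[4]*v[1] + R[5]*v[2] + origin[1] + trans[1];
    out[3*k+2] = R[6]*v[0] + R[7]*v[1] + R[8]*v[2] + origin[2] + trans[2];
  }
}

// Delta energy of a proposal; movedIdx must map bead -> row in prop.newPos.
static double deltaEnergy(const System& S, MCState& st, const Proposal& prop,
                          std::vector<int>& movedIdx, bool rigid,
                          double* dSums /*4: dSx dSy dSz dSq*/) {
  const std::vector<double>& X = st.X;
  auto pos = [&](int i) -> const double* {
    int m = movedIdx[i];
    return m >= 0 ? &prop.newPos[3 * m] : &X[3 * i];
  };
  auto touched = [&](std::initializer_list<int> beads) {
    bool any = false, all = true;
    for (int b : beads) {
      if (movedIdx[b] >= 0) any = true; else all = false;
    }
    return any && !(rigid && all);
  };
  double dE = 0;
  for (size_t k = 0; k < S.bi.size(); ++k) {
    int i = S.bi[k], j = S.bj[k];
    if (!touched({i, j})) continue;
    double rOld = dist(&X[3 * i], &X[3 * j]);
    double rNew = dist(pos(i), pos(j));
    dE += 0.5 * S.bk[k] * ((rNew - S.b0[k]) * (rNew - S.b0[k]) -
                           (rOld - S.b0[k]) * (rOld - S.b0[k]));
  }
  for (size_t k = 0; k < S.ai.size(); ++k) {
    int i = S.ai[k], j = S.aj[k], l = S.ak[k];
    if (!touched({i, j, l})) continue;
    double tOld = angleRad(&X[3*i], &X[3*j], &X[3*l]);
    double tNew = angleRad(pos(i), pos(j), pos(l));
    dE += 0.5 * S.akc[k] * ((tNew - S.a0[k]) * (tNew - S.a0[k]) -
                            (tOld - S.a0[k]) * (tOld - S.a0[k]));
  }
  for (size_t k = 0; k < S.di.size(); ++k) {
    int i = S.di[k], j = S.dj[k], l = S.dk[k], m = S.dl[k];
    if (!touched({i, j, l, m})) continue;
    double pOld = dihedralRad(&X[3*i], &X[3*j], &X[3*l], &X[3*m]);
    double pNew = dihedralRad(pos(i), pos(j), pos(l), pos(m));
    dE += S.dkc[k] * (std::cos(pOld - S.dphi0[k]) - std::cos(pNew - S.dphi0[k]));
  }
  for (size_t k = 0; k < S.ti.size(); ++k) {
    int i = S.ti[k], j = S.tj[k];
    if (!touched({i, j})) continue;
    double rOld = dist(&X[3 * i], &X[3 * j]);
    double rNew = dist(pos(i), pos(j));
    double zo = (rOld - S.tr0[k]) / S.tw[k], zn = (rNew - S.tr0[k]) / S.tw[k];
    dE += -S.teps[k] * (std::exp(-0.5 * zn * zn) - std::exp(-0.5 * zo * zo));
  }
  for (size_t k = 0; k < S.ni.size(); ++k) {
    int i = S.ni[k], j = S.nj[k];
    if (!touched({i, j})) continue;
    double rOld = dist(&X[3 * i], &X[3 * j]);
    double rNew = dist(pos(i), pos(j));
    dE += noeEnergy(rNew, S.nrmin[k], S.nrmax[k], S.nkmin[k], S.nkmax[k],
                    S.nfmax[k]) -
          noeEnergy(rOld, S.nrmin[k], S.nrmax[k], S.nkmin[k], S.nkmax[k],
                    S.nfmax[k]);
  }
  for (size_t k = 0; k < S.ri.size(); ++k) {
    int i = S.ri[k], j = S.rj[k], l = S.rk[k], m = S.rl[k];
    if (!touched({i, j, l, m})) continue;
    double pOld = dihedralRad(&X[3*i], &X[3*j], &X[3*l], &X[3*m]);
    double pNew = dihedralRad(pos(i), pos(j), pos(l), pos(m));
    dE += S.rK[k] * (std::cos(pOld - S.rphi0[k]) - std::cos(pNew - S.rphi0[k]));
  }
  if (S.evOn) {
    // moved vs static through the grid (moved-moved pairs are internal to a
    // rigid transform, or absent for single-bead moves)
    for (size_t k = 0; k < prop.moved.size(); ++k) {
      int i = prop.moved[k];
      const double* po = &X[3 * i];
      const double* pn = &prop.newPos[3 * k];
      for (int pass = 0; pass < 2; ++pass) {
        const double* p = pass == 0 ? po : pn;
        double sign = pass == 0 ? -1.0 : 1.0;
        int cx = (int)((p[0] - st.grid.ox) / st.grid.cell);
        int cy = (int)((p[1] - st.grid.oy) / st.grid.cell);
        int cz = (int)((p[2] - st.grid.oz) / st.grid.cell);
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int gx = cx + dx, gy = cy + dy, gz = cz + dz;
              if (gx < 0 || gy < 0 || gz < 0 || gx >= st.grid.nx ||
                  gy >= st.grid.ny || gz >= st.grid.nz)
                continue;
              const std::vector<int>& cell =
                st.grid.cells[((size_t)gx * st.grid.ny + gy) * st.grid.nz + gz];
              for (int j : cell) {
                if (movedIdx[j] >= 0) continue;
                if (evExcluded(S, i, j)) continue;
                double r = dist(p, &X[3 * j]);
                if (r < S.evCut) dE += sign * evPair(S, i, j, r);
              }
            }
      }
    }
  }
  // Rg term / sums
  dSums[0] = dSums[1] = dSums[2] = dSums[3] = 0;
  for (size_t k = 0; k < prop.moved.size(); ++k) {
    const double* po = &st.X[3 * prop.moved[k]];
    const double* pn = &prop.newPos[3 * k];
    for (int d = 0; d < 3; ++d) dSums[d] += pn[d] - po[d];
    dSums[3] += pn[0]*pn[0] + pn[1]*pn[1] + pn[2]*pn[2] -
                (po[0]*po[0] + po[1]*po[1] + po[2]*po[2]);
  }
  if (S.rgOn) {
    double rgOld = rgFromSums(S.nb, st.Ssum, st.Sq);
    double Sn[3] = {st.Ssum[0] + dSums[0], st.Ssum[1] + dSums[1],
                    st.Ssum[2] + dSums[2]};
    double rgNew = rgFromSums(S.nb, Sn, st.Sq + dSums[3]);
    dE += 0.5 * S.rgK * ((rgNew - S.rgTarget) * (rgNew - S.rgTarget) -
                         (rgOld - S.rgTarget) * (rgOld - S.rgTarget));
  }
  return dE;
}

static bool propose(const System& S, MCState& st, RNG& rng, double beta,
                    std::vector<int>& movedIdx, int& moveType) {
  double wtot = S.wPivot + S.wSeg + S.wHelix + S.wLocal;
  double u = rng.unif() * wtot;
  Proposal prop;
  bool rigid = true;
  double origin[3], ax[3], R[9], trans[3] = {0, 0, 0};
  if (u < S.wPivot) {
    moveType = 0;
    double uu = rng.unif();
    int k = (int)(std::lower_bound(S.pivotCum.begin(), S.pivotCum.end(), uu) -
                  S.pivotCum.begin());
    if (k >= (int)S.pivotSets.size()) k = (int)S.pivotSets.size() - 1;
    prop.moved = S.pivotSets[k];
    const double* o = &st.X[3 * S.pivotAxis[k]];
    origin[0] = o[0]; origin[1] = o[1]; origin[2] = o[2];
    rng.axis(ax);
    // amplitude mixture: full-range reorientations decorrelate arms when
    // accepted; quarter-range proposals keep acceptance up in crowded states
    double amp = rng.unif() < 0.5 ? S.ampPivot : S.ampPivot * 0.25;
    rotMat(ax, rng.unif(-amp, amp), R);
    applyRigid(st.X, prop.moved, origin, R, trans, prop.newPos);
  } else if (u < S.wPivot + S.wSeg) {
    moveType = 1;
    int k = rng.pick((int)S.segU.size());
    segmentBeads(S, S.segA[k], S.segB[k], prop.moved);
    const double* pu = &st.X[3 * S.segU[k]];
    const double* pv = &st.X[3 * S.segV[k]];
    double d[3] = {pv[0]-pu[0], pv[1]-pu[1], pv[2]-pu[2]};
    double n = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    if (n > 1e-6) { ax[0]=d[0]/n; ax[1]=d[1]/n; ax[2]=d[2]/n; }
    else rng.axis(ax);
    origin[0] = pu[0]; origin[1] = pu[1]; origin[2] = pu[2];
    rotMat(ax, rng.unif(-S.ampSeg, S.ampSeg), R);
    applyRigid(st.X, prop.moved, origin, R, trans, prop.newPos);
  } else if (u < S.wPivot + S.wSeg + S.wHelix) {
    moveType = 2;
    int k = rng.pick((int)S.helixSets.size());
    prop.moved = S.helixSets[k];
    origin[0] = origin[1] = origin[2] = 0;
    for (int b : prop.moved)
      for (int d = 0; d < 3; ++d) origin[d] += st.X[3 * b + d];
    for (int d = 0; d < 3; ++d) origin[d] /= prop.moved.size();
    rng.axis(ax);
    rotMat(ax, rng.unif(-S.ampHelix, S.ampHelix), R);
    for (int d = 0; d < 3; ++d)
      trans[d] = rng.unif(-S.ampHelixT, S.ampHelixT);
    applyRigid(st.X, prop.moved, origin, R, trans, prop.newPos);
  } else {
    moveType = 3;
    int b = S.localBeads[rng.pick((int)S.localBeads.size())];
    prop.moved = {b};
    prop.newPos = {st.X[3*b] + rng.unif(-S.ampLocal, S.ampLocal),
                   st.X[3*b+1] + rng.unif(-S.ampLocal, S.ampLocal),
                   st.X[3*b+2] + rng.unif(-S.ampLocal, S.ampLocal)};
    rigid = false;
  }
  for (size_t k = 0; k < prop.moved.size(); ++k)
    movedIdx[prop.moved[k]] = (int)k;
  double dSums[4];
  double dE = deltaEnergy(S, st, prop, movedIdx, rigid || prop.moved.size() > 1,
                          dSums);
  bool accept = dE <= 0 || rng.unif() < std::exp(-beta * dE);
  if (accept) {
    bool rebuild = false;
    for (size_t k = 0; k < prop.moved.size(); ++k)
      if (!st.grid.inside(&prop.newPos[3 * k])) rebuild = true;
    for (size_t k = 0; k < prop.moved.size(); ++k) {
      int b = prop.moved[k];
      if (!rebuild) st.grid.remove(b, &st.X[3 * b]);
      st.X[3*b] = prop.newPos[3*k];
      st.X[3*b+1] = prop.newPos[3*k+1];
      st.X[3*b+2] = prop.newPos[3*k+2];
      if (!rebuild) st.grid.add(b, &st.X[3 * b]);
    }
    if (rebuild) st.grid.build(S, st.X);
    st.E += dE;
    for (int d = 0; d < 3; ++d) st.Ssum[d] += dSums[d];
    st.Sq += dSums[3];
  }
  for (int b : prop.moved) movedIdx[b] = -1;
  return accept;
}

// re-snap rigid groups onto their templates (removes FP drift)
static void resnapGroups(const System& S, std::vector<double>& X) {
  for (size_t g = 0; g < S.groupBeads.size(); ++g) {
    const std::vector<int>& beads = S.groupBeads[g];
    const arma::mat& tpl = S.groupTpl[g]; // m x 3
    int m = (int)beads.size();
    arma::mat cur(m, 3);
    for (int k = 0; k < m; ++k)
      for (int d = 0; d < 3; ++d) cur(k, d) = X[3 * beads[k] + d];
    arma::rowvec cT = arma::mean(tpl, 0), cC = arma::mean(cur, 0);
    arma::mat H = (tpl.each_row() - cT).t() * (cur.each_row() - cC);
    arma::mat U, V; arma::vec s;
    if (!arma::svd(U, s, V, H)) continue;
    arma::mat Rm = V * U.t();
    if (arma::det(Rm) < 0) { V.col(2) *= -1; Rm = V * U.t(); }
    arma::mat fit = (tpl.each_row() - cT) * Rm.t();
    fit.each_row() += cC;
    for (int k = 0; k < m; ++k)
      for (int d = 0; d < 3; ++d) X[3 * beads[k] + d] = fit(k, d);
  }
}

// [[Rcpp::export(name = ".cppRemdRun")]]
List cppRemdRun(List sys, NumericMatrix coords, NumericVector temps,
                int rounds, int movesPerRound, int recordEvery,
                IntegerVector selIdx, double seed, int resyncEvery) {
  System S = parseSystem(sys);
  int nT = temps.size();
  RNG rng((uint64_t)seed);
  std::vector<MCState> reps(nT);
  for (int t = 0; t < nT; ++t) {
    reps[t].X.resize(3 * S.nb);
    for (int i = 0; i < S.nb; ++i)
      for (int d = 0; d < 3; ++d) reps[t].X[3 * i + d] = coords(i, d);
    reps[t].initSums(S.nb);
    reps[t].E = fullEnergy(S, reps[t].X)["total"];
  }
  std::vector<int> tempOf(nT); // replica -> temperature index
  for (int t = 0; t < nT; ++t) tempOf[t] = t;
  std::vector<double> beta(nT);
  for (int t = 0; t < nT; ++t) beta[t] = 1.0 / (RGAS * temps[t]);

  int framesPerRound = recordEvery > 0 ? movesPerRound / recordEvery : 0;
  int nFrames = rounds * framesPerRound;
  int ns = selIdx.size();
  NumericMatrix frames(std::max(nFrames, 1), std::max(3 * ns, 1));
  NumericVector frg(std::max(nFrames, 1));
  IntegerVector fstep(std::max(nFrames, 1)), frep(std::max(nFrames, 1));
  int fcount = 0;

  std::vector<int> movedIdx(S.nb, -1);
  std::vector<long> exchAtt(std::max(nT - 1, 1), 0),
      exchAcc(std::max(nT - 1, 1), 0);
  std::vector<long> moveAtt(4, 0), moveAcc(4, 0);
  std::vector<int> sel(ns);
  for (int k = 0; k < ns; ++k) sel[k] = selIdx[k] - 1;

  for (int round = 0; round < rounds; ++round) {
    for (int r = 0; r < nT; ++r) {
      MCState& st = reps[r];
      st.grid.build(S, st.X);
      double b = beta[tempOf[r]];
      bool rec = (tempOf[r] == 0) && recordEvery > 0;
      for (int mv = 0; mv < movesPerRound; ++mv) {
        int type = -1;
        bool acc = propose(S, st, rng, b, movedIdx, type);
        moveAtt[type]++; if (acc) moveAcc[type]++;
        if (rec && ((mv + 1) % recordEvery == 0) && fcount < nFrames) {
          for (int k = 0; k < ns; ++k)
            for (int d = 0; d < 3; ++d)
              frames(fcount, 3 * k + d) = st.X[3 * sel[k] + d];
          frg[fcount] = rgFromSums(S.nb, st.Ssum, st.Sq);
          fstep[fcount] = round * movesPerRound + mv + 1;
          frep[fcount] = r + 1;
          fcount++;
        }
      }
      if (!std::isfinite(st.E)) stop("non-finite energy mid-run");
    }
    // neighbour exchanges, alternating parity
    std::vector<int> repOf(nT);
    for (int r = 0; r < nT; ++r) repOf[tempOf[r]] = r;
    for (int t = round % 2; t + 1 < nT; t += 2) {
      int rA = repOf[t], rB = repOf[t + 1];
      double del = (beta[t] - beta[t + 1]) * (reps[rA].E - reps[rB].E);
      exchAtt[t]++;
      if (del >= 0 || rng.unif() < std::exp(del)) {
        std::swap(tempOf[rA], tempOf[rB]);
        std::swap(repOf[t], repOf[t + 1]);
        exchAcc[t]++;
      }
    }
    if (resyncEvery > 0 && (round + 1) % resyncEvery == 0) {
      for (int r = 0; r < nT; ++r) {
        resnapGroups(S, reps[r].X);
        reps[r].initSums(S.nb);
        reps[r].E = fullEnergy(S, reps[r].X)["total"];
      }
    }
  }
  List finalCoords(nT);
  NumericVector finalE(nT);
  IntegerVector finalTemp(nT);
  for (int r = 0; r < nT; ++r) {
    NumericMatrix Xm(S.nb, 3);
    for (int i = 0; i < S.nb; ++i)
      for (int d = 0; d < 3; ++d) Xm(i, d) = reps[r].X[3 * i + d];
    finalCoords[r] = Xm;
    finalE[r] = fullEnergy(S, reps[r].X)["total"];
    finalTemp[r] = tempOf[r] + 1;
  }
  return List::create(
    _["frames"] = frames, _["nFrames"] = fcount, _["rg"] = frg,
    _["step"] = fstep, _["replica"] = frep,
    _["exchAtt"] = wrap(exchAtt), _["exchAcc"] = wrap(exchAcc),
    _["moveAtt"] = wrap(moveAtt), _["moveAcc"] = wrap(moveAcc),
    _["finalCoords"] = finalCoords, _["finalE"] = finalE,
    _["finalTemp"] = finalTemp);
}

// ------------------------------------------------------------ analysis

// Kabsch rotation fitting template S-beads to each frame
// frames: F x (3*ns); rows: 1-based rows (into ns) of the template beads
// [[Rcpp::export(name = ".cppFitFrames")]]
List cppFitFrames(NumericMatrix frames, NumericMatrix tpl,
                  IntegerVector rows) {
  int F = frames.nrow(), m = rows.size();
  arma::mat T(m, 3);
  for (int k = 0; k < m; ++k)
    for (int d = 0; d < 3; ++d) T(k, d) = tpl(k, d);
  arma::rowvec cT = arma::mean(T, 0);
  arma::mat Tc = T.each_row() - cT;
  NumericMatrix rot(F, 9), origin(F, 3);
  arma::mat cur(m, 3);
  for (int f = 0; f < F; ++f) {
    for (int k = 0; k < m; ++k) {
      int r = rows[k] - 1;
      for (int d = 0; d < 3; ++d) cur(k, d) = frames(f, 3 * r + d);
    }
    arma::rowvec cC = arma::mean(cur, 0);
    arma::mat H = Tc.t() * (cur.each_row() - cC);
    arma::mat U, V; arma::vec s;
    arma::svd(U, s, V, H);
    arma::mat Rm = V * U.t();
    if (arma::det(Rm) < 0) { V.col(2) *= -1; Rm = V * U.t(); }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) rot(f, 3 * a + b) = Rm(a, b);
    for (int d = 0; d < 3; ++d) origin(f, d) = cC(d);
  }
  return List::create(_["rot"] = rot, _["origin"] = origin);
}

// least-squares superposition RMSD of two point sets
// [[Rcpp::export(name = ".cppKabschRmsd")]]
double cppKabschRmsd(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow();
  arma::mat P(n, 3), Q(n, 3);
  for (int k = 0; k < n; ++k)
    for (int d = 0; d < 3; ++d) { P(k, d) = A(k, d); Q(k, d) = B(k, d); }
  P.each_row() -= arma::mean(P, 0);
  Q.each_row() -= arma::mean(Q, 0);
  arma::mat H = P.t() * Q;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::vec sg = {1, 1, d};
  double num = arma::accu(arma::square(P)) + arma::accu(arma::square(Q)) -
               2.0 * arma::dot(sg, s);
  return std::sqrt(std::max(0.0, num / n));
}

// per-frame count of (a, b) bead pairs within cutoff
// [[Rcpp::export(name = ".cppContactCounts")]]
IntegerVector cppContactCounts(NumericMatrix frames, IntegerVector rowsA,
                               IntegerVector rowsB, double cutoff) {
  int F = frames.nrow();
  double c2 = cutoff * cutoff;
  IntegerVector out(F);
  for (int f = 0; f < F; ++f) {
    int cnt = 0;
    for (int a = 0; a < rowsA.size(); ++a) {
      int ra = rowsA[a] - 1;
      double ax = frames(f, 3*ra), ay = frames(f, 3*ra+1), az = frames(f, 3*ra+2);
      for (int b = 0; b < rowsB.size(); ++b) {
        int rb = rowsB[b] - 1;
        double dx = ax - frames(f, 3*rb), dy = ay - frames(f, 3*rb+1),
               dz = az - frames(f, 3*rb+2);
        if (dx*dx + dy*dy + dz*dz < c2) cnt++;
      }
    }
    out[f] = cnt;
  }
  return out;
}

// per-frame contact counts of a region (rowsA) against every recorded bead
// [[Rcpp::export(name = ".cppRegionContact")]]
IntegerMatrix cppRegionContact(NumericMatrix frames, IntegerVector rowsA,
                               double cutoff) {
  int F = frames.nrow(), ns = frames.ncol() / 3;
  double c2 = cutoff * cutoff;
  IntegerMatrix out(F, ns);
  for (int f = 0; f < F; ++f)
    for (int a = 0; a < rowsA.size(); ++a) {
      int ra = rowsA[a] - 1;
      double ax = frames(f, 3*ra), ay = frames(f, 3*ra+1), az = frames(f, 3*ra+2);
      for (int j = 0; j < ns; ++j) {
        double dx = ax - frames(f, 3*j), dy = ay - frames(f, 3*j+1),
               dz = az - frames(f, 3*j+2);
        if (dx*dx + dy*dy + dz*dz < c2) out(f, j)++;
      }
    }
  return out;
}

// worst steric overlap (penetration depth) for diagnostics
// [[Rcpp::export(name = ".cppMaxOverlap")]]
double cppMaxOverlap(List sys, NumericMatrix coords) {
  System S = parseSystem(sys);
  double worst = 0;
  for (int i = 0; i < S.nb - 1; ++i)
    for (int j = i + 1; j < S.nb; ++j) {
      if (evExcluded(S, i, j)) continue;
      double dx = coords(i,0)-coords(j,0), dy = coords(i,1)-coords(j,1),
             dz = coords(i,2)-coords(j,2);
      double r = std::sqrt(dx*dx+dy*dy+dz*dz);
      double sig = S.evr[i] + S.evr[j];
      if (sig - r > worst) worst = sig - r;
    }
  return worst;
}

// worst bond strain |r - b0|
// [[Rcpp::export(name = ".cppMaxStrain")]]
double cppMaxStrain(List sys, NumericMatrix coords) {
  System S = parseSystem(sys);
  double worst = 0;
  for (size_t k = 0; k < S.bi.size(); ++k) {
    double dx = coords(S.bi[k],0)-coords(S.bj[k],0),
           dy = coords(S.bi[k],1)-coords(S.bj[k],1),
           dz = coords(S.bi[k],2)-coords(S.bj[k],2);
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    worst = std::max(worst, std::abs(r - S.b0[k]));
  }
  return worst;
}
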
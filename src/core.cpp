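// Computational core: masked reaction-diffusion stepping, stochastic
// protrusion/retraction engine with digital-topology guards, and mass
// redistribution across mask changes.
//
// Conventions: matrices are column-major (R layout), linear index
// idx = r + c*nr with 0-based r, c. Foreground and background of the cell
// mask are both kept 4-connected; corner-only (diagonal) contacts are
// prohibited for either set.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64, Box-Muller normals.
// A dedicated stream (seeded from the user's single seed) keeps the cost of
// the ~1e9 per-pixel noise draws of a full simulation negligible while
// remaining exactly reproducible.
// ---------------------------------------------------------------------------

namespace {

// ziggurat tables (Doornik layout, 128 layers), built once
struct ZigTables {
  double X[129], Rr[128];
  ZigTables() {
    const double R = 3.442619855899, V = 9.91256303526217e-3;
    double f = std::exp(-0.5 * R * R);
    X[0] = V / f;
    X[1] = R;
    X[128] = 0.0;
    for (int i = 2; i < 128; ++i) {
      X[i] = std::sqrt(-2.0 * std::log(V / X[i - 1] + f));
      f = std::exp(-0.5 * X[i] * X[i]);
    }
    for (int i = 0; i < 128; ++i) Rr[i] = X[i + 1] / X[i];
  }
};
static const ZigTables ZIG;

struct XRng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit XRng(uint64_t seed) {
    uint64_t x = seed;
    for (int k = 0; k < 4; ++k) s[k] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1)
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double norm_tail(double dmin, bool negative) {
    double x, y;
    do {
      x = std::log(unif()) / dmin;
      y = std::log(unif());
    } while (-2.0 * y < x * x);
    return negative ? x - dmin : dmin - x;
  }

  // standard normal via the ziggurat method (rectangles cover ~98% of draws)
  inline double norm() {
    for (;;) {
      const uint64_t b = next();
      const double u =
          2.0 * ((static_cast<double>(b >> 11) + 0.5) *
                 (1.0 / 9007199254740992.0)) - 1.0;
      const unsigned i = static_cast<unsigned>(b & 0x7F);
      if (std::fabs(u) < ZIG.Rr[i]) return u * ZIG.X[i];
      if (i == 0) return norm_tail(3.442619855899, u < 0);
      const double x = u * ZIG.X[i];
      const double f0 = std::exp(-0.5 * (ZIG.X[i] * ZIG.X[i] - x * x));
      const double f1 = std::exp(-0.5 * (ZIG.X[i + 1] * ZIG.X[i + 1] - x * x));
      if (f1 + unif() * (f0 - f1) < 1.0) return x;
    }
  }
};

// ---------------------------------------------------------------------------
// Reaction pairs
// ---------------------------------------------------------------------------

struct PairSpec {
  int a, i;           // component indices (0-based) of active/inactive form
  double kon, koff;   // basal activation / deactivation rates
  double gamma;       // feedback magnitude
  double alpha; int src1;  // cross-activation gain and source (active form), -1 = none
  double mu;    int src2;  // second cross-activation source, -1 = none
  double beta;  int inhib; // inhibitor weight in the Hill threshold, -1 = none
  double Kedge2, Kbasal2;  // squared activation thresholds (edge / basal pixels)
  bool hill;          // TRUE: Hill-type GTPase pair; FALSE: inhibitor pair
  double Da, Di;      // diffusion coefficients of active / inactive form
};

std::vector<PairSpec> parse_pairs(const List &pairs, const NumericVector &D) {
  std::vector<PairSpec> out;
  for (int k = 0; k < pairs.size(); ++k) {
    List p = pairs[k];
    PairSpec s;
    s.a = as<int>(p["a"]) - 1;
    s.i = as<int>(p["i"]) - 1;
    s.kon = as<double>(p["kon"]);
    s.koff = as<double>(p["koff"]);
    s.gamma = as<double>(p["gamma"]);
    s.alpha = as<double>(p["alpha"]);
    s.src1 = as<int>(p["src1"]) - 1;   // 0 in R means none -> -1
    s.mu = as<double>(p["mu"]);
    s.src2 = as<int>(p["src2"]) - 1;
    s.beta = as<double>(p["beta"]);
    s.inhib = as<int>(p["inhib"]) - 1;
    double Ke = as<double>(p["Kedge"]), Kb = as<double>(p["Kbasal"]);
    s.Kedge2 = Ke * Ke;
    s.Kbasal2 = Kb * Kb;
    s.hill = as<bool>(p["hill"]);
    s.Da = D[s.a];
    s.Di = D[s.i];
    out.push_back(s);
  }
  return out;
}

inline double pair_rate(const PairSpec &P, const std::vector<const double *> &f,
                        int idx, bool edgepx) {
  const double xa = f[P.a][idx], xi = f[P.i][idx];
  double act;
  if (P.hill) {
    double g = P.gamma;
    if (P.src1 >= 0) { const double s = f[P.src1][idx]; g += P.alpha * s * s; }
    if (P.src2 >= 0) { const double s = f[P.src2][idx]; g += P.mu * s * s; }
    double den = (edgepx ? P.Kedge2 : P.Kbasal2) + xa * xa;
    if (P.inhib >= 0) { const double ia = f[P.inhib][idx]; den += P.beta * ia * ia; }
    act = P.kon + g * xa * xa / den;
  } else {
    const double s = (P.src1 >= 0) ? f[P.src1][idx] : 0.0;
    act = P.kon + P.gamma * s * s;
  }
  return act * xi - P.koff * xa;
}

// ---------------------------------------------------------------------------
// Mask indexing: list of foreground pixels with 4-neighbor indices
// (self-substitution outside the mask implements the mirror/ghost no-flux
// boundary of the five-point stencil) and an edge-pixel flag.
// ---------------------------------------------------------------------------

struct MaskIndex {
  int nr, nc;
  std::vector<int> px;       // linear indices of mask pixels
  std::vector<int> nb;       // 4 * npx neighbor indices (self if outside mask)
  std::vector<uint8_t> edge; // 1 if pixel has a 4-neighbor outside the mask
};

void build_index(const int *mask, int nr, int nc, MaskIndex &mi) {
  mi.nr = nr; mi.nc = nc;
  mi.px.clear(); mi.nb.clear(); mi.edge.clear();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int idx = r + c * nr;
      if (!mask[idx]) continue;
      mi.px.push_back(idx);
      int n[4];
      bool e = false;
      // up, down, left, right
      if (r > 0 && mask[idx - 1]) n[0] = idx - 1; else { n[0] = idx; e = true; }
      if (r < nr - 1 && mask[idx + 1]) n[1] = idx + 1; else { n[1] = idx; e = true; }
      if (c > 0 && mask[idx - nr]) n[2] = idx - nr; else { n[2] = idx; e = true; }
      if (c < nc - 1 && mask[idx + nr]) n[3] = idx + nr; else { n[3] = idx; e = true; }
      for (int k = 0; k < 4; ++k) mi.nb.push_back(n[k]);
      mi.edge.push_back(e ? 1 : 0);
    }
  }
}

// ---------------------------------------------------------------------------
// RD stepping (forward Euler, mass-conserving pairwise noise)
// ---------------------------------------------------------------------------

void rd_steps_core(std::vector<std::vector<double> > &F,
                   std::vector<std::vector<double> > &G,
                   const MaskIndex &mi, const std::vector<PairSpec> &pairs,
                   double dt, double dx, double noise_amp, int noise_scaling,
                   int nsteps, XRng &rng) {
  const int npx = static_cast<int>(mi.px.size());
  const int ncomp = static_cast<int>(F.size());
  const double inv_dx2 = 1.0 / (dx * dx);
  const double eta_scale =
      noise_amp * (noise_scaling == 1 ? std::sqrt(dt) : dt);

  std::vector<const double *> fptr(ncomp);
  std::vector<double *> gptr(ncomp);

  for (int step = 0; step < nsteps; ++step) {
    for (int k = 0; k < ncomp; ++k) {
      fptr[k] = F[k].data();
      gptr[k] = G[k].data();
    }
    for (int q = 0; q < npx; ++q) {
      const int idx = mi.px[q];
      const int *nb = &mi.nb[4 * q];
      const bool edgepx = mi.edge[q] != 0;
      for (size_t pp = 0; pp < pairs.size(); ++pp) {
        const PairSpec &P = pairs[pp];
        const double *va = fptr[P.a];
        const double *vi = fptr[P.i];
        const double xa = va[idx], xi = vi[idx];
        const double lap_a =
            (va[nb[0]] + va[nb[1]] + va[nb[2]] + va[nb[3]] - 4.0 * xa) * inv_dx2;
        const double lap_i =
            (vi[nb[0]] + vi[nb[1]] + vi[nb[2]] + vi[nb[3]] - 4.0 * xi) * inv_dx2;
        const double rate = pair_rate(P, fptr, idx, edgepx);
        double na = xa + dt * (rate + P.Da * lap_a);
        double ni = xi + dt * (-rate + P.Di * lap_i);
        if (eta_scale != 0.0) {
          const double eta = eta_scale * rng.norm();
          // positivity guard: skip the draw if it would push either form
          // of the pair negative (keeps pairing, hence exact conservation)
          if (na + eta >= 0.0 && ni - eta >= 0.0) {
            na += eta;
            ni -= eta;
          }
        }
        gptr[P.a][idx] = na;
        gptr[P.i][idx] = ni;
      }
    }
    F.swap(G);
  }
}

void check_state(const std::vector<std::vector<double> > &F,
                 const MaskIndex &mi, const CharacterVector &comp_names) {
  for (size_t k = 0; k < F.size(); ++k) {
    const double *v = F[k].data();
    for (size_t q = 0; q < mi.px.size(); ++q) {
      const double x = v[mi.px[q]];
      if (!std::isfinite(x) || x < 0.0) {
        const int idx = mi.px[q];
        stop("reaction-diffusion state invalid: component '%s' has value %f "
             "at pixel (row %d, col %d); reduce dt or check parameters",
             std::string(comp_names[k]).c_str(), x, idx % mi.nr + 1,
             idx / mi.nr + 1);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Digital topology: 8-neighborhood in circular order N, NE, E, SE, S, SW, W, NW
// (row decreases upward; orientation is irrelevant for the checks).
// ---------------------------------------------------------------------------

const int NB8_DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int NB8_DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

inline void pattern8(const int *mask, int nr, int nc, int r, int c, bool fg,
                     bool *x) {
  for (int k = 0; k < 8; ++k) {
    const int rr = r + NB8_DR[k], cc = c + NB8_DC[k];
    bool m = false; // outside the frame counts as background
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) m = mask[rr + cc * nr] != 0;
    x[k] = fg ? m : !m;
  }
}

// Yokoi connectivity number for 4-connectivity: the number of 4-connected
// components of the pattern within the 8-neighborhood that touch the center
// through a 4-neighbor.
inline int conn4(const bool *x) {
  int cnum = 0;
  for (int k = 0; k < 8; k += 2) {
    const int k1 = (k + 1) & 7, k2 = (k + 2) & 7;
    cnum += (x[k] ? 1 : 0) - ((x[k] && x[k1] && x[k2]) ? 1 : 0);
  }
  return cnum;
}

// no corner-only contact: every diagonal member of the pattern must share an
// orthogonal member with the center
inline bool no_corner_touch(const bool *x) {
  for (int k = 1; k < 8; k += 2) {
    if (x[k] && !x[k - 1] && !x[(k + 1) & 7]) return false;
  }
  return true;
}

// Is it safe to flip background pixel (r, c) to foreground?
bool can_add_px(const int *mask, int nr, int nc, int r, int c) {
  if (r < 1 || r >= nr - 1 || c < 1 || c >= nc - 1) return false; // keep margin
  if (mask[r + c * nr]) return false;
  bool F[8], B[8];
  pattern8(mask, nr, nc, r, c, true, F);
  for (int k = 0; k < 8; ++k) B[k] = !F[k];
  if (!(F[0] || F[2] || F[4] || F[6])) return false; // needs a 4-neighbor in mask
  if (conn4(F) != 1) return false;  // no bridging of locally distinct arms
  if (conn4(B) != 1) return false;  // background must not be split locally
  if (!no_corner_touch(F)) return false; // no diagonal spur with the mask
  return true;
}

// Is it safe to flip foreground pixel (r, c) to background?
bool can_remove_px(const int *mask, int nr, int nc, int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
  if (!mask[r + c * nr]) return false;
  bool F[8], B[8];
  pattern8(mask, nr, nc, r, c, true, F);
  for (int k = 0; k < 8; ++k) B[k] = !F[k];
  if (!(B[0] || B[2] || B[4] || B[6])) return false; // must be an outline pixel
  if (conn4(F) != 1) return false;  // mask must not be split locally
  if (conn4(B) != 1) return false;  // no enclosed background created
  if (!no_corner_touch(B)) return false; // no diagonal pinch of the mask
  return true;
}

// ---------------------------------------------------------------------------
// Probability factors
// ---------------------------------------------------------------------------

double geom_factor(const int *mask, int nr, int nc, int r, int c, bool protrude,
                   double g, double k) {
  bool M[8];
  pattern8(mask, nr, nc, r, c, protrude, M); // inverted pattern for retraction
  const double wd = std::pow(2.0, -0.5 * g);  // (sqrt 2)^(-g)
  double num = 0.0, den = 0.0;
  for (int q = 0; q < 8; ++q) {
    const double w = (q % 2 == 0) ? 1.0 : wd;
    den += w;
    if (M[q]) num += w;
  }
  return std::pow(num / den, k);
}

inline double sigmoid_rise(double x) { // 1 - 1/(1 + e^x)
  return 1.0 - 1.0 / (1.0 + std::exp(x));
}

inline double vol_factor(double V, double V0, double aV, double bV, double gV,
                         bool protrude) {
  const double s = sigmoid_rise(aV * (V - V0));
  return protrude ? 0.5 + bV - (bV + gV) * s : 0.5 - bV + (bV + gV) * s;
}

inline double act_factor(double A, double aA, double bA, double gA, double Aact,
                         bool protrude) {
  const double s = sigmoid_rise(aA * (A - Aact));
  return protrude ? 0.5 - bA + (bA + gA) * s : 0.5 + bA - (bA + gA) * s;
}

// mean of a field over the in-mask 8-neighborhood (Eq.-45-style extrapolation)
inline bool masked_nb_mean(const double *v, const int *mask, int nr, int nc,
                           int r, int c, double &out) {
  double s = 0.0; int n = 0;
  for (int k = 0; k < 8; ++k) {
    const int rr = r + NB8_DR[k], cc = c + NB8_DC[k];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    const int idx = rr + cc * nr;
    if (mask[idx]) { s += v[idx]; ++n; }
  }
  if (n == 0) return false;
  out = s / n;
  return true;
}

// ---------------------------------------------------------------------------
// Mass redistribution over mask changes
// ---------------------------------------------------------------------------

// subtract `mass` evenly from mask pixels, skipping pixels that would go
// negative; iterate on the remainder so that conservation is exact
void subtract_evenly(double *v, const std::vector<int> &px, double mass) {
  double remaining = mass;
  for (int iter = 0; iter < 50 && remaining > 1e-15 * (1.0 + mass); ++iter) {
    int nel = 0;
    const double sub = remaining / static_cast<double>(px.size());
    for (size_t q = 0; q < px.size(); ++q) if (v[px[q]] >= sub) ++nel;
    if (nel == 0) break;
    const double sub2 = remaining / nel;
    double taken = 0.0;
    for (size_t q = 0; q < px.size(); ++q) {
      if (v[px[q]] >= sub2) { v[px[q]] -= sub2; taken += sub2; }
    }
    remaining -= taken;
    if (taken == 0.0) break;
  }
}

void add_evenly(double *v, const std::vector<int> &px, double mass) {
  const double add = mass / static_cast<double>(px.size());
  for (size_t q = 0; q < px.size(); ++q) v[px[q]] += add;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_normal_draws(int n, double seed) {
  XRng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = rng.norm();
  return out;
}

// ---------------------------------------------------------------------------
// Exported: masked five-point Laplacian with no-flux (mirror ghost) boundary
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_masked_laplacian(NumericMatrix values, IntegerMatrix mask,
                                   double dx) {
  const int nr = values.nrow(), nc = values.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("mask and field dimensions differ");
  NumericMatrix out(nr, nc);
  const double inv_dx2 = 1.0 / (dx * dx);
  const int *m = mask.begin();
  const double *v = values.begin();
  bool any = false;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int idx = r + c * nr;
      if (!m[idx]) { out[idx] = NA_REAL; continue; }
      any = true;
      const double x = v[idx];
      double s = 0.0;
      if (r > 0 && m[idx - 1]) s += v[idx - 1] - x;
      if (r < nr - 1 && m[idx + 1]) s += v[idx + 1] - x;
      if (c > 0 && m[idx - nr]) s += v[idx - nr] - x;
      if (c < nc - 1 && m[idx + nr]) s += v[idx + nr] - x;
      out[idx] = s * inv_dx2;
    }
  }
  if (!any) stop("empty mask");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_edge_pixels(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  const int *m = mask.begin();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int idx = r + c * nr;
      if (!m[idx]) continue;
      bool e = false;
      if (r == 0 || !m[idx - 1]) e = true;
      else if (r == nr - 1 || !m[idx + 1]) e = true;
      else if (c == 0 || !m[idx - nr]) e = true;
      else if (c == nc - 1 || !m[idx + nr]) e = true;
      out[idx] = e ? 1 : 0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: n forward-Euler RD steps on a masked domain
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rd_steps(List fields, IntegerMatrix mask, List pairs, NumericVector D,
                  double dt, double dx, double noise_amp, int noise_scaling,
                  int nsteps, double seed) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int ncomp = fields.size();
  CharacterVector comp_names = fields.names();
  std::vector<std::vector<double> > F(ncomp), G(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    NumericMatrix fk = fields[k];
    if (fk.nrow() != nr || fk.ncol() != nc) stop("field/mask dimension mismatch");
    F[k].assign(fk.begin(), fk.end());
    G[k] = F[k];
  }
  MaskIndex mi;
  build_index(mask.begin(), nr, nc, mi);
  if (mi.px.empty()) stop("empty mask");
  std::vector<PairSpec> ps = parse_pairs(pairs, D);
  XRng rng(static_cast<uint64_t>(seed));
  rd_steps_core(F, G, mi, ps, dt, dx, noise_amp, noise_scaling, nsteps, rng);
  check_state(F, mi, comp_names);
  List out(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    NumericMatrix fk(nr, nc);
    std::copy(F[k].begin(), F[k].end(), fk.begin());
    out[k] = fk;
  }
  out.names() = comp_names;
  return out;
}

// ---------------------------------------------------------------------------
// Exported helpers for the morphodynamic engine
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_geometry_factor(IntegerMatrix mask, int r, int c, bool protrude,
                           double g, double k) {
  return geom_factor(mask.begin(), mask.nrow(), mask.ncol(), r - 1, c - 1,
                     protrude, g, k);
}

// [[Rcpp::export]]
bool cpp_can_add(IntegerMatrix mask, int r, int c) {
  return can_add_px(mask.begin(), mask.nrow(), mask.ncol(), r - 1, c - 1);
}

// [[Rcpp::export]]
bool cpp_can_remove(IntegerMatrix mask, int r, int c) {
  return can_remove_px(mask.begin(), mask.nrow(), mask.ncol(), r - 1, c - 1);
}

// Apply one protrusion (or retraction) event given per-pixel acceptance
// probabilities. Candidates are drawn independently; the accepted set is then
// committed sequentially in random order with the topology guard re-checked
// against the updated mask, so conflicting events cannot both take place.
static List mask_event(IntegerMatrix mask, NumericMatrix prob, bool protrude,
                       double seed, int min_pixels) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  int *mp = m.begin();
  XRng rng(static_cast<uint64_t>(seed));
  std::vector<int> accepted;
  int V = 0;
  for (int idx = 0; idx < nr * nc; ++idx) if (mp[idx]) ++V;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int idx = r + c * nr;
      const bool is_cand =
          protrude ? (!mp[idx] && (  (r > 0 && mp[idx - 1]) ||
                                     (r < nr - 1 && mp[idx + 1]) ||
                                     (c > 0 && mp[idx - nr]) ||
                                     (c < nc - 1 && mp[idx + nr])))
                   : (mp[idx] != 0);
      if (!is_cand) continue;
      const double p = prob[idx];
      if (p > 0.0 && rng.unif() < p) accepted.push_back(idx);
    }
  }
  // Fisher-Yates shuffle
  for (int q = static_cast<int>(accepted.size()) - 1; q > 0; --q) {
    const int j = static_cast<int>(rng.unif() * (q + 1));
    std::swap(accepted[q], accepted[j]);
  }
  std::vector<int> applied;
  for (size_t q = 0; q < accepted.size(); ++q) {
    const int idx = accepted[q];
    const int r = idx % nr, c = idx / nr;
    if (protrude) {
      if (can_add_px(mp, nr, nc, r, c)) { mp[idx] = 1; ++V; applied.push_back(idx); }
    } else {
      if (V > min_pixels && can_remove_px(mp, nr, nc, r, c)) {
        mp[idx] = 0; --V; applied.push_back(idx);
      }
    }
  }
  IntegerVector app(applied.size());
  for (size_t q = 0; q < applied.size(); ++q) app[q] = applied[q] + 1; // 1-based linear
  return List::create(_["mask"] = m, _["applied"] = app);
}

// [[Rcpp::export]]
List cpp_protrusion_step(IntegerMatrix mask, NumericMatrix prob, double seed) {
  return mask_event(mask, prob, true, seed, 0);
}

// [[Rcpp::export]]
List cpp_retraction_step(IntegerMatrix mask, NumericMatrix prob, double seed,
                         int min_pixels) {
  return mask_event(mask, prob, false, seed, min_pixels);
}

// [[Rcpp::export]]
List cpp_redistribute(List fields, IntegerMatrix old_mask,
                      IntegerMatrix new_mask) {
  const int nr = old_mask.nrow(), nc = old_mask.ncol();
  const int *om = old_mask.begin(), *nm = new_mask.begin();
  std::vector<int> added, removed, newpx;
  for (int idx = 0; idx < nr * nc; ++idx) {
    if (nm[idx] && !om[idx]) added.push_back(idx);
    if (om[idx] && !nm[idx]) removed.push_back(idx);
    if (nm[idx]) newpx.push_back(idx);
  }
  if (!added.empty() && !removed.empty())
    stop("masks must be nested (pixels only added or only removed)");
  if (newpx.empty()) stop("new mask is empty");
  const int ncomp = fields.size();
  List out(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    NumericMatrix f = clone(as<NumericMatrix>(fields[k]));
    double *v = f.begin();
    if (!added.empty()) {
      // initialize new pixels from the old-mask neighborhood mean, then take
      // their total mass back evenly from the whole new mask
      double mass = 0.0;
      for (size_t q = 0; q < added.size(); ++q) {
        const int idx = added[q];
        double a = 0.0;
        if (!masked_nb_mean(v, om, nr, nc, idx % nr, idx / nr, a)) a = 0.0;
        v[idx] = a;
        mass += a;
      }
      subtract_evenly(v, newpx, mass);
    } else if (!removed.empty()) {
      double mass = 0.0;
      for (size_t q = 0; q < removed.size(); ++q) {
        mass += v[removed[q]];
        v[removed[q]] = 0.0;
      }
      add_evenly(v, newpx, mass);
    }
    out[k] = f;
  }
  out.names() = as<CharacterVector>(fields.names());
  return out;
}

// ---------------------------------------------------------------------------
// Exported: full coupled simulation engine
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_cell(IntegerMatrix mask0, List fields0, List pairs,
                       NumericVector D, List morpho, double dt, double dx,
                       double noise_amp, int noise_scaling, int iters_per_event,
                       int save_every, int n_frames, double seed) {
  const int nr = mask0.nrow(), nc = mask0.ncol();
  const int ncomp = fields0.size();
  CharacterVector comp_names = fields0.names();

  // morpho parameters
  const double g = as<double>(morpho["g"]);
  const double kk = as<double>(morpho["k"]);
  const double aV = as<double>(morpho["alphaV"]);
  const double bV = as<double>(morpho["betaV"]);
  const double gV = as<double>(morpho["gammaV"]);
  const double aA = as<double>(morpho["alphaA"]);
  const double bA = as<double>(morpho["betaA"]);
  const double gA = as<double>(morpho["gammaA"]);
  const double Aact = as<double>(morpho["Aact"]);
  const int actin_mode = as<int>(morpho["actinMode"]); // 0 concentration, 1 rate
  const int actin_comp = as<int>(morpho["actinComp"]) - 1;
  const int min_pixels = as<int>(morpho["minPixels"]);

  std::vector<int> mask(mask0.begin(), mask0.end());
  std::vector<std::vector<double> > F(ncomp), G(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    NumericMatrix fk = fields0[k];
    F[k].assign(fk.begin(), fk.end());
    G[k] = F[k];
  }
  std::vector<PairSpec> ps = parse_pairs(pairs, D);
  XRng rng(static_cast<uint64_t>(seed));

  MaskIndex mi;
  build_index(mask.data(), nr, nc, mi);
  if (mi.px.empty()) stop("empty mask");
  int V = static_cast<int>(mi.px.size());
  const double V0 = as<double>(morpho["V0"]) > 0 ? as<double>(morpho["V0"])
                                                 : static_cast<double>(V);

  // actin input state
  std::vector<double> prev(F[actin_comp]); // snapshot one cycle ago
  std::vector<double> A(nr * nc, 0.0);     // actin input field
  const double delta_t = iters_per_event * dt;
  if (actin_mode == 0) A = F[actin_comp];

  // outputs
  IntegerVector masks_out(static_cast<R_xlen_t>(nr) * nc * n_frames);
  List fields_out(ncomp);
  std::vector<double *> fo(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    NumericVector arr(static_cast<R_xlen_t>(nr) * nc * n_frames);
    fields_out[k] = arr;
    fo[k] = REAL(fields_out[k]);
  }
  NumericVector vol_out(n_frames);

  std::vector<int> newpx, chg;
  for (int frame = 0; frame < n_frames; ++frame) {
    int iters_done = 0;
    while (iters_done < save_every) {
      // ---- one protrusion event, then one retraction event ----
      for (int ev = 0; ev < 2; ++ev) {
        const bool protrude = (ev == 0);
        const double wv = vol_factor(V, V0, aV, bV, gV, protrude);
        std::vector<int> accepted;
        if (wv > 0.0) {
          for (int c = 1; c < nc - 1; ++c) {
            for (int r = 1; r < nr - 1; ++r) {
              const int idx = r + c * nr;
              bool is_cand;
              double Aval = 0.0;
              if (protrude) {
                is_cand = !mask[idx] &&
                          (mask[idx - 1] || mask[idx + 1] || mask[idx - nr] ||
                           mask[idx + nr]);
                if (is_cand &&
                    !masked_nb_mean(A.data(), mask.data(), nr, nc, r, c, Aval))
                  is_cand = false;
              } else {
                is_cand = mask[idx] &&
                          (!mask[idx - 1] || !mask[idx + 1] ||
                           !mask[idx - nr] || !mask[idx + nr]);
                Aval = A[idx];
              }
              if (!is_cand) continue;
              const double wg =
                  geom_factor(mask.data(), nr, nc, r, c, protrude, g, kk);
              if (wg <= 0.0) continue;
              const double wa = act_factor(Aval, aA, bA, gA, Aact, protrude);
              const double p = wg * wv * wa;
              if (p > 0.0 && rng.unif() < p) accepted.push_back(idx);
            }
          }
        }
        for (int q = static_cast<int>(accepted.size()) - 1; q > 0; --q) {
          const int j = static_cast<int>(rng.unif() * (q + 1));
          std::swap(accepted[q], accepted[j]);
        }
        chg.clear();
        for (size_t q = 0; q < accepted.size(); ++q) {
          const int idx = accepted[q];
          const int r = idx % nr, c = idx / nr;
          if (protrude) {
            if (can_add_px(mask.data(), nr, nc, r, c)) {
              mask[idx] = 1; ++V; chg.push_back(idx);
            }
          } else {
            if (V > min_pixels && can_remove_px(mask.data(), nr, nc, r, c)) {
              mask[idx] = 0; --V; chg.push_back(idx);
            }
          }
        }
        if (!chg.empty()) {
          newpx.clear();
          for (int idx = 0; idx < nr * nc; ++idx)
            if (mask[idx]) newpx.push_back(idx);
          if (protrude) {
            for (int k = 0; k < ncomp; ++k) {
              double *v = F[k].data();
              double mass = 0.0;
              for (size_t q = 0; q < chg.size(); ++q) {
                const int idx = chg[q];
                // neighbor mean over the updated mask minus just-added pixels
                // is approximated by the committed mask (sequential init)
                double a = 0.0;
                masked_nb_mean(v, mask.data(), nr, nc, idx % nr, idx / nr, a);
                v[idx] = a;
                mass += a;
              }
              subtract_evenly(v, newpx, mass);
            }
            // new pixels must not spuriously contribute a rate spike
            for (size_t q = 0; q < chg.size(); ++q)
              prev[chg[q]] = F[actin_comp][chg[q]];
          } else {
            for (int k = 0; k < ncomp; ++k) {
              double *v = F[k].data();
              double mass = 0.0;
              for (size_t q = 0; q < chg.size(); ++q) {
                mass += v[chg[q]];
                v[chg[q]] = 0.0;
              }
              add_evenly(v, newpx, mass);
            }
          }
          for (int k = 0; k < ncomp; ++k) G[k] = F[k];
        }
      }
      // ---- threshold map refresh + RD steps ----
      build_index(mask.data(), nr, nc, mi);
      const int nit = std::min(iters_per_event, save_every - iters_done);
      rd_steps_core(F, G, mi, ps, dt, dx, noise_amp, noise_scaling, nit, rng);
      iters_done += nit;
      // ---- actin input update ----
      if (actin_mode == 0) {
        A = F[actin_comp];
      } else {
        const double *cur = F[actin_comp].data();
        for (int idx = 0; idx < nr * nc; ++idx)
          A[idx] = (cur[idx] - prev[idx]) / delta_t;
        prev = F[actin_comp];
      }
    }
    check_state(F, mi, comp_names);
    // ---- save frame ----
    const R_xlen_t off = static_cast<R_xlen_t>(frame) * nr * nc;
    for (int idx = 0; idx < nr * nc; ++idx) masks_out[off + idx] = mask[idx];
    for (int k = 0; k < ncomp; ++k)
      std::copy(F[k].begin(), F[k].end(), fo[k] + off);
    vol_out[frame] = V;
  }

  masks_out.attr("dim") = IntegerVector::create(nr, nc, n_frames);
  for (int k = 0; k < ncomp; ++k) {
    NumericVector arr = fields_out[k];
    arr.attr("dim") = IntegerVector::create(nr, nc, n_frames);
  }
  fields_out.names() = comp_names;
  return List::create(_["masks"] = masks_out, _["fields"] = fields_out,
                      _["volume"] = vol_out);
}
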
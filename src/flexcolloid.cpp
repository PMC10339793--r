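// Compiled kernels: superball geometry queries, configurational-volume
// Monte Carlo integration, and the Metropolis surface sampler.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: decorrelates small user seeds before feeding the generator
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// xoshiro256+ : deterministic across platforms, cheap
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) { seed = splitmix64(seed); s[i] = seed; }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

struct Superball {
  double n, sigma;
  Superball(double n_, double sigma_) : n(n_), sigma(sigma_) {}

  inline double f(const double* p) const {
    double s = 0.0;
    for (int i = 0; i < 3; ++i) s += std::pow(std::fabs(2.0 * p[i] / sigma), n);
    return s - 1.0;
  }
  // scale t such that t*p lies on the surface (p != 0)
  inline double radialScale(const double* p) const {
    double s = 0.0;
    for (int i = 0; i < 3; ++i) s += std::pow(std::fabs(2.0 * p[i] / sigma), n);
    return std::pow(s, -1.0 / n);
  }
  inline void grad(const double* p, double* g) const {
    for (int i = 0; i < 3; ++i) {
      double a = std::fabs(2.0 * p[i] / sigma);
      g[i] = (2.0 * n / sigma) * std::pow(a, n - 1.0) *
             ((p[i] > 0) - (p[i] < 0));
    }
  }
  inline void unitNormal(const double* p, double* nh) const {
    double g[3]; grad(p, g);
    double m = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
    for (int i = 0; i < 3; ++i) nh[i] = g[i] / m;
  }
  // Euclidean distance from exterior point p to the surface.
  // Starts from the (closed-form) radial projection and walks the foot
  // point tangentially toward p, reprojecting radially each step.
  double distance(const double* p, double tol, int maxit = 60) const {
    double t = radialScale(p);
    double x[3] = { t * p[0], t * p[1], t * p[2] };
    for (int it = 0; it < maxit; ++it) {
      double nh[3]; unitNormal(x, nh);
      double v[3] = { p[0]-x[0], p[1]-x[1], p[2]-x[2] };
      double vn = v[0]*nh[0] + v[1]*nh[1] + v[2]*nh[2];
      double tg[3] = { v[0]-vn*nh[0], v[1]-vn*nh[1], v[2]-vn*nh[2] };
      double tm = std::sqrt(tg[0]*tg[0] + tg[1]*tg[1] + tg[2]*tg[2]);
      if (tm < tol) break;
      double y[3] = { x[0]+0.8*tg[0], x[1]+0.8*tg[1], x[2]+0.8*tg[2] };
      double ty = radialScale(y);
      x[0] = ty*y[0]; x[1] = ty*y[1]; x[2] = ty*y[2];
    }
    double d[3] = { p[0]-x[0], p[1]-x[1], p[2]-x[2] };
    return std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  }
  // Is exterior point p within distance l of the surface?  Uses cheap
  // upper (radial chord) and lower (tangent-plane) bounds; refines only
  // in the undecided band.
  bool inExteriorShell(const double* p, double l, double tol) const {
    if (f(p) <= 0.0) return false;
    double t = radialScale(p);
    double q[3] = { t*p[0], t*p[1], t*p[2] };
    double d[3] = { p[0]-q[0], p[1]-q[1], p[2]-q[2] };
    double ub = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (ub <= l) return true;
    double nh[3]; unitNormal(q, nh);
    double lb = d[0]*nh[0] + d[1]*nh[1] + d[2]*nh[2];
    if (lb > l) return false;
    return distance(p, tol) <= l;
  }
};

inline void orthoBasis(const double* a, double* e1, double* e2) {
  // a is unit; build any orthonormal completion
  if (std::fabs(a[0]) < 0.9) { e1[0] = 0; e1[1] = -a[2]; e1[2] = a[1]; }
  else { e1[0] = -a[2]; e1[1] = 0; e1[2] = a[0]; }
  double m = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  e1[0]/=m; e1[1]/=m; e1[2]/=m;
  e2[0] = a[1]*e1[2] - a[2]*e1[1];
  e2[1] = a[2]*e1[0] - a[0]*e1[2];
  e2[2] = a[0]*e1[1] - a[1]*e1[0];
}

} // namespace

// [[Rcpp::export(name = ".cppDistanceToSuperball")]]
NumericVector cppDistanceToSuperball(NumericMatrix points, double n,
                                     double sigma, double tol) {
  Superball sb(n, sigma);
  int m = points.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    out[i] = sb.distance(p, tol);
  }
  return out;
}

// [[Rcpp::export(name = ".cppShellVolumeSuperball")]]
NumericVector cppShellVolumeSuperball(double n, double sigma, double l,
                                      int nSamples, double seed) {
  Superball sb(n, sigma);
  Rng rng(static_cast<uint64_t>(seed));
  double half = sigma / 2.0 + l;
  double boxVol = 8.0 * half * half * half;
  double tol = l / 100.0;
  long k = 0;
  for (int i = 0; i < nSamples; ++i) {
    double p[3] = { (2.0*rng.unif()-1.0)*half,
                    (2.0*rng.unif()-1.0)*half,
                    (2.0*rng.unif()-1.0)*half };
    if (sb.inExteriorShell(p, l, tol)) ++k;
  }
  double p = static_cast<double>(k) / nSamples;
  double vol = boxVol * p;
  double se = boxVol * std::sqrt(p * (1.0 - p) / nSamples);
  return NumericVector::create(_["volume"] = vol, _["stderr"] = se,
                               _["n_accept"] = static_cast<double>(k));
}

// Overlap of the sphere's exterior shell (radius r, thickness l, centred at
// site + (r+l)*normal) with the superball's exterior shell.  Sampling region
// is the spherical-cap slice of the sphere shell facing the site
// (cos >= r/(r+l) toward -normal), which provably contains the overlap.
// [[Rcpp::export(name = ".cppOverlapVolumes")]]
NumericMatrix cppOverlapVolumes(NumericMatrix sites, NumericMatrix normals,
                                double alpha, double l, double n, double sigma,
                                int nSamples, double seed) {
  Superball sb(n, sigma);
  int m = sites.nrow();
  double r = alpha * sigma / 2.0;
  double rl = r + l;
  double cmin = r / rl;
  double shellVol = (4.0 * M_PI / 3.0) * (rl*rl*rl - r*r*r);
  double regionVol = shellVol * (1.0 - cmin) / 2.0;
  double tol = l / 100.0;
  double r3 = r*r*r, rl3 = rl*rl*rl;
  NumericMatrix out(m, 3);
  colnames(out) = CharacterVector::create("volume", "stderr", "n_accept");
  for (int i = 0; i < m; ++i) {
    double a[3] = { -normals(i,0), -normals(i,1), -normals(i,2) };
    double C[3] = { sites(i,0) + rl*normals(i,0),
                    sites(i,1) + rl*normals(i,1),
                    sites(i,2) + rl*normals(i,2) };
    double e1[3], e2[3];
    orthoBasis(a, e1, e2);
    Rng rng(splitmix64(static_cast<uint64_t>(seed)) ^
            splitmix64(static_cast<uint64_t>(i) + 0x51ed2701ULL));
    long k = 0;
    for (int s = 0; s < nSamples; ++s) {
      double rho = std::cbrt(r3 + rng.unif() * (rl3 - r3));
      double c = cmin + rng.unif() * (1.0 - cmin);
      double st = std::sqrt(std::max(0.0, 1.0 - c*c));
      double phi = 2.0 * M_PI * rng.unif();
      double cp = std::cos(phi), spn = std::sin(phi);
      double p[3];
      for (int d = 0; d < 3; ++d)
        p[d] = C[d] + rho * (c*a[d] + st*(cp*e1[d] + spn*e2[d]));
      if (sb.inExteriorShell(p, l, tol)) ++k;
    }
    double pf = static_cast<double>(k) / nSamples;
    out(i,0) = regionVol * pf;
    out(i,1) = regionVol * std::sqrt(pf * (1.0 - pf) / nSamples);
    out(i,2) = static_cast<double>(k);
  }
  return out;
}

// Metropolis dynamics of nSpheres hopping on the site graph.
// adjIdx/adjPtr: CSR adjacency (0-based); energy: per-site beta*F;
// centers: per-site sphere-centre coordinates for the current alpha;
// excluded: quasi-2D mask; sigmaS: hard-sphere centre-centre cutoff.
// One MC step = one attempted move per sphere.  Acceptance
// min(1, (k_i/k_j) exp(-(E_j - E_i))) with k the neighbour count.
// [[Rcpp::export(name = ".cppRunSurfaceMC")]]
List cppRunSurfaceMC(IntegerVector adjIdx, IntegerVector adjPtr,
                     NumericVector energy, NumericMatrix centers,
                     LogicalVector excluded, IntegerVector start0,
                     double sigmaS, double nSweepsD, int recordEvery,
                     int equilSweeps, double seed) {
  long nSweeps = static_cast<long>(nSweepsD);
  int ns = start0.size();
  std::vector<int> pos(start0.begin(), start0.end());
  Rng rng(static_cast<uint64_t>(seed));
  double sig2 = sigmaS * sigmaS;
  long nRec = nSweeps / recordEvery + 1;
  IntegerMatrix rec(nRec, ns);
  long accepted = 0, attempted = 0;

  auto overlaps = [&](int sphere, int site) {
    for (int m = 0; m < ns; ++m) {
      if (m == sphere) continue;
      double dx = centers(site,0) - centers(pos[m],0);
      double dy = centers(site,1) - centers(pos[m],1);
      double dz = centers(site,2) - centers(pos[m],2);
      if (dx*dx + dy*dy + dz*dz < sig2) return true;
    }
    return false;
  };
  auto sweep = [&](bool count) {
    for (int s = 0; s < ns; ++s) {
      int i = pos[s];
      int ki = adjPtr[i+1] - adjPtr[i];
      int j = adjIdx[adjPtr[i] + static_cast<int>(rng.unif() * ki)];
      if (count) ++attempted;
      if (excluded[j]) continue;
      if (!std::isfinite(energy[j])) continue;
      if (ns > 1 && overlaps(s, j)) continue;
      int kj = adjPtr[j+1] - adjPtr[j];
      double dE = energy[j] - energy[i];
      double acc = (static_cast<double>(ki) / kj) * std::exp(-dE);
      if (acc >= 1.0 || rng.unif() < acc) {
        pos[s] = j;
        if (count) ++accepted;
      }
    }
  };

  for (long t = 0; t < equilSweeps; ++t) sweep(false);
  long ridx = 0;
  for (int s = 0; s < ns; ++s) rec(ridx, s) = pos[s] + 1;
  ++ridx;
  for (long t = 1; t <= nSweeps; ++t) {
    sweep(true);
    if (t % recordEvery == 0) {
      for (int s = 0; s < ns; ++s) rec(ridx, s) = pos[s] + 1;
      ++ridx;
    }
  }
  double accRate = attempted > 0 ?
    static_cast<double>(accepted) / attempted : NA_REAL;
  return List::create(_["sites"] = rec, _["acceptance_rate"] = accRate);
}
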
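// Monte Carlo core for the second-virial stage: site-site pair energies
// (hard core + screened Coulomb), conformationally averaged Mayer
// sampling, the orientation-binned virial kernel, the twist elastic
// modulus / chiral strength integrals, and the fixed-angle chiral PMF
// scan. All randomness comes from R's RNG so results are reproducible
// under set.seed().
//
// Particles are passed in body coordinates: rows are sites (nm), the body
// x-axis is the molecular long axis u, and the origin is the backbone
// center of mass. Each body carries a two-level bounding hierarchy
// (a capsule around the whole filament, then bounding spheres over short
// contour segments) so that the O(n1*n2) site loop only runs over segment
// pairs that can actually interact. A "spherocylinder" mode replaces the
// site model by an exact hard spherocylinder (segment of length L,
// diameter D) used as the analytically solvable reference particle.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Model {
  double d0;      // hard-core site diameter (nm)
  double pref;    // Bjerrum length * q_eff^2 (kT nm)
  double lambda;  // Debye length (nm)
  double cutoff;  // electrostatic cutoff (nm)
};

// body-frame particle with segment hierarchy (flattened copies)
struct BodyC {
  std::vector<double> sites;   // 3n
  std::vector<double> segc;    // 3k segment centers
  std::vector<double> segr;    // k segment radii
  std::vector<int> s0, s1;     // site index range per segment [s0, s1)
  double hl, rp;               // capsule half-length (x) and radial extent
  int n, k;
};

static inline void quat_rotation(double *R) {
  // uniform rotation from a normalized Gaussian quaternion (R RNG);
  // column-major, R[col*3 + row]
  double q0 = norm_rand(), q1 = norm_rand(), q2 = norm_rand(), q3 = norm_rand();
  double n = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
  q0 /= n; q1 /= n; q2 /= n; q3 /= n;
  R[0] = 1 - 2 * (q2 * q2 + q3 * q3);
  R[1] = 2 * (q1 * q2 + q0 * q3);
  R[2] = 2 * (q1 * q3 - q0 * q2);
  R[3] = 2 * (q1 * q2 - q0 * q3);
  R[4] = 1 - 2 * (q1 * q1 + q3 * q3);
  R[5] = 2 * (q2 * q3 + q0 * q1);
  R[6] = 2 * (q1 * q3 + q0 * q2);
  R[7] = 2 * (q2 * q3 - q0 * q1);
  R[8] = 1 - 2 * (q1 * q1 + q2 * q2);
}

static inline void ball_point(double rmax, double *p) {
  double x, y, z;
  do {
    x = 2 * unif_rand() - 1;
    y = 2 * unif_rand() - 1;
    z = 2 * unif_rand() - 1;
  } while (x * x + y * y + z * z > 1);
  p[0] = x * rmax; p[1] = y * rmax; p[2] = z * rmax;
}

static inline void apply_rot(const double *R, const double *v, const double *sh,
                             double *out) {
  out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2] + sh[0];
  out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2] + sh[1];
  out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2] + sh[2];
}

// minimum distance between segment c1 +/- (L1/2) u1 and segment
// c2 +/- (L2/2) u2; exact closest-point clamp (Ericson)
static double segment_distance(const double *c1, const double *u1, double L1,
                               const double *c2, const double *u2, double L2) {
  double p1[3], d1[3], p2[3], d2[3];
  for (int k = 0; k < 3; ++k) {
    p1[k] = c1[k] - 0.5 * L1 * u1[k]; d1[k] = L1 * u1[k];
    p2[k] = c2[k] - 0.5 * L2 * u2[k]; d2[k] = L2 * u2[k];
  }
  double r[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
  double a = d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2];
  double e = d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2];
  double f = d2[0] * r[0] + d2[1] * r[1] + d2[2] * r[2];
  double c = d1[0] * r[0] + d1[1] * r[1] + d1[2] * r[2];
  double b = d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2];
  double denom = a * e - b * b;
  double s = 0.0, t = 0.0;
  if (denom > 1e-14 * a * e) s = (b * f - c * e) / denom;
  if (s < 0) s = 0; else if (s > 1) s = 1;
  t = (b * s + f) / e;
  if (t < 0) { t = 0; s = (a > 0) ? -c / a : 0; }
  else if (t > 1) { t = 1; s = (a > 0) ? (b - c) / a : 0; }
  if (s < 0) s = 0; else if (s > 1) s = 1;
  double w[3];
  for (int k = 0; k < 3; ++k) w[k] = r[k] + s * d1[k] - t * d2[k];
  return std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// scratch buffers reused across samples
struct Scratch {
  std::vector<double> cA, cB;      // transformed segment centers
  std::vector<double> sA, sB;      // transformed sites (lazy, per segment)
  std::vector<char> doneA, doneB;  // segment transform flags
  std::vector<int> pairI, pairJ;
};

// site-site energy with segment-hierarchy culling; +Inf on hard overlap
static double body_pair_energy(const BodyC &A, const BodyC &B,
                               const double *R1, const double *R2,
                               const double *r12, const Model &m,
                               Scratch &sc) {
  double u1[3] = {R1[0], R1[1], R1[2]};
  double u2[3] = {R2[0], R2[1], R2[2]};
  double c0[3] = {0, 0, 0};
  double reach = m.cutoff > m.d0 ? m.cutoff : m.d0;
  // level 0: bounding capsules around the long axes
  double axdist = segment_distance(c0, u1, 2 * A.hl, r12, u2, 2 * B.hl);
  if (axdist > A.rp + B.rp + reach) return 0.0;
  // level 1: segment bounding spheres
  sc.cA.resize(3 * A.k); sc.cB.resize(3 * B.k);
  double zero[3] = {0, 0, 0};
  for (int i = 0; i < A.k; ++i)
    apply_rot(R1, &A.segc[3 * i], zero, &sc.cA[3 * i]);
  for (int j = 0; j < B.k; ++j)
    apply_rot(R2, &B.segc[3 * j], r12, &sc.cB[3 * j]);
  sc.pairI.clear(); sc.pairJ.clear();
  for (int i = 0; i < A.k; ++i) {
    double ax = sc.cA[3 * i], ay = sc.cA[3 * i + 1], az = sc.cA[3 * i + 2];
    for (int j = 0; j < B.k; ++j) {
      double dx = ax - sc.cB[3 * j], dy = ay - sc.cB[3 * j + 1],
             dz = az - sc.cB[3 * j + 2];
      double lim = A.segr[i] + B.segr[j] + reach;
      if (dx * dx + dy * dy + dz * dz < lim * lim) {
        sc.pairI.push_back(i); sc.pairJ.push_back(j);
      }
    }
  }
  if (sc.pairI.empty()) return 0.0;
  // level 2: site-site over surviving segment pairs (lazy transforms)
  sc.sA.resize(3 * A.n); sc.sB.resize(3 * B.n);
  sc.doneA.assign(A.k, 0); sc.doneB.assign(B.k, 0);
  double e = 0.0;
  double cut2 = m.cutoff * m.cutoff, d02 = m.d0 * m.d0;
  for (size_t p = 0; p < sc.pairI.size(); ++p) {
    int i = sc.pairI[p], j = sc.pairJ[p];
    if (!sc.doneA[i]) {
      for (int s = A.s0[i]; s < A.s1[i]; ++s)
        apply_rot(R1, &A.sites[3 * s], zero, &sc.sA[3 * s]);
      sc.doneA[i] = 1;
    }
    if (!sc.doneB[j]) {
      for (int s = B.s0[j]; s < B.s1[j]; ++s)
        apply_rot(R2, &B.sites[3 * s], r12, &sc.sB[3 * s]);
      sc.doneB[j] = 1;
    }
    for (int a = A.s0[i]; a < A.s1[i]; ++a) {
      double ax = sc.sA[3 * a], ay = sc.sA[3 * a + 1], az = sc.sA[3 * a + 2];
      for (int b = B.s0[j]; b < B.s1[j]; ++b) {
        double dx = ax - sc.sB[3 * b], dy = ay - sc.sB[3 * b + 1],
               dz = az - sc.sB[3 * b + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < d02) return R_PosInf;
        if (r2 < cut2 && m.pref > 0) {
          double r = std::sqrt(r2);
          e += m.pref * std::exp(-r / m.lambda) / r;
        }
      }
    }
  }
  return e;
}

// unpack the R-side body list (list of list(sites, segc, segr, s0, s1,
// hl, rp)) into flat C++ structs once per entry point
static void unpack_bodies(const List &bodies, std::vector<BodyC> &out) {
  int nc = bodies.size();
  out.resize(nc);
  for (int c = 0; c < nc; ++c) {
    List b = bodies[c];
    NumericMatrix S = b["sites"], C = b["segc"];
    NumericVector r = b["segr"];
    IntegerVector s0 = b["s0"], s1 = b["s1"];
    BodyC &bc = out[c];
    bc.n = S.nrow(); bc.k = C.nrow();
    bc.sites.resize(3 * bc.n);
    for (int i = 0; i < bc.n; ++i)
      for (int d = 0; d < 3; ++d) bc.sites[3 * i + d] = S(i, d);
    bc.segc.resize(3 * bc.k);
    for (int i = 0; i < bc.k; ++i)
      for (int d = 0; d < 3; ++d) bc.segc[3 * i + d] = C(i, d);
    bc.segr.assign(r.begin(), r.end());
    bc.s0.assign(s0.begin(), s0.end());
    bc.s1.assign(s1.begin(), s1.end());
    bc.hl = as<double>(b["hl"]);
    bc.rp = as<double>(b["rp"]);
  }
}

static inline double sample_energy(bool sph_mode, double scL, double scD,
                                   const std::vector<BodyC> &bodies, int ia,
                                   int ib, const double *R1, const double *R2,
                                   const double *r12, const Model &m,
                                   Scratch &sc) {
  if (sph_mode) {
    double u1[3] = {R1[0], R1[1], R1[2]};
    double u2[3] = {R2[0], R2[1], R2[2]};
    double c0[3] = {0, 0, 0};
    double dist = segment_distance(c0, u1, scL, r12, u2, scL);
    return dist < scD ? R_PosInf : 0.0;
  }
  return body_pair_energy(bodies[ia], bodies[ib], R1, R2, r12, m, sc);
}

// [[Rcpp::export]]
double cpp_pair_energy(List bodyA, List bodyB, NumericVector r12,
                       NumericMatrix R1, NumericMatrix R2, double d0,
                       double pref, double lambda, double cutoff) {
  Model m = {d0, pref, lambda, cutoff};
  List bl = List::create(bodyA, bodyB);
  std::vector<BodyC> bodies;
  unpack_bodies(bl, bodies);
  double Rm1[9], Rm2[9], rr[3] = {r12[0], r12[1], r12[2]};
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) {
      Rm1[3 * c + r] = R1(r, c);
      Rm2[3 * c + r] = R2(r, c);
    }
  Scratch sc;
  return body_pair_energy(bodies[0], bodies[1], Rm1, Rm2, rr, m, sc);
}

// [[Rcpp::export]]
List cpp_mayer_average(List bodies, NumericVector r12, NumericMatrix R1,
                       NumericMatrix R2, double d0, double pref,
                       double lambda, double cutoff, int n_samples,
                       bool sph_mode, double scL, double scD) {
  Model m = {d0, pref, lambda, cutoff};
  std::vector<BodyC> bd;
  if (!sph_mode) unpack_bodies(bodies, bd);
  int nc = sph_mode ? 1 : (int)bd.size();
  double Rm1[9], Rm2[9], rr[3] = {r12[0], r12[1], r12[2]};
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) {
      Rm1[3 * c + r] = R1(r, c);
      Rm2[3 * c + r] = R2(r, c);
    }
  Scratch sc;
  double s = 0, s2 = 0;
  for (int it = 0; it < n_samples; ++it) {
    int ia = (int)(unif_rand() * nc); if (ia == nc) ia = nc - 1;
    int ib = (int)(unif_rand() * nc); if (ib == nc) ib = nc - 1;
    double e = sample_energy(sph_mode, scL, scD, bd, ia, ib, Rm1, Rm2, rr,
                             m, sc);
    double f = std::isinf(e) ? -1.0 : std::expm1(-e);
    s += f; s2 += f * f;
  }
  double mean = s / n_samples;
  double var = s2 / n_samples - mean * mean;
  return List::create(_["mean"] = mean,
                      _["se"] = std::sqrt(std::max(var, 0.0) / n_samples));
}

// [[Rcpp::export]]
List cpp_virial_kernel(List bodies, double d0, double pref, double lambda,
                       double cutoff, int n_bins, double n_samples,
                       double rmax, bool sph_mode, double scL, double scD) {
  Model m = {d0, pref, lambda, cutoff};
  std::vector<BodyC> bd;
  if (!sph_mode) unpack_bodies(bodies, bd);
  int nc = sph_mode ? 1 : (int)bd.size();
  NumericMatrix S(n_bins, n_bins), S2(n_bins, n_bins), CNT(n_bins, n_bins);
  double R1[9], R2[9], r12[3];
  Scratch sc;
  double vol = 4.0 / 3.0 * M_PI * rmax * rmax * rmax;
  long long N = (long long)n_samples;
  for (long long it = 0; it < N; ++it) {
    quat_rotation(R1);
    quat_rotation(R2);
    ball_point(rmax, r12);
    int ia = (int)(unif_rand() * nc); if (ia == nc) ia = nc - 1;
    int ib = (int)(unif_rand() * nc); if (ib == nc) ib = nc - 1;
    double x1 = R1[0], x2 = R2[0]; // cos theta = u . e_x
    int a = (int)((x1 + 1) / 2 * n_bins); if (a == n_bins) a = n_bins - 1;
    int b = (int)((x2 + 1) / 2 * n_bins); if (b == n_bins) b = n_bins - 1;
    double e = sample_energy(sph_mode, scL, scD, bd, ia, ib, R1, R2, r12,
                             m, sc);
    double f = std::isinf(e) ? -1.0 : std::expm1(-e);
    S(a, b) += f; S2(a, b) += f * f; CNT(a, b) += 1;
  }
  NumericMatrix K(n_bins, n_bins), SE(n_bins, n_bins);
  for (int a = 0; a < n_bins; ++a)
    for (int b = 0; b < n_bins; ++b) {
      double cnt = CNT(a, b);
      if (cnt > 0) {
        double mean = S(a, b) / cnt;
        double var = S2(a, b) / cnt - mean * mean;
        K(a, b) = vol * mean;
        SE(a, b) = vol * std::sqrt(std::max(var, 0.0) / cnt);
      } else {
        K(a, b) = NA_REAL; SE(a, b) = NA_REAL;
      }
    }
  return List::create(_["kappa"] = K, _["se"] = SE, _["count"] = CNT,
                      _["volume"] = vol);
}

static inline double lin_interp(const NumericVector &y, double x, int ng) {
  double t = (x + 1.0) / 2.0 * (ng - 1);
  int i = (int)t;
  if (i >= ng - 1) return y[ng - 1];
  if (i < 0) return y[0];
  double f = t - i;
  return y[i] * (1 - f) + y[i + 1] * f;
}

// build a rotation whose first column is the axis direction given by
// cos(theta) = x and azimuth phi, with spin chi about that axis
static void axis_rotation(double x, double phi, double chi, double *R) {
  double s = std::sqrt(std::max(1.0 - x * x, 0.0));
  double d[3] = {x, s * std::cos(phi), s * std::sin(phi)};
  double ref[3] = {0, 0, 1};
  if (std::fabs(d[2]) > 0.9) { ref[1] = 1; ref[2] = 0; }
  double b[3] = {d[1] * ref[2] - d[2] * ref[1],
                 d[2] * ref[0] - d[0] * ref[2],
                 d[0] * ref[1] - d[1] * ref[0]};
  double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  for (int k = 0; k < 3; ++k) b[k] /= nb;
  double c[3] = {d[1] * b[2] - d[2] * b[1],
                 d[2] * b[0] - d[0] * b[2],
                 d[0] * b[1] - d[1] * b[0]};
  double cc = std::cos(chi), scn = std::sin(chi);
  R[0] = d[0]; R[1] = d[1]; R[2] = d[2];
  R[3] = cc * b[0] + scn * c[0];
  R[4] = cc * b[1] + scn * c[1];
  R[5] = cc * b[2] + scn * c[2];
  R[6] = -scn * b[0] + cc * c[0];
  R[7] = -scn * b[1] + cc * c[1];
  R[8] = -scn * b[2] + cc * c[2];
}

// Elastic-constant integrals with orientations importance-sampled from the
// converged distribution psi: invcdf maps a uniform deviate to cos(theta),
// gprime tabulates d(ln psi)/d(cos theta) on a uniform grid over [-1, 1].
// Estimators (per sample, r12 uniform in the ball of volume vol):
//   I_k2 = E[f gp(x1) gp(x2) rz^2 u1y u2y],  beta K2 = (rho^2/2) vol I_k2
//   I_kt = E[f gp(x2) rz u2y],               beta kt = (rho^2/2) vol I_kt
// With antithetic = true each sample is also evaluated against the
// mirror-image bodies (bodies_m) at the same random configuration; the
// pseudoscalar kt keeps the antisymmetric half (f - f_m)/2 and K2 the
// symmetric half, cancelling the achiral noise from the chiral strength.
// [[Rcpp::export]]
List cpp_elastic_mc(List bodies, List bodies_m, bool antithetic, double d0,
                    double pref, double lambda, double cutoff,
                    NumericVector invcdf, NumericVector gprime,
                    double n_samples, int n_batches, double rmax,
                    bool sph_mode, double scL, double scD) {
  Model m = {d0, pref, lambda, cutoff};
  std::vector<BodyC> bd, bdm;
  if (!sph_mode) {
    unpack_bodies(bodies, bd);
    if (antithetic) unpack_bodies(bodies_m, bdm);
  }
  int nc = sph_mode ? 1 : (int)bd.size();
  int ng = gprime.size();
  int nq = invcdf.size();
  double R1[9], R2[9], r12[3];
  Scratch sc;
  double vol = 4.0 / 3.0 * M_PI * rmax * rmax * rmax;
  long long N = (long long)n_samples;
  long long per = N / n_batches;
  NumericVector bk2(n_batches), bkt(n_batches);
  double sA = 0, sB = 0;
  for (int b = 0; b < n_batches; ++b) {
    double a_acc = 0, b_acc = 0;
    for (long long it = 0; it < per; ++it) {
      double q1 = unif_rand() * (nq - 1), q2 = unif_rand() * (nq - 1);
      int i1 = (int)q1, i2 = (int)q2;
      if (i1 >= nq - 1) i1 = nq - 2;
      if (i2 >= nq - 1) i2 = nq - 2;
      double x1 = invcdf[i1] + (q1 - i1) * (invcdf[i1 + 1] - invcdf[i1]);
      double x2 = invcdf[i2] + (q2 - i2) * (invcdf[i2 + 1] - invcdf[i2]);
      axis_rotation(x1, 2 * M_PI * unif_rand(), 2 * M_PI * unif_rand(), R1);
      axis_rotation(x2, 2 * M_PI * unif_rand(), 2 * M_PI * unif_rand(), R2);
      ball_point(rmax, r12);
      int ia = (int)(unif_rand() * nc); if (ia == nc) ia = nc - 1;
      int ib = (int)(unif_rand() * nc); if (ib == nc) ib = nc - 1;
      double e = sample_energy(sph_mode, scL, scD, bd, ia, ib, R1, R2, r12,
                               m, sc);
      double f = std::isinf(e) ? -1.0 : std::expm1(-e);
      double fs = f, fa = f;
      if (antithetic && !sph_mode) {
        double em = sample_energy(sph_mode, scL, scD, bdm, ia, ib, R1, R2,
                                  r12, m, sc);
        double fm = std::isinf(em) ? -1.0 : std::expm1(-em);
        fs = 0.5 * (f + fm);
        fa = 0.5 * (f - fm);
      }
      if (fs != 0.0 || fa != 0.0) {
        double u1y = R1[1], u2y = R2[1];     // u_i . e_y
        double rz = r12[2];
        double gp1 = lin_interp(gprime, x1, ng);
        double gp2 = lin_interp(gprime, x2, ng);
        a_acc += fs * gp1 * gp2 * rz * rz * u1y * u2y;
        b_acc += fa * gp2 * rz * u2y;
      }
    }
    bk2[b] = vol * a_acc / per;
    bkt[b] = vol * b_acc / per;
    sA += bk2[b]; sB += bkt[b];
  }
  double mA = sA / n_batches, mB = sB / n_batches;
  double vA = 0, vB = 0;
  for (int b = 0; b < n_batches; ++b) {
    vA += (bk2[b] - mA) * (bk2[b] - mA);
    vB += (bkt[b] - mB) * (bkt[b] - mB);
  }
  vA /= (n_batches - 1.0) * n_batches;
  vB /= (n_batches - 1.0) * n_batches;
  return List::create(_["I_k2"] = mA, _["I_k2_se"] = std::sqrt(vA),
                      _["I_kt"] = mB, _["I_kt_se"] = std::sqrt(vB),
                      _["volume"] = vol, _["n"] = (double)(per * n_batches));
}

// [[Rcpp::export]]
List cpp_pmf_gamma(List bodies, double d0, double pref, double lambda,
                   double cutoff, double gamma, double dmax,
                   double n_samples, bool sph_mode, double scL, double scD) {
  Model m = {d0, pref, lambda, cutoff};
  std::vector<BodyC> bd;
  if (!sph_mode) unpack_bodies(bodies, bd);
  int nc = sph_mode ? 1 : (int)bd.size();
  Scratch sc;
  double s = 0, s2 = 0;
  long long N = (long long)n_samples;
  for (long long it = 0; it < N; ++it) {
    double chi1 = 2 * M_PI * unif_rand(), chi2 = 2 * M_PI * unif_rand();
    double dz = dmax * unif_rand();
    double r12[3] = {0, 0, dz};
    // R_i = Rz(+/- gamma/2) * Rx(chi_i); body long axis is e_x
    double halves[2] = {-gamma / 2, gamma / 2};
    double R[2][9];
    double chis[2] = {chi1, chi2};
    for (int p = 0; p < 2; ++p) {
      double cg = std::cos(halves[p]), sg = std::sin(halves[p]);
      double cc = std::cos(chis[p]), scn = std::sin(chis[p]);
      R[p][0] = cg;         R[p][1] = sg;         R[p][2] = 0;
      R[p][3] = -sg * cc;   R[p][4] = cg * cc;    R[p][5] = scn;
      R[p][6] = sg * scn;   R[p][7] = -cg * scn;  R[p][8] = cc;
    }
    int ia = (int)(unif_rand() * nc); if (ia == nc) ia = nc - 1;
    int ib = (int)(unif_rand() * nc); if (ib == nc) ib = nc - 1;
    double e = sample_energy(sph_mode, scL, scD, bd, ia, ib, R[0], R[1],
                             r12, m, sc);
    double w = std::isinf(e) ? 0.0 : std::exp(-e);
    s += w; s2 += w * w;
  }
  double mean = s / N;
  double var = s2 / N - mean * mean;
  return List::create(_["mean_weight"] = mean,
                      _["se"] = std::sqrt(std::max(var, 0.0) / N));
}
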
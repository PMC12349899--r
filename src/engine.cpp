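// Brownian-dynamics engine for bead-spring actomyosin systems.
//
// Internal units: length nm, force pN, time s, energy pN nm.
// The R wrappers convert from the user-facing SI parameter set.
//
// Geometry conventions:
//  - filament vertex order: index 0 = barbed end; segment tangent a->b points
//    barbed -> pointed; motor arms walk toward the barbed end (-tangent).
//  - binding sites sit at fixed material fractions site/nsites along a
//    segment (7-nm spacing at rest length 140 nm).
//  - periodic axes use minimum-image displacements everywhere.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Domain {
  double box[3];
  int kind[3]; // 0 open, 1 periodic, 2 repulsive wall
  // minimum image; wrapped coordinates keep |d| < L, so two
  // comparisons replace a division+round (falls back for larger |d|)
  inline double mi(double d, int ax) const {
    if (kind[ax] == 1) {
      const double L = box[ax];
      if (d > 0.5 * L) {
        d -= L;
        if (d > 0.5 * L) d -= L * std::round(d / L);
      } else if (d < -0.5 * L) {
        d += L;
        if (d < -0.5 * L) d -= L * std::round(d / L);
      }
    }
    return d;
  }
};

// Fast internal RNG (xoshiro256++), seeded from R's RNG stream at run
// start so identical R seeds give identical trajectories, with Marsaglia
// polar normal deviates. State is call-local.
struct Rng {
  uint64_t s[4];
  bool has;
  double spare;
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Rng() : has(false), spare(0.0) {
    // derive a 64-bit seed from R's uniform stream (determinism contract)
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0);
    seed = (seed << 32) ^ (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double operator()() {
    if (has) { has = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has = true;
    return u * f;
  }
};

struct System {
  int N;
  std::vector<double> px, py, pz;
  std::vector<double> zeta;     // pN s / nm
  std::vector<int> vtype;       // 0 actin, 1 motor backbone, 2 ACP center
  std::vector<int> clamped;

  // bonds (vertex-vertex springs)
  std::vector<int> b_i, b_j, b_cat; // cat: 0 actin, 1 backbone
  std::vector<double> b_r0, b_ks;

  // bending triples (i,j,k consecutive); theta between (j-i) and (k-j)
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_kb;

  // global segment table
  std::vector<int> s_a, s_b, s_fil, s_local;
  std::vector<int> fil_nseg; // per filament

  // occupancy: nseg x nsites, 0 free, 1 ACP, >=2 arm id + 2
  std::vector<int> occ;
  int nsites;

  // motor arms
  std::vector<int> m_anchor, m_wfrom, m_wto, m_sib;
  std::vector<int> m_bound, m_seg, m_site;

  // ACP attachments (center vertex + two (seg,site) anchors)
  std::vector<int> c_center, c_seg1, c_site1, c_seg2, c_site2;

  Domain dom;

  // parameters (engine units)
  double dt, kBT;
  double ks_acp, r0_acp, kb_acp;
  double km2, km3, r0m2;
  double kr, rc, wallk;
  double site_sp, seg_r0;
  double kbind, kw0, Fstall, ku0, kumin_frac, Fcat, capture;
  int kin_every, nlist_every;
  double skin, max_disp;
};

inline void minImagePoint(const System& S, double ax, double ay, double az,
                          double bx, double by, double bz,
                          double& ox, double& oy, double& oz) {
  ox = ax + S.dom.mi(bx - ax, 0);
  oy = ay + S.dom.mi(by - ay, 1);
  oz = az + S.dom.mi(bz - az, 2);
}

// position of a binding site, unwrapped relative to a reference point (rx,ry,rz)
inline void sitePos(const System& S, int seg, int site,
                    double rx, double ry, double rz,
                    double& sx, double& sy, double& sz,
                    double& tx, double& ty, double& tz, double& frac,
                    double* seg_len = 0) {
  const int a = S.s_a[seg], b = S.s_b[seg];
  double ax, ay, az, bx, by, bz;
  minImagePoint(S, rx, ry, rz, S.px[a], S.py[a], S.pz[a], ax, ay, az);
  // b relative to a (segment never spans more than half the box)
  bx = ax + S.dom.mi(S.px[b] - S.px[a], 0);
  by = ay + S.dom.mi(S.py[b] - S.py[a], 1);
  bz = az + S.dom.mi(S.pz[b] - S.pz[a], 2);
  frac = (double)site / (double)S.nsites;
  sx = ax + frac * (bx - ax);
  sy = ay + frac * (by - ay);
  sz = az + frac * (bz - az);
  tx = bx - ax; ty = by - ay; tz = bz - az;
  const double n = std::sqrt(tx * tx + ty * ty + tz * tz);
  if (n > 0) { tx /= n; ty /= n; tz /= n; }
  if (seg_len) *seg_len = n;
}

struct Forces {
  std::vector<double> fx, fy, fz;
  void init(int N) { fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0); }
  inline void add(int i, double x, double y, double z) {
    fx[i] += x; fy[i] += y; fz[i] += z;
  }
};

// add a force applied at fraction `frac` of a segment onto its endpoints
inline void addToSegment(Forces& F, const System& S, int seg, double frac,
                         double gx, double gy, double gz) {
  const int a = S.s_a[seg], b = S.s_b[seg];
  F.add(a, (1.0 - frac) * gx, (1.0 - frac) * gy, (1.0 - frac) * gz);
  F.add(b, frac * gx, frac * gy, frac * gz);
}

// ---------- stretch ----------
void stretchForces(const System& S, Forces& F, double* U) {
  const size_t nb = S.b_i.size();
  for (size_t m = 0; m < nb; ++m) {
    const int i = S.b_i[m], j = S.b_j[m];
    double dx = S.dom.mi(S.px[j] - S.px[i], 0);
    double dy = S.dom.mi(S.py[j] - S.py[i], 1);
    double dz = S.dom.mi(S.pz[j] - S.pz[i], 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) stop("zero-length segment: stretch direction undefined");
    const double e = S.b_ks[m] * (r - S.b_r0[m]);
    if (U) *U += 0.5 * e * (r - S.b_r0[m]);
    const double f = e / r;
    F.add(i, f * dx, f * dy, f * dz);
    F.add(j, -f * dx, -f * dy, -f * dz);
  }
}

// bending force between generic points; returns forces on the three points.
// theta is the bending angle between u = q2-q1 and v = q3-q2 (0 = straight).
inline double bendPoints(double u1, double u2, double u3,
                         double v1, double v2, double v3, double kb,
                         double* F1, double* F2, double* F3) {
  const double nu = std::sqrt(u1 * u1 + u2 * u2 + u3 * u3);
  const double nv = std::sqrt(v1 * v1 + v2 * v2 + v3 * v3);
  if (nu < 1e-9 || nv < 1e-9) stop("degenerate bending triple");
  const double iu = 1.0 / nu, iv = 1.0 / nv;
  const double ux = u1 * iu, uy = u2 * iu, uz = u3 * iu;
  const double vx = v1 * iv, vy = v2 * iv, vz = v3 * iv;
  double c = ux * vx + uy * vy + uz * vz;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  const double th = std::acos(c);
  const double tau = kb * th;
  // w1 = vhat - c*uhat, |w1| = sin(theta); same for w2 = uhat - c*vhat
  double w1x = vx - c * ux, w1y = vy - c * uy, w1z = vz - c * uz;
  double w2x = ux - c * vx, w2y = uy - c * vy, w2z = uz - c * vz;
  double n1 = std::sqrt(w1x * w1x + w1y * w1y + w1z * w1z);
  double n2 = std::sqrt(w2x * w2x + w2y * w2y + w2z * w2z);
  if (n1 < 1e-9 || n2 < 1e-9) {
    if (th < 1.0) {
      // straight: torque ~ 0, no force
      for (int d = 0; d < 3; ++d) { F1[d] = F2[d] = F3[d] = 0.0; }
      return 0.5 * kb * th * th;
    }
    // folded (theta ~ pi): direction degenerate; fixed perpendicular tie-break
    double ex = -uy, ey = ux, ez = 0.0;
    double ne = std::sqrt(ex * ex + ey * ey);
    if (ne < 1e-6) { ex = 1.0; ey = 0.0; ez = 0.0; ne = 1.0; }
    ex /= ne; ey /= ne; ez /= ne;
    w1x = ex; w1y = ey; w1z = ez; n1 = 1.0;
    w2x = -ex; w2y = -ey; w2z = -ez; n2 = 1.0;
  }
  w1x /= n1; w1y /= n1; w1z /= n1;
  w2x /= n2; w2y /= n2; w2z /= n2;
  // F1 = -tau * w1hat / |u| ; F3 = +tau * w2hat / |v| ; F2 = -(F1+F3)
  F1[0] = -tau * w1x * iu; F1[1] = -tau * w1y * iu; F1[2] = -tau * w1z * iu;
  F3[0] = tau * w2x * iv;  F3[1] = tau * w2y * iv;  F3[2] = tau * w2z * iv;
  F2[0] = -(F1[0] + F3[0]); F2[1] = -(F1[1] + F3[1]); F2[2] = -(F1[2] + F3[2]);
  return 0.5 * kb * th * th;
}

// ---------- bend (vertex triples) ----------
void bendForces(const System& S, Forces& F, double* U) {
  const size_t na = S.a_i.size();
  double F1[3], F2[3], F3[3];
  for (size_t m = 0; m < na; ++m) {
    const int i = S.a_i[m], j = S.a_j[m], k = S.a_k[m];
    const double u1 = S.dom.mi(S.px[j] - S.px[i], 0);
    const double u2 = S.dom.mi(S.py[j] - S.py[i], 1);
    const double u3 = S.dom.mi(S.pz[j] - S.pz[i], 2);
    const double v1 = S.dom.mi(S.px[k] - S.px[j], 0);
    const double v2 = S.dom.mi(S.py[k] - S.py[j], 1);
    const double v3 = S.dom.mi(S.pz[k] - S.pz[j], 2);
    const double e = bendPoints(u1, u2, u3, v1, v2, v3, S.a_kb[m], F1, F2, F3);
    if (U) *U += e;
    F.add(i, F1[0], F1[1], F1[2]);
    F.add(j, F2[0], F2[1], F2[2]);
    F.add(k, F3[0], F3[1], F3[2]);
  }
}

// ---------- ACP springs + hinge ----------
void acpForces(const System& S, Forces& F, double* U) {
  const size_t nc = S.c_center.size();
  for (size_t m = 0; m < nc; ++m) {
    const int cv = S.c_center[m];
    const double cx = S.px[cv], cy = S.py[cv], cz = S.pz[cv];
    double s1x, s1y, s1z, s2x, s2y, s2z, tx, ty, tz, fr1, fr2;
    sitePos(S, S.c_seg1[m], S.c_site1[m], cx, cy, cz,
            s1x, s1y, s1z, tx, ty, tz, fr1);
    sitePos(S, S.c_seg2[m], S.c_site2[m], cx, cy, cz,
            s2x, s2y, s2z, tx, ty, tz, fr2);
    // two arm springs center<->site
    const double d1x = s1x - cx, d1y = s1y - cy, d1z = s1z - cz;
    const double d2x = s2x - cx, d2y = s2y - cy, d2z = s2z - cz;
    const double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
    const double r2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
    if (r1 < 1e-9 || r2 < 1e-9) stop("ACP arm of zero length");
    const double e1 = S.ks_acp * (r1 - S.r0_acp);
    const double e2 = S.ks_acp * (r2 - S.r0_acp);
    if (U) *U += 0.5 * e1 * (r1 - S.r0_acp) + 0.5 * e2 * (r2 - S.r0_acp);
    const double f1 = e1 / r1, f2 = e2 / r2;
    F.add(cv, f1 * d1x + f2 * d2x, f1 * d1y + f2 * d2y, f1 * d1z + f2 * d2z);
    addToSegment(F, S, S.c_seg1[m], fr1, -f1 * d1x, -f1 * d1y, -f1 * d1z);
    addToSegment(F, S, S.c_seg2[m], fr2, -f2 * d2x, -f2 * d2y, -f2 * d2z);
    // inter-arm hinge keeping the cross-linker straight (theta0 = 0 between
    // tangents site1->center and center->site2)
    if (S.kb_acp > 0) {
      double F1[3], F2[3], F3[3];
      const double e = bendPoints(cx - s1x, cy - s1y, cz - s1z,
                                  s2x - cx, s2y - cy, s2z - cz,
                                  S.kb_acp, F1, F2, F3);
      if (U) *U += e;
      addToSegment(F, S, S.c_seg1[m], fr1, F1[0], F1[1], F1[2]);
      F.add(cv, F2[0], F2[1], F2[2]);
      addToSegment(F, S, S.c_seg2[m], fr2, F3[0], F3[1], F3[2]);
    }
  }
}

// ---------- motor arm two-spring forces ----------
// Also records per-arm load (pN opposing the walking direction) and the
// force the arm exerts on the filament site (for measurement).
void armForces(const System& S, Forces& F, double* U,
               std::vector<double>* load, std::vector<double>* fsite) {
  const size_t na = S.m_anchor.size();
  for (size_t m = 0; m < na; ++m) {
    if (!S.m_bound[m]) {
      if (load) (*load)[m] = 0.0;
      continue;
    }
    const int av = S.m_anchor[m];
    const double ax = S.px[av], ay = S.py[av], az = S.pz[av];
    double sx, sy, sz, tx, ty, tz, fr, slen;
    sitePos(S, S.m_seg[m], S.m_site[m], ax, ay, az, sx, sy, sz, tx, ty, tz,
            fr, &slen);
    const double dx = sx - ax, dy = sy - ay, dz = sz - az;
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    // transverse spring (anchor-site distance vs r0_M2)
    double gx = 0, gy = 0, gz = 0; // force on site
    if (r > 1e-9) {
      const double et = S.km2 * (r - S.r0m2);
      if (U) *U += 0.5 * et * (r - S.r0m2);
      const double ft = et / r;
      // stretched spring pulls anchor toward site (+d) and site toward anchor
      F.add(av, ft * dx, ft * dy, ft * dz);
      gx -= ft * dx; gy -= ft * dy; gz -= ft * dz;
    }
    // longitudinal spring: axial offset of the site from the foot of the
    // perpendicular dropped from the anchor onto the filament axis
    const double o = dx * tx + dy * ty + dz * tz;
    if (U) *U += 0.5 * S.km3 * o * o;
    gx += -S.km3 * o * tx; gy += -S.km3 * o * ty; gz += -S.km3 * o * tz;
    F.add(av, S.km3 * o * tx, S.km3 * o * ty, S.km3 * o * tz);
    addToSegment(F, S, S.m_seg[m], fr, gx, gy, gz);
    // the axial offset also depends on the segment *direction*: the exact
    // gradient adds a force couple on the segment endpoints
    // (+km3 o d_perp/L on the barbed-side vertex, opposite on the other)
    if (slen > 1e-9) {
      const double cpl = S.km3 * o / slen;
      const double px_ = dx - o * tx, py_ = dy - o * ty, pz_ = dz - o * tz;
      F.add(S.s_a[S.m_seg[m]], cpl * px_, cpl * py_, cpl * pz_);
      F.add(S.s_b[S.m_seg[m]], -cpl * px_, -cpl * py_, -cpl * pz_);
    }
    if (fsite) {
      (*fsite)[3 * m] = gx; (*fsite)[3 * m + 1] = gy; (*fsite)[3 * m + 2] = gz;
    }
    if (load) {
      // walking direction on the filament is toward the barbed end (-tangent);
      // load = component of the site force opposing that direction
      const double l = gx * tx + gy * ty + gz * tz;
      (*load)[m] = l > 0 ? l : 0.0;
    }
  }
}

// ---------- segment-segment closest points (Ericson) ----------
inline double closestSegSeg(double p1x, double p1y, double p1z,
                            double q1x, double q1y, double q1z,
                            double p2x, double p2y, double p2z,
                            double q2x, double q2y, double q2z,
                            double& s, double& t) {
  const double d1x = q1x - p1x, d1y = q1y - p1y, d1z = q1z - p1z;
  const double d2x = q2x - p2x, d2y = q2y - p2y, d2z = q2z - p2z;
  const double rx = p1x - p2x, ry = p1y - p2y, rz = p1z - p2z;
  const double a = d1x * d1x + d1y * d1y + d1z * d1z;
  const double e = d2x * d2x + d2y * d2y + d2z * d2z;
  const double f = d2x * rx + d2y * ry + d2z * rz;
  const double eps = 1e-12;
  if (a <= eps && e <= eps) { s = t = 0.0; }
  else if (a <= eps) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    const double c = d1x * rx + d1y * ry + d1z * rz;
    if (e <= eps) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      const double b = d1x * d2x + d1y * d2y + d1z * d2z;
      const double denom = a * e - b * b;
      s = denom > eps ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom))
                      : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  const double c1x = p1x + s * d1x, c1y = p1y + s * d1y, c1z = p1z + s * d1z;
  const double c2x = p2x + t * d2x, c2y = p2y + t * d2y, c2z = p2z + t * d2z;
  const double wx = c1x - c2x, wy = c1y - c2y, wz = c1z - c2z;
  return std::sqrt(wx * wx + wy * wy + wz * wz);
}

// unwrapped endpoints of segments i and j in a common frame anchored at seg i
inline void segPair(const System& S, int i, int j,
                    double& p1x, double& p1y, double& p1z,
                    double& q1x, double& q1y, double& q1z,
                    double& p2x, double& p2y, double& p2z,
                    double& q2x, double& q2y, double& q2z) {
  const int a1 = S.s_a[i], b1 = S.s_b[i], a2 = S.s_a[j], b2 = S.s_b[j];
  p1x = S.px[a1]; p1y = S.py[a1]; p1z = S.pz[a1];
  q1x = p1x + S.dom.mi(S.px[b1] - p1x, 0);
  q1y = p1y + S.dom.mi(S.py[b1] - p1y, 1);
  q1z = p1z + S.dom.mi(S.pz[b1] - p1z, 2);
  p2x = p1x + S.dom.mi(S.px[a2] - p1x, 0);
  p2y = p1y + S.dom.mi(S.py[a2] - p1y, 1);
  p2z = p1z + S.dom.mi(S.pz[a2] - p1z, 2);
  q2x = p2x + S.dom.mi(S.px[b2] - S.px[a2], 0);
  q2y = p2y + S.dom.mi(S.py[b2] - S.py[a2], 1);
  q2z = p2z + S.dom.mi(S.pz[b2] - S.pz[a2], 2);
}

void repulsionPair(const System& S, int i, int j, Forces& F, double* U) {
  double p1x, p1y, p1z, q1x, q1y, q1z, p2x, p2y, p2z, q2x, q2y, q2z;
  segPair(S, i, j, p1x, p1y, p1z, q1x, q1y, q1z, p2x, p2y, p2z, q2x, q2y, q2z);
  double s, t;
  double d = closestSegSeg(p1x, p1y, p1z, q1x, q1y, q1z,
                           p2x, p2y, p2z, q2x, q2y, q2z, s, t);
  if (d >= S.rc) return;
  double nx, ny, nz;
  if (d > 1e-9) {
    nx = (p1x + s * (q1x - p1x)) - (p2x + t * (q2x - p2x));
    ny = (p1y + s * (q1y - p1y)) - (p2y + t * (q2y - p2y));
    nz = (p1z + s * (q1z - p1z)) - (p2z + t * (q2z - p2z));
    nx /= d; ny /= d; nz /= d;
  } else {
    // exactly coincident closest points: fixed tie-break direction
    nx = 1.0; ny = 0.0; nz = 0.0; d = 0.0;
  }
  const double mag = S.kr * (S.rc - d);
  if (U) *U += 0.5 * S.kr * (S.rc - d) * (S.rc - d);
  addToSegment(F, S, i, s, mag * nx, mag * ny, mag * nz);
  addToSegment(F, S, j, t, -mag * nx, -mag * ny, -mag * nz);
}

bool repelExcluded(const System& S, int i, int j) {
  return S.s_fil[i] == S.s_fil[j] && std::abs(S.s_local[i] - S.s_local[j]) <= 1;
}

// all-pairs repulsion (used for one-shot force/energy evaluations)
void repulsionAll(const System& S, Forces& F, double* U) {
  const int ns = (int)S.s_a.size();
  for (int i = 0; i < ns; ++i)
    for (int j = i + 1; j < ns; ++j)
      if (!repelExcluded(S, i, j)) repulsionPair(S, i, j, F, U);
}

void wallForces(const System& S, Forces& F, double* U) {
  for (int ax = 0; ax < 3; ++ax) {
    if (S.dom.kind[ax] != 2) continue;
    const double L = S.dom.box[ax];
    const std::vector<double>& c = (ax == 0 ? S.px : (ax == 1 ? S.py : S.pz));
    for (int i = 0; i < S.N; ++i) {
      double pen = 0.0;
      if (c[i] < 0) pen = -c[i];
      else if (c[i] > L) pen = L - c[i]; // negative
      if (pen != 0.0) {
        if (U) *U += 0.5 * S.wallk * pen * pen;
        const double f = S.wallk * pen;
        if (ax == 0) F.fx[i] += f;
        else if (ax == 1) F.fy[i] += f;
        else F.fz[i] += f;
      }
    }
  }
}

// ---------- System construction from R list ----------
System buildSystem(const List& sys) {
  System S;
  NumericMatrix pos = sys["pos"];
  S.N = pos.nrow();
  S.px.resize(S.N); S.py.resize(S.N); S.pz.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
  }
  S.zeta = as<std::vector<double> >(sys["zeta"]);
  S.vtype = as<std::vector<int> >(sys["vtype"]);
  S.clamped = as<std::vector<int> >(sys["clamped"]);
  S.b_i = as<std::vector<int> >(sys["bond_i"]);
  S.b_j = as<std::vector<int> >(sys["bond_j"]);
  S.b_cat = as<std::vector<int> >(sys["bond_cat"]);
  S.b_r0 = as<std::vector<double> >(sys["bond_r0"]);
  S.b_ks = as<std::vector<double> >(sys["bond_ks"]);
  S.a_i = as<std::vector<int> >(sys["ang_i"]);
  S.a_j = as<std::vector<int> >(sys["ang_j"]);
  S.a_k = as<std::vector<int> >(sys["ang_k"]);
  S.a_kb = as<std::vector<double> >(sys["ang_kb"]);
  S.s_a = as<std::vector<int> >(sys["seg_a"]);
  S.s_b = as<std::vector<int> >(sys["seg_b"]);
  S.s_fil = as<std::vector<int> >(sys["seg_fil"]);
  S.s_local = as<std::vector<int> >(sys["seg_local"]);
  S.fil_nseg = as<std::vector<int> >(sys["fil_nseg"]);
  S.occ = as<std::vector<int> >(sys["occ"]);
  S.m_anchor = as<std::vector<int> >(sys["arm_anchor"]);
  S.m_wfrom = as<std::vector<int> >(sys["arm_wfrom"]);
  S.m_wto = as<std::vector<int> >(sys["arm_wto"]);
  S.m_sib = as<std::vector<int> >(sys["arm_sib"]);
  S.m_bound = as<std::vector<int> >(sys["arm_bound"]);
  S.m_seg = as<std::vector<int> >(sys["arm_seg"]);
  S.m_site = as<std::vector<int> >(sys["arm_site"]);
  S.c_center = as<std::vector<int> >(sys["acp_center"]);
  S.c_seg1 = as<std::vector<int> >(sys["acp_seg1"]);
  S.c_site1 = as<std::vector<int> >(sys["acp_site1"]);
  S.c_seg2 = as<std::vector<int> >(sys["acp_seg2"]);
  S.c_site2 = as<std::vector<int> >(sys["acp_site2"]);
  NumericVector box = sys["box"];
  IntegerVector bk = sys["bkind"];
  for (int d = 0; d < 3; ++d) { S.dom.box[d] = box[d]; S.dom.kind[d] = bk[d]; }
  List par = sys["epar"];
  S.dt = par["dt"]; S.kBT = par["kBT"];
  S.ks_acp = par["ks_acp"]; S.r0_acp = par["r0_acp"]; S.kb_acp = par["kb_acp"];
  S.km2 = par["km2"]; S.km3 = par["km3"]; S.r0m2 = par["r0m2"];
  S.kr = par["kr"]; S.rc = par["rc"]; S.wallk = par["wallk"];
  S.site_sp = par["site_sp"]; S.seg_r0 = par["seg_r0"];
  S.nsites = as<int>(par["nsites"]);
  S.kbind = par["kbind"]; S.kw0 = par["kw0"]; S.Fstall = par["Fstall"];
  S.ku0 = par["ku0"]; S.kumin_frac = par["kumin_frac"]; S.Fcat = par["Fcat"];
  S.capture = par["capture"];
  S.kin_every = as<int>(par["kin_every"]);
  S.nlist_every = as<int>(par["nlist_every"]);
  S.skin = par["skin"]; S.max_disp = par["max_disp"];
  return S;
}

void allForces(System& S, Forces& F, double* U,
               std::vector<double>* load, std::vector<double>* fsite,
               const std::vector<std::pair<int, int> >* nlist) {
  F.init(S.N);
  stretchForces(S, F, U);
  bendForces(S, F, U);
  acpForces(S, F, U);
  armForces(S, F, U, load, fsite);
  if (nlist) {
    for (size_t q = 0; q < nlist->size(); ++q)
      repulsionPair(S, (*nlist)[q].first, (*nlist)[q].second, F, U);
  } else {
    repulsionAll(S, F, U);
  }
  wallForces(S, F, U);
}

// exact pre-filter for a candidate pair (midpoint bound then closest point)
inline bool pairWithinCut(const System& S, int i, int j, double cut,
                          const std::vector<double>& mx,
                          const std::vector<double>& my,
                          const std::vector<double>& mz,
                          const std::vector<double>& half) {
  const double ddx = S.dom.mi(mx[j] - mx[i], 0);
  const double ddy = S.dom.mi(my[j] - my[i], 1);
  const double ddz = S.dom.mi(mz[j] - mz[i], 2);
  const double lim = half[i] + half[j] + cut;
  if (ddx * ddx + ddy * ddy + ddz * ddz > lim * lim) return false;
  double p1x, p1y, p1z, q1x, q1y, q1z, p2x, p2y, p2z, q2x, q2y, q2z, s, t;
  segPair(S, i, j, p1x, p1y, p1z, q1x, q1y, q1z,
          p2x, p2y, p2z, q2x, q2y, q2z);
  return closestSegSeg(p1x, p1y, p1z, q1x, q1y, q1z,
                       p2x, p2y, p2z, q2x, q2y, q2z, s, t) < cut;
}

// uniform cell grid over segment midpoints; cell edge >= the largest
// center-to-center distance at which two segments can still interact
void rebuildNeighborList(const System& S,
                         std::vector<std::pair<int, int> >& nlist) {
  nlist.clear();
  const int ns = (int)S.s_a.size();
  if (ns < 2) return;
  const double cut = S.rc + S.skin;
  std::vector<double> mx(ns), my(ns), mz(ns), half(ns);
  double maxhalf = 0.0;
  for (int i = 0; i < ns; ++i) {
    const int a = S.s_a[i], b = S.s_b[i];
    const double dx = S.dom.mi(S.px[b] - S.px[a], 0);
    const double dy = S.dom.mi(S.py[b] - S.py[a], 1);
    const double dz = S.dom.mi(S.pz[b] - S.pz[a], 2);
    mx[i] = S.px[a] + 0.5 * dx; my[i] = S.py[a] + 0.5 * dy;
    mz[i] = S.pz[a] + 0.5 * dz;
    half[i] = 0.5 * std::sqrt(dx * dx + dy * dy + dz * dz);
    if (half[i] > maxhalf) maxhalf = half[i];
  }
  const double cell = 2.0 * maxhalf + cut;
  // grid extents: box length on periodic axes, midpoint range otherwise
  double org[3], ext[3];
  int nc[3];
  const std::vector<double>* mm[3] = { &mx, &my, &mz };
  bool gridded = true;
  for (int ax = 0; ax < 3; ++ax) {
    if (S.dom.kind[ax] == 1) {
      org[ax] = 0.0; ext[ax] = S.dom.box[ax];
    } else {
      double lo = (*mm[ax])[0], hi = lo;
      for (int i = 1; i < ns; ++i) {
        const double v = (*mm[ax])[i];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      org[ax] = lo; ext[ax] = hi - lo + 1.0;
    }
    nc[ax] = std::max(1, (int)(ext[ax] / cell));
    // periodic wrap of neighbor cells needs >= 3 cells on that axis
    if (S.dom.kind[ax] == 1 && nc[ax] < 3) nc[ax] = 1;
  }
  const long ncells = (long)nc[0] * nc[1] * nc[2];
  if (ncells <= 1 || ncells > 4000000L) gridded = false;
  if (!gridded) {
    for (int i = 0; i < ns; ++i)
      for (int j = i + 1; j < ns; ++j)
        if (!repelExcluded(S, i, j) &&
            pairWithinCut(S, i, j, cut, mx, my, mz, half))
          nlist.push_back(std::make_pair(i, j));
    return;
  }
  std::vector<int> head(ncells, -1), nxt(ns, -1), ci(ns), cj(ns), ck(ns);
  for (int i = 0; i < ns; ++i) {
    int c[3];
    const double pt[3] = { mx[i], my[i], mz[i] };
    for (int ax = 0; ax < 3; ++ax) {
      double v = pt[ax] - org[ax];
      if (S.dom.kind[ax] == 1) {
        v -= S.dom.box[ax] * std::floor(v / S.dom.box[ax]);
        c[ax] = std::min(nc[ax] - 1, (int)(v / S.dom.box[ax] * nc[ax]));
      } else {
        c[ax] = std::min(nc[ax] - 1, std::max(0, (int)(v / cell)));
      }
    }
    ci[i] = c[0]; cj[i] = c[1]; ck[i] = c[2];
    const long idx = ((long)c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[i] = head[idx];
    head[idx] = i;
  }
  for (int i = 0; i < ns; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int z = ck[i] + dz;
      if (nc[2] == 1) { if (dz != 0) continue; z = 0; }
      else if (S.dom.kind[2] == 1) z = (z + nc[2]) % nc[2];
      else if (z < 0 || z >= nc[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cj[i] + dy;
        if (nc[1] == 1) { if (dy != 0) continue; y = 0; }
        else if (S.dom.kind[1] == 1) y = (y + nc[1]) % nc[1];
        else if (y < 0 || y >= nc[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = ci[i] + dx;
          if (nc[0] == 1) { if (dx != 0) continue; x = 0; }
          else if (S.dom.kind[0] == 1) x = (x + nc[0]) % nc[0];
          else if (x < 0 || x >= nc[0]) continue;
          const long idx = ((long)z * nc[1] + y) * nc[0] + x;
          for (int j = head[idx]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            if (repelExcluded(S, i, j)) continue;
            if (pairWithinCut(S, i, j, cut, mx, my, mz, half))
              nlist.push_back(std::make_pair(i, j));
          }
        }
      }
    }
  }
}

// ---------- kinetics ----------
void tryBindArm(System& S, int m, double pbind, Rng& rng) {
  if (rng.runif() >= pbind) return;
  const int av = S.m_anchor[m];
  const double ax = S.px[av], ay = S.py[av], az = S.pz[av];
  // walking direction of this arm along its backbone
  double wx = S.dom.mi(S.px[S.m_wto[m]] - S.px[S.m_wfrom[m]], 0);
  double wy = S.dom.mi(S.py[S.m_wto[m]] - S.py[S.m_wfrom[m]], 1);
  double wz = S.dom.mi(S.pz[S.m_wto[m]] - S.pz[S.m_wfrom[m]], 2);
  const double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (wn < 1e-9) return;
  wx /= wn; wy /= wn; wz /= wn;
  const int sib = S.m_sib[m];
  const int excl_fil = (sib >= 0 && S.m_bound[sib]) ? S.s_fil[S.m_seg[sib]] : -1;
  int best_seg = -1, best_site = -1;
  double best_d2 = S.capture * S.capture;
  const int ns = (int)S.s_a.size();
  for (int sg = 0; sg < ns; ++sg) {
    if (S.s_fil[sg] == excl_fil) continue;
    const int a = S.s_a[sg], b = S.s_b[sg];
    double sax, say, saz;
    minImagePoint(S, ax, ay, az, S.px[a], S.py[a], S.pz[a], sax, say, saz);
    const double dx = S.dom.mi(S.px[b] - S.px[a], 0);
    const double dy = S.dom.mi(S.py[b] - S.py[a], 1);
    const double dz = S.dom.mi(S.pz[b] - S.pz[a], 2);
    const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    // quick reject on midpoint distance
    const double mxx = sax + 0.5 * dx - ax, myy = say + 0.5 * dy - ay,
                 mzz = saz + 0.5 * dz - az;
    const double lim = 0.5 * len + S.capture;
    if (mxx * mxx + myy * myy + mzz * mzz > lim * lim) continue;
    // polarity alignment: barbed-end direction = -tangent
    const double dot = -(dx * wx + dy * wy + dz * wz) / len;
    if (dot <= 0) continue;
    for (int st = 0; st < S.nsites; ++st) {
      if (S.occ[(size_t)sg * S.nsites + st] != 0) continue;
      const double fr = (double)st / (double)S.nsites;
      const double qx = sax + fr * dx - ax;
      const double qy = say + fr * dy - ay;
      const double qz = saz + fr * dz - az;
      const double d2 = qx * qx + qy * qy + qz * qz;
      if (d2 < best_d2) { best_d2 = d2; best_seg = sg; best_site = st; }
    }
  }
  if (best_seg >= 0) {
    S.m_bound[m] = 1; S.m_seg[m] = best_seg; S.m_site[m] = best_site;
    S.occ[(size_t)best_seg * S.nsites + best_site] = m + 2;
  }
}

void tryWalkArm(System& S, int m, double load, double dtk, Rng& rng) {
  const double kw = S.kw0 * std::max(0.0, 1.0 - load / S.Fstall);
  if (kw <= 0.0) return;
  if (rng.runif() >= 1.0 - std::exp(-kw * dtk)) return;
  int sg = S.m_seg[m], st = S.m_site[m];
  if (st > 0) { st -= 1; }
  else if (S.s_local[sg] > 0) { sg -= 1; st = S.nsites - 1; }
  else return; // barbed-end terminal site: no walking past the end
  if (S.occ[(size_t)sg * S.nsites + st] != 0) return; // occupied target
  S.occ[(size_t)S.m_seg[m] * S.nsites + S.m_site[m]] = 0;
  S.m_seg[m] = sg; S.m_site[m] = st;
  S.occ[(size_t)sg * S.nsites + st] = m + 2;
}

void tryUnbindArm(System& S, int m, double load, double dtk, Rng& rng) {
  double ku = S.ku0 * std::exp(-load / S.Fcat);
  const double kmin = S.ku0 * S.kumin_frac;
  if (ku < kmin) ku = kmin;
  if (rng.runif() >= 1.0 - std::exp(-ku * dtk)) return;
  S.occ[(size_t)S.m_seg[m] * S.nsites + S.m_site[m]] = 0;
  S.m_bound[m] = 0; S.m_seg[m] = -1; S.m_site[m] = -1;
}

List snapshotList(const System& S, int step) {
  NumericMatrix pos(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    pos(i, 0) = S.px[i]; pos(i, 1) = S.py[i]; pos(i, 2) = S.pz[i];
  }
  return List::create(_["step"] = step, _["pos"] = pos,
                      _["arm_bound"] = wrap(S.m_bound),
                      _["arm_seg"] = wrap(S.m_seg),
                      _["arm_site"] = wrap(S.m_site));
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".am_forces")]]
List am_forces(List sys) {
  System S = buildSystem(sys);
  // per-category accumulation
  Forces Fs, Fb, Fc, Fa, Fr, Fw;
  Fs.init(S.N); Fb.init(S.N); Fc.init(S.N); Fa.init(S.N); Fr.init(S.N);
  Fw.init(S.N);
  std::vector<double> load(S.m_anchor.size(), 0.0);
  std::vector<double> fsite(3 * S.m_anchor.size(), 0.0);
  stretchForces(S, Fs, 0);
  bendForces(S, Fb, 0);
  acpForces(S, Fc, 0);
  armForces(S, Fa, 0, &load, &fsite);
  repulsionAll(S, Fr, 0);
  wallForces(S, Fw, 0);
  const int N = S.N;
  NumericMatrix total(N, 3), stretch(N, 3), bend(N, 3), acp(N, 3), arm(N, 3),
      rep(N, 3), wall(N, 3);
  for (int i = 0; i < N; ++i) {
    stretch(i, 0) = Fs.fx[i]; stretch(i, 1) = Fs.fy[i]; stretch(i, 2) = Fs.fz[i];
    bend(i, 0) = Fb.fx[i]; bend(i, 1) = Fb.fy[i]; bend(i, 2) = Fb.fz[i];
    acp(i, 0) = Fc.fx[i]; acp(i, 1) = Fc.fy[i]; acp(i, 2) = Fc.fz[i];
    arm(i, 0) = Fa.fx[i]; arm(i, 1) = Fa.fy[i]; arm(i, 2) = Fa.fz[i];
    rep(i, 0) = Fr.fx[i]; rep(i, 1) = Fr.fy[i]; rep(i, 2) = Fr.fz[i];
    wall(i, 0) = Fw.fx[i]; wall(i, 1) = Fw.fy[i]; wall(i, 2) = Fw.fz[i];
    total(i, 0) = Fs.fx[i] + Fb.fx[i] + Fc.fx[i] + Fa.fx[i] + Fr.fx[i] + Fw.fx[i];
    total(i, 1) = Fs.fy[i] + Fb.fy[i] + Fc.fy[i] + Fa.fy[i] + Fr.fy[i] + Fw.fy[i];
    total(i, 2) = Fs.fz[i] + Fb.fz[i] + Fc.fz[i] + Fa.fz[i] + Fr.fz[i] + Fw.fz[i];
  }
  const int na = (int)S.m_anchor.size();
  NumericMatrix fsm(na, 3);
  for (int m = 0; m < na; ++m) {
    fsm(m, 0) = fsite[3 * m]; fsm(m, 1) = fsite[3 * m + 1];
    fsm(m, 2) = fsite[3 * m + 2];
  }
  return List::create(
      _["total"] = total, _["stretch"] = stretch, _["bend"] = bend,
      _["acp"] = acp, _["arm"] = arm, _["repulsion"] = rep, _["wall"] = wall,
      _["arm_load"] = wrap(load), _["arm_fsite"] = fsm);
}

//' @noRd
// [[Rcpp::export(name = ".am_energy")]]
double am_energy(List sys) {
  System S = buildSystem(sys);
  Forces F;
  double U = 0.0;
  allForces(S, F, &U, 0, 0, 0);
  return U;
}

//' @noRd
// [[Rcpp::export(name = ".am_run")]]
List am_run(List sys, int nsteps, int record_every,
            bool freeze_actin, bool thermal_on,
            bool bind_on, bool walk_on, bool unbind_on) {
  System S = buildSystem(sys);
  Rng rng;
  Forces F;
  std::vector<double> load(S.m_anchor.size(), 0.0);
  std::vector<std::pair<int, int> > nlist;
  std::vector<double> sigma(S.N);
  for (int i = 0; i < S.N; ++i)
    sigma[i] = std::sqrt(2.0 * S.kBT * S.zeta[i] / S.dt);
  std::vector<int> mobile(S.N);
  for (int i = 0; i < S.N; ++i)
    mobile[i] = !S.clamped[i] && !(freeze_actin && S.vtype[i] == 0);
  List snaps;
  std::vector<List> snapvec;
  bool aborted = false;
  int abort_vertex = -1;
  double abort_force[3] = {0, 0, 0};
  std::string abort_reason = "";
  const double dtk = S.kin_every * S.dt;
  const double pbind = 1.0 - std::exp(-S.kbind * dtk);
  const bool any_kin = bind_on || walk_on || unbind_on;
  int step = 0;
  for (step = 0; step < nsteps; ++step) {
    if (step % S.nlist_every == 0) rebuildNeighborList(S, nlist);
    allForces(S, F, 0, &load, 0, &nlist);
    // kinetics on the current force field
    if (any_kin && (step % S.kin_every == 0)) {
      const int na = (int)S.m_anchor.size();
      if (bind_on)
        for (int m = 0; m < na; ++m)
          if (!S.m_bound[m]) tryBindArm(S, m, pbind, rng);
      if (walk_on)
        for (int m = 0; m < na; ++m)
          if (S.m_bound[m]) tryWalkArm(S, m, load[m], dtk, rng);
      if (unbind_on)
        for (int m = 0; m < na; ++m)
          if (S.m_bound[m]) tryUnbindArm(S, m, load[m], dtk, rng);
    }
    // Euler update with thermal kicks
    for (int i = 0; i < S.N; ++i) {
      if (!mobile[i]) continue;
      double fx = F.fx[i], fy = F.fy[i], fz = F.fz[i];
      if (thermal_on) {
        fx += sigma[i] * rng();
        fy += sigma[i] * rng();
        fz += sigma[i] * rng();
      }
      const double h = S.dt / S.zeta[i];
      const double dx = fx * h, dy = fy * h, dz = fz * h;
      if (std::fabs(dx) > S.max_disp || std::fabs(dy) > S.max_disp ||
          std::fabs(dz) > S.max_disp ||
          !std::isfinite(dx) || !std::isfinite(dy) || !std::isfinite(dz)) {
        aborted = true;
        abort_vertex = i;
        abort_force[0] = F.fx[i]; abort_force[1] = F.fy[i];
        abort_force[2] = F.fz[i];
        abort_reason = "per-step displacement exceeded limit (instability)";
        break;
      }
      S.px[i] += dx; S.py[i] += dy; S.pz[i] += dz;
      for (int ax = 0; ax < 3; ++ax) {
        if (S.dom.kind[ax] != 1) continue;
        double& c = (ax == 0 ? S.px[i] : (ax == 1 ? S.py[i] : S.pz[i]));
        const double L = S.dom.box[ax];
        c -= L * std::floor(c / L);
      }
    }
    if (aborted) break;
    if (record_every > 0 && ((step + 1) % record_every == 0))
      snapvec.push_back(snapshotList(S, step + 1));
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix pos(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    pos(i, 0) = S.px[i]; pos(i, 1) = S.py[i]; pos(i, 2) = S.pz[i];
  }
  List snl(snapvec.size());
  for (size_t q = 0; q < snapvec.size(); ++q) snl[q] = snapvec[q];
  return List::create(
      _["pos"] = pos, _["occ"] = wrap(S.occ),
      _["arm_bound"] = wrap(S.m_bound), _["arm_seg"] = wrap(S.m_seg),
      _["arm_site"] = wrap(S.m_site),
      _["steps_done"] = aborted ? step : nsteps,
      _["aborted"] = aborted, _["abort_reason"] = abort_reason,
      _["abort_vertex"] = abort_vertex + 1,
      _["abort_force"] = NumericVector::create(abort_force[0],
                                               abort_force[1],
                                               abort_force[2]),
      _["snapshots"] = snl);
}
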
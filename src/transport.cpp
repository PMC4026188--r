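// Analog Monte Carlo optical-photon transport in a nested-volume scene.
//
// Geometry model: a priority-ordered list of axis-aligned volumes
// (box, full sphere, sphere section with radial/polar limits, ellipsoid,
// cylindrical tube). Point location returns the highest-priority volume
// containing the point ("innermost wins"); higher-priority volumes carve
// lower-priority ones, which replaces explicit CSG subtraction.
//
// Transport: per step, competing exponential free paths for bulk
// absorption and Rayleigh-type scattering (mean free paths per material)
// race against the distance to the nearest region boundary. Boundaries
// apply unpolarized Fresnel splitting (probabilistic reflect/refract,
// Snell refraction, total internal reflection); materials without a
// refractive index terminate photons at their surface. Scattering uses
// the (1 + cos^2 theta) phase function with uniform azimuth. Detectors
// are transparent finite planes normal to z that bin crossings into
// square grids without affecting transport.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const double GEOM_EPS = 1e-6;   // post-crossing nudge, mm
static const double TMIN = 1e-9;       // minimum accepted intersection distance
static const double INF_PATH = 1e30;

// ---------------------------------------------------------------------------
// small vector helpers
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 add(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 sub(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 mul(const V3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3& a) { double n = norm(a); return v3(a.x / n, a.y / n, a.z / n); }

// ---------------------------------------------------------------------------
// deterministic RNG (64-bit Mersenne Twister + own uniform/normal mapping so
// that streams are bit-identical across platforms and compilers)
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble so that small consecutive seeds give
    // well-separated states
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    gen.seed(z ^ (z >> 31));
  }
  double u01() { // uniform in (0,1); 53-bit mantissa, never exactly 0
    return (double)((gen() >> 11) + 1ULL) * (1.0 / 9007199254740993.0);
  }
  double rexp(double mfp) { return -mfp * std::log(u01()); }
  void normal2(double& n1, double& n2) { // Box-Muller pair
    double u1 = u01(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    n1 = r * std::cos(a);
    n2 = r * std::sin(a);
  }
};

// ---------------------------------------------------------------------------
// shapes and volumes
enum ShapeKind { K_BOX = 0, K_ORB = 1, K_SPH_SECTION = 2, K_ELLIPSOID = 3, K_TUBE = 4 };

struct Volume {
  int kind;
  double p[4];    // shape parameters (see below)
  V3 c;           // placement (translation; shapes are axis-aligned)
  int mat;        // 0-based material index
  std::string name;
  double brad;    // bounding-sphere radius about c
};
// parameter layout:
//   box:          p = half-sides (hx, hy, hz)
//   orb:          p = (R)
//   sph_section:  p = (rmin, rmax, theta0, theta1), polar angle from +z
//   ellipsoid:    p = semi-axes (a, b, c)
//   tube:         p = (rin, rout, hz), axis along z

struct Material {
  double abslength;  // <=0 encodes "no bulk absorption"
  double rayleigh;   // <=0 encodes "no scattering"
  double rindex;     // NaN encodes "no refractive index" (terminal absorber)
};

struct Detector {
  double z, cx, cy, hx, hy;
  int bins, filter;  // filter: -1 tally dz<0, +1 tally dz>0, 0 both
};

struct Scene {
  std::vector<Volume> vols;                 // ascending priority
  std::vector<std::vector<int> > cand;      // candidate volumes per current volume
};

static bool contains(const Volume& v, const V3& q) {
  V3 r = sub(q, v.c);
  switch (v.kind) {
  case K_BOX:
    return std::fabs(r.x) <= v.p[0] && std::fabs(r.y) <= v.p[1] && std::fabs(r.z) <= v.p[2];
  case K_ORB:
    return dot(r, r) <= v.p[0] * v.p[0];
  case K_SPH_SECTION: {
    double d2 = dot(r, r);
    double rmin = v.p[0], rmax = v.p[1];
    if (d2 > rmax * rmax || d2 < rmin * rmin) return false;
    double d = std::sqrt(d2);
    double th = (d > 0) ? std::acos(std::min(1.0, std::max(-1.0, r.z / d))) : 0.0;
    return th >= v.p[2] - 1e-12 && th <= v.p[3] + 1e-12;
  }
  case K_ELLIPSOID: {
    double sx = r.x / v.p[0], sy = r.y / v.p[1], sz = r.z / v.p[2];
    return sx * sx + sy * sy + sz * sz <= 1.0;
  }
  case K_TUBE: {
    double rho2 = r.x * r.x + r.y * r.y;
    return rho2 >= v.p[0] * v.p[0] && rho2 <= v.p[1] * v.p[1] && std::fabs(r.z) <= v.p[2];
  }
  }
  return false;
}

// highest-priority (last-listed) containing volume; -1 if outside the
// world box (the world clips everything)
static int locate(const Scene& sc, const V3& q) {
  if (!contains(sc.vols[0], q)) return -1;
  for (int i = (int)sc.vols.size() - 1; i >= 1; --i)
    if (contains(sc.vols[i], q)) return i;
  return 0;
}

// candidate boundary crossing
struct Hit { double t; int vol; int surf; };

static void push_quad(std::vector<Hit>& out, double A, double B, double C,
                      int vol, int surf) {
  // roots of A t^2 + B t + C = 0 (A may be ~0: linear)
  if (std::fabs(A) < 1e-14) {
    if (std::fabs(B) > 1e-14) {
      double t = -C / B;
      if (t > TMIN) { Hit h = { t, vol, surf }; out.push_back(h); }
    }
    return;
  }
  double disc = B * B - 4.0 * A * C;
  if (disc < 0) return;
  double sq = std::sqrt(disc);
  double q = (B >= 0) ? -0.5 * (B + sq) : -0.5 * (B - sq);
  double t1 = q / A, t2 = (std::fabs(q) > 1e-300) ? C / q : INF_PATH;
  if (t1 > TMIN && t1 < INF_PATH) { Hit h = { t1, vol, surf }; out.push_back(h); }
  if (t2 > TMIN && t2 < INF_PATH) { Hit h = { t2, vol, surf }; out.push_back(h); }
}

static void push_sphere(std::vector<Hit>& out, const V3& u, const V3& d,
                        double R, int vol, int surf) {
  push_quad(out, 1.0, 2.0 * dot(u, d), dot(u, u) - R * R, vol, surf);
}

static void push_cone(std::vector<Hit>& out, const V3& u, const V3& d,
                      double theta, int vol, int surf) {
  if (theta < 1e-9 || theta > M_PI - 1e-9) return; // degenerate: the axis
  if (std::fabs(theta - M_PI_2) < 1e-12) {         // equatorial plane z = cz
    if (std::fabs(d.z) > 1e-14) {
      double t = -u.z / d.z;
      if (t > TMIN) { Hit h = { t, vol, surf }; out.push_back(h); }
    }
    return;
  }
  double k = std::tan(theta), k2 = k * k;
  push_quad(out,
            d.x * d.x + d.y * d.y - k2 * d.z * d.z,
            2.0 * (u.x * d.x + u.y * d.y - k2 * u.z * d.z),
            u.x * u.x + u.y * u.y - k2 * u.z * u.z,
            vol, surf);
}

static void collect_hits(const Volume& v, int vi, const V3& p, const V3& d,
                         std::vector<Hit>& out) {
  V3 u = sub(p, v.c);
  switch (v.kind) {
  case K_BOX: {
    for (int ax = 0; ax < 3; ++ax) {
      double dc = (ax == 0) ? d.x : (ax == 1) ? d.y : d.z;
      double uc = (ax == 0) ? u.x : (ax == 1) ? u.y : u.z;
      if (std::fabs(dc) < 1e-14) continue;
      double h = v.p[ax];
      double ta = (h - uc) / dc, tb = (-h - uc) / dc;
      if (ta > TMIN) { Hit hh = { ta, vi, ax * 2 }; out.push_back(hh); }
      if (tb > TMIN) { Hit hh = { tb, vi, ax * 2 + 1 }; out.push_back(hh); }
    }
    break;
  }
  case K_ORB:
    push_sphere(out, u, d, v.p[0], vi, 0);
    break;
  case K_SPH_SECTION:
    push_sphere(out, u, d, v.p[1], vi, 0);
    if (v.p[0] > 0) push_sphere(out, u, d, v.p[0], vi, 1);
    push_cone(out, u, d, v.p[2], vi, 2);
    push_cone(out, u, d, v.p[3], vi, 3);
    break;
  case K_ELLIPSOID: {
    double a = v.p[0], b = v.p[1], c = v.p[2];
    V3 us = v3(u.x / a, u.y / b, u.z / c), ds = v3(d.x / a, d.y / b, d.z / c);
    push_quad(out, dot(ds, ds), 2.0 * dot(us, ds), dot(us, us) - 1.0, vi, 0);
    break;
  }
  case K_TUBE: {
    double A = d.x * d.x + d.y * d.y, B = 2.0 * (u.x * d.x + u.y * d.y);
    push_quad(out, A, B, u.x * u.x + u.y * u.y - v.p[1] * v.p[1], vi, 0);
    if (v.p[0] > 0) push_quad(out, A, B, u.x * u.x + u.y * u.y - v.p[0] * v.p[0], vi, 1);
    if (std::fabs(d.z) > 1e-14) {
      double ta = (v.p[2] - u.z) / d.z, tb = (-v.p[2] - u.z) / d.z;
      if (ta > TMIN) { Hit hh = { ta, vi, 2 }; out.push_back(hh); }
      if (tb > TMIN) { Hit hh = { tb, vi, 3 }; out.push_back(hh); }
    }
    break;
  }
  }
}

// outward-agnostic surface normal (unnormalized gradient) at a point
static V3 surface_normal(const Volume& v, int surf, const V3& q) {
  V3 r = sub(q, v.c);
  switch (v.kind) {
  case K_BOX: {
    int ax = surf / 2;
    double s = (surf % 2 == 0) ? 1.0 : -1.0;
    return v3(ax == 0 ? s : 0, ax == 1 ? s : 0, ax == 2 ? s : 0);
  }
  case K_ORB:
    return unit(r);
  case K_SPH_SECTION:
    if (surf <= 1) return unit(r);
    else {
      double theta = (surf == 2) ? v.p[2] : v.p[3];
      if (std::fabs(theta - M_PI_2) < 1e-12) return v3(0, 0, 1);
      double k2 = std::tan(theta) * std::tan(theta);
      V3 g = v3(2 * r.x, 2 * r.y, -2 * k2 * r.z);
      double n = norm(g);
      if (n < 1e-300) return v3(0, 0, 1);
      return mul(g, 1.0 / n);
    }
  case K_ELLIPSOID:
    return unit(v3(r.x / (v.p[0] * v.p[0]), r.y / (v.p[1] * v.p[1]),
                   r.z / (v.p[2] * v.p[2])));
  case K_TUBE:
    if (surf <= 1) return unit(v3(r.x, r.y, 0));
    return v3(0, 0, surf == 2 ? 1.0 : -1.0);
  }
  return v3(0, 0, 1);
}

struct Crossing {
  double t;
  V3 normal;   // oriented against the incoming direction
  int entered; // volume index after the crossing; -1 = out of world
  bool found;
};

// first region change along p + t*d from inside volume `cur`
static Crossing first_crossing(const Scene& sc, const V3& p, const V3& d, int cur) {
  Crossing cr; cr.found = false; cr.t = INF_PATH; cr.entered = -1;
  std::vector<Hit> hits;
  hits.reserve(16);
  const std::vector<int>& cl = sc.cand[cur];
  for (size_t i = 0; i < cl.size(); ++i)
    collect_hits(sc.vols[cl[i]], cl[i], p, d, hits);
  std::sort(hits.begin(), hits.end(),
            [](const Hit& a, const Hit& b) { return a.t < b.t; });
  for (size_t i = 0; i < hits.size(); ++i) {
    const Hit& h = hits[i];
    V3 q = add(p, mul(d, h.t + GEOM_EPS));
    int loc = locate(sc, q);
    if (loc != cur) {
      cr.t = h.t;
      cr.entered = loc;
      V3 hitp = add(p, mul(d, h.t));
      V3 n = surface_normal(sc.vols[h.vol], h.surf, hitp);
      if (dot(n, d) > 0) n = mul(n, -1.0);
      cr.normal = n;
      cr.found = true;
      return cr;
    }
  }
  return cr; // no change before candidates exhausted (should not happen in-world)
}

// ---------------------------------------------------------------------------
// physics primitives

static double fresnel_R(double cosi, double n1, double n2) {
  if (n1 == n2) return 0.0;
  cosi = std::min(1.0, std::max(0.0, cosi));
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0; // total internal reflection
  double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// sample cos(theta) from p(mu) = 3(1+mu^2)/8 by inverting
// mu^3 + 3 mu + 4 - 8u = 0 (depressed cubic, single real root)
static double sample_phase_cosine(double u) {
  double q = 8.0 * u - 4.0;          // mu^3 + 3 mu = q
  double s = std::sqrt(q * q / 4.0 + 1.0);
  return std::cbrt(q / 2.0 + s) + std::cbrt(q / 2.0 - s);
}

// rotate direction d by polar angle with cosine ct and azimuth phi
static V3 scatter_direction(const V3& d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  // orthonormal basis around d
  V3 a = (std::fabs(d.z) < 0.999) ? v3(0, 0, 1) : v3(1, 0, 0);
  V3 e1 = unit(v3(d.y * a.z - d.z * a.y, d.z * a.x - d.x * a.z, d.x * a.y - d.y * a.x));
  V3 e2 = v3(d.y * e1.z - d.z * e1.y, d.z * e1.x - d.x * e1.z, d.x * e1.y - d.y * e1.x);
  V3 out = add(mul(d, ct),
               add(mul(e1, st * std::cos(phi)), mul(e2, st * std::sin(phi))));
  return unit(out);
}

static V3 reflect_dir(const V3& d, const V3& n) {
  return sub(d, mul(n, 2.0 * dot(d, n)));
}

static V3 refract_dir(const V3& d, const V3& n, double n1, double n2) {
  double eta = n1 / n2;
  double cosi = -dot(n, d);
  double sint2 = eta * eta * (1.0 - cosi * cosi);
  double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
  return unit(add(mul(d, eta), mul(n, eta * cosi - cost)));
}

// ---------------------------------------------------------------------------
// scene construction from R lists

static int kind_code(const std::string& k) {
  if (k == "box") return K_BOX;
  if (k == "full-sphere") return K_ORB;
  if (k == "sphere-section") return K_SPH_SECTION;
  if (k == "ellipsoid") return K_ELLIPSOID;
  if (k == "tube") return K_TUBE;
  stop("unknown shape kind: " + k);
  return -1;
}

static double bound_radius(const Volume& v) {
  switch (v.kind) {
  case K_BOX: return std::sqrt(v.p[0] * v.p[0] + v.p[1] * v.p[1] + v.p[2] * v.p[2]);
  case K_ORB: return v.p[0];
  case K_SPH_SECTION: return v.p[1];
  case K_ELLIPSOID: return std::max(v.p[0], std::max(v.p[1], v.p[2]));
  case K_TUBE: return std::sqrt(v.p[1] * v.p[1] + v.p[2] * v.p[2]);
  }
  return 0;
}

static Scene build_scene(List scene) {
  Scene sc;
  List vols = scene["volumes"];
  int n = vols.size();
  for (int i = 0; i < n; ++i) {
    List vl = vols[i];
    Volume v;
    v.kind = kind_code(as<std::string>(vl["kind"]));
    NumericVector par = vl["params"];
    for (int j = 0; j < 4; ++j) v.p[j] = (j < par.size()) ? par[j] : 0.0;
    NumericVector ce = vl["center"];
    v.c = v3(ce[0], ce[1], ce[2]);
    v.mat = as<int>(vl["material_index"]) - 1;
    v.name = as<std::string>(vl["name"]);
    v.brad = bound_radius(v);
    sc.vols.push_back(v);
  }
  // candidate lists: own volume + every higher-priority volume whose
  // bounding sphere intersects this volume's bounding sphere
  sc.cand.resize(n);
  for (int i = 0; i < n; ++i) {
    sc.cand[i].push_back(i);
    for (int j = i + 1; j < n; ++j) {
      double dd = norm(sub(sc.vols[j].c, sc.vols[i].c));
      if (dd <= sc.vols[i].brad + sc.vols[j].brad + 1e-9)
        sc.cand[i].push_back(j);
    }
  }
  return sc;
}

static std::vector<Material> build_materials(List mats) {
  NumericVector ab = mats["abslength"], ra = mats["rayleigh"], ri = mats["rindex"];
  std::vector<Material> out(ab.size());
  for (int i = 0; i < ab.size(); ++i) {
    out[i].abslength = NumericVector::is_na(ab[i]) ? -1.0 : ab[i];
    out[i].rayleigh = NumericVector::is_na(ra[i]) ? -1.0 : ra[i];
    out[i].rindex = NumericVector::is_na(ri[i]) ? NA_REAL : ri[i];
  }
  return out;
}

static std::vector<Detector> build_detectors(List dets) {
  std::vector<Detector> out;
  int n = dets.size();
  for (int i = 0; i < n; ++i) {
    List d = dets[i];
    Detector dt;
    dt.z = as<double>(d["z"]);
    NumericVector ce = d["center_xy"];
    dt.cx = ce[0]; dt.cy = ce[1];
    NumericVector side = d["side_lengths"];
    dt.hx = side[0] / 2.0; dt.hy = side[1] / 2.0;
    dt.bins = as<int>(d["bins"]);
    std::string f = as<std::string>(d["filter"]);
    dt.filter = (f == "-z") ? -1 : (f == "+z") ? 1 : 0;
    out.push_back(dt);
  }
  return out;
}

// half-open bins [low, high), last bin closed at the top edge; the
// fractional position is computed from the plane center so that a
// crossing exactly at the center bins exactly (no edge rounding noise)
static inline int bin_index(double coord, double half, int bins) {
  if (coord < -half || coord > half) return -1;
  int ix = (int)std::floor((coord / (2.0 * half) + 0.5) * bins);
  if (ix == bins) ix = bins - 1; // coord exactly at the top edge
  return ix;
}

static void tally_segment(const V3& p, const V3& d, double t,
                          const std::vector<Detector>& dets,
                          std::vector<IntegerMatrix>& counts,
                          std::vector<long>& crossings) {
  if (std::fabs(d.z) < 1e-14) return;
  for (size_t k = 0; k < dets.size(); ++k) {
    const Detector& dt = dets[k];
    if (dt.filter == -1 && d.z >= 0) continue;
    if (dt.filter == 1 && d.z <= 0) continue;
    double s = (dt.z - p.z) / d.z;
    if (s <= TMIN || s > t) continue;
    double x = p.x + s * d.x - dt.cx;
    double y = p.y + s * d.y - dt.cy;
    int ix = bin_index(x, dt.hx, dt.bins);
    int iy = bin_index(y, dt.hy, dt.bins);
    if (ix < 0 || iy < 0) continue;
    counts[k](ix, iy) += 1;
    crossings[k] += 1;
  }
}

// ---------------------------------------------------------------------------
// exported geometry queries

// [[Rcpp::export]]
IntegerVector cpp_locate(List scene, NumericMatrix pts) {
  Scene sc = build_scene(scene);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = locate(sc, v3(pts(i, 0), pts(i, 1), pts(i, 2))) + 1; // 1-based, 0 = outside
  return out;
}

// [[Rcpp::export]]
List cpp_first_intersection(List scene, NumericVector origin,
                            NumericVector direction, int current) {
  Scene sc = build_scene(scene);
  V3 p = v3(origin[0], origin[1], origin[2]);
  V3 d = v3(direction[0], direction[1], direction[2]);
  Crossing cr = first_crossing(sc, p, d, current - 1);
  return List::create(
    _["found"] = cr.found,
    _["distance"] = cr.t,
    _["normal"] = NumericVector::create(cr.normal.x, cr.normal.y, cr.normal.z),
    _["entered"] = cr.entered + 1);
}

// ---------------------------------------------------------------------------
// exported physics primitives (single implementation shared with the kernel)

// [[Rcpp::export]]
NumericVector cpp_sample_free_path(int n, double mfp, double seed) {
  Rng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rexp(mfp);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_scatter_cosine(int n, double seed) {
  Rng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_phase_cosine(rng.u01());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_phase_cosine_from_u(NumericVector u) {
  NumericVector out(u.size());
  for (int i = 0; i < u.size(); ++i) out[i] = sample_phase_cosine(u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fresnel_reflectance(NumericVector cos_incident,
                                      double n1, double n2) {
  NumericVector out(cos_incident.size());
  for (int i = 0; i < cos_incident.size(); ++i)
    out[i] = fresnel_R(cos_incident[i], n1, n2);
  return out;
}

// [[Rcpp::export]]
List cpp_boundary_interaction(NumericVector direction, NumericVector normal,
                              double n1, double n2, bool n2_absent, double u) {
  V3 d = unit(v3(direction[0], direction[1], direction[2]));
  V3 n = v3(normal[0], normal[1], normal[2]);
  if (std::fabs(norm(n) - 1.0) > 1e-9) stop("'normal' must be a unit vector");
  if (dot(n, d) >= 0) stop("'normal' must oppose the incoming direction");
  if (n2_absent) {
    return List::create(_["event"] = "absorbed_at_boundary",
                        _["direction"] = direction);
  }
  double cosi = -dot(n, d);
  double R = fresnel_R(cosi, n1, n2);
  if (u < R) {
    V3 r = reflect_dir(d, n);
    return List::create(_["event"] = "reflected",
                        _["direction"] = NumericVector::create(r.x, r.y, r.z),
                        _["reflectance"] = R);
  }
  V3 tr = refract_dir(d, n, n1, n2);
  return List::create(_["event"] = "refracted",
                      _["direction"] = NumericVector::create(tr.x, tr.y, tr.z),
                      _["reflectance"] = R);
}

// ---------------------------------------------------------------------------
// deterministic ray trace (always refract, reflect only on TIR; no
// absorption or scattering). Used for scan-angle calibration and for
// checking the refractive focusing of the eye model.

// [[Rcpp::export]]
List cpp_trace_ray(List scene, List materials, NumericVector origin,
                   NumericVector direction, int max_steps) {
  Scene sc = build_scene(scene);
  std::vector<Material> mats = build_materials(materials);
  V3 p = v3(origin[0], origin[1], origin[2]);
  V3 d = unit(v3(direction[0], direction[1], direction[2]));
  int cur = locate(sc, p);
  if (cur < 0) stop("ray origin is outside the world");
  std::vector<double> px, py, pz;
  std::vector<int> volumes;
  px.push_back(p.x); py.push_back(p.y); pz.push_back(p.z);
  volumes.push_back(cur + 1);
  std::string fate = "max_steps";
  for (int step = 0; step < max_steps; ++step) {
    Crossing cr = first_crossing(sc, p, d, cur);
    if (!cr.found) { fate = "lost"; break; }
    V3 hit = add(p, mul(d, cr.t));
    if (cr.entered < 0) {
      p = hit;
      px.push_back(p.x); py.push_back(p.y); pz.push_back(p.z);
      volumes.push_back(0);
      fate = "world_exit";
      break;
    }
    const Material& m1 = mats[sc.vols[cur].mat];
    const Material& m2 = mats[sc.vols[cr.entered].mat];
    if (ISNAN(m2.rindex)) {
      p = hit;
      px.push_back(p.x); py.push_back(p.y); pz.push_back(p.z);
      volumes.push_back(cr.entered + 1);
      fate = "absorbed_boundary";
      break;
    }
    double cosi = -dot(cr.normal, d);
    double R = fresnel_R(cosi, m1.rindex, m2.rindex);
    if (R >= 1.0) d = reflect_dir(d, cr.normal);
    else d = refract_dir(d, cr.normal, m1.rindex, m2.rindex);
    p = add(hit, mul(d, GEOM_EPS));
    cur = locate(sc, p);
    px.push_back(p.x); py.push_back(p.y); pz.push_back(p.z);
    volumes.push_back(cur + 1);
    if (cur < 0) { fate = "world_exit"; break; }
  }
  int np = px.size();
  NumericMatrix path(np, 3);
  for (int i = 0; i < np; ++i) { path(i, 0) = px[i]; path(i, 1) = py[i]; path(i, 2) = pz[i]; }
  return List::create(_["path"] = path, _["volume"] = wrap(volumes),
                      _["fate"] = fate,
                      _["direction"] = NumericVector::create(d.x, d.y, d.z));
}

// ---------------------------------------------------------------------------
// the analog transport kernel

// [[Rcpp::export]]
List cpp_simulate(List scene, List materials, List detectors,
                  NumericVector origin, NumericVector axis, double sigma,
                  int n_photons, double seed, int max_scatters,
                  int record_limit) {
  Scene sc = build_scene(scene);
  std::vector<Material> mats = build_materials(materials);
  std::vector<Detector> dets = build_detectors(detectors);
  Rng rng((uint64_t)seed);

  std::vector<IntegerMatrix> counts;
  std::vector<long> crossings(dets.size(), 0);
  for (size_t k = 0; k < dets.size(); ++k) {
    IntegerMatrix m(dets[k].bins, dets[k].bins);
    counts.push_back(m);
  }

  V3 ax = unit(v3(axis[0], axis[1], axis[2]));
  // transverse basis for beam offsets
  V3 ref = (std::fabs(ax.z) < 0.999) ? v3(0, 0, 1) : v3(1, 0, 0);
  V3 e1 = unit(v3(ax.y * ref.z - ax.z * ref.y, ax.z * ref.x - ax.x * ref.z,
                  ax.x * ref.y - ax.y * ref.x));
  V3 e2 = v3(ax.y * e1.z - ax.z * e1.y, ax.z * e1.x - ax.x * e1.z,
             ax.x * e1.y - ax.y * e1.x);
  V3 org = v3(origin[0], origin[1], origin[2]);

  long n_abs_bulk = 0, n_abs_boundary = 0, n_exit = 0, n_capped = 0, n_lost = 0;

  bool record = record_limit > 0;
  std::vector<double> rec_path, rec_x, rec_y, rec_z, rec_dx, rec_dy, rec_dz;
  std::vector<int> rec_id, rec_ns;
  std::vector<std::string> rec_fate;

  for (int i = 0; i < n_photons; ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    double o1, o2;
    rng.normal2(o1, o2);
    o1 *= sigma; o2 *= sigma;
    V3 p = add(org, add(mul(e1, o1), mul(e2, o2)));
    V3 d = ax;
    int cur = locate(sc, p);
    int ns = 0;
    double path_len = 0.0;
    const char* fate = "world_exit";
    if (cur < 0) { ++n_exit; fate = "world_exit"; }
    else {
      for (;;) {
        const Material& m = mats[sc.vols[cur].mat];
        double la = (m.abslength > 0) ? rng.rexp(m.abslength) : INF_PATH;
        double ls = (m.rayleigh > 0) ? rng.rexp(m.rayleigh) : INF_PATH;
        Crossing cr = first_crossing(sc, p, d, cur);
        double tb = cr.found ? cr.t : INF_PATH;
        double t = std::min(la, std::min(ls, tb));
        if (t >= INF_PATH) { ++n_lost; fate = "lost"; break; }
        tally_segment(p, d, t, dets, counts, crossings);
        path_len += t;
        if (la <= ls && la <= tb) {           // bulk absorption
          p = add(p, mul(d, la));
          ++n_abs_bulk; fate = "absorbed_bulk";
          break;
        } else if (ls < la && ls <= tb) {     // Rayleigh-type scatter
          p = add(p, mul(d, ls));
          double ct = sample_phase_cosine(rng.u01());
          double phi = 2.0 * M_PI * rng.u01();
          d = scatter_direction(d, ct, phi);
          ++ns;
          if (ns > max_scatters) { ++n_capped; fate = "capped"; break; }
        } else {                              // boundary
          V3 hit = add(p, mul(d, tb));
          if (cr.entered < 0) {
            p = hit; ++n_exit; fate = "world_exit";
            break;
          }
          const Material& m2 = mats[sc.vols[cr.entered].mat];
          if (ISNAN(m2.rindex)) {
            p = hit; ++n_abs_boundary; fate = "absorbed_boundary";
            break;
          }
          double cosi = -dot(cr.normal, d);
          double R = fresnel_R(cosi, m.rindex, m2.rindex);
          if (rng.u01() < R) d = reflect_dir(d, cr.normal);
          else d = refract_dir(d, cr.normal, m.rindex, m2.rindex);
          p = add(hit, mul(d, GEOM_EPS));
          path_len += GEOM_EPS;
          cur = locate(sc, p);
          if (cur < 0) { ++n_exit; fate = "world_exit"; break; }
        }
      }
    }
    if (record && i < record_limit) {
      rec_id.push_back(i + 1); rec_fate.push_back(fate);
      rec_path.push_back(path_len); rec_ns.push_back(ns);
      rec_x.push_back(p.x); rec_y.push_back(p.y); rec_z.push_back(p.z);
      rec_dx.push_back(d.x); rec_dy.push_back(d.y); rec_dz.push_back(d.z);
    }
  }

  List tallies(counts.size());
  NumericVector ncross(counts.size());
  for (size_t k = 0; k < counts.size(); ++k) {
    tallies[k] = counts[k];
    ncross[k] = (double)crossings[k];
  }
  List fates = List::create(
    _["generated"] = (double)n_photons,
    _["absorbed_bulk"] = (double)n_abs_bulk,
    _["absorbed_boundary"] = (double)n_abs_boundary,
    _["world_exit"] = (double)n_exit,
    _["capped"] = (double)n_capped,
    _["lost"] = (double)n_lost);
  List out = List::create(_["tallies"] = tallies, _["n_crossings"] = ncross,
                          _["fates"] = fates);
  if (record) {
    out["records"] = DataFrame::create(
      _["id"] = rec_id, _["fate"] = rec_fate, _["path_mm"] = rec_path,
      _["n_scatters"] = rec_ns, _["x"] = rec_x, _["y"] = rec_y, _["z"] = rec_z,
      _["dx"] = rec_dx, _["dy"] = rec_dy, _["dz"] = rec_dz);
  }
  return out;
}
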
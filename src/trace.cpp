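// Monte Carlo forward ray transport for band-level canopy light interception.
//
// Rays are launched from rectangular Lambertian emitters (LED bars facing the
// bed), intersected against all scene triangles through a BVH, and terminated
// by Russian-roulette sampling of the surface interaction (absorb / diffuse
// reflect / diffuse transmit).  One outcome per hit keeps the estimator
// unbiased with bounded work per ray, and makes the energy balance
// emitted = absorbed + escaped exact by construction: every ray's (equal)
// weight ends up in exactly one bin.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256+.  Hand-rolled so that tallies are
// bit-reproducible for a fixed seed regardless of the C++ standard library.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }
};

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

struct Tri {
  Vec3 v0, e1, e2;  // v0 + edges
  Vec3 n;           // unit geometric normal
};

struct Aabb {
  Vec3 lo, hi;
  Aabb() {
    lo = {1e30, 1e30, 1e30};
    hi = {-1e30, -1e30, -1e30};
  }
  void grow(const Vec3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void grow(const Aabb& b) { grow(b.lo); grow(b.hi); }
};

struct BvhNode {
  Aabb box;
  int left = -1, right = -1;  // children, or leaf when left < 0
  int start = 0, count = 0;   // triangle index range for leaves
};

struct Bvh {
  std::vector<BvhNode> nodes;
  std::vector<int> order;  // permutation of triangle indices

  void build(const std::vector<Tri>& tris, const std::vector<Vec3>& centroids) {
    int n = (int)tris.size();
    order.resize(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    nodes.reserve(2 * std::max(n, 1));
    build_node(tris, centroids, 0, n);
  }

  int build_node(const std::vector<Tri>& tris, const std::vector<Vec3>& cents,
                 int start, int count) {
    int idx = (int)nodes.size();
    nodes.push_back(BvhNode());
    Aabb box;
    for (int i = start; i < start + count; ++i) {
      const Tri& t = tris[order[i]];
      box.grow(t.v0);
      box.grow(t.v0 + t.e1);
      box.grow(t.v0 + t.e2);
    }
    nodes[idx].box = box;
    if (count <= 4) {
      nodes[idx].left = -1;
      nodes[idx].start = start;
      nodes[idx].count = count;
      return idx;
    }
    Aabb cbox;
    for (int i = start; i < start + count; ++i) cbox.grow(cents[order[i]]);
    Vec3 ext = cbox.hi - cbox.lo;
    int axis = 0;
    if (ext.y > ext.x) axis = 1;
    if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       const Vec3& ca = cents[a];
                       const Vec3& cb = cents[b];
                       return axis == 0 ? ca.x < cb.x : (axis == 1 ? ca.y < cb.y : ca.z < cb.z);
                     });
    int l = build_node(tris, cents, start, mid - start);
    int r = build_node(tris, cents, mid, start + count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    return idx;
  }
};

static inline bool hit_aabb(const Aabb& b, const Vec3& o, const Vec3& inv_d, double t_max) {
  double tx1 = (b.lo.x - o.x) * inv_d.x, tx2 = (b.hi.x - o.x) * inv_d.x;
  double tmin = std::min(tx1, tx2), tmax = std::max(tx1, tx2);
  double ty1 = (b.lo.y - o.y) * inv_d.y, ty2 = (b.hi.y - o.y) * inv_d.y;
  tmin = std::max(tmin, std::min(ty1, ty2));
  tmax = std::min(tmax, std::max(ty1, ty2));
  double tz1 = (b.lo.z - o.z) * inv_d.z, tz2 = (b.hi.z - o.z) * inv_d.z;
  tmin = std::max(tmin, std::min(tz1, tz2));
  tmax = std::min(tmax, std::max(tz1, tz2));
  return tmax >= std::max(tmin, 0.0) && tmin < t_max;
}

// Moller-Trumbore
static inline bool hit_tri(const Tri& t, const Vec3& o, const Vec3& d,
                           double t_min, double t_max, double& t_out) {
  Vec3 p = cross(d, t.e2);
  double det = dot(t.e1, p);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 s = o - t.v0;
  double u = dot(s, p) * inv;
  if (u < 0.0 || u > 1.0) return false;
  Vec3 q = cross(s, t.e1);
  double v = dot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double tt = dot(t.e2, q) * inv;
  if (tt <= t_min || tt >= t_max) return false;
  t_out = tt;
  return true;
}

struct Hit {
  int tri = -1;
  double t = 1e30;
};

static Hit intersect(const Bvh& bvh, const std::vector<Tri>& tris,
                     const Vec3& o, const Vec3& d, int skip_tri) {
  Hit best;
  if (bvh.nodes.empty()) return best;
  Vec3 inv_d = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
  int stack[64];
  int sp = 0;
  stack[sp++] = 0;
  const double t_min = 1e-7;
  while (sp > 0) {
    const BvhNode& node = bvh.nodes[stack[--sp]];
    if (!hit_aabb(node.box, o, inv_d, best.t)) continue;
    if (node.left < 0) {
      for (int i = node.start; i < node.start + node.count; ++i) {
        int ti = bvh.order[i];
        if (ti == skip_tri) continue;
        double tt;
        if (hit_tri(tris[ti], o, d, t_min, best.t, tt)) {
          best.t = tt;
          best.tri = ti;
        }
      }
    } else {
      stack[sp++] = node.left;
      stack[sp++] = node.right;
    }
  }
  return best;
}

// cosine-weighted direction about unit axis n
static inline Vec3 cosine_dir(Rng& rng, const Vec3& n) {
  double r1 = rng.runif();
  double r2 = rng.runif();
  double phi = 2.0 * M_PI * r2;
  double r = std::sqrt(r1);
  // orthonormal basis around n (Duff et al. branchless would do; keep simple)
  Vec3 a = std::fabs(n.x) > 0.9 ? Vec3{0, 1, 0} : Vec3{1, 0, 0};
  Vec3 u = cross(a, n);
  double un = norm(u);
  u = (1.0 / un) * u;
  Vec3 v = cross(n, u);
  double z = std::sqrt(std::max(0.0, 1.0 - r1));
  return (r * std::cos(phi)) * u + (r * std::sin(phi)) * v + z * n;
}

}  // namespace

// [[Rcpp::export(name = ".trace_cpp")]]
List trace_cpp(NumericMatrix tri_verts, IntegerVector tri_surface,
               NumericMatrix optics, NumericMatrix sources,
               double n_rays, int max_bounces, double seed) {
  int n_tri = tri_verts.nrow();
  int n_surf = optics.nrow();
  int n_src = sources.nrow();
  if (tri_surface.size() != n_tri) stop("tri_surface length mismatch");

  std::vector<Tri> tris(n_tri);
  std::vector<Vec3> cents(n_tri);
  for (int i = 0; i < n_tri; ++i) {
    Vec3 v0 = {tri_verts(i, 0), tri_verts(i, 1), tri_verts(i, 2)};
    Vec3 v1 = {tri_verts(i, 3), tri_verts(i, 4), tri_verts(i, 5)};
    Vec3 v2 = {tri_verts(i, 6), tri_verts(i, 7), tri_verts(i, 8)};
    Tri t;
    t.v0 = v0;
    t.e1 = v1 - v0;
    t.e2 = v2 - v0;
    Vec3 n = cross(t.e1, t.e2);
    double a2 = norm(n);
    if (a2 <= 0.0) stop("degenerate triangle at row %d", i + 1);
    t.n = (1.0 / a2) * n;
    tris[i] = t;
    cents[i] = (1.0 / 3.0) * (v0 + v1 + v2);
  }
  for (int s = 0; s < n_surf; ++s) {
    double rho = optics(s, 0), tau = optics(s, 1), alpha = optics(s, 2);
    if (rho < 0 || tau < 0 || alpha < 0 || std::fabs(rho + tau + alpha - 1.0) > 1e-9)
      stop("invalid optics for surface %d (rho+tau+alpha must be 1)", s + 1);
  }

  Bvh bvh;
  bvh.build(tris, cents);

  // sources: columns cx, cy, cz, wx, wy, power (axis-aligned rectangles, emit -z)
  std::vector<double> cum_power(n_src);
  double total_power = 0.0;
  for (int s = 0; s < n_src; ++s) {
    double p = sources(s, 5);
    if (p < 0) stop("negative source power");
    total_power += p;
    cum_power[s] = total_power;
  }

  std::vector<int64_t> counts(n_surf, 0);
  int64_t escaped = 0;
  int64_t N = (int64_t)n_rays;

  Rng rng((uint64_t)seed);
  const Vec3 down = {0, 0, -1};

  if (total_power > 0.0 && N > 0) {
    for (int64_t r = 0; r < N; ++r) {
      // pick source by power
      double u = rng.runif() * total_power;
      int s = 0;
      while (s < n_src - 1 && u > cum_power[s]) ++s;
      Vec3 o = {sources(s, 0) + (rng.runif() - 0.5) * sources(s, 3),
                sources(s, 1) + (rng.runif() - 0.5) * sources(s, 4),
                sources(s, 2)};
      Vec3 d = cosine_dir(rng, down);
      int last = -1;
      bool absorbed = false;
      for (int b = 0; b <= max_bounces; ++b) {
        Hit h = intersect(bvh, tris, o, d, last);
        if (h.tri < 0) break;  // leaves the open domain
        int surf = tri_surface[h.tri];
        double rho = optics(surf, 0), alpha = optics(surf, 2);
        double xi = rng.runif();
        if (xi < alpha) {
          counts[surf]++;
          absorbed = true;
          break;
        }
        Vec3 hp = o + h.t * d;
        const Vec3& n = tris[h.tri].n;
        Vec3 facing = dot(d, n) < 0 ? n : (-1.0) * n;
        if (xi < alpha + rho) {
          d = cosine_dir(rng, facing);            // diffuse reflection
        } else {
          d = cosine_dir(rng, (-1.0) * facing);   // diffuse transmission
        }
        o = hp;
        last = h.tri;
      }
      if (!absorbed) ++escaped;
    }
  } else {
    escaped = N;
  }

  double w = (N > 0) ? total_power / (double)N : 0.0;
  NumericVector absorbed_W(n_surf), mc_se(n_surf), cnt(n_surf);
  double absorbed_total = 0.0;
  for (int s = 0; s < n_surf; ++s) {
    double p = (N > 0) ? (double)counts[s] / (double)N : 0.0;
    absorbed_W[s] = w * (double)counts[s];
    mc_se[s] = (N > 0) ? total_power * std::sqrt(p * (1.0 - p) / (double)N) : 0.0;
    cnt[s] = (double)counts[s];
    absorbed_total += absorbed_W[s];
  }
  double escaped_W = w * (double)escaped;

  return List::create(_["absorbed_W"] = absorbed_W, _["mc_se"] = mc_se,
                      _["counts"] = cnt, _["emitted_W"] = total_power,
                      _["absorbed_total_W"] = absorbed_total,
                      _["escaped_W"] = escaped_W,
                      _["n_rays"] = (double)N);
}
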
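// Incremental Bowyer-Watson Delaunay tetrahedralization.
//
// Points are normalized to unit scale and enclosed in a large super-tetrahedron;
// each point is located by walking, the conflict cavity is grown by a
// breadth-first search over circumsphere tests, and the cavity is re-meshed by
// coning its boundary faces to the new point. Tetrahedra incident to super
// vertices are dropped at the end.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];   // vertex indices
  int nb[4];  // neighbor across the face opposite v[i]; -1 = none
  bool alive;
};

struct DT {
  std::vector<double> px, py, pz;  // normalized coordinates (n points + 4 super)
  std::vector<Tet> tets;
  int npts;  // real points (super vertices are npts..npts+3)

  double orient(int a, int b, int c, int d) const {
    const double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    const double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
    const double wx = px[d] - px[a], wy = py[d] - py[a], wz = pz[d] - pz[a];
    return ux * (vy * wz - vz * wy) - uy * (vx * wz - vz * wx) +
           uz * (vx * wy - vy * wx);
  }

  // squared distance of p to the circumcenter minus squared circumradius (< 0
  // means p is inside the circumsphere of tet t)
  double insphere_margin(const Tet& t, int p) const {
    const int a = t.v[0];
    double u[3] = {px[t.v[1]] - px[a], py[t.v[1]] - py[a], pz[t.v[1]] - pz[a]};
    double v[3] = {px[t.v[2]] - px[a], py[t.v[2]] - py[a], pz[t.v[2]] - pz[a]};
    double w[3] = {px[t.v[3]] - px[a], py[t.v[3]] - py[a], pz[t.v[3]] - pz[a]};
    double rhs[3] = {0.5 * (u[0] * u[0] + u[1] * u[1] + u[2] * u[2]),
                     0.5 * (v[0] * v[0] + v[1] * v[1] + v[2] * v[2]),
                     0.5 * (w[0] * w[0] + w[1] * w[1] + w[2] * w[2])};
    // solve [u; v; w] y = rhs by Cramer's rule
    const double det =
        u[0] * (v[1] * w[2] - v[2] * w[1]) - u[1] * (v[0] * w[2] - v[2] * w[0]) +
        u[2] * (v[0] * w[1] - v[1] * w[0]);
    if (det == 0.0) return -1.0;  // degenerate: treat as always in conflict
    const double d0 =
        rhs[0] * (v[1] * w[2] - v[2] * w[1]) - u[1] * (rhs[1] * w[2] - v[2] * rhs[2]) +
        u[2] * (rhs[1] * w[1] - v[1] * rhs[2]);
    const double d1 =
        u[0] * (rhs[1] * w[2] - v[2] * rhs[2]) - rhs[0] * (v[0] * w[2] - v[2] * w[0]) +
        u[2] * (v[0] * rhs[2] - rhs[1] * w[0]);
    const double d2 =
        u[0] * (v[1] * rhs[2] - rhs[1] * w[1]) - u[1] * (v[0] * rhs[2] - rhs[1] * w[0]) +
        rhs[0] * (v[0] * w[1] - v[1] * w[0]);
    const double cx = d0 / det, cy = d1 / det, cz = d2 / det;  // relative to a
    const double r2 = cx * cx + cy * cy + cz * cz;
    const double qx = px[p] - px[a] - cx, qy = py[p] - py[a] - cy,
                 qz = pz[p] - pz[a] - cz;
    return (qx * qx + qy * qy + qz * qz) - r2;
  }

  // vertices of the face opposite local index i (stored order)
  void face(const Tet& t, int i, int f[3]) const {
    int k = 0;
    for (int j = 0; j < 4; ++j)
      if (j != i) f[k++] = t.v[j];
  }

  // walk from tet `start` to a tet containing point p; -1 on failure
  int locate(int start, int p) const {
    int cur = start;
    const int maxstep = (int)tets.size() + 16;
    for (int step = 0; step < maxstep; ++step) {
      const Tet& t = tets[cur];
      int next = -1;
      for (int i = 0; i < 4; ++i) {
        int f[3];
        face(t, i, f);
        const double ov = orient(f[0], f[1], f[2], t.v[i]);
        const double op = orient(f[0], f[1], f[2], p);
        if (ov * op < 0.0) {  // p strictly on the far side of this face
          next = t.nb[i];
          break;
        }
      }
      if (next == -1) return cur;
      if (next < 0 || !tets[next].alive) return -1;
      cur = next;
    }
    return -1;
  }

  int any_alive() const {
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive) return i;
    return -1;
  }

  void insert(int p) {
    // Degenerate (e.g. exactly cospherical) configurations can make the
    // floating-point conflict cavity non-star-shaped. The cavity is validated
    // before any mutation; on failure the insertion is retried with a tiny
    // deterministic jitter of the point's working coordinates (output indices
    // refer to the caller's exact coordinates regardless).
    const double ox = px[p], oy = py[p], oz = pz[p];
    for (int attempt = 0; attempt < 12; ++attempt) {
      if (attempt > 0) {
        const double mag = 1e-10 * std::pow(4.0, attempt - 1);
        unsigned h = (unsigned)(p * 2654435761u) + 97u * attempt;
        px[p] = ox + mag * (((h >> 0) & 0xff) / 127.5 - 1.0);
        py[p] = oy + mag * (((h >> 8) & 0xff) / 127.5 - 1.0);
        pz[p] = oz + mag * (((h >> 16) & 0xff) / 127.5 - 1.0);
      }
      if (try_insert(p)) return;
    }
    stop("point insertion failed (degenerate geometry)");
  }

  bool try_insert(int p) {
    int t0 = locate(any_alive(), p);
    if (t0 == -1 || insphere_margin(tets[t0], p) >= 0.0) {
      // fallback: scan for any conflicting tet (a containing tet always conflicts)
      t0 = -1;
      for (int i = 0; i < (int)tets.size(); ++i)
        if (tets[i].alive && insphere_margin(tets[i], p) < 0.0) { t0 = i; break; }
      if (t0 == -1) return false;
    }

    // grow conflict cavity
    std::vector<int> bad;
    std::vector<char> inbad(tets.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    inbad[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back();
      stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 4; ++i) {
        const int nbi = tets[t].nb[i];
        if (nbi >= 0 && !inbad[nbi] && tets[nbi].alive &&
            insphere_margin(tets[nbi], p) < 0.0) {
          inbad[nbi] = 1;
          stack.push_back(nbi);
        }
      }
    }

    // boundary faces of the cavity: (face vertices, outside neighbor)
    struct BFace { int a, b, c, outside; };
    std::vector<BFace> bf;
    for (int t : bad) {
      for (int i = 0; i < 4; ++i) {
        const int nbi = tets[t].nb[i];
        if (nbi < 0 || !inbad[nbi]) {
          int f[3];
          face(tets[t], i, f);
          bf.push_back({f[0], f[1], f[2], nbi});
        }
      }
    }

    // the boundary must be a closed surface: every edge on exactly 2 faces,
    // and every new tet must be strictly positively oriented
    {
      auto ekey = [](int a, int b) -> std::int64_t {
        if (a > b) std::swap(a, b);
        return (std::int64_t)a * 0x100000000LL + b;
      };
      std::unordered_map<std::int64_t, int> ecount;
      bool ok = true;
      for (const BFace& f : bf) {
        ++ecount[ekey(f.a, f.b)];
        ++ecount[ekey(f.b, f.c)];
        ++ecount[ekey(f.a, f.c)];
        if (orient(f.a, f.b, f.c, p) == 0.0) ok = false;
      }
      for (const auto& kv : ecount)
        if (kv.second != 2) ok = false;
      if (!ok) return false;
    }

    for (int t : bad) tets[t].alive = false;

    // cone the boundary faces to p
    auto key = [](int a, int b) -> std::int64_t {
      if (a > b) std::swap(a, b);
      return (std::int64_t)a * 0x100000000LL + b;
    };
    std::unordered_map<std::int64_t, std::pair<int, int>> open;  // edge -> (tet, face idx)
    std::vector<int> created;
    for (const BFace& f : bf) {
      Tet nt;
      int a = f.a, b = f.b, c = f.c;
      if (orient(a, b, c, p) < 0.0) std::swap(b, c);
      nt.v[0] = a; nt.v[1] = b; nt.v[2] = c; nt.v[3] = p;
      nt.nb[0] = nt.nb[1] = nt.nb[2] = -1;
      nt.nb[3] = f.outside;
      nt.alive = true;
      const int id = (int)tets.size();
      tets.push_back(nt);
      created.push_back(id);
      if (f.outside >= 0) {  // re-point the outside neighbor across the shared face
        Tet& o = tets[f.outside];
        int fa = f.a, fb = f.b, fc = f.c;
        if (fa > fb) std::swap(fa, fb);
        if (fb > fc) std::swap(fb, fc);
        if (fa > fb) std::swap(fa, fb);
        for (int i = 0; i < 4; ++i) {
          int g[3];
          face(o, i, g);
          if (g[0] > g[1]) std::swap(g[0], g[1]);
          if (g[1] > g[2]) std::swap(g[1], g[2]);
          if (g[0] > g[1]) std::swap(g[0], g[1]);
          if (g[0] == fa && g[1] == fb && g[2] == fc) {
            o.nb[i] = id;
            break;
          }
        }
      }
      // link faces containing p: opposite v[0] is (b,c,p) -> edge (b,c), etc.
      const int edges[3][2] = {{b, c}, {a, c}, {a, b}};
      for (int i = 0; i < 3; ++i) {
        const std::int64_t k = key(edges[i][0], edges[i][1]);
        auto it = open.find(k);
        if (it == open.end()) {
          open[k] = {id, i};
        } else {
          tets[id].nb[i] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          open.erase(it);
        }
      }
    }
    if (!open.empty()) stop("cavity boundary inconsistent (degenerate geometry)");
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // normalize to unit scale
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = R_PosInf;
    hi[k] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo[k] = std::min(lo[k], pts(i, k));
      hi[k] = std::max(hi[k], pts(i, k));
    }
  }
  double scale = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  if (scale <= 0.0) scale = 1.0;
  const double cx = 0.5 * (lo[0] + hi[0]), cy = 0.5 * (lo[1] + hi[1]),
               cz = 0.5 * (lo[2] + hi[2]);

  DT dt;
  dt.npts = n;
  dt.px.resize(n + 4);
  dt.py.resize(n + 4);
  dt.pz.resize(n + 4);
  for (int i = 0; i < n; ++i) {
    dt.px[i] = (pts(i, 0) - cx) / scale;
    dt.py[i] = (pts(i, 1) - cy) / scale;
    dt.pz[i] = (pts(i, 2) - cz) / scale;
  }
  // regular super-tetrahedron far outside the unit box
  const double L = 3.0e3;
  const double sv[4][3] = {
      {L, L, L}, {L, -L, -L}, {-L, L, -L}, {-L, -L, L}};
  for (int i = 0; i < 4; ++i) {
    dt.px[n + i] = sv[i][0];
    dt.py[n + i] = sv[i][1];
    dt.pz[n + i] = sv[i][2];
  }
  Tet super;
  super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2; super.v[3] = n + 3;
  if (dt.orient(n, n + 1, n + 2, n + 3) < 0.0) std::swap(super.v[2], super.v[3]);
  super.nb[0] = super.nb[1] = super.nb[2] = super.nb[3] = -1;
  super.alive = true;
  dt.tets.push_back(super);

  for (int i = 0; i < n; ++i) dt.insert(i);

  int m = 0;
  for (const Tet& t : dt.tets)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Tet& t : dt.tets) {
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) {
      for (int k = 0; k < 4; ++k) out(r, k) = t.v[k] + 1;
      ++r;
    }
  }
  return out;
}
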
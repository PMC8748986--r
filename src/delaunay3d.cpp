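#include <Rcpp.h>
#include <array>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Incremental 3D Delaunay triangulation (Bowyer-Watson) with a single
// symbolic vertex at infinity, so hull tetrahedra need no far-away
// bounding box and conflict tests on them reduce to facet visibility.
// Degenerate configurations (cospherical / coplanar inputs) are expected
// to be broken upstream by a tiny seeded jitter.

static const int INF_V = -1;

struct Tet {
  int v[4];
  int adj[4]; // adj[i] = tetra sharing the facet opposite v[i], -1 if none
  bool alive;
};

typedef long double ld;

static inline ld orient3d(const double* a, const double* b, const double* c,
                          const double* d) {
  ld adx = (ld)a[0] - d[0], ady = (ld)a[1] - d[1], adz = (ld)a[2] - d[2];
  ld bdx = (ld)b[0] - d[0], bdy = (ld)b[1] - d[1], bdz = (ld)b[2] - d[2];
  ld cdx = (ld)c[0] - d[0], cdy = (ld)c[1] - d[1], cdz = (ld)c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

// > 0 iff p strictly inside the circumsphere of positively oriented (a,b,c,d)
static inline ld insphere(const double* a, const double* b, const double* c,
                          const double* d, const double* p) {
  ld aex = (ld)a[0] - p[0], aey = (ld)a[1] - p[1], aez = (ld)a[2] - p[2];
  ld bex = (ld)b[0] - p[0], bey = (ld)b[1] - p[1], bez = (ld)b[2] - p[2];
  ld cex = (ld)c[0] - p[0], cey = (ld)c[1] - p[1], cez = (ld)c[2] - p[2];
  ld dex = (ld)d[0] - p[0], dey = (ld)d[1] - p[1], dez = (ld)d[2] - p[2];
  ld alift = aex * aex + aey * aey + aez * aez;
  ld blift = bex * bex + bey * bey + bez * bez;
  ld clift = cex * cex + cey * cey + cez * cez;
  ld dlift = dex * dex + dey * dey + dez * dez;
  ld ab = aex * bey - bex * aey, ac = aex * cey - cex * aey;
  ld ad = aex * dey - dex * aey, bc = bex * cey - cex * bey;
  ld bd = bex * dey - dex * bey, cd = cex * dey - dex * cey;
  ld abc = aez * bc - bez * ac + cez * ab;
  ld abd = aez * bd - bez * ad + dez * ab;
  ld acd = aez * cd - cez * ad + dez * ac;
  ld bcd = bez * cd - cez * bd + dez * bc;
  return dlift * abc - clift * abd + blift * acd - alift * bcd;
}

struct Triangulator {
  const double* P; // n x 3, row major
  int n;
  std::vector<Tet> tets;
  std::vector<int> freelist;
  int last_tet;

  const double* pt(int i) const { return P + 3 * (size_t)i; }

  int new_tet(int a, int b, int c, int d) {
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.adj[0] = t.adj[1] = t.adj[2] = t.adj[3] = -1;
    t.alive = true;
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); tets[id] = t; }
    else { id = (int)tets.size(); tets.push_back(t); }
    return id;
  }

  bool is_inf(int tid) const {
    const Tet& t = tets[tid];
    return t.v[0] == INF_V || t.v[1] == INF_V || t.v[2] == INF_V || t.v[3] == INF_V;
  }

  int inf_slot(int tid) const {
    const Tet& t = tets[tid];
    for (int i = 0; i < 4; ++i) if (t.v[i] == INF_V) return i;
    return -1;
  }

  // strictly inside circumsphere (finite) / strictly visible (infinite)
  bool in_conflict(int tid, int p) {
    const Tet& t = tets[tid];
    int s = inf_slot(tid);
    if (s < 0) {
      ld o = orient3d(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]));
      ld is = insphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), pt(p));
      if (o > 0) return is > 0;
      if (o < 0) return is < 0;
      return true; // flat tetra: absorb into cavity
    }
    // facet opposite the infinite vertex, inside apex from the neighbor
    int f[3], k = 0;
    for (int i = 0; i < 4; ++i) if (i != s) f[k++] = t.v[i];
    int nb = t.adj[s];
    if (nb < 0) return true;
    const Tet& tn = tets[nb];
    int q = -2;
    for (int i = 0; i < 4; ++i) {
      int v = tn.v[i];
      if (v != f[0] && v != f[1] && v != f[2]) { q = v; break; }
    }
    ld oq = orient3d(pt(f[0]), pt(f[1]), pt(f[2]), pt(q));
    ld op = orient3d(pt(f[0]), pt(f[1]), pt(f[2]), pt(p));
    if (oq > 0) return op < 0;
    if (oq < 0) return op > 0;
    return true;
  }

  // visibility walk from a finite tetra; returns a tetra in conflict with p
  int locate(int p) {
    int cur = last_tet;
    if (cur < 0 || !tets[cur].alive) {
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive && !is_inf(i)) { cur = i; break; }
    }
    if (cur >= 0 && is_inf(cur)) {
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive && !is_inf(i)) { cur = i; break; }
    }
    int guard = 8 * (int)tets.size() + 64;
    int start = 0;
    while (guard-- > 0) {
      if (cur < 0) break;
      if (is_inf(cur)) return cur; // stepped outside the hull: conflict
      const Tet& t = tets[cur];
      bool stepped = false;
      for (int k = 0; k < 4; ++k) {
        int i = (k + start) & 3;
        int f[3], m = 0;
        for (int j = 0; j < 4; ++j) if (j != i) f[m++] = t.v[j];
        ld od = orient3d(pt(f[0]), pt(f[1]), pt(f[2]), pt(t.v[i]));
        ld op = orient3d(pt(f[0]), pt(f[1]), pt(f[2]), pt(p));
        if (od > 0 ? (op < 0) : (od < 0 ? (op > 0) : false)) {
          cur = t.adj[i];
          stepped = true;
          ++start;
          break;
        }
      }
      if (!stepped) return cur; // p inside cur => inside its circumsphere
    }
    // fallback: exhaustive scan
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && in_conflict(i, p)) return i;
    return -1;
  }

  void insert(int p) {
    int seed = locate(p);
    if (seed < 0 || !in_conflict(seed, p)) {
      seed = -1;
      for (int i = 0; i < (int)tets.size(); ++i)
        if (tets[i].alive && in_conflict(i, p)) { seed = i; break; }
      if (seed < 0) stop("Delaunay insertion failed to find a conflict region");
    }
    // BFS the conflict cavity
    std::vector<int> cavity;
    std::unordered_set<int> incav;
    std::vector<int> stack;
    stack.push_back(seed);
    incav.insert(seed);
    struct BFacet { int f[3]; int nb; int nb_slot; };
    std::vector<BFacet> boundary;
    while (!stack.empty()) {
      int tid = stack.back(); stack.pop_back();
      cavity.push_back(tid);
      const Tet t = tets[tid];
      for (int i = 0; i < 4; ++i) {
        int nb = t.adj[i];
        if (nb >= 0 && incav.count(nb)) continue;
        bool nbconf = (nb >= 0) && in_conflict(nb, p);
        if (nbconf) {
          incav.insert(nb);
          stack.push_back(nb);
        } else {
          BFacet bf;
          int m = 0;
          for (int j = 0; j < 4; ++j) if (j != i) bf.f[m++] = t.v[j];
          bf.nb = nb;
          bf.nb_slot = -1;
          if (nb >= 0) {
            const Tet& tn = tets[nb];
            for (int j = 0; j < 4; ++j) {
              int v = tn.v[j];
              if (v != bf.f[0] && v != bf.f[1] && v != bf.f[2]) { bf.nb_slot = j; break; }
            }
          }
          boundary.push_back(bf);
        }
      }
    }
    for (int tid : cavity) { tets[tid].alive = false; freelist.push_back(tid); }
    // retriangulate: one new tetra per boundary facet
    std::unordered_map<uint64_t, std::pair<int,int> > edgemap; // facet edge -> (tet, slot)
    std::vector<int> created;
    for (const BFacet& bf : boundary) {
      int id = new_tet(bf.f[0], bf.f[1], bf.f[2], p);
      created.push_back(id);
      tets[id].adj[3] = bf.nb;
      if (bf.nb >= 0 && bf.nb_slot >= 0) tets[bf.nb].adj[bf.nb_slot] = id;
      // three facets containing p, keyed by their base edge
      for (int i = 0; i < 3; ++i) {
        int a = bf.f[(i + 1) % 3], b = bf.f[(i + 2) % 3];
        int lo = a < b ? a : b, hi = a < b ? b : a;
        uint64_t key = ((uint64_t)(uint32_t)(lo + 2) << 32) | (uint32_t)(hi + 2);
        auto it = edgemap.find(key);
        if (it == edgemap.end()) {
          edgemap[key] = std::make_pair(id, i);
        } else {
          int oid = it->second.first, oslot = it->second.second;
          tets[id].adj[i] = oid;
          tets[oid].adj[oslot] = id;
          edgemap.erase(it);
        }
      }
    }
    last_tet = created.empty() ? -1 : created.back();
    for (int id : created) if (!is_inf(id)) { last_tet = id; break; }
  }
};

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts, IntegerVector order) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("pts must have 3 columns");
  if (n < 4) stop("need at least 4 points");
  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) P[3 * (size_t)i + j] = pts(i, j);

  std::vector<int> ord(order.begin(), order.end());
  if ((int)ord.size() != n) stop("order must have length nrow(pts)");
  for (int& o : ord) { o -= 1; if (o < 0 || o >= n) stop("order out of range"); }

  Triangulator T;
  T.P = P.data();
  T.n = n;
  T.last_tet = -1;

  // first four affinely independent points along the insertion order
  double tol = 0.0;
  {
    double lo[3], hi[3];
    for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) {
        double v = P[3 * (size_t)i + j];
        if (v < lo[j]) lo[j] = v;
        if (v > hi[j]) hi[j] = v;
      }
    double d = 0;
    for (int j = 0; j < 3; ++j) d = std::max(d, hi[j] - lo[j]);
    tol = 1e-12 * d * d * d;
  }
  int s0 = ord[0], s1 = -1, s2 = -1, s3 = -1;
  size_t k = 1;
  for (; k < ord.size() && s1 < 0; ++k) {
    const double* a = T.pt(s0); const double* b = T.pt(ord[k]);
    double dd = 0;
    for (int j = 0; j < 3; ++j) dd += (a[j] - b[j]) * (a[j] - b[j]);
    if (dd > 0) s1 = ord[k];
  }
  size_t k2 = k;
  for (; k2 < ord.size() && s2 < 0; ++k2) {
    const double* a = T.pt(s0); const double* b = T.pt(s1); const double* c = T.pt(ord[k2]);
    double ux = b[0]-a[0], uy = b[1]-a[1], uz = b[2]-a[2];
    double vx = c[0]-a[0], vy = c[1]-a[1], vz = c[2]-a[2];
    double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
    if (cx*cx + cy*cy + cz*cz > 0) s2 = ord[k2];
  }
  size_t k3 = k2;
  for (; k3 < ord.size() && s3 < 0; ++k3) {
    ld o = orient3d(T.pt(s0), T.pt(s1), T.pt(s2), T.pt(ord[k3]));
    if (std::abs((double)o) > tol) s3 = ord[k3];
  }
  if (s3 < 0) {
    return List::create(_["ok"] = false, _["edges"] = IntegerMatrix(0, 2),
                        _["hull"] = IntegerMatrix(0, 3));
  }
  if (orient3d(T.pt(s0), T.pt(s1), T.pt(s2), T.pt(s3)) < 0) std::swap(s1, s2);

  int t0 = T.new_tet(s0, s1, s2, s3);
  // four infinite tetra glued on the facets of t0
  int ti[4];
  for (int i = 0; i < 4; ++i) {
    int f[3], m = 0;
    for (int j = 0; j < 4; ++j) if (j != i) f[m++] = T.tets[t0].v[j];
    ti[i] = T.new_tet(f[0], f[1], f[2], INF_V);
    T.tets[ti[i]].adj[3] = t0;
    T.tets[t0].adj[i] = ti[i];
  }
  // glue infinite tetra to each other along facets (edge of t0 + INF)
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      if (i == j) continue;
      // facet of ti[i] opposite its vertex not shared with ti[j]:
      const Tet& a = T.tets[ti[i]];
      for (int s = 0; s < 3; ++s) {
        int excl = a.v[s];
        // facet = remaining two finite + INF; shared with ti[j] iff both in ti[j]
        int o1 = a.v[(s + 1) % 3], o2 = a.v[(s + 2) % 3];
        const Tet& b = T.tets[ti[j]];
        bool h1 = false, h2 = false, he = false;
        for (int q = 0; q < 3; ++q) {
          if (b.v[q] == o1) h1 = true;
          if (b.v[q] == o2) h2 = true;
          if (b.v[q] == excl) he = true;
        }
        if (h1 && h2 && !he) T.tets[ti[i]].adj[s] = ti[j];
      }
    }
  T.last_tet = t0;

  std::unordered_set<int> used;
  used.insert(s0); used.insert(s1); used.insert(s2); used.insert(s3);
  for (size_t q = 0; q < ord.size(); ++q) {
    int p = ord[q];
    if (used.count(p)) continue;
    used.insert(p);
    T.insert(p);
  }

  // edges among finite vertices
  std::unordered_set<uint64_t> eset;
  for (size_t i = 0; i < T.tets.size(); ++i) {
    if (!T.tets[i].alive) continue;
    const Tet& t = T.tets[i];
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int va = t.v[a], vb = t.v[b];
        if (va < 0 || vb < 0) continue;
        int lo = va < vb ? va : vb, hi = va < vb ? vb : va;
        eset.insert(((uint64_t)(uint32_t)lo << 32) | (uint32_t)hi);
      }
  }
  IntegerMatrix edges((int)eset.size(), 2);
  int r = 0;
  for (uint64_t key : eset) {
    edges(r, 0) = (int)(key >> 32) + 1;
    edges(r, 1) = (int)(key & 0xffffffffu) + 1;
    ++r;
  }

  // hull facets = finite facets of infinite tetra, oriented outward
  std::vector<std::array<int,3> > hull;
  for (size_t i = 0; i < T.tets.size(); ++i) {
    if (!T.tets[i].alive) continue;
    int s = T.inf_slot((int)i);
    if (s < 0) continue;
    const Tet& t = T.tets[i];
    int f[3], m = 0;
    for (int j = 0; j < 4; ++j) if (j != s) f[m++] = t.v[j];
    int nb = t.adj[s];
    int apex = -2;
    if (nb >= 0) {
      const Tet& tn = T.tets[nb];
      for (int j = 0; j < 4; ++j) {
        int v = tn.v[j];
        if (v != f[0] && v != f[1] && v != f[2]) { apex = v; break; }
      }
    }
    if (apex >= 0 && orient3d(T.pt(f[0]), T.pt(f[1]), T.pt(f[2]), T.pt(apex)) > 0)
      std::swap(f[1], f[2]); // outward: apex below the facet plane
    std::array<int,3> fc = { { f[0] + 1, f[1] + 1, f[2] + 1 } };
    hull.push_back(fc);
  }
  IntegerMatrix H((int)hull.size(), 3);
  for (int i = 0; i < (int)hull.size(); ++i)
    for (int j = 0; j < 3; ++j) H(i, j) = hull[i][j];

  return List::create(_["ok"] = true, _["edges"] = edges, _["hull"] = H);
}
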
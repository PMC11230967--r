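#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <unordered_set>
using namespace Rcpp;

// Incremental quickhull in 3D. Returns the (1-based, sorted, unique) indices
// of the input points that are vertices of the convex hull. Written for the
// spherical-flipping step of hidden point removal, where hulls carry
// thousands of vertices and exact predicates are not required: a tolerance
// proportional to the bounding-box diagonal decides face visibility.

namespace {

struct Face {
  int a, b, c;          // vertex indices
  double n[3], d;       // outward plane: n.x = d
  bool alive;
  std::vector<int> outside;  // unassigned points seeing this face
};

struct HullBuilder {
  const double *X; int n;
  std::vector<Face> faces;
  double eps;

  double px(int i, int k) const { return X[i + (size_t)n * k]; }

  void plane(Face &f) {
    double u[3], v[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = px(f.b, k) - px(f.a, k);
      v[k] = px(f.c, k) - px(f.a, k);
    }
    f.n[0] = u[1]*v[2] - u[2]*v[1];
    f.n[1] = u[2]*v[0] - u[0]*v[2];
    f.n[2] = u[0]*v[1] - u[1]*v[0];
    double nn = std::sqrt(f.n[0]*f.n[0] + f.n[1]*f.n[1] + f.n[2]*f.n[2]);
    if (nn > 0) { f.n[0] /= nn; f.n[1] /= nn; f.n[2] /= nn; }
    f.d = f.n[0]*px(f.a,0) + f.n[1]*px(f.a,1) + f.n[2]*px(f.a,2);
  }

  double dist(const Face &f, int i) const {
    return f.n[0]*px(i,0) + f.n[1]*px(i,1) + f.n[2]*px(i,2) - f.d;
  }

  void orient(Face &f, double ix, double iy, double iz) {
    // flip so that the interior point is below the plane
    double s = f.n[0]*ix + f.n[1]*iy + f.n[2]*iz - f.d;
    if (s > 0) {
      std::swap(f.b, f.c);
      f.n[0] = -f.n[0]; f.n[1] = -f.n[1]; f.n[2] = -f.n[2]; f.d = -f.d;
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_convex_hull_vertices(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  HullBuilder H;
  std::vector<double> buf(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) buf[i + (size_t)n * k] = P(i, k);
  H.X = buf.data(); H.n = n;

  // bounding box & tolerance
  double lo[3] = {DBL_MAX, DBL_MAX, DBL_MAX}, hi[3] = {-DBL_MAX, -DBL_MAX, -DBL_MAX};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = H.px(i, k);
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double diag = 0;
  for (int k = 0; k < 3; ++k) diag += (hi[k]-lo[k])*(hi[k]-lo[k]);
  diag = std::sqrt(diag);
  H.eps = 1e-10 * (diag > 0 ? diag : 1.0);

  // initial simplex: two extreme points, then farthest from the line,
  // then farthest from the plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    for (int k = 0; k < 3; ++k) {
      int a = 0, b = 0;
      for (int i = 1; i < n; ++i) {
        if (H.px(i,k) < H.px(a,k)) a = i;
        if (H.px(i,k) > H.px(b,k)) b = i;
      }
      double d2 = 0;
      for (int kk = 0; kk < 3; ++kk) { double d = H.px(a,kk)-H.px(b,kk); d2 += d*d; }
      if (d2 > best) { best = d2; i0 = a; i1 = b; }
    }
    if (best <= H.eps * H.eps) stop("degenerate point set (all points coincide)");
  }
  int i2 = -1;
  {
    double u[3]; double un2 = 0;
    for (int k = 0; k < 3; ++k) { u[k] = H.px(i1,k) - H.px(i0,k); un2 += u[k]*u[k]; }
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double w[3];
      for (int k = 0; k < 3; ++k) w[k] = H.px(i,k) - H.px(i0,k);
      double t = (w[0]*u[0]+w[1]*u[1]+w[2]*u[2]) / un2;
      double d2 = 0;
      for (int k = 0; k < 3; ++k) { double d = w[k] - t*u[k]; d2 += d*d; }
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (best <= H.eps * H.eps) stop("degenerate point set (collinear)");
  }
  int i3 = -1;
  {
    Face f; f.a = i0; f.b = i1; f.c = i2; H.plane(f);
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(H.dist(f, i));
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= H.eps) stop("degenerate point set (coplanar)");
  }

  double cx = (H.px(i0,0)+H.px(i1,0)+H.px(i2,0)+H.px(i3,0))/4.0;
  double cy = (H.px(i0,1)+H.px(i1,1)+H.px(i2,1)+H.px(i3,1))/4.0;
  double cz = (H.px(i0,2)+H.px(i1,2)+H.px(i2,2)+H.px(i3,2))/4.0;

  int init[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = init[t][0]; f.b = init[t][1]; f.c = init[t][2];
    f.alive = true;
    H.plane(f); H.orient(f, cx, cy, cz);
    H.faces.push_back(f);
  }

  // assign points to faces
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t f = 0; f < H.faces.size(); ++f) {
      if (H.dist(H.faces[f], i) > H.eps) { H.faces[f].outside.push_back(i); break; }
    }
  }

  std::vector<size_t> stack;
  for (size_t f = 0; f < H.faces.size(); ++f)
    if (!H.faces[f].outside.empty()) stack.push_back(f);

  while (!stack.empty()) {
    size_t fi = stack.back(); stack.pop_back();
    if (!H.faces[fi].alive || H.faces[fi].outside.empty()) continue;
    // farthest point of this face
    int far = -1; double best = -DBL_MAX;
    for (size_t k = 0; k < H.faces[fi].outside.size(); ++k) {
      int i = H.faces[fi].outside[k];
      double d = H.dist(H.faces[fi], i);
      if (d > best) { best = d; far = i; }
    }
    if (far < 0 || best <= H.eps) { H.faces[fi].outside.clear(); continue; }

    // find all alive faces visible from `far`
    std::vector<size_t> visible;
    for (size_t f = 0; f < H.faces.size(); ++f)
      if (H.faces[f].alive && H.dist(H.faces[f], far) > H.eps) visible.push_back(f);

    // horizon edges: edges of visible faces shared with a non-visible face.
    // Collect directed edges of visible faces; an edge whose reverse is not
    // present belongs to the horizon.
    std::vector<std::pair<int,int>> edges;
    std::unordered_set<long long> dir;
    for (size_t vf = 0; vf < visible.size(); ++vf) {
      const Face &f = H.faces[visible[vf]];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    for (size_t e = 0; e < edges.size(); ++e)
      dir.insert((long long)edges[e].first * n + edges[e].second);
    std::vector<std::pair<int,int>> horizon;
    for (size_t e = 0; e < edges.size(); ++e)
      if (!dir.count((long long)edges[e].second * n + edges[e].first))
        horizon.push_back(edges[e]);

    // gather orphaned outside points, kill visible faces
    std::vector<int> orphans;
    for (size_t vf = 0; vf < visible.size(); ++vf) {
      Face &f = H.faces[visible[vf]];
      orphans.insert(orphans.end(), f.outside.begin(), f.outside.end());
      f.outside.clear();
      f.alive = false;
    }

    // build new faces over the horizon
    std::vector<size_t> fresh;
    for (size_t e = 0; e < horizon.size(); ++e) {
      Face f; f.a = horizon[e].first; f.b = horizon[e].second; f.c = far;
      f.alive = true;
      H.plane(f);
      H.orient(f, cx, cy, cz);
      H.faces.push_back(f);
      fresh.push_back(H.faces.size() - 1);
    }

    // reassign orphans
    for (size_t k = 0; k < orphans.size(); ++k) {
      int i = orphans[k];
      if (i == far) continue;
      for (size_t nf = 0; nf < fresh.size(); ++nf) {
        if (H.dist(H.faces[fresh[nf]], i) > H.eps) {
          H.faces[fresh[nf]].outside.push_back(i);
          break;
        }
      }
    }
    for (size_t nf = 0; nf < fresh.size(); ++nf)
      if (!H.faces[fresh[nf]].outside.empty()) stack.push_back(fresh[nf]);
  }

  std::vector<bool> onHull(n, false);
  for (size_t f = 0; f < H.faces.size(); ++f) {
    if (!H.faces[f].alive) continue;
    onHull[H.faces[f].a] = onHull[H.faces[f].b] = onHull[H.faces[f].c] = true;
  }
  std::vector<int> out;
  for (int i = 0; i < n; ++i) if (onHull[i]) out.push_back(i + 1);
  return wrap(out);
}
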
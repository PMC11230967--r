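#include <Rcpp.h>
#include <cfloat>
#include <vector>
using namespace Rcpp;

// Brute-force nearest neighbour from each query point to the target set.
// Returns 1-based indices and distances. Sizes here are a few thousand
// points, where the O(N*M) scan is fast and has no preprocessing cost.
// [[Rcpp::export]]
List cpp_nn_points(NumericMatrix query, NumericMatrix target) {
  const int n = query.nrow(), m = target.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) { tx[j] = target(j,0); ty[j] = target(j,1); tz[j] = target(j,2); }
  for (int i = 0; i < n; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    double best = DBL_MAX; int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = qx - tx[j], dy = qy - ty[j], dz = qz - tz[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// k nearest neighbours (including self when query == target) by brute force.
// [[Rcpp::export]]
List cpp_knn_points(NumericMatrix query, NumericMatrix target, int k) {
  const int n = query.nrow(), m = target.nrow();
  if (k > m) k = m;
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) { tx[j] = target(j,0); ty[j] = target(j,1); tz[j] = target(j,2); }
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < k; ++c) { bd[c] = DBL_MAX; bi[c] = -1; }
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    for (int j = 0; j < m; ++j) {
      const double dx = qx - tx[j], dy = qy - ty[j], dz = qz - tz[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= bd[k-1]) continue;
      int c = k - 1;
      while (c > 0 && bd[c-1] > d2) { bd[c] = bd[c-1]; bi[c] = bi[c-1]; --c; }
      bd[c] = d2; bi[c] = j;
    }
    for (int c = 0; c < k; ++c) { idx(i,c) = bi[c] + 1; dist(i,c) = std::sqrt(bd[c]); }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// All ordered pairs (i, j), i != j, with |p_i - p_j| <= radius. 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_radius_pairs(NumericMatrix P, double radius) {
  const int n = P.nrow();
  const double r2 = radius * radius;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    const double x = P(i,0), y = P(i,1), z = P(i,2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x - P(j,0), dy = y - P(j,1), dz = z - P(j,2);
      if (dx*dx + dy*dy + dz*dz <= r2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k,0) = ii[k]; out(k,1) = jj[k]; }
  return out;
}

static inline void closestPointOnTriangle(const double *p, const double *a,
                                          const double *b, const double *c,
                                          double *out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k]-a[k]; ac[k] = c[k]-a[k]; ap[k] = p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k=0;k<3;++k) out[k]=a[k]; return; }
  double bp[3]; for (int k=0;k<3;++k) bp[k] = p[k]-b[k];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    return;
  }
  double cp[3]; for (int k=0;k<3;++k) cp[k] = p[k]-c[k];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k]-b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// Closest point on a triangle mesh for each query point. Candidate triangles
// are those incident to the `kCand` nearest mesh vertices, which is exact in
// practice for meshes whose triangles are small relative to query distance.
// F is 1-based. Returns the foot points and distances.
// [[Rcpp::export]]
List cpp_nn_mesh(NumericMatrix query, NumericMatrix V, IntegerMatrix F, int kCand = 3) {
  const int n = query.nrow(), nv = V.nrow(), nf = F.nrow();
  // vertex -> incident triangle lists
  std::vector<std::vector<int>> inc(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) inc[F(f,k) - 1].push_back(f);
  NumericMatrix foot(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int j = 0; j < nv; ++j) { vx[j] = V(j,0); vy[j] = V(j,1); vz[j] = V(j,2); }
  std::vector<int> cand; cand.reserve(64);
  std::vector<int> nearv(kCand);
  std::vector<double> neard(kCand);
  for (int i = 0; i < n; ++i) {
    const double q[3] = { query(i,0), query(i,1), query(i,2) };
    for (int k = 0; k < kCand; ++k) { nearv[k] = -1; neard[k] = DBL_MAX; }
    for (int j = 0; j < nv; ++j) {
      const double dx = q[0]-vx[j], dy = q[1]-vy[j], dz = q[2]-vz[j];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= neard[kCand - 1]) continue;
      int k = kCand - 1;
      while (k > 0 && neard[k - 1] > d2) {
        neard[k] = neard[k - 1]; nearv[k] = nearv[k - 1]; --k;
      }
      neard[k] = d2; nearv[k] = j;
    }
    cand.clear();
    for (int k = 0; k < kCand; ++k) {
      if (nearv[k] < 0) continue;
      const std::vector<int> &tris = inc[nearv[k]];
      cand.insert(cand.end(), tris.begin(), tris.end());
    }
    double bp[3] = {vx[nearv[0]], vy[nearv[0]], vz[nearv[0]]};
    double best = neard[0];
    int bestFace = inc[nearv[0]].empty() ? 0 : inc[nearv[0]][0];
    double out[3];
    for (size_t c = 0; c < cand.size(); ++c) {
      const int f = cand[c];
      const int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
      const double a[3] = {vx[ia], vy[ia], vz[ia]};
      const double b[3] = {vx[ib], vy[ib], vz[ib]};
      const double cc[3] = {vx[ic], vy[ic], vz[ic]};
      closestPointOnTriangle(q, a, b, cc, out);
      const double dx = q[0]-out[0], dy = q[1]-out[1], dz = q[2]-out[2];
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bp[0]=out[0]; bp[1]=out[1]; bp[2]=out[2]; bestFace = f; }
    }
    foot(i,0) = bp[0]; foot(i,1) = bp[1]; foot(i,2) = bp[2];
    dist[i] = std::sqrt(best);
    face[i] = bestFace + 1;
  }
  return List::create(_["foot"] = foot, _["dist"] = dist, _["face"] = face);
}
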
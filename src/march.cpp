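#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra over a regular grid. Each cell is split into six
// tetrahedra; surface vertices are placed on cell edges by linear
// interpolation of the scalar field at `level`, deduplicated per grid edge.
// Vertices are returned in 0-based voxel-index coordinates (caller scales to
// mm). A union-find over shared vertices keeps only the largest connected
// component when `largestOnly` is set.

namespace {
struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, IntegerVector dims, double level,
                             bool largestOnly = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  // the six tetrahedra of a cube (corner offsets 0..7, bit order x,y,z)
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
  };
  static const int cornerOff[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  std::unordered_map<unsigned long long, int> edgeVert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F; // flat triples, 0-based

  auto gridIndex = [&](int x, int y, int z) -> size_t {
    return (size_t)x * sx + (size_t)y * sy + (size_t)z * sz;
  };
  auto edgeVertex = [&](size_t g1, double v1, int x1, int y1, int z1,
                        size_t g2, double v2, int x2, int y2, int z2) -> int {
    if (g2 < g1) { std::swap(g1, g2); std::swap(v1, v2);
                   std::swap(x1, x2); std::swap(y1, y2); std::swap(z1, z2); }
    unsigned long long key = (unsigned long long)g1 * (unsigned long long)(sz * (size_t)nz) +
                             (unsigned long long)g2;
    std::unordered_map<unsigned long long, int>::iterator it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double t = (level - v1) / (v2 - v1);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = (int)VX.size();
    VX.push_back(x1 + t * (x2 - x1));
    VY.push_back(y1 + t * (y2 - y1));
    VZ.push_back(z1 + t * (z2 - z1));
    edgeVert[key] = id;
    return id;
  };

  for (int z = 0; z < nz - 1; ++z)
  for (int y = 0; y < ny - 1; ++y)
  for (int x = 0; x < nx - 1; ++x) {
    double cv[8]; size_t cg[8]; int cc[8][3];
    bool anyAbove = false, anyBelow = false;
    for (int c = 0; c < 8; ++c) {
      const int cx = x + cornerOff[c][0], cy = y + cornerOff[c][1], cz = z + cornerOff[c][2];
      cg[c] = gridIndex(cx, cy, cz);
      cv[c] = vol[cg[c]];
      cc[c][0] = cx; cc[c][1] = cy; cc[c][2] = cz;
      if (cv[c] >= level) anyAbove = true; else anyBelow = true;
    }
    if (!anyAbove || !anyBelow) continue;
    for (int t = 0; t < 6; ++t) {
      int vi[4]; bool in[4]; int nin = 0;
      for (int k = 0; k < 4; ++k) {
        vi[k] = tets[t][k];
        in[k] = cv[vi[k]] >= level;
        if (in[k]) ++nin;
      }
      if (nin == 0 || nin == 4) continue;
      // collect inside / outside corner slots
      int A[4], B[4]; int na = 0, nb = 0;
      for (int k = 0; k < 4; ++k) (in[k] ? A[na++] : B[nb++]) = vi[k];
      if (nin == 1 || nin == 3) {
        const int apex = (nin == 1) ? A[0] : B[0];
        const int *base = (nin == 1) ? B : A;
        int e[3];
        for (int k = 0; k < 3; ++k)
          e[k] = edgeVertex(cg[apex], cv[apex], cc[apex][0], cc[apex][1], cc[apex][2],
                            cg[base[k]], cv[base[k]], cc[base[k]][0], cc[base[k]][1], cc[base[k]][2]);
        F.push_back(e[0]); F.push_back(e[1]); F.push_back(e[2]);
      } else { // 2-2: a quad, split into two triangles
        int e00 = edgeVertex(cg[A[0]], cv[A[0]], cc[A[0]][0], cc[A[0]][1], cc[A[0]][2],
                             cg[B[0]], cv[B[0]], cc[B[0]][0], cc[B[0]][1], cc[B[0]][2]);
        int e01 = edgeVertex(cg[A[0]], cv[A[0]], cc[A[0]][0], cc[A[0]][1], cc[A[0]][2],
                             cg[B[1]], cv[B[1]], cc[B[1]][0], cc[B[1]][1], cc[B[1]][2]);
        int e10 = edgeVertex(cg[A[1]], cv[A[1]], cc[A[1]][0], cc[A[1]][1], cc[A[1]][2],
                             cg[B[0]], cv[B[0]], cc[B[0]][0], cc[B[0]][1], cc[B[0]][2]);
        int e11 = edgeVertex(cg[A[1]], cv[A[1]], cc[A[1]][0], cc[A[1]][1], cc[A[1]][2],
                             cg[B[1]], cv[B[1]], cc[B[1]][0], cc[B[1]][1], cc[B[1]][2]);
        F.push_back(e00); F.push_back(e01); F.push_back(e11);
        F.push_back(e00); F.push_back(e11); F.push_back(e10);
      }
    }
  }

  const int nv = (int)VX.size();
  const int nf = (int)F.size() / 3;
  if (nv == 0) return List::create(_["V"] = NumericMatrix(0, 3),
                                   _["F"] = IntegerMatrix(0, 3));

  std::vector<bool> keepV(nv, true);
  std::vector<bool> keepF(nf, true);
  if (largestOnly) {
    UF uf(nv);
    for (int f = 0; f < nf; ++f) {
      uf.unite(F[3*f], F[3*f+1]);
      uf.unite(F[3*f], F[3*f+2]);
    }
    std::unordered_map<int,int> compSize;
    for (int i = 0; i < nv; ++i) ++compSize[uf.find(i)];
    int bestRoot = -1, bestSize = -1;
    for (std::unordered_map<int,int>::iterator it = compSize.begin(); it != compSize.end(); ++it)
      if (it->second > bestSize) { bestSize = it->second; bestRoot = it->first; }
    for (int i = 0; i < nv; ++i) keepV[i] = (uf.find(i) == bestRoot);
    for (int f = 0; f < nf; ++f) keepF[f] = keepV[F[3*f]];
  }

  std::vector<int> remap(nv, -1);
  int nkeep = 0;
  for (int i = 0; i < nv; ++i) if (keepV[i]) remap[i] = nkeep++;
  NumericMatrix V(nkeep, 3);
  for (int i = 0; i < nv; ++i)
    if (keepV[i]) { V(remap[i],0) = VX[i]; V(remap[i],1) = VY[i]; V(remap[i],2) = VZ[i]; }
  int nfk = 0;
  for (int f = 0; f < nf; ++f) if (keepF[f]) ++nfk;
  IntegerMatrix Fm(nfk, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f)
    if (keepF[f]) {
      Fm(r,0) = remap[F[3*f]] + 1; Fm(r,1) = remap[F[3*f+1]] + 1; Fm(r,2) = remap[F[3*f+2]] + 1;
      ++r;
    }
  return List::create(_["V"] = V, _["F"] = Fm);
}
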
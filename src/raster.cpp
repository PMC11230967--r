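#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Perspective-correct z-buffer rasteriser. Vertices arrive already projected
// to pixel coordinates (u = column, v = row, origin at the top-left pixel
// centre) with their camera-frame z in mm. 1/z is interpolated linearly in
// screen space. Returns a height x width matrix of z-depths, 0 = background.
// Triangles with any vertex at or behind the camera are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_rasterize_zbuffer(NumericVector u, NumericVector v, NumericVector z,
                                    IntegerMatrix F, int width, int height) {
  NumericMatrix depth(height, width);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
    const double za = z[ia], zb = z[ib], zc = z[ic];
    if (za <= 0 || zb <= 0 || zc <= 0) continue;
    const double ua = u[ia], ub = u[ib], uc = u[ic];
    const double va = v[ia], vb = v[ib], vc = v[ic];
    const double area = (ub-ua)*(vc-va) - (uc-ua)*(vb-va);
    if (std::fabs(area) < 1e-12) continue;
    int u0 = (int)std::floor(std::fmin(ua, std::fmin(ub, uc)));
    int u1 = (int)std::ceil (std::fmax(ua, std::fmax(ub, uc)));
    int v0 = (int)std::floor(std::fmin(va, std::fmin(vb, vc)));
    int v1 = (int)std::ceil (std::fmax(va, std::fmax(vb, vc)));
    if (u0 < 0) u0 = 0; if (v0 < 0) v0 = 0;
    if (u1 > width - 1) u1 = width - 1;
    if (v1 > height - 1) v1 = height - 1;
    const double inva = 1.0 / area;
    const double wza = 1.0/za, wzb = 1.0/zb, wzc = 1.0/zc;
    for (int pv = v0; pv <= v1; ++pv) {
      for (int pu = u0; pu <= u1; ++pu) {
        const double px = (double)pu, py = (double)pv;
        double l0 = ((ub-px)*(vc-py) - (uc-px)*(vb-py)) * inva;
        double l1 = ((uc-px)*(va-py) - (ua-px)*(vc-py)) * inva;
        double l2 = 1.0 - l0 - l1;
        if (l0 < -1e-9 || l1 < -1e-9 || l2 < -1e-9) continue;
        const double invz = l0*wza + l1*wzb + l2*wzc;
        if (invz <= 0) continue;
        const double zd = 1.0 / invz;
        double &cell = depth(pv, pu);
        if (cell == 0.0 || zd < cell) cell = zd;
      }
    }
  }
  return depth;
}
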
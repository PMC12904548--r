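#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Trilinear affine resampling by inverse mapping.
//
// vol: input volume, column-major array with dim (d1, d2, d3) = (plane, row, col).
// out_dim: integer triple for the output grid.
// binv: 3x4 matrix mapping 0-based output indices (k, j, i) to continuous
//       0-based input indices; reads outside the input image return 0.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector out_dim, NumericMatrix binv) {
  const int d1 = dim_in[0], d2 = dim_in[1], d3 = dim_in[2];
  const int o1 = out_dim[0], o2 = out_dim[1], o3 = out_dim[2];
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  const double b11 = binv(0,0), b12 = binv(0,1), b13 = binv(0,2), b14 = binv(0,3);
  const double b21 = binv(1,0), b22 = binv(1,1), b23 = binv(1,2), b24 = binv(1,3);
  const double b31 = binv(2,0), b32 = binv(2,1), b33 = binv(2,2), b34 = binv(2,3);
  const double *v = vol.begin();
  double *o = out.begin();
  R_xlen_t pos = 0;
  for (int i = 0; i < o3; ++i) {
    for (int j = 0; j < o2; ++j) {
      // source position for (k = 0) plus per-k increment (b*1 column)
      double x0 = b12 * j + b13 * i + b14;
      double y0 = b22 * j + b23 * i + b24;
      double z0 = b32 * j + b33 * i + b34;
      for (int k = 0; k < o1; ++k, ++pos) {
        const double x = x0 + b11 * k;   // input plane coordinate
        const double y = y0 + b21 * k;   // input row coordinate
        const double z = z0 + b31 * k;   // input col coordinate
        if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
            x >= d1 || y >= d2 || z >= d3) continue;
        int xf = (int)std::floor(x), yf = (int)std::floor(y), zf = (int)std::floor(z);
        double fx = x - xf, fy = y - yf, fz = z - zf;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          int zi = zf + dz;
          if (zi < 0 || zi >= d3) continue;
          double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            int yi = yf + dy;
            if (yi < 0 || yi >= d2) continue;
            double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            for (int dx = 0; dx <= 1; ++dx) {
              int xi = xf + dx;
              if (xi < 0 || xi >= d1) continue;
              double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              acc += wx * wy * wz * v[xi + (R_xlen_t)d1 * (yi + (R_xlen_t)d2 * zi)];
            }
          }
        }
        o[pos] = acc;
      }
    }
  }
  return out;
}

// 3D connected-component labelling (6- or 26-connectivity) on a logical mask.
// Returns an integer volume of labels (0 = background), labelled in raster order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim_in,
                                   int connectivity = 6) {
  const int d1 = dim_in[0], d2 = dim_in[1], d3 = dim_in[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        off1.push_back(dx); off2.push_back(dy); off3.push_back(dz);
      }
  const size_t nn = off1.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int k = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int i = (int)(cur / ((R_xlen_t)d1 * d2));
      for (size_t q = 0; q < nn; ++q) {
        int k2 = k + off1[q], j2 = j + off2[q], i2 = i + off3[q];
        if (k2 < 0 || k2 >= d1 || j2 < 0 || j2 >= d2 || i2 < 0 || i2 >= d3) continue;
        R_xlen_t t = k2 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * i2);
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dim_in;
  return lab;
}
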
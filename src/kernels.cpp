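#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Low-level numeric kernels. All coordinates are 0-based voxel indices;
// displacement fields are stored (X, Y, Z, 3) with the component order
// (x, y, z) along the last margin.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Unfold 3x3x3 neighbourhoods (zero padding 1) into a patch matrix so the
// convolution reduces to one GEMM.  Rows run over output voxels with the x
// index fastest (matching R's column-major reshape); columns are ordered
// offset-fastest within each input channel, matching the R-flattened
// (3,3,3,Cin,Cout) weight layout.  zo0/zn select an output-z slab so large
// volumes can be convolved in bounded memory.
// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int stride, int zo0, int zn) {
  IntegerVector d = x.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2], C = d.size() > 3 ? d[3] : 1;
  const int Xo = (X - 1) / stride + 1, Yo = (Y - 1) / stride + 1;
  const double *px = x.begin();
  NumericMatrix out((R_xlen_t)Xo * Yo * zn, 27 * C);
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Xo * Yo * zn;
  for (int c = 0; c < C; ++c) {
    const double *pc = px + (R_xlen_t)c * X * Y * Z;
    for (int dz = 0; dz < 3; ++dz)
      for (int dy = 0; dy < 3; ++dy)
        for (int dx = 0; dx < 3; ++dx) {
          const int col = 27 * c + dx + 3 * dy + 9 * dz;
          double *pcol = po + (R_xlen_t)col * nrow;
          R_xlen_t r = 0;
          for (int zo = zo0; zo < zo0 + zn; ++zo) {
            const int zi = zo * stride + dz - 1;
            const bool zok = zi >= 0 && zi < Z;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride + dy - 1;
              const bool yok = yi >= 0 && yi < Y;
              if (!zok || !yok) {
                std::fill(pcol + r, pcol + r + Xo, 0.0);
                r += Xo;
                continue;
              }
              const double *line = pc + (R_xlen_t)(zi * Y + yi) * X;
              if (stride == 1) {
                // xi = xo + dx - 1: a shifted copy with zeroed border
                if (dx == 0) {
                  pcol[r] = 0.0;
                  std::memcpy(pcol + r + 1, line, (X - 1) * sizeof(double));
                } else if (dx == 1) {
                  std::memcpy(pcol + r, line, X * sizeof(double));
                } else {
                  std::memcpy(pcol + r, line + 1, (X - 1) * sizeof(double));
                  pcol[r + X - 1] = 0.0;
                }
                r += Xo;
              } else {
                for (int xo = 0; xo < Xo; ++xo) {
                  const int xi = xo * stride + dx - 1;
                  pcol[r++] = (xi >= 0 && xi < X) ? line[xi] : 0.0;
                }
              }
            }
          }
        }
  }
  return out;
}

// Adjoint of im2col3 (full volume): scatter-add a patch-space matrix back to
// the input grid.  Used for the input-gradient of a convolution.
// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix m, IntegerVector dims, int stride) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = (X - 1) / stride + 1, Yo = (Y - 1) / stride + 1,
            Zo = (Z - 1) / stride + 1;
  NumericVector out((R_xlen_t)X * Y * Z * C);
  out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  double *po = out.begin();
  const double *pm = m.begin();
  const R_xlen_t nrow = (R_xlen_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    double *pc = po + (R_xlen_t)c * X * Y * Z;
    for (int dz = 0; dz < 3; ++dz)
      for (int dy = 0; dy < 3; ++dy)
        for (int dx = 0; dx < 3; ++dx) {
          const int col = 27 * c + dx + 3 * dy + 9 * dz;
          const double *pcol = pm + (R_xlen_t)col * nrow;
          R_xlen_t r = 0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride + dz - 1;
            const bool zok = zi >= 0 && zi < Z;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride + dy - 1;
              if (!zok || yi < 0 || yi >= Y) { r += Xo; continue; }
              double *line = pc + (R_xlen_t)(zi * Y + yi) * X;
              if (stride == 1) {
                const int off = dx - 1;
                const int x0 = off < 0 ? 1 : 0;
                const int x1 = off > 0 ? Xo - 1 : Xo;
                const double *src = pcol + r;
                for (int xo = x0; xo < x1; ++xo) line[xo + off] += src[xo];
                r += Xo;
              } else {
                for (int xo = 0; xo < Xo; ++xo, ++r) {
                  const int xi = xo * stride + dx - 1;
                  if (xi >= 0 && xi < X) line[xi] += pcol[r];
                }
              }
            }
          }
        }
  }
  return out;
}

// Trilinear resampling of img at (grid + sign * u); sample coordinates are
// clamped to the volume boundary (border replication).
// [[Rcpp::export]]
NumericVector warp3(NumericVector img, NumericVector u, double sign) {
  IntegerVector d = img.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  const double *pi = img.begin(), *pu = u.begin();
  NumericVector out(N);
  out.attr("dim") = d;
  double *po = out.begin();
  R_xlen_t v = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++v) {
        double cx = x + sign * pu[v];
        double cy = y + sign * pu[v + N];
        double cz = z + sign * pu[v + 2 * N];
        if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
        if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
        if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
        const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                  z0 = (int)std::floor(cz);
        const int x1 = clampi(x0 + 1, 0, X - 1), y1 = clampi(y0 + 1, 0, Y - 1),
                  z1 = clampi(z0 + 1, 0, Z - 1);
        const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        #define IM(a, b, c) pi[(R_xlen_t)(a) + (R_xlen_t)X * ((b) + (R_xlen_t)Y * (c))]
        const double c00 = IM(x0, y0, z0) * (1 - fx) + IM(x1, y0, z0) * fx;
        const double c10 = IM(x0, y1, z0) * (1 - fx) + IM(x1, y1, z0) * fx;
        const double c01 = IM(x0, y0, z1) * (1 - fx) + IM(x1, y0, z1) * fx;
        const double c11 = IM(x0, y1, z1) * (1 - fx) + IM(x1, y1, z1) * fx;
        const double c0 = c00 * (1 - fy) + c10 * fy;
        const double c1 = c01 * (1 - fy) + c11 * fy;
        po[v] = c0 * (1 - fz) + c1 * fz;
      }
  return out;
}

// Gradient of warp3 with respect to the displacement field: for each voxel
// the spatial derivative of the trilinear interpolant at the sample point,
// times sign, times the incoming output gradient.  The derivative is zero in
// any direction whose coordinate was clamped outside the volume.
// [[Rcpp::export]]
NumericVector warp3_grad_field(NumericVector img, NumericVector u, double sign,
                               NumericVector gout) {
  IntegerVector d = img.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  const double *pi = img.begin(), *pu = u.begin(), *pg = gout.begin();
  NumericVector gu(3 * N);
  gu.attr("dim") = IntegerVector::create(X, Y, Z, 3);
  double *pgu = gu.begin();
  R_xlen_t v = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++v) {
        double cx = x + sign * pu[v];
        double cy = y + sign * pu[v + N];
        double cz = z + sign * pu[v + 2 * N];
        const bool inx = cx > 0 && cx < X - 1;
        const bool iny = cy > 0 && cy < Y - 1;
        const bool inz = cz > 0 && cz < Z - 1;
        if (cx < 0) cx = 0; if (cx > X - 1) cx = X - 1;
        if (cy < 0) cy = 0; if (cy > Y - 1) cy = Y - 1;
        if (cz < 0) cz = 0; if (cz > Z - 1) cz = Z - 1;
        const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                  z0 = (int)std::floor(cz);
        const int x1 = clampi(x0 + 1, 0, X - 1), y1 = clampi(y0 + 1, 0, Y - 1),
                  z1 = clampi(z0 + 1, 0, Z - 1);
        const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        const double g = pg[v] * sign;
        const double v000 = IM(x0, y0, z0), v100 = IM(x1, y0, z0);
        const double v010 = IM(x0, y1, z0), v110 = IM(x1, y1, z0);
        const double v001 = IM(x0, y0, z1), v101 = IM(x1, y0, z1);
        const double v011 = IM(x0, y1, z1), v111 = IM(x1, y1, z1);
        double dx = 0, dy = 0, dz = 0;
        if (inx)
          dx = ((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
               ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz;
        if (iny)
          dy = ((v010 - v000) * (1 - fx) + (v110 - v100) * fx) * (1 - fz) +
               ((v011 - v001) * (1 - fx) + (v111 - v101) * fx) * fz;
        if (inz)
          dz = ((v001 - v000) * (1 - fx) + (v101 - v100) * fx) * (1 - fy) +
               ((v011 - v010) * (1 - fx) + (v111 - v110) * fx) * fy;
        pgu[v] = g * dx;
        pgu[v + N] = g * dy;
        pgu[v + 2 * N] = g * dz;
        #undef IM
      }
  return gu;
}

static void boxsum_axis(const double *in, double *out, int n, int stride,
                        R_xlen_t nlines, const R_xlen_t *line0, int r) {
  for (R_xlen_t l = 0; l < nlines; ++l) {
    const double *p = in + line0[l];
    double *q = out + line0[l];
    double acc = 0;
    for (int i = 0; i <= r && i < n; ++i) acc += p[(R_xlen_t)i * stride];
    q[0] = acc;
    for (int i = 1; i < n; ++i) {
      const int add = i + r, del = i - r - 1;
      if (add < n) acc += p[(R_xlen_t)add * stride];
      if (del >= 0) acc -= p[(R_xlen_t)del * stride];
      q[(R_xlen_t)i * stride] = acc;
    }
  }
}

// Sum of x over the cube window of half-width r centred at each voxel,
// truncated at the volume border (separable sliding sums).
// [[Rcpp::export]]
NumericVector boxsum3(NumericVector x, int r) {
  IntegerVector d = x.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  NumericVector a = clone(x), b((R_xlen_t)X * Y * Z);
  b.attr("dim") = d;
  // x axis: lines start at x=0 for each (y,z)
  {
    std::vector<R_xlen_t> l0((R_xlen_t)Y * Z);
    R_xlen_t k = 0;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) l0[k++] = (R_xlen_t)X * (y + (R_xlen_t)Y * z);
    boxsum_axis(a.begin(), b.begin(), X, 1, (R_xlen_t)Y * Z, l0.data(), r);
  }
  {
    std::vector<R_xlen_t> l0((R_xlen_t)X * Z);
    R_xlen_t k = 0;
    for (int z = 0; z < Z; ++z)
      for (int x0 = 0; x0 < X; ++x0) l0[k++] = x0 + (R_xlen_t)X * Y * z;
    boxsum_axis(b.begin(), a.begin(), Y, X, (R_xlen_t)X * Z, l0.data(), r);
  }
  {
    std::vector<R_xlen_t> l0((R_xlen_t)X * Y);
    R_xlen_t k = 0;
    for (int y = 0; y < Y; ++y)
      for (int x0 = 0; x0 < X; ++x0) l0[k++] = x0 + (R_xlen_t)X * y;
    boxsum_axis(a.begin(), b.begin(), Z, X * Y, (R_xlen_t)X * Y, l0.data(), r);
  }
  return b;
}

static void gauss_axis(const double *in, double *out, int n, int stride,
                       R_xlen_t nlines, const R_xlen_t *line0,
                       const std::vector<double> &k, int r) {
  for (R_xlen_t l = 0; l < nlines; ++l) {
    const double *p = in + line0[l];
    double *q = out + line0[l];
    for (int i = 0; i < n; ++i) {
      double acc = 0, wsum = 0;
      const int j0 = std::max(0, i - r), j1 = std::min(n - 1, i + r);
      for (int j = j0; j <= j1; ++j) {
        const double w = k[j - i + r];
        acc += w * p[(R_xlen_t)j * stride];
        wsum += w;
      }
      q[(R_xlen_t)i * stride] = acc / wsum;
    }
  }
}

// Separable Gaussian smoothing with a truncated kernel (radius 3*sigma),
// renormalized at the border so flat fields stay flat.
// [[Rcpp::export]]
NumericVector gauss3(NumericVector x, double sigma) {
  if (sigma <= 0) return clone(x);
  IntegerVector d = x.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  NumericVector a = clone(x), b((R_xlen_t)X * Y * Z);
  b.attr("dim") = d;
  {
    std::vector<R_xlen_t> l0((R_xlen_t)Y * Z);
    R_xlen_t kk = 0;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) l0[kk++] = (R_xlen_t)X * (y + (R_xlen_t)Y * z);
    gauss_axis(a.begin(), b.begin(), X, 1, (R_xlen_t)Y * Z, l0.data(), k, r);
  }
  {
    std::vector<R_xlen_t> l0((R_xlen_t)X * Z);
    R_xlen_t kk = 0;
    for (int z = 0; z < Z; ++z)
      for (int x0 = 0; x0 < X; ++x0) l0[kk++] = x0 + (R_xlen_t)X * Y * z;
    gauss_axis(b.begin(), a.begin(), Y, X, (R_xlen_t)X * Z, l0.data(), k, r);
  }
  {
    std::vector<R_xlen_t> l0((R_xlen_t)X * Y);
    R_xlen_t kk = 0;
    for (int y = 0; y < Y; ++y)
      for (int x0 = 0; x0 < X; ++x0) l0[kk++] = x0 + (R_xlen_t)X * y;
    gauss_axis(a.begin(), b.begin(), Z, X * Y, (R_xlen_t)X * Y, l0.data(), k, r);
  }
  return b;
}
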
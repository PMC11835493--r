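#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic convolution kernel, a = -0.5 (Catmull-Rom). Shared by the renderer
// and the DIC refinement so both sides live in the same interpolation family.
static inline double cubicKernel(double t) {
  double at = std::fabs(t);
  if (at <= 1.0) return ((1.5 * at - 2.5) * at) * at + 1.0;
  if (at < 2.0)  return ((-0.5 * at + 2.5) * at - 4.0) * at + 2.0;
  return 0.0;
}

// img is column-major with h rows; pixel (x, y) = img[(size_t)x * h + y].
// Pixel centers at integer 0-based coordinates, (0,0) top-left.
// Valid where the full 4x4 stencil fits; NA outside.
static inline double bicubicAt(const double* img, int h, int w,
                               double x, double y, bool& ok) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 < 1 || x0 > w - 3 || y0 < 1 || y0 > h - 3) { ok = false; return NA_REAL; }
  double fx = x - x0, fy = y - y0;
  double wx[4], wy[4];
  wx[0] = cubicKernel(fx + 1.0); wx[1] = cubicKernel(fx);
  wx[2] = cubicKernel(fx - 1.0); wx[3] = cubicKernel(fx - 2.0);
  wy[0] = cubicKernel(fy + 1.0); wy[1] = cubicKernel(fy);
  wy[2] = cubicKernel(fy - 1.0); wy[3] = cubicKernel(fy - 2.0);
  double s = 0.0;
  for (int i = 0; i < 4; ++i) {
    const double* col = img + (size_t)(x0 + i - 1) * h + (y0 - 1);
    s += wx[i] * (wy[0] * col[0] + wy[1] * col[1] +
                  wy[2] * col[2] + wy[3] * col[3]);
  }
  ok = true;
  return s;
}

// [[Rcpp::export]]
NumericVector interpBicubicCpp(const NumericMatrix& img,
                               const NumericVector& x, const NumericVector& y) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* p = &img[0];
  int h = img.nrow(), w = img.ncol();
  bool ok;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i])) { out[i] = NA_REAL; continue; }
    out[i] = bicubicAt(p, h, w, x[i], y[i], ok);
  }
  return out;
}

// Integer-displacement ZNCC search. Status codes: 0 matched, 1 flat/low-variance
// reference subset, 2 no in-bounds candidate. Ties broken toward the smallest
// total displacement magnitude, then lexicographically on (dx, dy).
// Window sums of the target come from integral images; only the cross term
// is accumulated per candidate.
// [[Rcpp::export]]
List matchIntegerCpp(const NumericMatrix& ref, const NumericMatrix& tgt,
                     const NumericVector& cx, const NumericVector& cy,
                     int radius, int search,
                     const NumericVector& initdx, const NumericVector& initdy) {
  const int hR = ref.nrow(), wR = ref.ncol();
  const int hT = tgt.nrow(), wT = tgt.ncol();
  const double* pR = &ref[0];
  const double* pT = &tgt[0];
  const int n = cx.size();
  const int side = 2 * radius + 1;
  const int m = side * side;
  const int win = 2 * search + 1;
  NumericVector outdx(n), outdy(n), score(n);
  IntegerVector status(n);
  NumericMatrix nbhd(n, 9);
  std::vector<double> f(m);
  std::vector<double> sgrid(win * win);
  // integral images of tgt and tgt^2, (hT+1) x (wT+1), column-major
  std::vector<double> I1((size_t)(hT + 1) * (wT + 1), 0.0);
  std::vector<double> I2((size_t)(hT + 1) * (wT + 1), 0.0);
  const size_t hi = hT + 1;
  for (int x = 1; x <= wT; ++x) {
    const double* col = pT + (size_t)(x - 1) * hT;
    double c1 = 0.0, c2 = 0.0;
    for (int y = 1; y <= hT; ++y) {
      double v = col[y - 1];
      c1 += v; c2 += v * v;
      I1[(size_t)x * hi + y] = I1[(size_t)(x - 1) * hi + y] + c1;
      I2[(size_t)x * hi + y] = I2[(size_t)(x - 1) * hi + y] + c2;
    }
  }
  auto boxSum = [&](const std::vector<double>& I, int x0, int y0, int x1, int y1) {
    // inclusive pixel box [x0, x1] x [y0, y1]
    return I[(size_t)(x1 + 1) * hi + (y1 + 1)] - I[(size_t)x0 * hi + (y1 + 1)]
         - I[(size_t)(x1 + 1) * hi + y0] + I[(size_t)x0 * hi + y0];
  };

  for (int p = 0; p < n; ++p) {
    int x0 = (int)std::lround(cx[p]), y0 = (int)std::lround(cy[p]);
    int idx0 = (int)std::lround(initdx[p]), idy0 = (int)std::lround(initdy[p]);
    for (int j = 0; j < 9; ++j) nbhd(p, j) = NA_REAL;
    outdx[p] = idx0; outdy[p] = idy0; score[p] = 0.0;
    if (x0 - radius < 0 || x0 + radius >= wR || y0 - radius < 0 || y0 + radius >= hR) {
      status[p] = 2; continue;
    }
    double fsum = 0.0;
    int k = 0;
    for (int dx = -radius; dx <= radius; ++dx) {
      const double* col = pR + (size_t)(x0 + dx) * hR + (y0 - radius);
      for (int dy = 0; dy < side; ++dy, ++k) {
        f[k] = col[dy];
        fsum += f[k];
      }
    }
    double fmean = fsum / m, fss = 0.0;
    for (k = 0; k < m; ++k) { f[k] -= fmean; fss += f[k] * f[k]; }
    double fnorm = std::sqrt(fss);
    if (fnorm < 1e-12) { status[p] = 1; continue; }

    std::fill(sgrid.begin(), sgrid.end(), NA_REAL);
    double best = -2.0;
    double bestmag2 = 0.0;
    int bdx = 0, bdy = 0;
    bool any = false;
    for (int sy = -search; sy <= search; ++sy) {
      for (int sx = -search; sx <= search; ++sx) {
        int tx = x0 + idx0 + sx, ty = y0 + idy0 + sy;
        if (tx - radius < 0 || tx + radius >= wT || ty - radius < 0 || ty + radius >= hT)
          continue;
        double cross = 0.0;
        k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          const double* col = pT + (size_t)(tx + dx) * hT + (ty - radius);
          for (int dy = 0; dy < side; ++dy, ++k)
            cross += f[k] * col[dy];
        }
        double gsum = boxSum(I1, tx - radius, ty - radius, tx + radius, ty + radius);
        double gss = boxSum(I2, tx - radius, ty - radius, tx + radius, ty + radius);
        double gvar = gss - gsum * gsum / m;
        double z = (gvar < 1e-20) ? 0.0 : cross / (fnorm * std::sqrt(gvar));
        sgrid[(sy + search) * win + (sx + search)] = z;
        int tdx = idx0 + sx, tdy = idy0 + sy;
        double mag2 = (double)tdx * tdx + (double)tdy * tdy;
        bool better;
        if (!any) better = true;
        else if (z > best + 1e-12) better = true;
        else if (z < best - 1e-12) better = false;
        else if (mag2 < bestmag2 - 1e-9) better = true;
        else if (mag2 > bestmag2 + 1e-9) better = false;
        else if (tdx != bdx) better = tdx < bdx;
        else better = tdy < bdy;
        if (better) { best = z; bdx = tdx; bdy = tdy; bestmag2 = mag2; any = true; }
      }
    }
    if (!any) { status[p] = 2; continue; }
    outdx[p] = bdx; outdy[p] = bdy; score[p] = best; status[p] = 0;
    int bsx = bdx - idx0 + search, bsy = bdy - idy0 + search;
    for (int j = -1; j <= 1; ++j)
      for (int i = -1; i <= 1; ++i) {
        int xx = bsx + i, yy = bsy + j;
        if (xx >= 0 && xx < win && yy >= 0 && yy < win)
          nbhd(p, (j + 1) * 3 + (i + 1)) = sgrid[yy * win + xx];
      }
  }
  return List::create(_["dx"] = outdx, _["dy"] = outdy, _["score"] = score,
                      _["status"] = status, _["nbhd"] = nbhd);
}

// Gaussian elimination with partial pivoting for the 6x6 IC-GN Hessian.
static bool solve6(double A[6][6], double b[6], double x[6]) {
  for (int col = 0; col < 6; ++col) {
    int pr = col;
    double pv = std::fabs(A[col][col]);
    for (int r = col + 1; r < 6; ++r)
      if (std::fabs(A[r][col]) > pv) { pv = std::fabs(A[r][col]); pr = r; }
    if (pv < 1e-14) return false;
    if (pr != col) {
      for (int c = 0; c < 6; ++c) std::swap(A[col][c], A[pr][c]);
      std::swap(b[col], b[pr]);
    }
    for (int r = col + 1; r < 6; ++r) {
      double fac = A[r][col] / A[col][col];
      for (int c = col; c < 6; ++c) A[r][c] -= fac * A[col][c];
      b[r] -= fac * b[col];
    }
  }
  for (int r = 5; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < 6; ++c) s -= A[r][c] * x[c];
    x[r] = s / A[r][r];
  }
  return true;
}

// Inverse-compositional Gauss-Newton with a first-order (affine) subset shape
// function and bicubic target interpolation. Parameter order per point:
// (u, ux, uy, v, vx, vy). Convergence when the update norm, with the gradient
// terms scaled by the subset radius, drops below tol (in px).
// Status: 0 converged, 1 flat reference subset, 2 out of bounds, 3 diverged
// (iteration cap or singular Hessian).
// [[Rcpp::export]]
List refineICGNCpp(const NumericMatrix& ref, const NumericMatrix& tgt,
                   const NumericVector& cx, const NumericVector& cy,
                   const NumericMatrix& pinit, int radius, int maxIter, double tol) {
  const int hR = ref.nrow(), wR = ref.ncol();
  const int hT = tgt.nrow(), wT = tgt.ncol();
  const double* pR = &ref[0];
  const double* pT = &tgt[0];
  const int n = cx.size();
  const int side = 2 * radius + 1;
  const int m = side * side;
  NumericMatrix pout(n, 6);
  NumericVector score(n);
  IntegerVector iters(n), status(n);
  std::vector<double> f(m), J0(m), J3(m), g(m);
  // J columns 1,2,4,5 are gx*dx, gx*dy, gy*dx, gy*dy: derived from J0/J3 on
  // the fly using the dx/dy of the pixel
  std::vector<int> DX(m), DY(m);
  {
    int k = 0;
    for (int dx = -radius; dx <= radius; ++dx)
      for (int dy = -radius; dy <= radius; ++dy, ++k) { DX[k] = dx; DY[k] = dy; }
  }

  for (int p = 0; p < n; ++p) {
    int x0 = (int)std::lround(cx[p]), y0 = (int)std::lround(cy[p]);
    for (int k2 = 0; k2 < 6; ++k2) pout(p, k2) = pinit(p, k2);
    score[p] = NA_REAL; iters[p] = 0;
    if (x0 - radius - 1 < 0 || x0 + radius + 1 >= wR ||
        y0 - radius - 1 < 0 || y0 + radius + 1 >= hR) {
      status[p] = 2; continue;
    }
    // reference subset, gradients, Hessian (column-contiguous walk)
    double fsum = 0.0;
    int k = 0;
    for (int dx = -radius; dx <= radius; ++dx) {
      const double* col  = pR + (size_t)(x0 + dx) * hR + (y0 - radius);
      const double* colL = pR + (size_t)(x0 + dx - 1) * hR + (y0 - radius);
      const double* colR = pR + (size_t)(x0 + dx + 1) * hR + (y0 - radius);
      for (int dy = 0; dy < side; ++dy, ++k) {
        f[k] = col[dy];
        fsum += f[k];
        J0[k] = 0.5 * (colR[dy] - colL[dy]);          // d/dx
        J3[k] = 0.5 * (col[dy + 1] - col[dy - 1]);    // d/dy (in-column)
      }
    }
    double fmean = fsum / m, fss = 0.0;
    for (k = 0; k < m; ++k) { f[k] -= fmean; fss += f[k] * f[k]; }
    double fnorm = std::sqrt(fss);
    if (fnorm < 1e-12) { status[p] = 1; continue; }
    double H0[6][6];
    for (int a = 0; a < 6; ++a)
      for (int b2 = 0; b2 < 6; ++b2) H0[a][b2] = 0.0;
    for (k = 0; k < m; ++k) {
      const double jx = J0[k], jy = J3[k];
      const double dx = DX[k], dy = DY[k];
      const double Jk[6] = {jx, jx * dx, jx * dy, jy, jy * dx, jy * dy};
      for (int a = 0; a < 6; ++a)
        for (int b2 = a; b2 < 6; ++b2) H0[a][b2] += Jk[a] * Jk[b2];
    }
    for (int a = 0; a < 6; ++a)
      for (int b2 = 0; b2 < a; ++b2) H0[a][b2] = H0[b2][a];

    double a11 = 1.0 + pinit(p, 1), a12 = pinit(p, 2), a13 = pinit(p, 0);
    double a21 = pinit(p, 4), a22 = 1.0 + pinit(p, 5), a23 = pinit(p, 3);
    int st = 3;
    int it = 0;
    for (it = 0; it < maxIter; ++it) {
      bool oob = false, okflag;
      double gsum = 0.0;
      for (k = 0; k < m; ++k) {
        double X = x0 + a11 * DX[k] + a12 * DY[k] + a13;
        double Y = y0 + a21 * DX[k] + a22 * DY[k] + a23;
        g[k] = bicubicAt(pT, hT, wT, X, Y, okflag);
        if (!okflag) { oob = true; break; }
        gsum += g[k];
      }
      if (oob) { st = 2; break; }
      double gmean = gsum / m, gss = 0.0;
      for (k = 0; k < m; ++k) { g[k] -= gmean; gss += g[k] * g[k]; }
      double gnorm = std::sqrt(gss);
      if (gnorm < 1e-12) { st = 3; break; }
      double ratio = fnorm / gnorm;
      double b[6] = {0, 0, 0, 0, 0, 0};
      for (k = 0; k < m; ++k) {
        double e = f[k] - ratio * g[k];
        const double jx = J0[k], jy = J3[k];
        const double dx = DX[k], dy = DY[k];
        b[0] += jx * e; b[1] += jx * dx * e; b[2] += jx * dy * e;
        b[3] += jy * e; b[4] += jy * dx * e; b[5] += jy * dy * e;
      }
      double A[6][6];
      for (int a = 0; a < 6; ++a)
        for (int c = 0; c < 6; ++c) A[a][c] = H0[a][c];
      double dp[6];
      if (!solve6(A, b, dp)) { st = 3; break; }
      for (int a = 0; a < 6; ++a) dp[a] = -dp[a];
      double d11 = 1.0 + dp[1], d12 = dp[2], d13 = dp[0];
      double d21 = dp[4], d22 = 1.0 + dp[5], d23 = dp[3];
      double det = d11 * d22 - d12 * d21;
      if (std::fabs(det) < 1e-12) { st = 3; break; }
      double i11 = d22 / det, i12 = -d12 / det;
      double i21 = -d21 / det, i22 = d11 / det;
      double i13 = -(i11 * d13 + i12 * d23);
      double i23 = -(i21 * d13 + i22 * d23);
      double n11 = a11 * i11 + a12 * i21;
      double n12 = a11 * i12 + a12 * i22;
      double n13 = a11 * i13 + a12 * i23 + a13;
      double n21 = a21 * i11 + a22 * i21;
      double n22 = a21 * i12 + a22 * i22;
      double n23 = a21 * i13 + a22 * i23 + a23;
      a11 = n11; a12 = n12; a13 = n13; a21 = n21; a22 = n22; a23 = n23;
      double nrm = std::sqrt(dp[0] * dp[0] + dp[3] * dp[3] +
                             (double)radius * radius * (dp[1] * dp[1] + dp[2] * dp[2] +
                                                        dp[4] * dp[4] + dp[5] * dp[5]));
      if (nrm < tol) { st = 0; ++it; break; }
    }
    iters[p] = it;
    pout(p, 0) = a13; pout(p, 1) = a11 - 1.0; pout(p, 2) = a12;
    pout(p, 3) = a23; pout(p, 4) = a21; pout(p, 5) = a22 - 1.0;
    status[p] = st;
    if (st == 0 || st == 3) {
      bool oob = false, okflag;
      double gsum = 0.0;
      for (k = 0; k < m; ++k) {
        double X = x0 + a11 * DX[k] + a12 * DY[k] + a13;
        double Y = y0 + a21 * DX[k] + a22 * DY[k] + a23;
        g[k] = bicubicAt(pT, hT, wT, X, Y, okflag);
        if (!okflag) { oob = true; break; }
        gsum += g[k];
      }
      if (!oob) {
        double gmean = gsum / m, gss = 0.0, cross = 0.0;
        for (k = 0; k < m; ++k) {
          double gc = g[k] - gmean;
          gss += gc * gc; cross += f[k] * gc;
        }
        if (gss > 1e-20) score[p] = cross / (fnorm * std::sqrt(gss));
        else score[p] = 0.0;
      } else if (st == 0) {
        status[p] = 2;
      }
    }
  }
  return List::create(_["p"] = pout, _["score"] = score,
                      _["iters"] = iters, _["status"] = status);
}
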
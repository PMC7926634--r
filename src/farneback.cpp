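// Dense two-frame optical flow by polynomial expansion (Farneback).
//
// Each pixel neighbourhood of a frame is approximated by a quadratic
//   f(x, y) ~ c + bx*x + by*y + axx*x^2 + ayy*y^2 + axy*x*y
// via Gaussian-weighted least squares (separable moment filters).  The
// displacement field is recovered from the coefficient changes between the
// two frames, iteratively refined over a coarse-to-fine image pyramid with
// local averaging of the normal-equation matrices.
//
// Conventions: images are R matrices (column-major, H x W); x = column
// offset, y = row offset (y grows downward); borders handled by replication.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Img {
  int H = 0, W = 0;
  std::vector<double> v;
  Img() = default;
  Img(int h, int w) : H(h), W(w), v((size_t)h * w, 0.0) {}
  inline double at(int r, int c) const { return v[(size_t)c * H + r]; }
  inline double& at(int r, int c) { return v[(size_t)c * H + r]; }
};

inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

Img fromMatrix(const NumericMatrix& m) {
  Img im(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), im.v.begin());
  return im;
}

NumericMatrix toMatrix(const Img& im) {
  NumericMatrix m(im.H, im.W);
  std::copy(im.v.begin(), im.v.end(), m.begin());
  return m;
}

std::vector<double> gaussKernel(int n, double sigma) {
  std::vector<double> g(2 * n + 1);
  double s = 0.0;
  for (int k = -n; k <= n; ++k) {
    g[k + n] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += g[k + n];
  }
  for (double& x : g) x /= s;
  return g;
}

// Quadratic expansion coefficient planes.
struct PolyCoef {
  Img c, bx, by, axx, ayy, axy;
  PolyCoef() = default;
  PolyCoef(int h, int w) : c(h, w), bx(h, w), by(h, w),
                           axx(h, w), ayy(h, w), axy(h, w) {}
};

// Gaussian-weighted moments by separable correlation with edge replication,
// then an analytic solve of the (separable) normal equations.
PolyCoef polyExpansion(const Img& f, int n, double sigma) {
  const int H = f.H, W = f.W;
  std::vector<double> g = gaussKernel(n, sigma);
  double s2 = 0.0, s4 = 0.0;
  for (int k = -n; k <= n; ++k) {
    s2 += g[k + n] * k * k;
    s4 += g[k + n] * k * k * k * k;
  }
  const double denomA = s4 - s2 * s2;  // > 0 for n >= 1

  // vertical pass: t0 = <f>, t1 = <y f>, t2 = <y^2 f> along rows
  Img t0(H, W), t1(H, W), t2(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double a0 = 0.0, a1 = 0.0, a2 = 0.0;
      for (int k = -n; k <= n; ++k) {
        double val = f.at(clampi(r + k, 0, H - 1), c) * g[k + n];
        a0 += val;
        a1 += val * k;
        a2 += val * k * k;
      }
      t0.at(r, c) = a0;
      t1.at(r, c) = a1;
      t2.at(r, c) = a2;
    }
  }

  PolyCoef P(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m00 = 0, m10 = 0, m20 = 0, m01 = 0, m11 = 0, m02 = 0;
      for (int j = -n; j <= n; ++j) {
        int cc = clampi(c + j, 0, W - 1);
        double w = g[j + n];
        double u0 = t0.at(r, cc), u1 = t1.at(r, cc), u2 = t2.at(r, cc);
        m00 += w * u0;
        m10 += w * j * u0;
        m20 += w * j * j * u0;
        m01 += w * u1;
        m11 += w * j * u1;
        m02 += w * u2;
      }
      double axx = (m20 - s2 * m00) / denomA;
      double ayy = (m02 - s2 * m00) / denomA;
      P.bx.at(r, c) = m10 / s2;
      P.by.at(r, c) = m01 / s2;
      P.axy.at(r, c) = m11 / (s2 * s2);
      P.axx.at(r, c) = axx;
      P.ayy.at(r, c) = ayy;
      P.c.at(r, c) = m00 - s2 * (axx + ayy);
    }
  }
  return P;
}

inline double bilerp(const Img& im, double fy, double fx) {
  fx = std::min(std::max(fx, 0.0), (double)im.W - 1);
  fy = std::min(std::max(fy, 0.0), (double)im.H - 1);
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
  int x1 = std::min(x0 + 1, im.W - 1), y1 = std::min(y0 + 1, im.H - 1);
  double ax = fx - x0, ay = fy - y0;
  return (1 - ay) * ((1 - ax) * im.at(y0, x0) + ax * im.at(y0, x1)) +
         ay * ((1 - ax) * im.at(y1, x0) + ax * im.at(y1, x1));
}

// separable box blur with edge replication (window = 2*m + 1)
void boxBlur(Img& im, int m) {
  if (m <= 0) return;
  const int H = im.H, W = im.W;
  const double norm = 1.0 / (2 * m + 1);
  Img tmp(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int k = -m; k <= m; ++k) s += im.at(clampi(r + k, 0, H - 1), c);
      tmp.at(r, c) = s * norm;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int k = -m; k <= m; ++k) s += tmp.at(r, clampi(c + k, 0, W - 1));
      im.at(r, c) = s * norm;
    }
}

void gaussBlur(Img& im, double sigma) {
  if (sigma <= 0) return;
  int n = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> g = gaussKernel(n, sigma);
  const int H = im.H, W = im.W;
  Img tmp(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int k = -n; k <= n; ++k)
        s += g[k + n] * im.at(clampi(r + k, 0, H - 1), c);
      tmp.at(r, c) = s;
    }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int k = -n; k <= n; ++k)
        s += g[k + n] * tmp.at(r, clampi(c + k, 0, W - 1));
      im.at(r, c) = s;
    }
}

Img resizeBilinear(const Img& im, int Hn, int Wn) {
  Img out(Hn, Wn);
  double sy = (double)im.H / Hn, sx = (double)im.W / Wn;
  for (int c = 0; c < Wn; ++c)
    for (int r = 0; r < Hn; ++r) {
      double fy = (r + 0.5) * sy - 0.5;
      double fx = (c + 0.5) * sx - 0.5;
      out.at(r, c) = bilerp(im, fy, fx);
    }
  return out;
}

// One Farneback refinement: given expansions of both frames and a prior
// displacement, rebuild the locally averaged normal equations and solve.
void updateFlow(const PolyCoef& P1, const PolyCoef& P2,
                Img& dx, Img& dy, int smooth) {
  const int H = dx.H, W = dx.W;
  Img G11(H, W), G12(H, W), G22(H, W), h1(H, W), h2(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double u = dx.at(r, c), v = dy.at(r, c);
      double fx = std::min(std::max(c + u, 0.0), (double)W - 1);
      double fy = std::min(std::max(r + v, 0.0), (double)H - 1);
      int x0 = (int)fx, y0 = (int)fy;
      int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      double ax = fx - x0, ay = fy - y0;
      double w00 = (1 - ay) * (1 - ax), w01 = (1 - ay) * ax;
      double w10 = ay * (1 - ax), w11 = ay * ax;
      size_t i00 = (size_t)x0 * H + y0, i01 = (size_t)x1 * H + y0;
      size_t i10 = (size_t)x0 * H + y1, i11 = (size_t)x1 * H + y1;
      auto samp = [&](const Img& im) {
        return w00 * im.v[i00] + w01 * im.v[i01] +
               w10 * im.v[i10] + w11 * im.v[i11];
      };
      double a11 = 0.5 * (P1.axx.at(r, c) + samp(P2.axx));
      double a22 = 0.5 * (P1.ayy.at(r, c) + samp(P2.ayy));
      double a12 = 0.25 * (P1.axy.at(r, c) + samp(P2.axy));
      double db1 = -0.5 * (samp(P2.bx) - P1.bx.at(r, c)) +
                   a11 * u + a12 * v;
      double db2 = -0.5 * (samp(P2.by) - P1.by.at(r, c)) +
                   a12 * u + a22 * v;
      G11.at(r, c) = a11 * a11 + a12 * a12;
      G12.at(r, c) = a12 * (a11 + a22);
      G22.at(r, c) = a12 * a12 + a22 * a22;
      h1.at(r, c) = a11 * db1 + a12 * db2;
      h2.at(r, c) = a12 * db1 + a22 * db2;
    }
  }
  int m = smooth / 2;
  boxBlur(G11, m); boxBlur(G12, m); boxBlur(G22, m);
  boxBlur(h1, m); boxBlur(h2, m);
  const double maxDisp = 0.45 * std::max(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double g11 = G11.at(r, c), g12 = G12.at(r, c), g22 = G22.at(r, c);
      double det = g11 * g22 - g12 * g12;
      double tr = g11 + g22;
      // ill-conditioned normal equations (flat or aperture-limited patch):
      // keep the prior displacement instead of amplifying noise
      if (det > 1e-300 && det > 1e-6 * tr * tr) {
        double u = (g22 * h1.at(r, c) - g12 * h2.at(r, c)) / det;
        double v = (-g12 * h1.at(r, c) + g11 * h2.at(r, c)) / det;
        u = std::min(std::max(u, -maxDisp), maxDisp);
        v = std::min(std::max(v, -maxDisp), maxDisp);
        dx.at(r, c) = u;
        dy.at(r, c) = v;
      }
    }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".fb_poly_exp")]]
List fb_poly_exp(NumericMatrix image, int window, double sigma) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  int n = window / 2;
  PolyCoef P = polyExpansion(fromMatrix(image), n, sigma);
  return List::create(
      _["c"] = toMatrix(P.c), _["bx"] = toMatrix(P.bx), _["by"] = toMatrix(P.by),
      _["axx"] = toMatrix(P.axx), _["ayy"] = toMatrix(P.ayy),
      _["axy"] = toMatrix(P.axy));
}

//' @noRd
// [[Rcpp::export(name = ".fb_dense_flow")]]
List fb_dense_flow(NumericMatrix prev, NumericMatrix nxt, int window,
                   double sigma, int levels, double pyr_scale, int iterations,
                   int smoothing) {
  if (prev.nrow() != nxt.nrow() || prev.ncol() != nxt.ncol())
    stop("frame shapes differ");
  if (pyr_scale <= 0 || pyr_scale >= 1) stop("pyramid scale must be in (0,1)");
  if (window < 3 || window % 2 == 0) stop("window must be odd >= 3");
  const int n = window / 2;

  Img f1 = fromMatrix(prev), f2 = fromMatrix(nxt);
  const int H = f1.H, W = f1.W;

  // build pyramids (level 0 = full resolution); stop when frames get tiny
  std::vector<Img> pyr1{f1}, pyr2{f2};
  // anti-alias blur before each decimation; deliberately strong so that
  // texture near the coarse-level Nyquist limit is suppressed rather than
  // aliased into spurious motion
  const double blurSigma = 0.8 * std::sqrt(1.0 / (pyr_scale * pyr_scale) - 1.0);
  // a level only carries information if it can hold a few expansion windows;
  // smaller levels produce confident nonsense that poisons finer levels
  const int minDim = std::max(6, 2 * window);
  for (int lev = 1; lev < levels; ++lev) {
    int Hn = (int)std::lround(pyr1.back().H * pyr_scale);
    int Wn = (int)std::lround(pyr1.back().W * pyr_scale);
    if (Hn < minDim || Wn < minDim) break;
    Img b1 = pyr1.back(), b2 = pyr2.back();
    gaussBlur(b1, blurSigma);
    gaussBlur(b2, blurSigma);
    pyr1.push_back(resizeBilinear(b1, Hn, Wn));
    pyr2.push_back(resizeBilinear(b2, Hn, Wn));
  }

  Img dx, dy;
  for (int lev = (int)pyr1.size() - 1; lev >= 0; --lev) {
    const Img& a = pyr1[lev];
    const Img& b = pyr2[lev];
    if (lev == (int)pyr1.size() - 1) {
      dx = Img(a.H, a.W);
      dy = Img(a.H, a.W);
    } else {
      double rx = (double)a.W / dx.W, ry = (double)a.H / dx.H;
      Img ndx = resizeBilinear(dx, a.H, a.W);
      Img ndy = resizeBilinear(dy, a.H, a.W);
      for (double& x : ndx.v) x *= rx;
      for (double& x : ndy.v) x *= ry;
      dx = std::move(ndx);
      dy = std::move(ndy);
    }
    PolyCoef P1 = polyExpansion(a, n, sigma);
    PolyCoef P2 = polyExpansion(b, n, sigma);
    for (int it = 0; it < iterations; ++it)
      updateFlow(P1, P2, dx, dy, smoothing);
  }

  (void)H; (void)W;
  return List::create(_["dx"] = toMatrix(dx), _["dy"] = toMatrix(dy));
}
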
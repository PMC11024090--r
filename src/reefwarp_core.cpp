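#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of a single-channel matrix at (x = col, y = row), 1-based
// pixel-centre coordinates. Returns `fill` outside [1,W]x[1,H].
static inline double sample_bilinear(const double* img, int H, int W,
                                     double x, double y, double fill) {
  if (x < 1.0 || x > (double)W || y < 1.0 || y > (double)H) return fill;
  int x0 = (int)std::floor(x); int y0 = (int)std::floor(y);
  if (x0 >= W) x0 = W - 1;
  if (y0 >= H) y0 = H - 1;
  int x1 = x0 + 1, y1 = y0 + 1;
  double fx = x - x0, fy = y - y0;
  // column-major: img[(col-1)*H + (row-1)]
  double v00 = img[(x0 - 1) * H + (y0 - 1)];
  double v10 = img[(x1 - 1) * H + (y0 - 1)];
  double v01 = img[(x0 - 1) * H + (y1 - 1)];
  double v11 = img[(x1 - 1) * H + (y1 - 1)];
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Warp an H x W x C image by the inverse homography Hinv (maps destination
// pixel -> source pixel). Returns list(img = outH x outW x C array, mask).
// [[Rcpp::export]]
List warp_homography_cpp(NumericVector img, IntegerVector dims,
                         NumericMatrix Hinv, int outW, int outH,
                         double fill) {
  int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  NumericVector out(outH * (R_xlen_t)outW * C, fill);
  LogicalMatrix mask(outH, outW);
  double h11 = Hinv(0, 0), h12 = Hinv(0, 1), h13 = Hinv(0, 2);
  double h21 = Hinv(1, 0), h22 = Hinv(1, 1), h23 = Hinv(1, 2);
  double h31 = Hinv(2, 0), h32 = Hinv(2, 1), h33 = Hinv(2, 2);
  const double* src = img.begin();
  for (int xo = 1; xo <= outW; ++xo) {
    for (int yo = 1; yo <= outH; ++yo) {
      double den = h31 * xo + h32 * yo + h33;
      if (std::fabs(den) < 1e-12) continue;
      double xs = (h11 * xo + h12 * yo + h13) / den;
      double ys = (h21 * xo + h22 * yo + h23) / den;
      bool ok = xs >= 1.0 && xs <= (double)W && ys >= 1.0 && ys <= (double)H;
      mask(yo - 1, xo - 1) = ok;
      if (!ok) continue;
      for (int c = 0; c < C; ++c) {
        out[(R_xlen_t)c * outH * outW + (xo - 1) * outH + (yo - 1)] =
          sample_bilinear(src + (R_xlen_t)c * H * W, H, W, xs, ys, fill);
      }
    }
  }
  out.attr("dim") = C > 1 ? IntegerVector::create(outH, outW, C)
                          : IntegerVector::create(outH, outW);
  return List::create(_["img"] = out, _["mask"] = mask);
}

// Generic remap: sample img at (xs, ys) given per output pixel (column-major
// over outH x outW). Used by lens undistortion.
// [[Rcpp::export]]
List remap_bilinear_cpp(NumericVector img, IntegerVector dims,
                        NumericVector xs, NumericVector ys,
                        int outW, int outH, double fill) {
  int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  NumericVector out(outH * (R_xlen_t)outW * C, fill);
  LogicalMatrix mask(outH, outW);
  const double* src = img.begin();
  for (R_xlen_t i = 0; i < (R_xlen_t)outH * outW; ++i) {
    double x = xs[i], y = ys[i];
    bool ok = x >= 1.0 && x <= (double)W && y >= 1.0 && y <= (double)H;
    mask[i] = ok;
    if (!ok) continue;
    for (int c = 0; c < C; ++c)
      out[(R_xlen_t)c * outH * outW + i] =
        sample_bilinear(src + (R_xlen_t)c * H * W, H, W, x, y, fill);
  }
  out.attr("dim") = C > 1 ? IntegerVector::create(outH, outW, C)
                          : IntegerVector::create(outH, outW);
  return List::create(_["img"] = out, _["mask"] = mask);
}

// Canny hysteresis: keep weak edge pixels 8-connected to a strong pixel.
// [[Rcpp::export]]
IntegerMatrix hysteresis_cpp(IntegerMatrix strong, IntegerMatrix weak) {
  int H = strong.nrow(), W = strong.ncol();
  IntegerMatrix out(H, W);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (strong(r, c)) { out(r, c) = 1; q.push(std::make_pair(r, c)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        int r = p.first + dr, c = p.second + dc;
        if (r < 0 || r >= H || c < 0 || c >= W) continue;
        if (!out(r, c) && weak(r, c)) { out(r, c) = 1; q.push(std::make_pair(r, c)); }
      }
    }
  }
  return out;
}

// Probabilistic Hough transform, after Matas et al.: visit edge points in the
// supplied (seeded) order, vote, and when a point's best bin reaches
// `threshold`, walk along that direction gathering a segment (gap-tolerant),
// un-voting consumed points. Angles theta index k = 0..nTheta-1 correspond to
// theta = k * pi / nTheta (line normal angle).
// [[Rcpp::export]]
NumericMatrix hough_prob_cpp(IntegerVector pr, IntegerVector pc,
                             int H, int W, int nTheta, int threshold,
                             int minLen, int maxGap, IntegerVector order) {
  int n = pr.size();
  if (n == 0) return NumericMatrix(0, 4);
  double rhoMax = std::sqrt((double)H * H + (double)W * W);
  int nRho = (int)(2.0 * rhoMax) + 3;
  std::vector<int> acc((size_t)nTheta * nRho, 0);
  std::vector<double> cosT(nTheta), sinT(nTheta);
  for (int k = 0; k < nTheta; ++k) {
    double th = M_PI * k / nTheta;
    cosT[k] = std::cos(th); sinT[k] = std::sin(th);
  }
  // presence grid (1-based coords in pr/pc)
  std::vector<signed char> mask((size_t)H * W, 0);
  for (int i = 0; i < n; ++i) mask[(size_t)(pc[i] - 1) * H + (pr[i] - 1)] = 1;
  std::vector<std::pair<double, double> > segs;
  std::vector<double> segd;
  for (int oi = 0; oi < n; ++oi) {
    int i = order[oi] - 1;
    int x = pc[i], y = pr[i];
    if (!mask[(size_t)(x - 1) * H + (y - 1)]) continue;  // consumed
    // vote
    int bestK = -1, bestV = 0;
    for (int k = 0; k < nTheta; ++k) {
      int rh = (int)std::lround(x * cosT[k] + y * sinT[k] + rhoMax);
      int v = ++acc[(size_t)k * nRho + rh];
      if (v > bestV) { bestV = v; bestK = k; }
    }
    if (bestV < threshold) continue;
    // walk along the line direction (tangent is perpendicular to normal)
    double dx = -sinT[bestK], dy = cosT[bestK];
    if (std::fabs(dx) < std::fabs(dy)) { // iterate along y dominant
      if (dy < 0) { dx = -dx; dy = -dy; }
    } else if (dx < 0) { dx = -dx; dy = -dy; }
    double ex[2] = {0, 0}, ey[2] = {0, 0};
    std::vector<std::pair<int, int> > line_pts;
    for (int dir = 0; dir < 2; ++dir) {
      double sx = dir == 0 ? dx : -dx, sy = dir == 0 ? dy : -dy;
      double cxp = x, cyp = y;
      int gap = 0;
      double lx = x, ly = y;
      while (true) {
        cxp += sx; cyp += sy;
        int xi = (int)std::lround(cxp), yi = (int)std::lround(cyp);
        if (xi < 1 || xi > W || yi < 1 || yi > H) break;
        if (mask[(size_t)(xi - 1) * H + (yi - 1)]) {
          gap = 0; lx = xi; ly = yi;
          line_pts.push_back(std::make_pair(yi, xi));
        } else if (++gap > maxGap) break;
      }
      ex[dir] = lx; ey[dir] = ly;
    }
    double len = std::hypot(ex[0] - ex[1], ey[0] - ey[1]);
    // consume points on the walked segment (always, as in OpenCV) and un-vote
    line_pts.push_back(std::make_pair(y, x));
    for (size_t j = 0; j < line_pts.size(); ++j) {
      int yr = line_pts[j].first, xc = line_pts[j].second;
      if (!mask[(size_t)(xc - 1) * H + (yr - 1)]) continue;
      mask[(size_t)(xc - 1) * H + (yr - 1)] = 0;
      for (int k = 0; k < nTheta; ++k) {
        int rh = (int)std::lround(xc * cosT[k] + yr * sinT[k] + rhoMax);
        int idx = (int)((size_t)k * nRho + rh);
        if (acc[idx] > 0) --acc[idx];
      }
    }
    if (len >= minLen) {
      segs.push_back(std::make_pair(ex[0], ey[0]));
      segs.push_back(std::make_pair(ex[1], ey[1]));
      segd.push_back(len);
    }
  }
  NumericMatrix out(segd.size(), 4);
  for (size_t i = 0; i < segd.size(); ++i) {
    out(i, 0) = segs[2 * i].first;  out(i, 1) = segs[2 * i].second;
    out(i, 2) = segs[2 * i + 1].first; out(i, 3) = segs[2 * i + 1].second;
  }
  colnames(out) = CharacterVector::create("x1", "y1", "x2", "y2");
  return out;
}

// Largest all-ones axis-aligned rectangle in a binary matrix, by the
// row-histogram + monotone stack method. Returns c(r1, c1, r2, c2) 1-based.
// [[Rcpp::export]]
IntegerVector largest_rect_cpp(IntegerMatrix m) {
  int H = m.nrow(), W = m.ncol();
  std::vector<int> hist(W, 0);
  int bestA = 0; IntegerVector best = IntegerVector::create(0, 0, 0, 0);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) hist[c] = m(r, c) ? hist[c] + 1 : 0;
    // largest rectangle in histogram: stack of (start column, height)
    std::vector<std::pair<int, int> > stk;
    for (int c = 0; c <= W; ++c) {
      int h = c < W ? hist[c] : 0;
      int start = c;
      while (!stk.empty() && stk.back().second >= h) {
        int idx = stk.back().first, hh = stk.back().second;
        stk.pop_back();
        int area = hh * (c - idx);
        if (area > bestA) {
          bestA = area;
          best[0] = r - hh + 2; best[1] = idx + 1;
          best[2] = r + 1; best[3] = c;
        }
        start = idx;
      }
      stk.push_back(std::make_pair(start, h));
    }
  }
  best.attr("area") = bestA;
  return best;
}
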
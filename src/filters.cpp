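#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// mirror reflection about the edges without repeating the edge sample
// (0-based: -1 -> 1, n -> n-2), applied modularly for far overshoots
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * (n - 1);
  i = ((i % p) + p) % p;
  return (i >= n) ? p - i : i;
}

// value at 0-based rank round(q * (m-1)) of buf[0..m-1]
static inline double rank_value(std::vector<double>& buf, double q) {
  const int m = (int)buf.size();
  int k = (int)std::lround(q * (m - 1));
  if (k < 0) k = 0;
  if (k >= m) k = m - 1;
  std::nth_element(buf.begin(), buf.begin() + k, buf.end());
  return buf[k];
}

// Rank filter with one fixed footprint (logical matrix, odd dimensions,
// centre included). q is the rank fraction: 0 = min (erosion),
// 1 = max (dilation), 0.5 = median.
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter(const NumericMatrix& img,
                              const LogicalMatrix& foot, double q) {
  const int nr = img.nrow(), nc = img.ncol();
  const int fr = foot.nrow(), fc = foot.ncol();
  const int ry = fr / 2, rx = fc / 2;
  std::vector<std::pair<int,int> > off;
  for (int j = 0; j < fc; ++j)
    for (int i = 0; i < fr; ++i)
      if (foot(i, j)) off.push_back(std::make_pair(i - ry, j - rx));
  if (off.empty()) stop("footprint must contain at least one pixel");
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(off.size());
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        const int rr = reflect(r + off[k].first, nr);
        const int cc = reflect(c + off[k].second, nc);
        buf.push_back(img(rr, cc));
      }
      out(r, c) = rank_value(buf, q);
    }
  }
  return out;
}

// Rank filter with per-pixel elliptical footprints inside a
// (2p+1)x(2p+1) region. The ellipse at (r,c) has semi-axis semi_u along
// direction theta (measured from the +x / column axis) and semi_v
// perpendicular to it. The centre pixel is always included.
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter_varying(const NumericMatrix& img,
                                      const NumericMatrix& semi_u,
                                      const NumericMatrix& semi_v,
                                      const NumericMatrix& theta,
                                      int p, double q) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * p + 1) * (2 * p + 1));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double a = std::max(semi_u(r, c), 0.5);
      const double b = std::max(semi_v(r, c), 0.5);
      const double ct = std::cos(theta(r, c)), st = std::sin(theta(r, c));
      buf.clear();
      for (int dy = -p; dy <= p; ++dy) {
        for (int dx = -p; dx <= p; ++dx) {
          const double u = (dx * ct + dy * st) / a;
          const double v = (-dx * st + dy * ct) / b;
          if (u * u + v * v <= 1.0) {
            const int rr = reflect(r + dy, nr);
            const int cc = reflect(c + dx, nc);
            buf.push_back(img(rr, cc));
          }
        }
      }
      if (buf.empty()) buf.push_back(img(r, c));
      out(r, c) = rank_value(buf, q);
    }
  }
  return out;
}

// Sliding-window median and median absolute deviation over a w x w window
// (w odd), mirror padding. Returns both as a list of matrices.
// [[Rcpp::export]]
List cpp_sliding_median_mad(const NumericMatrix& img, int w) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rad = w / 2;
  NumericMatrix med(nr, nc), madm(nr, nc);
  std::vector<double> buf, dev;
  buf.reserve((size_t)w * w);
  dev.reserve((size_t)w * w);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int dy = -rad; dy <= rad; ++dy) {
        const int rr = reflect(r + dy, nr);
        for (int dx = -rad; dx <= rad; ++dx) {
          const int cc = reflect(c + dx, nc);
          buf.push_back(img(rr, cc));
        }
      }
      const size_t m = buf.size();
      const size_t half = m / 2;
      std::nth_element(buf.begin(), buf.begin() + half, buf.end());
      double mv = buf[half];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + half);
        mv = 0.5 * (mv + lo);
      }
      med(r, c) = mv;
      dev.clear();
      for (size_t k = 0; k < m; ++k) dev.push_back(std::fabs(buf[k] - mv));
      std::nth_element(dev.begin(), dev.begin() + half, dev.end());
      double dv = dev[half];
      if (m % 2 == 0) {
        double lo = *std::max_element(dev.begin(), dev.begin() + half);
        dv = 0.5 * (dv + lo);
      }
      madm(r, c) = dv;
    }
  }
  return List::create(Named("median") = med, Named("mad") = madm);
}
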
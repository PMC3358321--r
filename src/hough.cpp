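#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Integer pixels of a Bresenham segment between integer endpoints.
// [[Rcpp::export]]
IntegerMatrix cpp_line_pixels(int x1, int y1, int x2, int y2) {
  std::vector<int> xs, ys;
  int dx = std::abs(x2 - x1), dy = std::abs(y2 - y1);
  int sx = (x1 < x2) ? 1 : -1, sy = (y1 < y2) ? 1 : -1;
  int err = dx - dy, x = x1, y = y1;
  while (true) {
    xs.push_back(x); ys.push_back(y);
    if (x == x2 && y == y2) break;
    int e2 = 2 * err;
    if (e2 > -dy) { err -= dy; x += sx; }
    if (e2 <  dx) { err += dx; y += sy; }
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Offsets of the midpoint-algorithm circle of integer radius r about (0,0).
// The set is symmetric under negation, so p lies on the discrete circle
// centred at c iff c lies on the discrete circle centred at p.
static void midpoint_offsets(int r, std::vector<int> &ox, std::vector<int> &oy) {
  ox.clear(); oy.clear();
  if (r <= 0) { ox.push_back(0); oy.push_back(0); return; }
  int x = 0, y = r, d = 1 - r;
  while (x <= y) {
    // 8-fold symmetry; skip duplicates on the diagonals/axes
    ox.push_back(x);  oy.push_back(y);
    ox.push_back(x);  oy.push_back(-y);
    if (x != 0) { ox.push_back(-x); oy.push_back(y); ox.push_back(-x); oy.push_back(-y); }
    if (x != y) {
      ox.push_back(y);  oy.push_back(x);
      ox.push_back(-y); oy.push_back(x);
      if (x != 0) { ox.push_back(y); oy.push_back(-x); ox.push_back(-y); oy.push_back(-x); }
    }
    if (d < 0) d += 2 * x + 3; else { d += 2 * (x - y) + 5; --y; }
    ++x;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_circle_pixels(int cx, int cy, int r) {
  std::vector<int> ox, oy;
  midpoint_offsets(r, ox, oy);
  IntegerMatrix out(ox.size(), 2);
  for (size_t i = 0; i < ox.size(); ++i) { out(i, 0) = cx + ox[i]; out(i, 1) = cy + oy[i]; }
  return out;
}

// Line Hough voting: accumulator is n_rho x n_theta, rho bin = nearest bin of
// x cos(theta) + y sin(theta) on the grid rho0 + (i-1)*rho_step (1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_line_vote(NumericVector x, NumericVector y,
                            NumericVector theta_rad,
                            double rho0, double rho_step, int n_rho) {
  int np = x.size(), nt = theta_rad.size();
  IntegerMatrix acc(n_rho, nt);
  std::vector<double> ct(nt), st(nt);
  for (int j = 0; j < nt; ++j) { ct[j] = std::cos(theta_rad[j]); st[j] = std::sin(theta_rad[j]); }
  for (int i = 0; i < np; ++i) {
    for (int j = 0; j < nt; ++j) {
      double rho = x[i] * ct[j] + y[i] * st[j];
      int bin = (int)std::lround((rho - rho0) / rho_step);
      if (bin >= 0 && bin < n_rho) acc(bin, j) += 1;
    }
  }
  return acc;
}

// Circle Hough voting. For each point and each radius bin the midpoint circle
// of radius round(r) centred at the point is rasterized into the (a,b) plane
// of that bin. Accumulator dims: width x height x n_r, x fastest (column a,
// row b follows image convention a = x of centre, b = y of centre); cell
// (a,b,k) sits at index a + width*b + width*height*k, 0-based coords.
// [[Rcpp::export]]
IntegerVector cpp_circle_vote(NumericVector x, NumericVector y,
                              int width, int height, NumericVector radii) {
  int np = x.size(), nr = radii.size();
  IntegerVector acc(width * height * nr);
  std::vector<int> ox, oy;
  for (int k = 0; k < nr; ++k) {
    int r = (int)std::lround(radii[k]);
    midpoint_offsets(r, ox, oy);
    int base = width * height * k;
    for (int i = 0; i < np; ++i) {
      int px = (int)std::lround(x[i]), py = (int)std::lround(y[i]);
      for (size_t m = 0; m < ox.size(); ++m) {
        int a = px + ox[m], b = py + oy[m];
        if (a >= 0 && a < width && b >= 0 && b < height)
          acc[base + b * width + a] += 1;
      }
    }
  }
  return acc;
}

// 2-d median filter with zero padding (as MATLAB medfilt2 default).
// wr, wc are odd window sizes along rows and columns.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2(NumericMatrix m, int wr, int wc) {
  int nr = m.nrow(), nc = m.ncol();
  int hr = wr / 2, hc = wc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(wr * wc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -hc; dj <= hc; ++dj) {
        for (int di = -hr; di <= hr; ++di) {
          int ii = i + di, jj = j + dj;
          double v = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? m(ii, jj) : 0.0;
          buf.push_back(v);
        }
      }
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Local maxima of a 3-d array (dims d1 x d2 x d3, d3 may be 1 for 2-d use)
// at or above `threshold`; a cell qualifies if >= all of its (up to 26)
// neighbours. Returns a matrix of (i, j, k, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima3(NumericVector arr, int d1, int d2, int d3,
                                double threshold) {
  std::vector<double> ri, rj, rk, rv;
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        double v = arr[i + d1 * (j + (long long)d2 * k)];
        if (v < threshold) continue;
        bool ok = true;
        for (int dk = -1; dk <= 1 && ok; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= d3) continue;
          for (int dj = -1; dj <= 1 && ok; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= d2) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di; if (ii < 0 || ii >= d1) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (arr[ii + d1 * (jj + (long long)d2 * kk)] > v) { ok = false; break; }
            }
          }
        }
        if (ok) { ri.push_back(i + 1); rj.push_back(j + 1); rk.push_back(k + 1); rv.push_back(v); }
      }
    }
  }
  NumericMatrix out(ri.size(), 4);
  for (size_t t = 0; t < ri.size(); ++t) {
    out(t, 0) = ri[t]; out(t, 1) = rj[t]; out(t, 2) = rk[t]; out(t, 3) = rv[t];
  }
  colnames(out) = CharacterVector::create("i", "j", "k", "value");
  return out;
}
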
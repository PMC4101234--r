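#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Siddon-style exact ray/pixel intersection tracing for a parallel
// pencil-beam geometry. The image occupies [-N/2, N/2] x [-M/2, M/2] in
// pixel units with row 0 at the top; a ray for view angle theta (degrees,
// counterclockwise from the +x axis) and detector offset s runs along the
// direction (-sin theta, cos theta) through the point s*(cos theta, sin
// theta). Pixel columns are the x axis. Returns a CSR triplet list with
// 0-based, column-major pixel indices; one row per (view, detector) pair,
// detectors fastest.
// [[Rcpp::export]]
List siddon_trace(int M, int N, NumericVector angles_deg, int n_det,
                  double spacing) {
  const double xmin = -N / 2.0, xmax = N / 2.0;
  const double ymin = -M / 2.0, ymax = M / 2.0;
  std::vector<double> vals;
  std::vector<int> cols;
  std::vector<int> row_ptr;
  row_ptr.reserve((size_t)angles_deg.size() * n_det + 1);
  row_ptr.push_back(0);
  vals.reserve((size_t)angles_deg.size() * n_det * (M + N) / 2);
  cols.reserve(vals.capacity());
  std::vector<double> tcross;
  const double eps = 1e-12;

  for (int a = 0; a < angles_deg.size(); ++a) {
    double th = angles_deg[a] * M_PI / 180.0;
    double ux = std::cos(th), uy = std::sin(th);
    double vx = -uy, vy = ux;
    for (int d = 0; d < n_det; ++d) {
      double s = (d + 1 - (n_det + 1) / 2.0) * spacing;
      double px = s * ux, py = s * uy;
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      bool miss = false;
      if (std::fabs(vx) > eps) {
        double t1 = (xmin - px) / vx, t2 = (xmax - px) / vx;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1);
        tmax = std::min(tmax, t2);
      } else if (px <= xmin || px >= xmax) {
        miss = true;
      }
      if (std::fabs(vy) > eps) {
        double t1 = (ymin - py) / vy, t2 = (ymax - py) / vy;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1);
        tmax = std::min(tmax, t2);
      } else if (py <= ymin || py >= ymax) {
        miss = true;
      }
      if (miss || tmax - tmin <= eps) {
        row_ptr.push_back((int)vals.size());
        continue;
      }
      tcross.clear();
      tcross.push_back(tmin);
      tcross.push_back(tmax);
      if (std::fabs(vx) > eps) {
        for (int k = 0; k <= N; ++k) {
          double t = (xmin + k - px) / vx;
          if (t > tmin && t < tmax) tcross.push_back(t);
        }
      }
      if (std::fabs(vy) > eps) {
        for (int k = 0; k <= M; ++k) {
          double t = (ymin + k - py) / vy;
          if (t > tmin && t < tmax) tcross.push_back(t);
        }
      }
      std::sort(tcross.begin(), tcross.end());
      for (size_t q = 0; q + 1 < tcross.size(); ++q) {
        double len = tcross[q + 1] - tcross[q];
        if (len <= eps) continue;
        double tm = 0.5 * (tcross[q] + tcross[q + 1]);
        double x = px + tm * vx, y = py + tm * vy;
        int j = (int)std::floor(x - xmin);  // column, 0..N-1
        int i = (int)std::floor(ymax - y);  // row, 0..M-1 (top first)
        if (j < 0 || j >= N || i < 0 || i >= M) continue;
        cols.push_back(j * M + i);
        vals.push_back(len);
      }
      row_ptr.push_back((int)vals.size());
    }
  }
  return List::create(
      _["row_ptr"] = IntegerVector(row_ptr.begin(), row_ptr.end()),
      _["cols"] = IntegerVector(cols.begin(), cols.end()),
      _["vals"] = NumericVector(vals.begin(), vals.end()));
}
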
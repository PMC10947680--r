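// Windowed neighbor-median statistics for the universal outlier detection
// (normalized median) test and for median replacement of flagged vectors.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// median of a scratch vector (modified in place)
static double med_of(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t m = n / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  const double hi = v[m];
  if (n % 2 == 1) return hi;
  const double lo = *std::max_element(v.begin(), v.begin() + m);
  return 0.5 * (lo + hi);
}

// For each node of a 2D field: median of valid window neighbors (center
// excluded), median absolute residual of those neighbors about their median,
// and the neighbor count. NA where no valid neighbor exists.
// [[Rcpp::export]]
List neighbor_median_stats(NumericMatrix v, LogicalMatrix valid, int h) {
  const int ny = v.nrow(), nx = v.ncol();
  NumericMatrix med(ny, nx), resmed(ny, nx);
  IntegerMatrix cnt(ny, nx);
  std::vector<double> buf, buf2;
  buf.reserve((2 * h + 1) * (2 * h + 1));
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        for (int di = -h; di <= h; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
          if (!valid(ii, jj)) continue;
          buf.push_back(v(ii, jj));
        }
      }
      cnt(i, j) = static_cast<int>(buf.size());
      if (buf.empty()) {
        med(i, j) = NA_REAL;
        resmed(i, j) = NA_REAL;
        continue;
      }
      buf2 = buf;
      const double m = med_of(buf2);
      med(i, j) = m;
      for (double& x : buf) x = std::fabs(x - m);
      resmed(i, j) = med_of(buf);
    }
  }
  return List::create(_["median"] = med, _["resmed"] = resmed,
                      _["count"] = cnt);
}

// 3D counterpart; v and valid are ny x nx x nz arrays (column-major).
// [[Rcpp::export]]
List neighbor_median_stats3d(NumericVector v, LogicalVector valid,
                             IntegerVector dims, int h) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  NumericVector med(v.size()), resmed(v.size());
  IntegerVector cnt(v.size());
  std::vector<double> buf, buf2;
  buf.reserve((2 * h + 1) * (2 * h + 1) * (2 * h + 1));
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        buf.clear();
        for (int dk = -h; dk <= h; ++dk) {
          for (int dj = -h; dj <= h; ++dj) {
            for (int di = -h; di <= h; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= ny || jj < 0 || jj >= nx ||
                  kk < 0 || kk >= nz) continue;
              const R_xlen_t idx =
                ii + static_cast<R_xlen_t>(ny) * (jj + static_cast<R_xlen_t>(nx) * kk);
              if (!valid[idx]) continue;
              buf.push_back(v[idx]);
            }
          }
        }
        const R_xlen_t at =
          i + static_cast<R_xlen_t>(ny) * (j + static_cast<R_xlen_t>(nx) * k);
        cnt[at] = static_cast<int>(buf.size());
        if (buf.empty()) {
          med[at] = NA_REAL;
          resmed[at] = NA_REAL;
          continue;
        }
        buf2 = buf;
        const double m = med_of(buf2);
        med[at] = m;
        for (double& x : buf) x = std::fabs(x - m);
        resmed[at] = med_of(buf);
      }
    }
  }
  med.attr("dim") = dims;
  resmed.attr("dim") = dims;
  cnt.attr("dim") = dims;
  return List::create(_["median"] = med, _["resmed"] = resmed,
                      _["count"] = cnt);
}
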
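#include <Rcpp.h>
#include <queue>
#include <random>
#include "sampling.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_resample_trilinear")]]
NumericVector cpp_resample_trilinear(NumericVector arr, NumericVector spacing,
                                     double target) {
  IntegerVector dim = arr.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int o1 = (int)std::max(1.0, std::round(d1 * spacing[0] / target));
  int o2 = (int)std::max(1.0, std::round(d2 * spacing[1] / target));
  int o3 = (int)std::max(1.0, std::round(d3 * spacing[2] / target));
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  const double *in = arr.begin();
  double *op = out.begin();
  // pixel-center alignment: x_in = (x_out + 0.5) * target/spacing - 0.5
  double s1 = target / spacing[0], s2 = target / spacing[1], s3 = target / spacing[2];
  R_xlen_t idx = 0;
  for (int i3 = 0; i3 < o3; ++i3) {
    double f3 = (i3 + 0.5) * s3 - 0.5;
    for (int i2 = 0; i2 < o2; ++i2) {
      double f2 = (i2 + 0.5) * s2 - 0.5;
      for (int i1 = 0; i1 < o1; ++i1, ++idx) {
        double f1 = (i1 + 0.5) * s1 - 0.5;
        op[idx] = ipet::sample3(in, d1, d2, d3, f1, f2, f3, 1, 0.0);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_rotate3")]]
NumericVector cpp_rotate3(NumericVector arr, double a1, double a2, double a3) {
  IntegerVector dim = arr.attr("dim");
  NumericVector out(arr.size());
  out.attr("dim") = dim;
  ipet::rotate_array(arr.begin(), out.begin(), dim[0], dim[1], dim[2], a1, a2, a3);
  return out;
}

// n rotated copies with per-copy angles drawn uniformly in [amin, amax)
// for the three axes in fixed order; deterministic in seed (mt19937_64).
// [[Rcpp::export(name = ".cpp_random_rotations")]]
List cpp_random_rotations(NumericVector arr, int n, double amin, double amax,
                          int seed) {
  IntegerVector dim = arr.attr("dim");
  std::mt19937_64 rng((std::uint64_t)seed);
  std::uniform_real_distribution<double> unif(amin, amax);
  List out(n);
  NumericMatrix angles(n, 3);
  for (int k = 0; k < n; ++k) {
    double a1 = unif(rng), a2 = unif(rng), a3 = unif(rng);
    NumericVector rot(arr.size());
    rot.attr("dim") = dim;
    ipet::rotate_array(arr.begin(), rot.begin(), dim[0], dim[1], dim[2], a1, a2, a3);
    out[k] = rot;
    angles(k, 0) = a1; angles(k, 1) = a2; angles(k, 2) = a3;
  }
  return List::create(_["cubes"] = out, _["angles"] = angles);
}

// Connected component (26-neighbourhood) of `mask` containing `seed`
// (1-based linear index).
// [[Rcpp::export(name = ".cpp_flood26")]]
LogicalVector cpp_flood26(LogicalVector mask, int seed) {
  IntegerVector dim = mask.attr("dim");
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out(mask.size(), false);
  out.attr("dim") = dim;
  R_xlen_t s = (R_xlen_t)seed - 1;
  if (s < 0 || s >= mask.size() || !mask[s]) return out;
  std::queue<R_xlen_t> q;
  q.push(s);
  out[s] = true;
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int i1 = v % d1, i2 = (v / d1) % d2, i3 = v / ((R_xlen_t)d1 * d2);
    for (int o3 = -1; o3 <= 1; ++o3)
      for (int o2 = -1; o2 <= 1; ++o2)
        for (int o1 = -1; o1 <= 1; ++o1) {
          if (!o1 && !o2 && !o3) continue;
          int j1 = i1 + o1, j2 = i2 + o2, j3 = i3 + o3;
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          R_xlen_t w = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
          if (mask[w] && !out[w]) { out[w] = true; q.push(w); }
        }
  }
  return out;
}
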
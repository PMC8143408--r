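#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of an odd-length buffer (destructive)
static double median_odd(std::vector<double>& buf) {
  const size_t m = buf.size() / 2;
  std::nth_element(buf.begin(), buf.begin() + m, buf.end());
  return buf[m];
}

// Running median with symmetric shrinking windows at the edges: the window
// centred at i is x[i-h .. i+h] with h = min(half, i, n-1-i), always odd.
// [[Rcpp::export]]
NumericVector cpp_running_median(NumericVector x, int window) {
  const int n = x.size();
  const int half = (window - 1) / 2;
  NumericVector out(n);
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    int h = std::min(half, std::min(i, n - 1 - i));
    buf.assign(x.begin() + (i - h), x.begin() + (i + h + 1));
    out[i] = median_odd(buf);
  }
  return out;
}

// Segment one smoothed profile: points of interest are indices with
// |x - median| > 2 * population sd; the extreme indices of that set give the
// two boundaries. Returns {ilm, bm, valid} with 1-based indices; with
// inner_high the ILM is the maximum index, with inner_low the minimum.
static void segment_profile(const std::vector<double>& sm, bool inner_high,
                            double& ilm, double& bm, bool& valid) {
  const int n = (int)sm.size();
  std::vector<double> tmp(sm);
  const int m = n / 2;
  // median (handle even length as mean of the two central order stats)
  std::nth_element(tmp.begin(), tmp.begin() + m, tmp.end());
  double med = tmp[m];
  if (n % 2 == 0) {
    std::nth_element(tmp.begin(), tmp.begin() + m - 1, tmp.end());
    med = 0.5 * (med + tmp[m - 1]);
  }
  double mean = 0.0;
  for (double v : sm) mean += v;
  mean /= n;
  double ss = 0.0;
  for (double v : sm) ss += (v - mean) * (v - mean);
  const double sdev = std::sqrt(ss / n);
  const double thr = 2.0 * sdev;

  int lo = -1, hi = -1, count = 0;
  for (int i = 0; i < n; ++i) {
    if (std::abs(sm[i] - med) > thr) {
      if (lo < 0) lo = i;
      hi = i;
      ++count;
    }
  }
  if (count < 2) {
    ilm = NA_REAL; bm = NA_REAL; valid = false;
    return;
  }
  valid = true;
  if (inner_high) { ilm = hi + 1; bm = lo + 1; }
  else            { ilm = lo + 1; bm = hi + 1; }
}

// [[Rcpp::export]]
List cpp_segment_ascan(NumericVector ascan, int window, bool inner_high) {
  NumericVector sm = cpp_running_median(ascan, window);
  std::vector<double> v(sm.begin(), sm.end());
  double ilm, bm; bool valid;
  segment_profile(v, inner_high, ilm, bm, valid);
  return List::create(_["ilm"] = ilm, _["bm"] = bm, _["valid"] = valid);
}

// Apply running-median smoothing + boundary extraction to every A-scan of a
// (b_scan, a_scan, depth) volume.
// [[Rcpp::export]]
List cpp_segment_volume(NumericVector vol, int window, bool inner_high) {
  IntegerVector dims = vol.attr("dim");
  const int nb = dims[0], na = dims[1], nd = dims[2];
  NumericMatrix ilm(nb, na), bm(nb, na);
  LogicalMatrix valid(nb, na);
  std::vector<double> prof(nd), smv(nd);
  const double* p = REAL(vol);
  std::vector<double> buf;
  const int half = (window - 1) / 2;
  for (int a = 0; a < na; ++a) {
    for (int b = 0; b < nb; ++b) {
      const R_xlen_t base = (R_xlen_t)b + (R_xlen_t)nb * a;
      const R_xlen_t stride = (R_xlen_t)nb * na;
      for (int d = 0; d < nd; ++d) prof[d] = p[base + stride * d];
      for (int i = 0; i < nd; ++i) {
        int h = std::min(half, std::min(i, nd - 1 - i));
        buf.assign(prof.begin() + (i - h), prof.begin() + (i + h + 1));
        smv[i] = median_odd(buf);
      }
      double vi, vb; bool ok;
      segment_profile(smv, inner_high, vi, vb, ok);
      ilm(b, a) = vi; bm(b, a) = vb; valid(b, a) = ok;
    }
  }
  return List::create(_["ilm"] = ilm, _["bm"] = bm, _["valid"] = valid);
}
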
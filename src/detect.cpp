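#include <Rcpp.h>
using namespace Rcpp;

// Peak-to-peak threshold detection core.
// Slides a window of `win` samples; where the excursion (max - min) over
// valid samples exceeds `thr`, the index of the absolute extremum of the
// window (ties -> earlier sample) becomes a candidate.  Candidates are then
// thinned so consecutive events are separated by at least `refr` samples,
// keeping the earlier one.  Returns 1-based sample indices.
// [[Rcpp::export]]
IntegerVector detect_peaks_cpp(NumericVector x, LogicalVector valid,
                               int win, double thr, int refr) {
  int n = x.size();
  if (valid.size() != n) stop("valid mask length mismatch");
  std::vector<char> cand(n, 0);
  for (int s = 0; s + win <= n; ++s) {
    double mn = R_PosInf, mx = R_NegInf, besta = -1.0;
    int best = -1, nv = 0;
    for (int i = s; i < s + win; ++i) {
      if (valid[i] == FALSE) continue;
      ++nv;
      double v = x[i];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
      double a = std::fabs(v);
      if (a > besta) { besta = a; best = i; }   // strict > keeps earlier tie
    }
    if (nv >= 2 && best >= 0 && (mx - mn) > thr) cand[best] = 1;
  }
  std::vector<int> out;
  long last = -1 - (long)refr;
  for (int i = 0; i < n; ++i) {
    if (!cand[i]) continue;
    if ((long)i - last >= refr) { out.push_back(i + 1); last = i; }
  }
  return wrap(out);
}
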
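#include <Rcpp.h>
using namespace Rcpp;

// Fisher exact dynamic programme for 1-D natural breaks: partition the
// sorted vector v into k contiguous classes minimising the sum of
// within-class squared deviations (SDCM). Class starts never split runs
// of equal values, so break values classify consistently. Ties resolve
// to the smallest start indices (lowest break values).

// [[Rcpp::export]]
List jenks_dp(NumericVector v, int k) {
  int n = v.size();
  if (k < 1 || n < k) stop("need at least k values");
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + v[i];
    s2[i + 1] = s2[i] + v[i] * v[i];
  }
  // cost of class v[i..j] (0-based inclusive)
  auto cost = [&](int i, int j) {
    double sum = s1[j + 1] - s1[i];
    double sq = s2[j + 1] - s2[i];
    int m = j - i + 1;
    return sq - sum * sum / m;
  };
  const double INF = R_PosInf;
  std::vector<double> prev(n, 0.0), cur(n, 0.0);
  // back[c][j]: start index of class c+1 ending at j
  std::vector< std::vector<int> > back(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) { prev[j] = cost(0, j); back[0][j] = 0; }
  for (int c = 1; c < k; ++c) {
    for (int j = 0; j < n; ++j) {
      if (j < c) { cur[j] = INF; back[c][j] = -1; continue; }
      double best = INF; int arg = -1;
      for (int i = c; i <= j; ++i) {
        if (v[i] == v[i - 1]) continue;       // never split equal values
        double val = prev[i - 1] + cost(i, j);
        if (val < best - 1e-15) { best = val; arg = i; }
      }
      cur[j] = best; back[c][j] = arg;
    }
    std::swap(prev, cur);
  }
  double sdcm = prev[n - 1];
  IntegerVector starts(k - 1);
  int j = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int i = back[c][j];
    starts[c - 1] = i + 1;                    // 1-based start of class c+1
    j = i - 1;
  }
  return List::create(_["starts"] = starts, _["sdcm"] = sdcm);
}
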
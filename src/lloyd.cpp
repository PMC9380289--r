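#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The k-means engine works on row-major copies of the data so the inner
// distance loops run on contiguous memory; the permutation test calls it
// hundreds of thousands of times.

static inline double ptDist2(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    const double t = a[c] - b[c];
    s += t * t;
  }
  return s;
}

struct LloydResult {
  std::vector<double> centers;  // row-major k x d
  std::vector<int> assign;      // 0-based
  std::vector<int> sizes;
  std::vector<double> wssHist;
  double totss;
  int iterations;
};

// Lloyd iterations from given initial centers (row-major).
// - nearest-center ties broken by lowest center index (strict < update);
// - a cluster that empties is re-seeded at the point farthest from its
//   assigned center, so every cluster stays non-empty whenever the data
//   contain at least k distinct rows;
// - stops when the assignment is unchanged or after maxIter iterations.
static void lloydCore(const std::vector<double>& X, int n, int d, int k,
                      const std::vector<double>& init, int maxIter,
                      LloydResult& out) {
  std::vector<double>& centers = out.centers;
  centers = init;
  std::vector<int>& assign = out.assign;
  assign.assign(n, -1);
  std::vector<int> prev(n, -2);
  std::vector<double> dist2(n);
  std::vector<double> sums((size_t)k * d);
  std::vector<int> cnt(k);
  out.wssHist.clear();
  int iter;

  for (iter = 0; iter < maxIter; ++iter) {
    double wss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &X[(size_t)i * d];
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        const double s = ptDist2(xi, &centers[(size_t)j * d], d);
        if (s < best) { best = s; bj = j; }
      }
      assign[i] = bj;
      dist2[i] = best;
      wss += best;
    }
    out.wssHist.push_back(wss);

    if (assign == prev) break;
    prev = assign;

    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int j = assign[i];
      ++cnt[j];
      const double* xi = &X[(size_t)i * d];
      double* sj = &sums[(size_t)j * d];
      for (int c = 0; c < d; ++c) sj[c] += xi[c];
    }
    bool anyEmpty = false;
    for (int j = 0; j < k; ++j) {
      if (cnt[j] > 0) {
        double* cj = &centers[(size_t)j * d];
        const double* sj = &sums[(size_t)j * d];
        for (int c = 0; c < d; ++c) cj[c] = sj[c] / cnt[j];
      } else {
        anyEmpty = true;
      }
    }
    if (anyEmpty) {
      // distances to the freshly updated assigned centers
      for (int i = 0; i < n; ++i)
        dist2[i] = ptDist2(&X[(size_t)i * d],
                           &centers[(size_t)assign[i] * d], d);
      for (int j = 0; j < k; ++j) {
        if (cnt[j] > 0) continue;
        int far = -1;
        double fd = -1.0;
        for (int i = 0; i < n; ++i) {
          if (cnt[assign[i]] <= 1) continue;  // keep donors non-empty
          if (dist2[i] > fd) { fd = dist2[i]; far = i; }
        }
        if (far < 0) continue;  // nothing to steal: degenerate input
        --cnt[assign[far]];
        assign[far] = j;
        cnt[j] = 1;
        for (int c = 0; c < d; ++c)
          centers[(size_t)j * d + c] = X[(size_t)far * d + c];
        dist2[far] = 0.0;
      }
      prev[0] = -2;  // force at least one more assignment pass
    }
  }

  out.sizes.assign(k, 0);
  for (int i = 0; i < n; ++i) ++out.sizes[assign[i]];
  out.totss = out.wssHist.back();
  out.iterations = iter + 1;
}

// k-means++ initial centers driven by pre-drawn uniforms u (length k):
// the first center index is floor(u[0] * n); each subsequent center is
// chosen by inverse-CDF sampling proportional to the squared distance to
// the nearest chosen center. Rows of X are expected in canonical
// (lexicographic) order, making the choice invariant to the caller's
// row ordering.
static void kmeansppInit(const std::vector<double>& X, int n, int d, int k,
                         const double* u, std::vector<double>& init,
                         std::vector<char>& used,
                         std::vector<double>& d2) {
  std::fill(used.begin(), used.end(), 0);
  int c0 = (int)(u[0] * n);
  if (c0 >= n) c0 = n - 1;
  for (int c = 0; c < d; ++c) init[c] = X[(size_t)c0 * d + c];
  used[c0] = 1;
  for (int i = 0; i < n; ++i)
    d2[i] = ptDist2(&X[(size_t)i * d], &init[0], d);

  for (int j = 1; j < k; ++j) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += d2[i];
    int pick = -1;
    if (tot > 0.0) {
      const double target = u[j] * tot;
      double cum = 0.0;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (cum >= target) { pick = i; break; }
      }
      if (pick < 0) pick = n - 1;
    } else {
      // remaining points coincide with chosen centers; take the first
      // index not yet used (callers rule this out for valid inputs)
      for (int i = 0; i < n; ++i) if (!used[i]) { pick = i; break; }
      if (pick < 0) pick = 0;
    }
    used[pick] = 1;
    double* cj = &init[(size_t)j * d];
    for (int c = 0; c < d; ++c) cj[c] = X[(size_t)pick * d + c];
    for (int i = 0; i < n; ++i) {
      const double s = ptDist2(&X[(size_t)i * d], cj, d);
      if (s < d2[i]) d2[i] = s;
    }
  }
}

static std::vector<double> toRowMajor(const NumericMatrix& X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> out((size_t)n * d);
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * d + c] = X(i, c);
  return out;
}

static List resultToR(const LloydResult& res, int d) {
  const int k = (int)res.sizes.size();
  NumericMatrix centers(k, d);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) centers(j, c) = res.centers[(size_t)j * d + c];
  IntegerVector cluster(res.assign.size());
  for (size_t i = 0; i < res.assign.size(); ++i)
    cluster[i] = res.assign[i] + 1;
  return List::create(
    _["centers"] = centers,
    _["cluster"] = cluster,
    _["sizes"] = IntegerVector(res.sizes.begin(), res.sizes.end()),
    _["totss"] = res.totss,
    _["wss_history"] = NumericVector(res.wssHist.begin(),
                                     res.wssHist.end()),
    _["iterations"] = res.iterations);
}

// Single Lloyd run from explicit initial centers; exposed for the
// within-cluster-SS monotonicity checks.
// [[Rcpp::export]]
List lloyd_kmeans(const NumericMatrix& X, const NumericMatrix& init,
                  int maxIter) {
  const int n = X.nrow(), d = X.ncol(), k = init.nrow();
  if (init.ncol() != d) stop("init must have the same column count as X");
  std::vector<double> Xr = toRowMajor(X), initR = toRowMajor(init);
  LloydResult res;
  lloydCore(Xr, n, d, k, initR, maxIter, res);
  return resultToR(res, d);
}

// Full restarted k-means: one k-means++ + Lloyd run per column of U
// (a k x nRestarts matrix of uniforms), keeping the restart with the
// lowest total within-cluster SS (ties keep the earliest restart).
// [[Rcpp::export]]
List kmeans_restarts(const NumericMatrix& X, const NumericMatrix& U,
                     int maxIter) {
  const int n = X.nrow(), d = X.ncol();
  const int k = U.nrow(), nRestarts = U.ncol();
  if (k > n) stop("more centers requested than data points");
  std::vector<double> Xr = toRowMajor(X);
  std::vector<double> init((size_t)k * d), d2(n);
  std::vector<char> used(n);
  LloydResult res, best;
  double bestSS = R_PosInf;
  for (int r = 0; r < nRestarts; ++r) {
    kmeansppInit(Xr, n, d, k, &U(0, r), init, used, d2);
    lloydCore(Xr, n, d, k, init, maxIter, res);
    if (res.totss < bestSS) {
      bestSS = res.totss;
      best = res;
    }
  }
  return resultToR(best, d);
}
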
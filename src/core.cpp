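#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev distance between the m-length windows starting at i and j (0-based).
static inline double cheb_dist(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(x[i + k] - x[j + k]);
    if (v > d) d = v;
  }
  return d;
}

// Approximate entropy, literal construction: C_i^m counts all j (self-matches
// included), phi(m) = mean of ln(C_i^m), ApEn = phi(m) - phi(m+1).
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  const double* px = REAL(x);
  double phi[2];
  for (int w = 0; w < 2; ++w) {
    int mm = m + w;
    int n = N - mm + 1;           // number of template windows
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        if (cheb_dist(px, i, j, mm) <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)n);
    }
    phi[w] = acc / (double)n;
  }
  return phi[0] - phi[1];
}

// Fuzzy entropy (standard mean-centered construction): windows of length m are
// baseline-removed, similarity mu = exp(-d^grad / r), self-matches excluded,
// N - m windows used for both m and m+1 so the two scales are comparable.
// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector x, int m, double r, double grad) {
  int N = x.size();
  const double* px = REAL(x);
  int n = N - m;                  // windows compared at both scales
  double phi[2];
  for (int w = 0; w < 2; ++w) {
    int mm = m + w;
    // centered windows
    std::vector<double> z((size_t)n * mm);
    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += px[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) z[(size_t)i * mm + k] = px[i + k] - mu;
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double v = std::fabs(z[(size_t)i * mm + k] - z[(size_t)j * mm + k]);
          if (v > d) d = v;
        }
        s += std::exp(-std::pow(d, grad) / r);
      }
      acc += s / (double)(n - 1);
    }
    phi[w] = acc / (double)n;
  }
  return std::log(phi[0]) - std::log(phi[1]);
}

// Single-pass IIR filter, direct form II transposed. b, a normalized so a[0]=1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Project every participant (rows of theta, radius p) onto every axis
// (rows of that): A[i, s] = p[i] * prod_k cos(theta[i, k] + that[s, k]).
// [[Rcpp::export(name = ".project_population_cpp")]]
NumericMatrix project_population_cpp(NumericMatrix theta, NumericVector p,
                                     NumericMatrix that) {
  int n = theta.nrow(), k = theta.ncol(), s = that.nrow();
  NumericMatrix A(n, s);
  for (int ax = 0; ax < s; ++ax) {
    for (int i = 0; i < n; ++i) {
      double v = p[i];
      for (int j = 0; j < k; ++j) v *= std::cos(theta(i, j) + that(ax, j));
      A(i, ax) = v;
    }
  }
  return A;
}

// Pairwise group-separability estimator per column of A:
// E_z = sum_{i<j} |mean_i - mean_j| / sqrt(var_i + var_j), population variance,
// denominator floored at eps.
// [[Rcpp::export(name = ".ez_batch_cpp")]]
NumericVector ez_batch_cpp(NumericMatrix A, IntegerVector group, int ngroups,
                           double eps) {
  int n = A.nrow(), s = A.ncol();
  NumericVector out(s);
  std::vector<double> sum(ngroups), sq(ngroups);
  std::vector<int> cnt(ngroups, 0);
  for (int i = 0; i < n; ++i) cnt[group[i] - 1]++;
  for (int ax = 0; ax < s; ++ax) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sq.begin(), sq.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int g = group[i] - 1;
      double v = A(i, ax);
      sum[g] += v;
      sq[g] += v * v;
    }
    double ez = 0.0;
    for (int gi = 0; gi < ngroups - 1; ++gi) {
      double mi = sum[gi] / cnt[gi];
      double vi = sq[gi] / cnt[gi] - mi * mi;
      for (int gj = gi + 1; gj < ngroups; ++gj) {
        double mj = sum[gj] / cnt[gj];
        double vj = sq[gj] / cnt[gj] - mj * mj;
        double den = std::sqrt(std::max(vi + vj, eps));
        ez += std::fabs((mi - mj) / den);
      }
    }
    out[ax] = ez;
  }
  return out;
}
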
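// Subsample-median robust distances. The RNG is a std::mt19937 seeded from
// R (deterministic across platforms); subsamples are drawn without
// replacement by partial Fisher-Yates.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

// First nsub entries of idx become a uniform subsample without replacement.
void partial_shuffle(std::mt19937 &rng, std::vector<arma::uword> &idx,
                     int nsub) {
  const int m = static_cast<int>(idx.size());
  for (int i = 0; i < nsub; ++i) {
    int j = i + static_cast<int>(rng() % static_cast<unsigned>(m - i));
    std::swap(idx[i], idx[j]);
  }
}

double median_of(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  const size_t n = v.size();
  if (n == 0) return std::numeric_limits<double>::quiet_NaN();
  return (n % 2) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Ledoit-Wolf linear shrinkage toward the scaled identity, ML (1/n) base
// covariance. Returns the shrunk matrix; intensity written to rho_out.
arma::mat lw_shrink(const arma::mat &X, double &rho_out) {
  const double n = static_cast<double>(X.n_rows);
  const double p = static_cast<double>(X.n_cols);
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat A = X.each_row() - mu;
  arma::mat S = (A.t() * A) / n;
  const double m = arma::trace(S) / p;
  const double s2 = arma::accu(arma::square(S));
  const double d2 = s2 / p - m * m; // ||S - mI||_F^2 / p
  if (d2 <= 0.0) {                  // S already a multiple of the identity
    rho_out = 0.0;
    return S;
  }
  double sum4 = 0.0; // sum_k ||x_k||^4 over centered rows
  for (arma::uword k = 0; k < A.n_rows; ++k) {
    const double q = arma::dot(A.row(k), A.row(k));
    sum4 += q * q;
  }
  double b2 = (sum4 / (n * n) - s2 / n) / p;
  if (b2 < 0.0) b2 = 0.0;
  if (b2 > d2) b2 = d2;
  rho_out = b2 / d2;
  arma::mat C = (1.0 - rho_out) * S;
  C.diag() += rho_out * m;
  return C;
}

double mahal_from(const arma::vec &x, const arma::rowvec &mu,
                  const arma::mat &C, bool &ok) {
  arma::vec diff = x - mu.t();
  arma::mat L;
  ok = arma::chol(L, C, "lower");
  if (!ok) return 0.0;
  arma::vec v = arma::solve(arma::trimatl(L), diff);
  return std::sqrt(arma::dot(v, v));
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_lw_cov(const arma::mat &X) {
  double rho = 0.0;
  arma::mat C = lw_shrink(X, rho);
  return Rcpp::List::create(Rcpp::Named("matrix") = C,
                            Rcpp::Named("shrinkage_intensity") = rho);
}

// Median over nreps subsample z-scores of `value` against `reference`
// (subsample SD with the n-1 denominator). Zero-variance subsamples are
// discarded and counted.
// [[Rcpp::export]]
Rcpp::List cpp_robust_z(double value, const arma::vec &reference, int nsub,
                        int nreps, unsigned int seed) {
  std::mt19937 rng(seed);
  std::vector<arma::uword> idx(reference.n_elem);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<double> zs;
  zs.reserve(nreps);
  int discarded = 0;
  for (int r = 0; r < nreps; ++r) {
    partial_shuffle(rng, idx, nsub);
    double sum = 0.0, sum2 = 0.0;
    for (int i = 0; i < nsub; ++i) {
      const double v = reference[idx[i]];
      sum += v;
      sum2 += v * v;
    }
    const double mean = sum / nsub;
    double var = (sum2 - nsub * mean * mean) / (nsub - 1);
    if (var <= 0.0) {
      ++discarded;
      continue;
    }
    zs.push_back((value - mean) / std::sqrt(var));
  }
  return Rcpp::List::create(Rcpp::Named("value") = median_of(zs),
                            Rcpp::Named("n_discarded") = discarded);
}

// Median over nreps subsample Mahalanobis distances of x against the rows
// of `reference`; per subsample, mu and the (shrinkage) covariance are
// estimated from the subsample only. use_lw = FALSE uses the unbiased
// sample covariance instead.
// [[Rcpp::export]]
Rcpp::List cpp_robust_md(const arma::vec &x, const arma::mat &reference,
                         int nsub, int nreps, unsigned int seed,
                         bool use_lw) {
  std::mt19937 rng(seed);
  std::vector<arma::uword> idx(reference.n_rows);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<double> ds;
  ds.reserve(nreps);
  int discarded = 0;
  arma::uvec take(nsub);
  for (int r = 0; r < nreps; ++r) {
    partial_shuffle(rng, idx, nsub);
    for (int i = 0; i < nsub; ++i) take[i] = idx[i];
    arma::mat sub = reference.rows(take);
    arma::rowvec mu = arma::mean(sub, 0);
    double rho = 0.0;
    arma::mat C;
    if (use_lw) {
      C = lw_shrink(sub, rho);
    } else {
      C = arma::cov(sub); // n-1 denominator
    }
    bool ok = false;
    const double d = mahal_from(x, mu, C, ok);
    if (!ok) {
      ++discarded;
      continue;
    }
    ds.push_back(d);
  }
  return Rcpp::List::create(Rcpp::Named("value") = median_of(ds),
                            Rcpp::Named("n_discarded") = discarded);
}
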
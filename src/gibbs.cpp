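// Coordinate-wise Gibbs sampler for the Bernoulli-Laplace spike-and-slab
// source model.  All randomness comes from R's RNG stream via the Rcpp
// RNGScope, with exactly the same call pattern as the pure-R reference
// engine, so both produce bit-identical chains under one seed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One draw from N(mu, sd^2) truncated to (0, Inf).  Mirrors rtnorm_pos() in
// R/utils.R: inverse CDF in the bulk, Robert's shifted-exponential rejection
// when the lower bound is > 6 standard deviations above the mean.
static double rtnorm_pos_cpp(double mu, double sd) {
  double a = -mu / sd;
  if (a < 6.0) {
    double plo = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = unif_rand();
    double z = R::qnorm(plo + u * (1.0 - plo), 0.0, 1.0, 1, 0);
    if (R_finite(z)) return mu + sd * z;
  }
  double lambda = (a + std::sqrt(a * a + 4.0)) / 2.0;
  for (;;) {
    double z = a + exp_rand() / lambda;
    double d = z - lambda;
    if (unif_rand() <= std::exp(-d * d / 2.0)) return mu + sd * z;
  }
}

static double logsumexp3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (!R_finite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// [[Rcpp::export(name = ".gibbs_run_cpp")]]
List gibbs_run_cpp(NumericMatrix H, NumericVector y, NumericVector x0,
                   int n_iter, int burn_in, int thin,
                   double a0, double b0, double sigma2_floor,
                   double omega0, double lam0, double sigma2_0,
                   bool random_scan) {
  const int N = H.nrow(), M = H.ncol();
  RNGScope scope;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> hn2(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += H(i, j) * H(i, j);
    hn2[j] = s;
    if (s <= 0.0) stop("lead field column %d has zero norm", j + 1);
  }
  // residual r = y - H x
  std::vector<double> r(N);
  for (int i = 0; i < N; ++i) {
    double s = y[i];
    for (int j = 0; j < M; ++j) s -= H(i, j) * x[j];
    r[i] = s;
  }

  double sigma2 = std::max(sigma2_0, sigma2_floor);
  double omega = omega0, lam = lam0;

  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it)
    if ((it - burn_in) % thin == 0) ++n_keep;
  NumericMatrix xs(n_keep, M);
  NumericVector s2s(n_keep), oms(n_keep), lams(n_keep);

  std::vector<int> ord(M);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // sweep order
    if (random_scan) {
      std::vector<std::pair<double, int> > key(M);
      for (int j = 0; j < M; ++j) key[j] = std::make_pair(unif_rand(), j);
      std::stable_sort(key.begin(), key.end());
      for (int j = 0; j < M; ++j) ord[j] = key[j].second;
    } else {
      for (int j = 0; j < M; ++j) ord[j] = j;
    }

    for (int jj = 0; jj < M; ++jj) {
      int i = ord[jj];
      double hr = 0.0;
      for (int k = 0; k < N; ++k) hr += H(k, i) * r[k];
      double hv = hr + hn2[i] * x[i];       // h_i . nu_i
      double s2i = sigma2 / hn2[i];
      double si = std::sqrt(s2i);
      double mup = s2i * (hv / sigma2 - 1.0 / lam);
      double mum = s2i * (hv / sigma2 + 1.0 / lam);

      double lu1 = (omega >= 1.0) ? R_NegInf : std::log1p(-omega);
      double lu2, lu3;
      if (omega <= 0.0) {
        lu2 = R_NegInf; lu3 = R_NegInf;
      } else {
        double base = std::log(omega) - std::log(2.0 * lam) +
          0.5 * std::log(2.0 * M_PI * s2i);
        lu2 = base + mup * mup / (2.0 * s2i) +
          R::pnorm(mup / si, 0.0, 1.0, 1, 1);
        lu3 = base + mum * mum / (2.0 * s2i) +
          R::pnorm(-mum / si, 0.0, 1.0, 1, 1);
      }
      double lz = logsumexp3(lu1, lu2, lu3);
      double w1 = std::exp(lu1 - lz), w2 = std::exp(lu2 - lz);
      if (!R_finite(w1) || !R_finite(w2))
        stop("non-finite mixture weights at coordinate %d", i + 1);

      double u = unif_rand();
      double xnew;
      if (u < w1) xnew = 0.0;
      else if (u < w1 + w2) xnew = rtnorm_pos_cpp(mup, si);
      else xnew = -rtnorm_pos_cpp(-mum, si);

      if (xnew != x[i]) {
        double d = x[i] - xnew;
        for (int k = 0; k < N; ++k) r[k] += H(k, i) * d;
        x[i] = xnew;
      }
    }

    // sigma^2 | y, x  ~  InvGamma(N/2, ||y - Hx||^2 / 2)
    double rss = 0.0;
    for (int k = 0; k < N; ++k) rss += r[k] * r[k];
    if (rss / 2.0 <= 0.0) {
      sigma2 = sigma2_floor;
    } else {
      double g = R::rgamma(N / 2.0, 2.0 / rss);  // shape, scale = 1/rate
      sigma2 = std::max(1.0 / g, sigma2_floor);
    }

    // lambda | x  ~  InvGamma(a0 + n1, b0 + sum |x_i|)
    int n1 = 0; double sabs = 0.0;
    for (int j = 0; j < M; ++j)
      if (x[j] != 0.0) { ++n1; sabs += std::fabs(x[j]); }
    double gl = R::rgamma(a0 + n1, 1.0 / (b0 + sabs));
    lam = 1.0 / gl;

    // omega | x  ~  Beta(1 + n1, 1 + M - n1)
    omega = R::rbeta(1.0 + n1, 1.0 + (double)(M - n1));

    for (int j = 0; j < M; ++j)
      if (!R_finite(x[j]))
        stop("Gibbs state diverged (non-finite amplitude) at iteration %d",
             it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < M; ++j) xs(kept, j) = x[j];
      s2s[kept] = sigma2; oms[kept] = omega; lams[kept] = lam;
      ++kept;
    }
  }

  return List::create(_["x"] = xs, _["sigma2"] = s2s,
                      _["omega"] = oms, _["lam"] = lams);
}
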
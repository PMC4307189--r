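#include <Rcpp.h>
using namespace Rcpp;

// Sampler for the Polya-Gamma distribution PG(1, z), used for the
// data-augmented Gibbs updates of the logistic p1-model. Alternating-series
// rejection sampler for the tilted Jacobi distribution J*(1, z/2)
// (Devroye 2009; Polson, Scott & Windle 2013), with PG(1, z) = J*(1, z/2) / 4.
// All randomness comes from R's RNG so draws are reproducible via set.seed().

static const double TRUNC = 0.64;  // series crossover point t

// n-th coefficient of the alternating series bounding the J*(1, z) density,
// in the two regimes around the crossover point.
static double a_coef(int n, double x) {
  const double nph = n + 0.5;
  if (x > TRUNC)
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// CDF of inverse-Gaussian(mean 1/z, shape 1) at x; parameterized by z so the
// z = 0 (infinite-mean) limit is well defined.
static double pigauss(double x, double z) {
  const double rx = 1.0 / std::sqrt(x);
  return R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 0);
}

// Draw from inverse-Gaussian(mean 1/z, shape 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double x;
  if (z < 1.0 / TRUNC) {
    // mean exceeds the truncation point: inverted-chi-square tail proposal
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  // otherwise draw IG by the transformation method and retry until inside
  const double mu = 1.0 / z;
  for (;;) {
    double y = norm_rand();
    y *= y;
    const double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= TRUNC) return x;
  }
}

// One draw of J*(1, z), z >= 0.
static double sample_jstar(double z) {
  const double k = 0.125 * M_PI * M_PI + 0.5 * z * z;
  const double p = (M_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  const double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q))
      x = TRUNC + exp_rand() / k;       // exponential right tail
    else
      x = rtigauss(z);                  // truncated inverse-Gaussian body
    // squeeze acceptance via the alternating partial sums
    double s = a_coef(0, x);
    const double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;               // reject this proposal
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' Vectorized over `z` (the logistic linear predictor of each dyad). Uses R's
//' random number stream.
//'
//' @param z numeric vector of tilting parameters (any sign; PG(1, z) depends
//'   on |z|).
//' @return numeric vector of PG(1, z) draws, same length as `z`.
//' @export
// [[Rcpp::export]]
NumericVector rpg_devroye(NumericVector z) {
  const int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double zi = 0.5 * std::fabs(z[i]);
    out[i] = 0.25 * sample_jstar(zi);
  }
  return out;
}
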
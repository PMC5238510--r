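#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact inference for the state-space learning curve on a discretized
// state grid: latent random walk x_t = x_{t-1} + e_t, e_t ~ N(0, s2e),
// x_0 ~ N(0, prior_var), observed through Bernoulli outcomes with
// p_t = logistic(mu + x_t). Forward-backward gives exact marginals of the
// discretized model; EM re-estimates s2e from E[(x_t - x_{t-1})^2], so
// the (discretized-model) log-likelihood is non-decreasing by
// construction.

namespace {

inline double logistic_(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// banded Gaussian random-walk kernel; column j holds K(. | x_j),
// rows limited to [j - w, j + w], each column normalized
struct Kernel {
  int n, w;
  std::vector<double> k;  // (2w+1) x n, k[(i - j + w) + col*(2w+1)]
  void build(int n_grid, double h, double s2e) {
    n = n_grid;
    double sd = std::sqrt(s2e);
    w = (int)std::ceil(5.0 * sd / h);
    if (w < 1) w = 1;
    if (w > n - 1) w = n - 1;
    k.assign((2 * w + 1) * n, 0.0);
    for (int j = 0; j < n; ++j) {
      double s = 0;
      int lo = std::max(0, j - w), hi = std::min(n - 1, j + w);
      for (int i = lo; i <= hi; ++i) {
        double d = (i - j) * h;
        double v = std::exp(-0.5 * d * d / s2e);
        k[(i - j + w) + j * (2 * w + 1)] = v;
        s += v;
      }
      for (int i = lo; i <= hi; ++i) k[(i - j + w) + j * (2 * w + 1)] /= s;
    }
  }
  // out(i) = sum_j K(i|j) v(j)   (predict step)
  void fwd(const std::vector<double>& v, std::vector<double>& out) const {
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double vj = v[j];
      if (vj == 0) continue;
      int lo = std::max(0, j - w), hi = std::min(n - 1, j + w);
      const double* col = &k[j * (2 * w + 1)];
      for (int i = lo; i <= hi; ++i) out[i] += col[i - j + w] * vj;
    }
  }
  // out(j) = sum_i K(i|j) v(i)   (backward step)
  void bwd(const std::vector<double>& v, std::vector<double>& out) const {
    for (int j = 0; j < n; ++j) {
      int lo = std::max(0, j - w), hi = std::min(n - 1, j + w);
      const double* col = &k[j * (2 * w + 1)];
      double s = 0;
      for (int i = lo; i <= hi; ++i) s += col[i - j + w] * v[i];
      out[j] = s;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_ss_curve(IntegerVector outcomes, double mu, double level,
                  double s2e_init, double prior_var, int max_iter,
                  double tol, double xmin, double xmax, int n_grid) {
  int T = outcomes.size();
  int n = n_grid;
  double h = (xmax - xmin) / (n - 1);
  std::vector<double> x(n), pgrid(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xmin + i * h;
    pgrid[i] = logistic_(mu + x[i]);
  }
  // emission likelihoods per trial
  std::vector<std::vector<double>> em(T, std::vector<double>(n));
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      em[t][i] = outcomes[t] ? pgrid[i] : 1.0 - pgrid[i];
  // boundary prior
  std::vector<double> prior0(n);
  {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      prior0[i] = std::exp(-0.5 * x[i] * x[i] / prior_var);
      s += prior0[i];
    }
    for (int i = 0; i < n; ++i) prior0[i] /= s;
  }

  double s2e = s2e_init;
  std::vector<double> ll_trace;
  bool converged = false;
  Kernel K;
  // alpha[t], t = 0..T (0 = boundary); scaled to sum 1
  std::vector<std::vector<double>> alpha(T + 1, std::vector<double>(n));
  std::vector<std::vector<double>> beta(T + 1, std::vector<double>(n));
  std::vector<double> cnorm(T + 1, 1.0), tmp(n), tmp2(n);

  for (int iter = 0; iter < max_iter; ++iter) {
    K.build(n, h, s2e);
    // forward
    alpha[0] = prior0;
    double ll = 0;
    for (int t = 1; t <= T; ++t) {
      K.fwd(alpha[t - 1], tmp);
      double c = 0;
      for (int i = 0; i < n; ++i) {
        alpha[t][i] = tmp[i] * em[t - 1][i];
        c += alpha[t][i];
      }
      cnorm[t] = c;
      ll += std::log(c);
      for (int i = 0; i < n; ++i) alpha[t][i] /= c;
    }
    ll_trace.push_back(ll);
    // backward (scaled)
    std::fill(beta[T].begin(), beta[T].end(), 1.0);
    for (int t = T; t >= 1; --t) {
      for (int i = 0; i < n; ++i) tmp[i] = em[t - 1][i] * beta[t][i];
      K.bwd(tmp, beta[t - 1]);
      for (int i = 0; i < n; ++i) beta[t - 1][i] /= cnorm[t];
    }
    // M-step: expected squared increments
    double esum = 0;
    for (int t = 1; t <= T; ++t) {
      // xi_t(j, i) = alpha[t-1][j] K(i|j) em[t-1][i] beta[t][i] / cnorm[t]
      double e = 0;
      for (int j = 0; j < n; ++j) {
        double aj = alpha[t - 1][j];
        if (aj == 0) continue;
        int lo = std::max(0, j - K.w), hi = std::min(n - 1, j + K.w);
        const double* col = &K.k[j * (2 * K.w + 1)];
        for (int i = lo; i <= hi; ++i) {
          double xi = aj * col[i - j + K.w] * em[t - 1][i] * beta[t][i] /
                      cnorm[t];
          double d = (i - j) * h;
          e += xi * d * d;
        }
      }
      esum += e;
    }
    double s2e_new = esum / T;
    if (s2e_new < 1e-6) s2e_new = 1e-6;
    int m = ll_trace.size();
    if (m > 1) {
      double rel = std::fabs(ll_trace[m - 1] - ll_trace[m - 2]) /
                   std::max(std::fabs(ll_trace[m - 2]), 1e-12);
      if (rel < tol) { converged = true; s2e = s2e_new; break; }
    }
    s2e = s2e_new;
  }

  // posterior marginals and quantiles of p_t
  NumericVector pmean(T), plower(T), pupper(T);
  double qlo = (1.0 - level) / 2.0, qhi = 1.0 - qlo;
  for (int t = 1; t <= T; ++t) {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      tmp[i] = alpha[t][i] * beta[t][i];
      s += tmp[i];
    }
    for (int i = 0; i < n; ++i) tmp[i] /= s;
    double pm = 0;
    for (int i = 0; i < n; ++i) pm += tmp[i] * pgrid[i];
    pmean[t - 1] = pm;
    // interpolated quantiles of the state, mapped through the link
    double c = 0, xlo_q = x[0], xhi_q = x[n - 1];
    bool got_lo = false, got_hi = false;
    for (int i = 0; i < n; ++i) {
      double cprev = c;
      c += tmp[i];
      if (!got_lo && c >= qlo) {
        double f = (tmp[i] > 0) ? (qlo - cprev) / tmp[i] : 0.0;
        xlo_q = x[i] - h / 2.0 + f * h;
        got_lo = true;
      }
      if (!got_hi && c >= qhi) {
        double f = (tmp[i] > 0) ? (qhi - cprev) / tmp[i] : 0.0;
        xhi_q = x[i] - h / 2.0 + f * h;
        got_hi = true;
      }
    }
    plower[t - 1] = logistic_(mu + xlo_q);
    pupper[t - 1] = logistic_(mu + xhi_q);
  }

  return List::create(
    _["pmode"] = pmean, _["lower"] = plower, _["upper"] = pupper,
    _["sigma2e"] = s2e, _["loglik"] = NumericVector(ll_trace.begin(),
                                                    ll_trace.end()),
    _["converged"] = converged);
}
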
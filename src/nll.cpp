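#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Model ids follow model_names(): 0 FV, 1 FV+Decay, 2 FV+2Eta, 3 BI,
// 4 FW, 5 FW+ChoiceHistory, 6 FW+2Eta, 7 FW+Decay.
// FVC indices (0-based): 0 L, 1 R, 2 up, 3 down, 4 color1, 5 color2.

namespace {

struct Params {
  double eta = 0, eta1 = 0, eta0 = 0, beta = 0, omega = 1, alpha = 0,
         gamma = 1;
};

Params unpack(int model, const NumericVector& p) {
  Params q;
  switch (model) {
    case 0: q.eta = p[0]; q.beta = p[1]; break;
    case 1: q.eta = p[0]; q.beta = p[1]; q.omega = p[2]; break;
    case 2: q.eta1 = p[0]; q.eta0 = p[1]; q.beta = p[2]; break;
    case 3: q.beta = p[0]; break;
    case 4: q.eta = p[0]; q.beta = p[1]; q.alpha = p[2]; break;
    case 5: q.eta = p[0]; q.beta = p[1]; q.alpha = p[2]; q.gamma = p[3]; break;
    case 6: q.eta1 = p[0]; q.eta0 = p[1]; q.beta = p[2]; q.alpha = p[3]; break;
    case 7: q.eta = p[0]; q.beta = p[1]; q.alpha = p[2]; q.omega = p[3]; break;
    default: stop("bad model id");
  }
  return q;
}

struct State {
  double V[6];
  double belief[6];
  int prev_color;  // 4 or 5, -1 before first completed choice
  void reset() {
    for (int i = 0; i < 6; ++i) { V[i] = 0.5; belief[i] = 1.0 / 6.0; }
    prev_color = -1;
  }
};

inline void features(int left_color, int left_motion_up, int* lf, int* rf) {
  lf[0] = 0; rf[0] = 1;
  lf[1] = left_motion_up ? 2 : 3; rf[1] = left_motion_up ? 3 : 2;
  lf[2] = (left_color == 1) ? 4 : 5; rf[2] = (left_color == 1) ? 5 : 4;
}

inline void softmax2(double vl, double vr, double beta, double* p) {
  double zl = beta * vl, zr = beta * vr;
  double m = zl > zr ? zl : zr;
  double el = std::exp(zl - m), er = std::exp(zr - m);
  p[0] = el / (el + er);
  p[1] = er / (el + er);
}

inline void dim_weights(const double* belief, double alpha, double* w) {
  double g0 = belief[0] + belief[1];
  double g1 = belief[2] + belief[3];
  double g2 = belief[4] + belief[5];
  double a0 = std::pow(g0, alpha), a1 = std::pow(g1, alpha),
         a2 = std::pow(g2, alpha);
  double s = a0 + a1 + a2;
  w[0] = a0 / s; w[1] = a1 / s; w[2] = a2 / s;
}

inline void bayes_step(double* belief, const int* chosen, int reward,
                       double p_r) {
  double p_n = 1.0 - p_r;
  double lik_in = reward ? p_r : (1.0 - p_r);
  double lik_out = reward ? p_n : (1.0 - p_n);
  double lik[6];
  for (int i = 0; i < 6; ++i) lik[i] = lik_out;
  for (int j = 0; j < 3; ++j) lik[chosen[j]] = lik_in;
  double s = 0;
  for (int i = 0; i < 6; ++i) { belief[i] *= lik[i]; s += belief[i]; }
  for (int i = 0; i < 6; ++i) belief[i] /= s;
}

// choice probabilities (left, right) under the current state
inline void choice_probs(int model, const Params& q, const State& st,
                         const int* lf, const int* rf, double p_r,
                         double* p) {
  if (model <= 2) {
    double vl = st.V[lf[0]] + st.V[lf[1]] + st.V[lf[2]];
    double vr = st.V[rf[0]] + st.V[rf[1]] + st.V[rf[2]];
    softmax2(vl, vr, q.beta, p);
  } else if (model == 3) {
    double ml = st.belief[lf[0]] + st.belief[lf[1]] + st.belief[lf[2]];
    double p_n = 1.0 - p_r;
    double vl = p_r * ml + p_n * (1.0 - ml);
    double vr = p_r * (1.0 - ml) + p_n * ml;
    softmax2(vl, vr, q.beta, p);
  } else {
    double w[3];
    dim_weights(st.belief, q.alpha, w);
    double vl = w[0] * st.V[lf[0]] + w[1] * st.V[lf[1]] + w[2] * st.V[lf[2]];
    double vr = w[0] * st.V[rf[0]] + w[1] * st.V[rf[1]] + w[2] * st.V[rf[2]];
    softmax2(vl, vr, q.beta, p);
    if (model == 5 && st.prev_color >= 0) {
      int match = (lf[2] == st.prev_color) ? 0 : 1;
      int other = 1 - match;
      double pm = p[match] + (1.0 - q.gamma) * p[other];
      double po = q.gamma * p[other];
      p[match] = pm; p[other] = po;
    }
  }
}

inline void update_state(int model, const Params& q, State& st,
                         const int* lf, const int* rf, int choice,
                         int reward, double p_r) {
  const int* chosen = (choice == 1) ? lf : rf;
  const int* unchosen = (choice == 1) ? rf : lf;
  switch (model) {
    case 0:
    case 1: {
      for (int j = 0; j < 3; ++j) {
        int i = chosen[j];
        st.V[i] += q.eta * (reward - st.V[i]);
      }
      if (model == 1)
        for (int j = 0; j < 3; ++j) st.V[unchosen[j]] /= q.omega;
      break;
    }
    case 2: {
      double eta = reward ? q.eta1 : q.eta0;
      for (int j = 0; j < 3; ++j) {
        int i = chosen[j];
        st.V[i] += eta * (reward - st.V[i]);
      }
      break;
    }
    case 3:
      bayes_step(st.belief, chosen, reward, p_r);
      break;
    default: {
      double w[3];
      dim_weights(st.belief, q.alpha, w);
      double v_stim = w[0] * st.V[chosen[0]] + w[1] * st.V[chosen[1]] +
                      w[2] * st.V[chosen[2]];
      double eta = (model == 6) ? (reward ? q.eta1 : q.eta0) : q.eta;
      double pe = eta * (reward - v_stim);
      for (int j = 0; j < 3; ++j) st.V[chosen[j]] += pe;
      if (model == 7)
        for (int j = 0; j < 3; ++j) st.V[unchosen[j]] /= q.omega;
      bayes_step(st.belief, chosen, reward, p_r);
    }
  }
  st.prev_color = chosen[2];
}

}  // namespace

// [[Rcpp::export]]
double cpp_session_nll(int model, NumericVector params,
                       IntegerVector session, IntegerVector left_color,
                       IntegerVector left_motion, IntegerVector choice,
                       IntegerVector reward, double p_r, double floor) {
  Params q = unpack(model, params);
  int n = session.size();
  State st;
  int cur = -1;
  double nll = 0;
  int lf[3], rf[3];
  double p[2];
  for (int t = 0; t < n; ++t) {
    if (session[t] != cur) { st.reset(); cur = session[t]; }
    if (choice[t] == 0) continue;
    features(left_color[t], left_motion[t], lf, rf);
    choice_probs(model, q, st, lf, rf, p_r, p);
    double pc = p[choice[t] - 1];
    nll -= std::log(pc > floor ? pc : floor);
    update_state(model, q, st, lf, rf, choice[t], reward[t], p_r);
  }
  return nll;
}

// [[Rcpp::export]]
NumericVector cpp_correct_prob(int model, NumericVector params,
                               IntegerVector session,
                               IntegerVector left_color,
                               IntegerVector left_motion,
                               IntegerVector choice, IntegerVector reward,
                               IntegerVector rewarded_color, double p_r) {
  Params q = unpack(model, params);
  int n = session.size();
  State st;
  int cur = -1;
  NumericVector out(n, NA_REAL);
  int lf[3], rf[3];
  double p[2];
  for (int t = 0; t < n; ++t) {
    if (session[t] != cur) { st.reset(); cur = session[t]; }
    if (choice[t] == 0) continue;
    features(left_color[t], left_motion[t], lf, rf);
    choice_probs(model, q, st, lf, rf, p_r, p);
    // probability of choosing the stimulus carrying the rewarded color
    out[t] = (left_color[t] == rewarded_color[t]) ? p[0] : p[1];
    update_state(model, q, st, lf, rf, choice[t], reward[t], p_r);
  }
  return out;
}

static double median_of(std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// Per-column difference of group medians (group 1 minus group 2) for the
// observed labels and for n_perm random label permutations. Rows are
// blocks, columns trial positions; NA cells are ignored. Returns a matrix
// with n_perm + 1 rows: row 0 = observed, rows 1.. = permutations.
// [[Rcpp::export]]
NumericMatrix cpp_perm_median_diff(NumericMatrix curves,
                                   IntegerVector labels, int n_perm,
                                   int seed) {
  int n_blocks = curves.nrow(), n_trials = curves.ncol();
  NumericMatrix out(n_perm + 1, n_trials);
  std::vector<int> lab(labels.begin(), labels.end());
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<double> g1, g2;
  g1.reserve(n_blocks); g2.reserve(n_blocks);
  for (int r = 0; r <= n_perm; ++r) {
    if (r > 0) std::shuffle(lab.begin(), lab.end(), rng);
    for (int j = 0; j < n_trials; ++j) {
      g1.clear(); g2.clear();
      for (int i = 0; i < n_blocks; ++i) {
        double x = curves(i, j);
        if (NumericVector::is_na(x)) continue;
        if (lab[i] == 1) g1.push_back(x); else g2.push_back(x);
      }
      out(r, j) = median_of(g1) - median_of(g2);
    }
  }
  return out;
}
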
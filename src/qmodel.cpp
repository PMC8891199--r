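#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of the four-parameter Q-learning model on one
// session of a two-lever task. Fast path used by the fitter; the R-level
// q_update()/choice_prob() pair defines the model and must agree with this
// to floating-point accuracy (asserted in the test suite).
//
// choice: 0 = left, 1 = right; reward in {0, 1}.
// Choice rule: P(a) = softmax over beta*Q(a) + pi*1[a == last choice],
// stabilised with log-sum-exp. First trial has no stickiness term.
// Update rule: Q'(c) = Q(c) + alpha_eff * (r - Q(c)),
// alpha_eff = alpha_plus if r == 1 else alpha_minus; unchosen value untouched.
// [[Rcpp::export]]
double qnll_cpp(const IntegerVector& choice, const IntegerVector& reward,
                double alpha_plus, double alpha_minus, double pi,
                double beta, double q_init) {
  const int n = choice.size();
  double q[2] = {q_init, q_init};
  int last = -1;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int c = choice[t];
    const int r = reward[t];
    const double x0 = beta * q[0] + (last == 0 ? pi : 0.0);
    const double x1 = beta * q[1] + (last == 1 ? pi : 0.0);
    const double m = x0 > x1 ? x0 : x1;
    const double lse = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
    nll -= (c == 0 ? x0 : x1) - lse;
    const double a = (r == 1) ? alpha_plus : alpha_minus;
    q[c] += a * (static_cast<double>(r) - q[c]);
    last = c;
  }
  return nll;
}
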
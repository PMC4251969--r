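#include <Rcpp.h>
using namespace Rcpp;

// Probabilities this many log-units below the per-epoch maximum are
// treated as exactly zero. They are far below double precision relative
// to the dominant state, and flushing them avoids denormalized-float
// stalls in the recursions.
static const double LOG_FLUSH = 650.0;
static inline double flush_exp(double d) {
  return d < -LOG_FLUSH ? 0.0 : std::exp(d);
}

// Scaled forward recursion. logB is T x m with logB(t,i) = log f_i(x_t).
// Each row of logB is shifted by its maximum before exponentiating; the
// shifts are absorbed into the scaling constants, so the returned
// log-likelihood is exact up to floating point.
//
// Returns NA_real_ if some epoch has zero emission likelihood in every
// state (impossible observation); the offending epoch (1-based) is then
// reported through `bad_t`.
static double forward_scaled(const NumericMatrix& logB,
                             const NumericVector& delta,
                             const NumericMatrix& gamma,
                             NumericMatrix* alpha_out,
                             NumericVector* logc_out,
                             int* bad_t) {
  const int T = logB.nrow(), m = logB.ncol();
  NumericVector a(m), a_new(m);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int i = 0; i < m; ++i) mx = std::max(mx, logB(t, i));
    if (!R_finite(mx)) { *bad_t = t + 1; return NA_REAL; }
    double c = 0.0;
    if (t == 0) {
      for (int i = 0; i < m; ++i) {
        a_new[i] = delta[i] * flush_exp(logB(t, i) - mx);
        c += a_new[i];
      }
    } else {
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) s += a[i] * gamma(i, j);
        a_new[j] = s * flush_exp(logB(t, j) - mx);
        c += a_new[j];
      }
    }
    if (!(c > 0.0) || !R_finite(c)) { *bad_t = t + 1; return NA_REAL; }
    for (int i = 0; i < m; ++i) { a[i] = a_new[i] / c; if (a[i] < 1e-280) a[i] = 0.0; }
    ll += std::log(c) + mx;
    if (alpha_out) for (int i = 0; i < m; ++i) (*alpha_out)(t, i) = a[i];
    if (logc_out) (*logc_out)[t] = std::log(c) + mx;
  }
  return ll;
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
List hmm_forward_cpp(NumericMatrix logB, NumericVector delta,
                     NumericMatrix gamma) {
  int bad_t = 0;
  double ll = forward_scaled(logB, delta, gamma, nullptr, nullptr, &bad_t);
  return List::create(_["loglik"] = ll, _["bad_t"] = bad_t);
}

// Full scaled forward-backward pass: returns log-likelihood, smoothed
// state posteriors u (T x m) and the matrix of expected transition counts
// xi_sum (m x m), i.e. the sufficient statistics of the Baum-Welch E-step.
// [[Rcpp::export(name = ".hmm_estep_cpp")]]
List hmm_estep_cpp(NumericMatrix logB, NumericVector delta,
                   NumericMatrix gamma) {
  const int T = logB.nrow(), m = logB.ncol();
  NumericMatrix alpha(T, m);
  NumericVector logc(T);
  int bad_t = 0;
  double ll = forward_scaled(logB, delta, gamma, &alpha, &logc, &bad_t);
  if (!R_finite(ll))
    return List::create(_["loglik"] = NA_REAL, _["bad_t"] = bad_t);

  NumericMatrix u(T, m), xi(m, m);
  NumericVector b(m, 1.0), b_new(m), emis(m);
  for (int i = 0; i < m; ++i) u(T - 1, i) = alpha(T - 1, i);
  // row maxima of logB reconstructed from logc shifts are not needed:
  // using exp(logB - logc) keeps the same cancellation as the forward pass.
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < m; ++j)
      emis[j] = flush_exp(logB(t + 1, j) - logc[t + 1]);
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) {
        double term = gamma(i, j) * emis[j] * b[j];
        xi(i, j) += alpha(t, i) * term;
        s += term;
      }
      b_new[i] = s;
    }
    double usum = 0.0;
    for (int i = 0; i < m; ++i) { u(t, i) = alpha(t, i) * b_new[i]; usum += u(t, i); }
    // guard against slow drift of the scaled backward variables
    if (usum > 0) for (int i = 0; i < m; ++i) u(t, i) /= usum;
    for (int i = 0; i < m; ++i) b[i] = b_new[i] < 1e-280 ? 0.0 : b_new[i];
  }
  return List::create(_["loglik"] = ll, _["bad_t"] = 0,
                      _["posterior"] = u, _["xi_sum"] = xi);
}

// Viterbi in log space; ties broken toward the lower state index.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logB, NumericVector delta,
                              NumericMatrix gamma) {
  const int T = logB.nrow(), m = logB.ncol();
  NumericMatrix v(T, m);
  IntegerMatrix back(T, m);
  for (int i = 0; i < m; ++i) v(0, i) = std::log(delta[i]) + logB(0, i);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < m; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < m; ++i) {
        double cand = v(t - 1, i) + std::log(gamma(i, j));
        if (cand > best) { best = cand; arg = i; }  // strict > keeps lowest i
      }
      v(t, j) = best + logB(t, j);
      back(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int i = 0; i < m; ++i)
    if (v(T - 1, i) > best) { best = v(T - 1, i); arg = i; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = back(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
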
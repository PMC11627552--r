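#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over the compound promoter-history chain.
//
// L:    S x T emission likelihoods, already rescaled so max(L[,t]) = 1
//       (the per-column log offsets are added back to the loglik in R).
// init: length-S initial distribution over compound states.
// A:    K x K per-frame promoter transition probabilities.
// cur:  length-S, 0-based promoter symbol of each compound state's
//       current (newest) frame.
// succ: S x K, 1-based index of the successor compound state under each
//       new promoter symbol (as built in R).
//
// Returns the scaled loglik (offsets excluded), the compound posteriors
// gamma (S x T) and the expected promoter transition counts xi (K x K).
// [[Rcpp::export]]
List cpp_estep(NumericMatrix L, NumericVector init, NumericMatrix A,
               IntegerVector cur, IntegerMatrix succ) {
  const int S = L.nrow(), T = L.ncol(), K = A.ncol();
  NumericMatrix alpha(S, T), beta(S, T);
  NumericVector cscale(T);

  // forward
  double tot = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha(s, 0) = init[s] * L(s, 0);
    tot += alpha(s, 0);
  }
  if (!(tot > 0)) stop("forward pass underflowed at t = 1");
  cscale[0] = tot;
  for (int s = 0; s < S; ++s) alpha(s, 0) /= tot;

  std::vector<double> work(S);
  for (int t = 1; t < T; ++t) {
    std::fill(work.begin(), work.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      const double a = alpha(s, t - 1);
      if (a == 0.0) continue;
      const int c = cur[s];
      for (int j = 0; j < K; ++j) {
        work[succ(s, j) - 1] += a * A(c, j);
      }
    }
    tot = 0.0;
    for (int s = 0; s < S; ++s) {
      const double v = work[s] * L(s, t);
      alpha(s, t) = v;
      tot += v;
    }
    if (!(tot > 0)) stop("forward pass underflowed at t = %d", t + 1);
    cscale[t] = tot;
    for (int s = 0; s < S; ++s) alpha(s, t) /= tot;
  }

  // backward (Rabiner scaling by the forward constants)
  for (int s = 0; s < S; ++s) beta(s, T - 1) = 1.0;
  NumericMatrix xi(K, K);
  for (int t = T - 2; t >= 0; --t) {
    const double cs = cscale[t + 1];
    for (int s = 0; s < S; ++s) {
      const int c = cur[s];
      double acc = 0.0;
      for (int j = 0; j < K; ++j) {
        const int sp = succ(s, j) - 1;
        const double term = A(c, j) * L(sp, t + 1) * beta(sp, t + 1);
        acc += term;
        xi(c, j) += alpha(s, t) * term / cs;
      }
      beta(s, t) = acc / cs;
    }
  }

  NumericMatrix gamma(S, T);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(s, t) = alpha(s, t) * beta(s, t);
      g += gamma(s, t);
    }
    if (g > 0) for (int s = 0; s < S; ++s) gamma(s, t) /= g;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cscale[t]);

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding over compound states (log domain).
// logL: S x T emission log-likelihoods; loginit: length-S log initial
// distribution; logA: K x K log transition probabilities.
// Returns the 1-based most likely compound-state sequence.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix logL, NumericVector loginit,
                          NumericMatrix logA, IntegerVector cur,
                          IntegerMatrix succ) {
  const int S = logL.nrow(), T = logL.ncol(), K = logA.ncol();
  NumericVector delta(S), delta_new(S);
  IntegerMatrix back(S, T);
  const double NEG = -std::numeric_limits<double>::infinity();

  for (int s = 0; s < S; ++s) delta[s] = loginit[s] + logL(s, 0);
  for (int t = 1; t < T; ++t) {
    std::fill(delta_new.begin(), delta_new.end(), NEG);
    for (int s = 0; s < S; ++s) {
      if (delta[s] == NEG) continue;
      const int c = cur[s];
      for (int j = 0; j < K; ++j) {
        const int sp = succ(s, j) - 1;
        const double v = delta[s] + logA(c, j);
        if (v > delta_new[sp]) {
          delta_new[sp] = v;
          back(sp, t) = s;
        }
      }
    }
    for (int s = 0; s < S; ++s) delta_new[s] += logL(s, t);
    delta = clone(delta_new);
  }

  IntegerVector path(T);
  int best = 0;
  for (int s = 1; s < S; ++s) if (delta[s] > delta[best]) best = s;
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t) {
    best = back(best, t);
    path[t - 1] = best;
  }
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
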